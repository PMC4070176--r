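# Independent oracle implementations used to cross-check package results.
# These deliberately avoid the code paths they validate.

# Pearson correlation from the raw sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Simple linear regression via explicit normal equations.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Analytic magnitude response of an order-n Butterworth low-pass.
butterworth_gain <- function(f, cutoff, order = 5) {
  1 / sqrt(1 + (f / cutoff)^(2 * order))
}

# Fine-step (1 kHz) explicit Euler integration of the release-uptake
# kinetics; independent of simulate_response's 100-Hz loop.
euler_fine_peak <- function(stim, plant, stim_onset = 5, trace_duration = 20,
                            dt = 0.001) {
  rate <- stim$frequency * plant$release_per_pulse *
    recruitment(stim$amplitude, stim$pulse_width, plant) *
    frequency_modulation(stim$frequency, plant)
  n <- round(trace_duration / dt)
  conc <- 0
  peak <- 0
  t <- 0
  for (i in seq_len(n)) {
    on <- t >= stim_onset && t < stim_onset + stim$duration
    conc <- conc + dt * ((if (on) rate else 0) -
      plant$Vmax * conc / (plant$Km + conc))
    if (conc < 0) conc <- 0
    if (conc > peak) peak <- conc
    t <- t + dt
  }
  peak
}
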
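#' Parameters of the synthetic dopaminergic plant
#'
#' The plant is a minimal kinetic model of stimulation-evoked striatal
#' dopamine release measured by fast-scan cyclic voltammetry (FSCV): each
#' stimulus pulse releases a fixed quantum of dopamine scaled by how much of
#' the fiber population the pulse recruits (a logistic function of charge per
#' pulse, amplitude x pulse width) and by a frequency-dependent per-pulse
#' efficacy (release depression above ~100 Hz); clearance follows
#' Michaelis-Menten uptake. It stands in for the anesthetized-rat preparation
#' so the whole modeling/control pipeline can be exercised and tested in
#' silico.
#'
#' Absolute concentration scale is an order-of-magnitude choice: in vivo
#' voltammetry reports currents whose concentration calibration is
#' per-electrode, so only the qualitative dose-response structure (monotone in
#' amplitude and pulse width, unimodal in frequency with a 100 Hz peak)
#' constrains the defaults.
#'
#' @param release_per_pulse Dopamine released per pulse at full recruitment
#'   (uM/pulse).
#' @param Vmax Maximal Michaelis-Menten uptake rate (uM/s).
#' @param Km Michaelis constant of uptake (uM). `Vmax/Km` bounds the fastest
#'   clearance rate; the default keeps decay rates within the biexponential
#'   fitting bounds.
#' @param recruit_mid Charge per pulse (uA*ms) at half-maximal fiber
#'   recruitment.
#' @param recruit_slope Logistic steepness of recruitment (1/(uA*ms)).
#' @param freq_peak Frequency (Hz) at which evoked release is maximal.
#' @param freq_width Width (Hz) of the Gaussian per-pulse depression factor.
#'   The default is set so that the simulated peak-dopamine-versus-frequency
#'   curve attains its maximum at exactly `freq_peak` on the 20-Hz protocol
#'   grid (the grid argmax of `f * exp(-(f-100)^2/(2 w^2))` is 100 Hz for
#'   w < 33.1 Hz).
#' @param noise_sd Standard deviation of additive Gaussian measurement noise
#'   on the 10-Hz concentration trace (uM).
#' @param drift_rate Fractional change of `release_per_pulse` and `Vmax` per
#'   trial, modeling slow nonstationarity; 0 disables drift.
#' @param calib_slope Sensor sensitivity (nA per uM) used when simulating the
#'   voltammetric measurement chain.
#' @return An object of class `plant_params` (a named list).
#' @examples
#' p <- plant_params()
#' recruitment(300, 2, p)
#' @export
plant_params <- function(release_per_pulse = 0.05,
                         Vmax = 2.5,
                         Km = 1.0,
                         recruit_mid = 400,
                         recruit_slope = 0.01,
                         freq_peak = 100,
                         freq_width = 30,
                         noise_sd = 0.01,
                         drift_rate = 0,
                         calib_slope = 3.5) {
  check_number(release_per_pulse, "release_per_pulse", 0, strict_lower = TRUE)
  check_number(Vmax, "Vmax", 0, strict_lower = TRUE)
  check_number(Km, "Km", 0, strict_lower = TRUE)
  check_number(recruit_mid, "recruit_mid", 0, strict_lower = TRUE)
  check_number(recruit_slope, "recruit_slope", 0, strict_lower = TRUE)
  check_number(freq_peak, "freq_peak", 0, strict_lower = TRUE)
  check_number(freq_width, "freq_width", 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  check_number(drift_rate, "drift_rate", -1, strict_lower = TRUE)
  check_number(calib_slope, "calib_slope", 0, strict_lower = TRUE)
  structure(
    list(
      release_per_pulse = release_per_pulse, Vmax = Vmax, Km = Km,
      recruit_mid = recruit_mid, recruit_slope = recruit_slope,
      freq_peak = freq_peak, freq_width = freq_width,
      noise_sd = noise_sd, drift_rate = drift_rate,
      calib_slope = calib_slope
    ),
    class = "plant_params"
  )
}

#' @export
print.plant_params <- function(x, ...) {
  cat("<plant_params>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

# Table 1 parameter ranges; the hard envelope every stimulus must respect.
stim_ranges <- function() {
  list(
    frequency = c(20, 200), amplitude = c(100, 450),
    pulse_width = c(0.1, 2.0), duration = c(0.5, 8)
  )
}

#' Build a stimulation-parameter table
#'
#' One row per stimulus setting. Frequency (Hz), amplitude (uA), pulse width
#' (ms) and train duration (s) are validated against the protocol envelope
#' (20-200 Hz, 100-450 uA, 0.1-2.0 ms, 0.5-8 s).
#'
#' @param frequency Pulse frequency, Hz.
#' @param amplitude Pulse current amplitude, uA.
#' @param pulse_width Pulse width, ms.
#' @param duration Stimulus train duration, s.
#' @param validate Check the protocol envelope (default TRUE).
#' @return A tibble with columns `frequency`, `amplitude`, `pulse_width`,
#'   `duration`.
#' @examples
#' stimulus_tbl(100, 300, 2, 2)
#' @export
stimulus_tbl <- function(frequency, amplitude, pulse_width, duration = 2,
                         validate = TRUE) {
  out <- tibble::tibble(
    frequency = as.numeric(frequency), amplitude = as.numeric(amplitude),
    pulse_width = as.numeric(pulse_width), duration = as.numeric(duration)
  )
  if (validate) validate_stimuli(out)
  out
}

validate_stimuli <- function(stim) {
  r <- stim_ranges()
  for (nm in names(r)) {
    if (!nm %in% names(stim)) abort(sprintf("stimulus lacks column `%s`.", nm))
    v <- stim[[nm]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("stimulus `%s` must be finite and strictly positive.", nm))
    }
    if (any(v < r[[nm]][1]) || any(v > r[[nm]][2])) {
      abort(sprintf(
        "stimulus `%s` outside protocol range [%g, %g].",
        nm, r[[nm]][1], r[[nm]][2]
      ))
    }
  }
  invisible(stim)
}

#' Fraction of dopaminergic fibers recruited by one pulse
#'
#' Logistic function of charge per pulse q = amplitude x pulse width:
#' `1 / (1 + exp(-recruit_slope * (q - recruit_mid)))`. Strictly increasing in
#' amplitude and in pulse width, bounded in (0, 1); this encodes the monotone
#' amplitude and pulse-width dose-response of evoked dopamine.
#'
#' @param amplitude Pulse amplitude, uA (> 0).
#' @param pulse_width Pulse width, ms (> 0).
#' @param plant A [plant_params()] object.
#' @return Recruited fraction in (0, 1); vectorized over the first two
#'   arguments.
#' @export
recruitment <- function(amplitude, pulse_width, plant = plant_params()) {
  if (any(!is.finite(amplitude)) || any(amplitude <= 0)) {
    abort("`amplitude` must be strictly positive.")
  }
  if (any(!is.finite(pulse_width)) || any(pulse_width <= 0)) {
    abort("`pulse_width` must be strictly positive.")
  }
  q <- amplitude * pulse_width
  plogis(plant$recruit_slope * (q - plant$recruit_mid))
}

#' Per-pulse release efficacy as a function of pulse frequency
#'
#' Gaussian depression factor `exp(-(f - freq_peak)^2 / (2 freq_width^2))`,
#' normalized to 1 at `freq_peak`. Multiplied by the pulse rate it yields a
#' release rate that is unimodal in frequency, peaking at `freq_peak`
#' (100 Hz by default) on the protocol frequency grid.
#'
#' @param frequency Pulse frequency, Hz (> 0); vectorized.
#' @inheritParams recruitment
#' @return Nonnegative efficacy multiplier, equal to 1 at `freq_peak`.
#' @export
frequency_modulation <- function(frequency, plant = plant_params()) {
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    abort("`frequency` must be strictly positive.")
  }
  exp(-(frequency - plant$freq_peak)^2 / (2 * plant$freq_width^2))
}

#' Simulate one stimulation-evoked dopamine trace
#'
#' Integrates the release-uptake kinetics
#' \deqn{dC/dt = r(t) - V_{max} C / (K_m + C)}
#' where the release rate r(t) equals
#' `frequency * release_per_pulse * recruitment * frequency_modulation` while
#' the stimulus train is on and 0 otherwise. Integration is fixed-step
#' explicit Euler at 100 Hz (clamped at 0), downsampled to the 10-Hz FSCV
#' scan grid; i.i.d. Gaussian measurement noise is added after downsampling
#' unless `noiseless = TRUE`. Concentration is the stimulation-evoked change
#' above background (background-subtracted FSCV), so C(0) = 0.
#'
#' @param stim One stimulus: a one-row data frame from [stimulus_tbl()] (or a
#'   named list with the same fields).
#' @param plant A [plant_params()] object.
#' @param seed RNG seed for the measurement noise; ignored when
#'   `noiseless = TRUE`.
#' @param noiseless If TRUE the output is deterministic and seed-independent.
#' @param trace_duration Length of the recorded trace, s (>= one 20-s bin).
#' @param stim_onset Stimulus train onset time within the trace, s.
#' @return A `dopamine_trace`: a tibble with columns `time_s` (uniform 10-Hz
#'   grid) and `concentration_uM`, with attributes `stim_onset` and
#'   `stim_offset`.
#' @examples
#' tr <- simulate_response(stimulus_tbl(100, 300, 2, 2), plant_params(),
#'   noiseless = TRUE
#' )
#' max(tr$concentration_uM)
#' @export
simulate_response <- function(stim, plant = plant_params(), seed = NULL,
                              noiseless = FALSE, trace_duration = 20,
                              stim_onset = 5) {
  stim <- as.list(stim)
  stopifnot(
    all(c("frequency", "amplitude", "pulse_width", "duration") %in%
      names(stim))
  )
  validate_stimuli(tibble::as_tibble(stim[c(
    "frequency", "amplitude",
    "pulse_width", "duration"
  )]))
  check_number(trace_duration, "trace_duration", 20, 600)
  check_number(stim_onset, "stim_onset", 0)
  stim_offset <- stim_onset + stim$duration
  if (stim_offset > trace_duration) {
    abort("stimulus train extends beyond the recorded trace.")
  }

  rate <- stim$frequency * plant$release_per_pulse *
    recruitment(stim$amplitude, stim$pulse_width, plant) *
    frequency_modulation(stim$frequency, plant)

  dt <- 0.01 # 100-Hz internal Euler step
  n <- round(trace_duration / dt)
  conc <- numeric(n + 1)
  t_int <- seq(0, by = dt, length.out = n + 1)
  clamped <- FALSE
  c_now <- 0
  for (i in seq_len(n)) {
    on <- t_int[i] >= stim_onset && t_int[i] < stim_offset
    dC <- (if (on) rate else 0) - plant$Vmax * c_now / (plant$Km + c_now)
    c_now <- c_now + dt * dC
    if (c_now < 0) {
      clamped <- TRUE
      c_now <- 0
    }
    conc[i + 1] <- c_now
  }
  if (clamped) {
    warn("Euler step produced a negative concentration; clamped at 0.")
  }

  keep <- seq(1, n + 1, by = 10) # 100 Hz -> 10 Hz scan grid
  out_t <- t_int[keep]
  out_c <- conc[keep]
  if (!noiseless) {
    out_c <- out_c + with_seed(seed, rnorm(length(out_c), 0, plant$noise_sd))
  }
  new_trace(out_t, out_c, stim_onset, stim_offset)
}

new_trace <- function(time_s, concentration_uM, stim_onset, stim_offset) {
  structure(
    tibble::tibble(time_s = time_s, concentration_uM = concentration_uM),
    stim_onset = stim_onset, stim_offset = stim_offset,
    class = c("dopamine_trace", "tbl_df", "tbl", "data.frame")
  )
}

#' @export
print.dopamine_trace <- function(x, ...) {
  cat(sprintf(
    "<dopamine_trace> %d samples @ %.3g Hz, stim [%g, %g] s, peak %.4g uM\n",
    nrow(x), 1 / mean(diff(x$time_s)), attr(x, "stim_onset"),
    attr(x, "stim_offset"), max(x$concentration_uM)
  ))
  NextMethod()
}

#' Peak evoked concentration of a trace
#'
#' Maximum concentration at or after stimulus onset (the evoked transient),
#' the summary used throughout dose-response and closed-loop evaluation.
#'
#' @param trace A `dopamine_trace`.
#' @return Peak concentration, uM.
#' @export
trace_peak <- function(trace) {
  onset <- attr(trace, "stim_onset") %||% 0
  max(trace$concentration_uM[trace$time_s >= onset])
}

#' Apply slow trial-to-trial parameter drift to the plant
#'
#' Scales `release_per_pulse` and `Vmax` by `(1 + drift_rate)^trial_index`,
#' emulating slow nonstationarity of the neurochemical environment (electrode
#' sensitivity, release capacity). With `drift_rate = 0` this is the
#' identity.
#'
#' @param plant A [plant_params()] object.
#' @param trial_index Nonnegative trial counter.
#' @return A drifted copy of `plant`.
#' @export
apply_drift <- function(plant, trial_index) {
  stopifnot(trial_index >= 0)
  f <- (1 + plant$drift_rate)^trial_index
  plant$release_per_pulse <- plant$release_per_pulse * f
  plant$Vmax <- plant$Vmax * f
  plant
}

#' Plot a dopamine trace
#'
#' @param object A `dopamine_trace`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot dopamine_trace
#' @export
autoplot.dopamine_trace <- function(object, ...) {
  onset <- attr(object, "stim_onset")
  offset <- attr(object, "stim_offset")
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$concentration_uM)) +
    ggplot2::annotate("rect",
      xmin = onset, xmax = offset, ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "steelblue"
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (s)", y = expression("Dopamine (" * mu * "M)"),
      title = "Stimulation-evoked dopamine response"
    )
}
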
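#' Synthesize a background-subtracted FSCV voltammogram
#'
#' Generates the current response of a carbon fiber microelectrode to a given
#' dopamine concentration during one triangular scan (-0.4 V to 1.3 V and
#' back at 400 V/s, 8.5 ms total). The background-subtracted template has a
#' Gaussian oxidation peak at +0.6 V on the forward sweep and a mirrored
#' negative reduction peak at the same potential on the return sweep; peak
#' amplitude is `slope * concentration + intercept` from the calibration
#' model.
#'
#' @param concentration Dopamine concentration, uM (>= 0).
#' @param calib A [calibration_model()] (slope nA/uM, intercept nA).
#' @param seed Seed for additive current noise.
#' @param noise_sd Current noise standard deviation, nA (0 = clean template).
#' @param scan_rate Scan rate, V/s.
#' @param v_min,v_max Scan limits, V.
#' @param peak_potential Oxidation peak center, V.
#' @param peak_width Gaussian peak width, V.
#' @param n_points Samples per scan (odd, apex at the midpoint).
#' @return A `voltammogram`: tibble with `potential_V`, `current_nA`,
#'   `sweep` ("forward"/"return"), plus scan attributes.
#' @examples
#' v <- synth_voltammogram(1, calibration_model(3.5, 0))
#' extract_peak_current(v) # ~3.5 nA
#' @export
synth_voltammogram <- function(concentration, calib = calibration_model(),
                               seed = NULL, noise_sd = 0, scan_rate = 400,
                               v_min = -0.4, v_max = 1.3,
                               peak_potential = 0.6, peak_width = 0.1,
                               n_points = 851) {
  if (!is.finite(concentration) || concentration < 0) {
    abort("`concentration` must be >= 0.")
  }
  stopifnot(v_max > v_min, scan_rate > 0, n_points >= 11)
  half <- (n_points + 1) %/% 2
  fwd <- seq(v_min, v_max, length.out = half)
  ret <- seq(v_max, v_min, length.out = n_points - half + 1)[-1]
  pot <- c(fwd, ret)
  sweep <- rep(c("forward", "return"), c(half, n_points - half))
  amp <- calib$slope * concentration + calib$intercept
  cur <- numeric(n_points)
  i_f <- seq_len(half)
  cur[i_f] <- amp * exp(-(pot[i_f] - peak_potential)^2 / (2 * peak_width^2))
  i_r <- (half + 1):n_points
  cur[i_r] <- -amp * exp(-(pot[i_r] - peak_potential)^2 / (2 * peak_width^2))
  if (concentration == 0 && calib$intercept == 0) cur[] <- 0
  if (noise_sd > 0) {
    cur <- cur + with_seed(seed, rnorm(n_points, 0, noise_sd))
  }
  structure(
    tibble::tibble(potential_V = pot, current_nA = cur, sweep = sweep),
    scan_rate = scan_rate, v_min = v_min, v_max = v_max,
    scan_duration = 2 * (v_max - v_min) / scan_rate,
    class = c("voltammogram", "tbl_df", "tbl", "data.frame")
  )
}

#' Extract the dopamine oxidation peak current
#'
#' Maximum forward-sweep current within +/- `window` V of the dopamine
#' oxidation potential (+0.6 V).
#'
#' @param v A `voltammogram`.
#' @param peak_potential Oxidation potential, V.
#' @param window Half-width of the search window, V.
#' @return Peak oxidation current, nA.
#' @export
extract_peak_current <- function(v, peak_potential = 0.6, window = 0.15) {
  stopifnot(all(c("potential_V", "current_nA", "sweep") %in% names(v)))
  sel <- v$sweep == "forward" &
    abs(v$potential_V - peak_potential) <= window
  if (!any(sel)) {
    abort(sprintf(
      "no forward-sweep samples within %.2f V of %.2f V.",
      window, peak_potential
    ))
  }
  max(v$current_nA[sel])
}

#' Flow-injection calibration model of an FSCV electrode
#'
#' Linear map from dopamine concentration to oxidation peak current,
#' `current = slope * concentration + intercept`, as obtained from in vitro
#' flow-injection analysis of the electrode.
#'
#' @param slope Sensitivity, nA per uM (> 0).
#' @param intercept Offset current, nA.
#' @param r_squared Fit quality in `[0, 1]` (1 for a nominal model).
#' @return A `calibration_model` object.
#' @export
calibration_model <- function(slope = 3.5, intercept = 0, r_squared = 1) {
  check_number(slope, "slope", 0, strict_lower = TRUE)
  check_number(intercept, "intercept")
  check_number(r_squared, "r_squared", 0, 1)
  structure(list(slope = slope, intercept = intercept, r_squared = r_squared),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> %.4g nA/uM, intercept %.4g nA, R^2 %.4f\n",
    x$slope, x$intercept, x$r_squared
  ))
  invisible(x)
}

#' Fit a flow-injection calibration line
#'
#' Ordinary least squares of measured oxidation peak currents on known
#' standard concentrations, emulating post-experiment in vitro calibration.
#'
#' @param known_concentrations Standard concentrations, uM (>= 3 distinct
#'   design points).
#' @param measured_peaks Measured peak currents, nA (same length).
#' @return A [calibration_model()] with fitted slope, intercept and R^2.
#' @examples
#' calibrate(c(0, 1, 2), c(0, 3.5, 7))
#' @export
calibrate <- function(known_concentrations, measured_peaks) {
  x <- as.numeric(known_concentrations)
  y <- as.numeric(measured_peaks)
  if (length(x) != length(y)) abort("inputs must have equal length.")
  if (length(x) < 3) abort("calibration needs at least 3 points.")
  if (sd(x) == 0) abort("degenerate design: all concentrations equal.")
  fit <- lm(y ~ x)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  calibration_model(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2
  )
}

#' Convert an oxidation-current trace to a dopamine concentration trace
#'
#' Inverts the calibration line: `concentration = (current - intercept) /
#' slope`, clamped at 0, preserving the 10-Hz sampling grid.
#'
#' @param time_s Sample times, s.
#' @param current_nA Oxidation peak currents, nA.
#' @param calib A [calibration_model()].
#' @param stim_onset,stim_offset Stimulus timing carried onto the trace, s.
#' @return A `dopamine_trace`.
#' @export
current_trace_to_concentration <- function(time_s, current_nA,
                                           calib = calibration_model(),
                                           stim_onset = 0,
                                           stim_offset = max(time_s)) {
  if (calib$slope <= 0) abort("calibration slope must be > 0.")
  conc <- pmax(0, (current_nA - calib$intercept) / calib$slope)
  new_trace(time_s, conc, stim_onset, stim_offset)
}

#' Simulate the FSCV measurement chain for a concentration trace
#'
#' For each 10-Hz sample: synthesize a voltammogram at the true
#' concentration, extract the oxidation peak current, then convert back to
#' concentration with the calibration model. Validates that the measurement
#' model is self-consistent; the plant's default measurement path adds noise
#' directly in concentration units for speed.
#'
#' @param trace A `dopamine_trace` of true concentrations.
#' @param calib A [calibration_model()].
#' @param seed Seed for per-scan current noise.
#' @param noise_sd Current noise per scan, nA.
#' @return A measured `dopamine_trace` on the same grid.
#' @export
fscv_measure <- function(trace, calib = calibration_model(), seed = NULL,
                         noise_sd = 0) {
  peaks <- with_seed(seed, vapply(
    pmax(0, trace$concentration_uM),
    function(conc) {
      extract_peak_current(
        synth_voltammogram(conc, calib, noise_sd = noise_sd)
      )
    },
    numeric(1)
  ))
  current_trace_to_concentration(
    trace$time_s, peaks, calib,
    stim_onset = attr(trace, "stim_onset"),
    stim_offset = attr(trace, "stim_offset")
  )
}

#' Zero-phase Butterworth low-pass filter for raw FSCV current streams
#'
#' Applies a 5th-order Butterworth low-pass (100 Hz cutoff by default)
#' forward and backward (zero phase, unit DC gain) to denoise the raw
#' high-rate current stream before peak extraction. The cutoff must be below
#' the Nyquist frequency of the stream: a 100-Hz cutoff is only meaningful on
#' the raw current samples (kHz and above), never on the 10-Hz concentration
#' trace whose Nyquist frequency is 5 Hz.
#'
#' @param x Raw current samples, nA.
#' @param rate Sampling rate of `x`, Hz.
#' @param order Filter order.
#' @param cutoff Cutoff frequency, Hz.
#' @return Filtered samples, same length as `x`.
#' @export
lowpass_filter <- function(x, rate, order = 5, cutoff = 100) {
  check_number(rate, "rate", 0, strict_lower = TRUE)
  check_number(cutoff, "cutoff", 0, strict_lower = TRUE)
  if (cutoff >= rate / 2) {
    abort(paste0(
      "cutoff (", cutoff, " Hz) is at or above the Nyquist frequency (",
      rate / 2, " Hz); apply the filter to the raw high-rate current ",
      "stream, not a downsampled trace."
    ))
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # odd-reflection padding suppresses the start-up transients of the
  # zero-state forward and backward passes (the padding covers the filter's
  # settling time, ~ order / cutoff seconds)
  n <- length(x)
  npad <- min(ceiling(3 * order * rate / cutoff), n - 1)
  if (npad > 0) {
    front <- 2 * x[1] - x[seq(npad + 1, 2)]
    back <- 2 * x[n] - x[seq(n - 1, n - npad)]
    y <- as.numeric(signal::filtfilt(bf, c(front, x, back)))
    y[(npad + 1):(npad + n)]
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' @method autoplot voltammogram
#' @export
autoplot.voltammogram <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$potential_V, .data$current_nA, colour = .data$sweep)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Applied potential (V)", y = "Current (nA)",
      title = "Background-subtracted voltammogram"
    )
}
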
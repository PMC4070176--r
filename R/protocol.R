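#' The default 65-bin stimulation protocol
#'
#' Enumerates the full parameter sweep used to characterize the
#' stimulus-response relationship: 65 combinations of frequency, amplitude,
#' pulse width and duration, delivered in 20-s bins separated by a 180-s
#' washout. The printed parameter ranges are realized on their natural grids
#' (50 uA, 20 Hz, 0.1 ms steps; durations 0.5,1,2,3,4,5,6,8 s), the unique
#' regular grids totalling 65 bins:
#'
#' * 60 Hz, 100-450 uA (step 50), 2 ms, 2 s — 8 bins
#' * 100 Hz, 100-450 uA (step 50), 2 ms, 2 s — 8 bins
#' * 20-200 Hz (step 20), 250 uA, 2 ms, 2 s — 10 bins
#' * 20-200 Hz (step 20), 350 uA, 2 ms, 2 s — 10 bins
#' * 60 Hz, 300 uA, 2 ms, 2 s — 1 bin
#' * 100 Hz, 300 uA, 0.1-2.0 ms (step 0.1), 2 s — 20 bins
#' * 60 Hz, 300 uA, 2 ms, 0.5-8 s — 8 bins
#'
#' @param bin_duration Recorded bin length, s (default 20).
#' @param washout Inter-bin washout, s (default 180).
#' @return A tibble with one row per bin: `bin_index`, `frequency`,
#'   `amplitude`, `pulse_width`, `duration`, `bin_duration`, `washout`.
#' @examples
#' nrow(default_protocol()) # 65
#' @export
default_protocol <- function(bin_duration = 20, washout = 180) {
  check_number(bin_duration, "bin_duration", 20)
  check_number(washout, "washout", 0)
  amps <- seq(100, 450, by = 50)
  freqs <- seq(20, 200, by = 20)
  rows <- dplyr::bind_rows(
    tibble::tibble(frequency = 60, amplitude = amps, pulse_width = 2, duration = 2),
    tibble::tibble(frequency = 100, amplitude = amps, pulse_width = 2, duration = 2),
    tibble::tibble(frequency = freqs, amplitude = 250, pulse_width = 2, duration = 2),
    tibble::tibble(frequency = freqs, amplitude = 350, pulse_width = 2, duration = 2),
    tibble::tibble(frequency = 60, amplitude = 300, pulse_width = 2, duration = 2),
    tibble::tibble(frequency = 100, amplitude = 300, pulse_width = seq(0.1, 2.0, by = 0.1), duration = 2),
    tibble::tibble(frequency = 60, amplitude = 300, pulse_width = 2, duration = c(0.5, 1, 2, 3, 4, 5, 6, 8))
  )
  rows$pulse_width <- round(rows$pulse_width, 6)
  out <- dplyr::mutate(rows,
    bin_index = dplyr::row_number(),
    bin_duration = bin_duration, washout = washout,
    .before = 1
  )
  stopifnot(all(out$duration <= out$bin_duration))
  validate_stimuli(out)
  out
}

#' Run a stimulation protocol on the synthetic plant
#'
#' Simulates one dopamine trace per protocol bin. Each bin gets its own child
#' seed derived deterministically from `(seed, bin_index)`, so the full
#' dataset is reproducible from one master seed. The 180-s washout is modeled
#' as a full reset of concentration to baseline between bins (the washout far
#' exceeds the plant's clearance time constants). With `drift_rate > 0` in
#' the plant, bin k is simulated with [apply_drift()] at trial index k - 1.
#'
#' @param protocol A protocol tibble, e.g. [default_protocol()]; any data
#'   frame with `frequency`, `amplitude`, `pulse_width`, `duration` columns
#'   (a `bin_index` column is added if absent).
#' @param plant A [plant_params()] object.
#' @param seed Master seed for measurement noise.
#' @param noiseless Simulate without measurement noise.
#' @param stim_onset Stimulus onset within each bin, s.
#' @return The protocol tibble with a list-column `trace` of
#'   `dopamine_trace` objects and a `seed` column of per-bin child seeds.
#' @examples
#' ds <- default_protocol() |> run_protocol(plant_params(), seed = 1)
#' ds$trace[[1]]
#' @export
run_protocol <- function(protocol, plant = plant_params(), seed = 1,
                         noiseless = FALSE, stim_onset = 5) {
  if (nrow(protocol) == 0) abort("empty protocol.")
  if (!"bin_index" %in% names(protocol)) {
    protocol$bin_index <- seq_len(nrow(protocol))
  }
  if (anyDuplicated(protocol$bin_index)) abort("duplicate bin_index values.")
  bin_dur <- if ("bin_duration" %in% names(protocol)) {
    protocol$bin_duration
  } else {
    rep(20, nrow(protocol))
  }
  out <- protocol
  out$seed <- vapply(
    protocol$bin_index,
    function(i) derive_seed(seed, i), integer(1)
  )
  out$trace <- purrr::pmap(
    list(
      protocol$frequency, protocol$amplitude, protocol$pulse_width,
      protocol$duration, protocol$bin_index, out$seed, bin_dur
    ),
    function(f, a, pw, d, k, s, bd) {
      p_k <- apply_drift(plant, k - 1)
      tryCatch(
        simulate_response(
          list(frequency = f, amplitude = a, pulse_width = pw, duration = d),
          p_k,
          seed = s, noiseless = noiseless,
          trace_duration = bd, stim_onset = stim_onset
        ),
        error = function(e) {
          abort(sprintf("simulation failed at bin %d: %s", k, conditionMessage(e)))
        }
      )
    }
  )
  out
}
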
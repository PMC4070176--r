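# Plain-text persistence: plant/protocol configs and model weights as JSON,
# trace datasets as per-trial CSVs with JSON sidecars and a manifest.

# djb2 rolling hash over a canonical JSON rendering; used for manifest
# integrity checks, not cryptography. Trace hashes round to 10 significant
# digits so they survive the CSV round trip.
text_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Write / read plant parameters as JSON
#'
#' @param plant A [plant_params()] object.
#' @param path File path.
#' @return `read_plant_config()` returns a `plant_params` object;
#'   `write_plant_config()` returns `path` invisibly.
#' @export
write_plant_config <- function(plant, path) {
  jsonlite::write_json(unclass(plant), path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_plant_config
#' @export
read_plant_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(plant_params, lapply(x, as.numeric))
}

#' Write / read a protocol table as JSON
#'
#' @param protocol A protocol tibble (see [default_protocol()]).
#' @param path File path.
#' @return `read_protocol_config()` returns the protocol tibble.
#' @export
write_protocol_config <- function(protocol, path) {
  jsonlite::write_json(protocol, path,
    auto_unbox = FALSE, digits = NA,
    pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_protocol_config
#' @export
read_protocol_config <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  validate_stimuli(out)
  out
}

trace_hash <- function(tr) {
  text_hash(list(signif(tr$time_s, 10), signif(tr$concentration_uM, 10)))
}

#' Write a simulated trace dataset to a directory
#'
#' One CSV per trial (`time_s`, `concentration_uM`) plus a JSON sidecar
#' (stimulus, seed, stimulus timing, plant hash) and a `manifest.json`
#' listing all trials with their trace hashes.
#'
#' @param dataset Output of [run_protocol()].
#' @param dir Output directory (created if needed).
#' @param plant The plant used (hashed into sidecars).
#' @return `dir`, invisibly.
#' @export
write_trace_dataset <- function(dataset, dir, plant = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plant_hash <- if (!is.null(plant)) text_hash(unclass(plant)) else NA
  trials <- purrr::map(seq_len(nrow(dataset)), function(i) {
    tr <- dataset$trace[[i]]
    stem <- sprintf("trial_%03d", dataset$bin_index[i])
    utils::write.csv(as.data.frame(tr), file.path(dir, paste0(stem, ".csv")),
      row.names = FALSE
    )
    side <- list(
      bin_index = dataset$bin_index[i],
      stimulus = as.list(dataset[i, c(
        "frequency", "amplitude",
        "pulse_width", "duration"
      )]),
      seed = if ("seed" %in% names(dataset)) dataset$seed[i] else NA,
      stim_onset = attr(tr, "stim_onset"),
      stim_offset = attr(tr, "stim_offset"),
      plant_hash = plant_hash
    )
    jsonlite::write_json(side, file.path(dir, paste0(stem, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    list(
      stem = stem, bin_index = dataset$bin_index[i],
      trace_hash = trace_hash(tr)
    )
  })
  jsonlite::write_json(list(n_trials = length(trials), trials = trials),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a trace dataset written by [write_trace_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return A tibble with stimulus columns, `seed` and a `trace` list-column.
#' @export
read_trace_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = FALSE
  )
  rows <- purrr::map(man$trials, function(tr) {
    side <- jsonlite::read_json(file.path(dir, paste0(tr$stem, ".json")),
      simplifyVector = TRUE
    )
    df <- utils::read.csv(file.path(dir, paste0(tr$stem, ".csv")))
    trace <- new_trace(
      df$time_s, df$concentration_uM, side$stim_onset,
      side$stim_offset
    )
    got <- trace_hash(trace)
    if (!identical(got, tr$trace_hash)) {
      warn(sprintf("trace hash mismatch for %s (file edited?).", tr$stem))
    }
    tibble::tibble(
      bin_index = side$bin_index,
      frequency = side$stimulus$frequency,
      amplitude = side$stimulus$amplitude,
      pulse_width = side$stimulus$pulse_width,
      duration = side$stimulus$duration,
      seed = side$seed,
      trace = list(trace)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$bin_index)
}

#' Write / read a fitted feedforward model as JSON
#'
#' Serializes weights, scalers and layer names; `read_mlp()` restores a
#' `neuroloop_mlp` usable with [predict.neuroloop_mlp()].
#'
#' @param object A `neuroloop_mlp` or `mlp_fit` (the selected model is
#'   written).
#' @param path File path.
#' @return `read_mlp()` returns a `neuroloop_mlp`.
#' @export
write_mlp <- function(object, path) {
  model <- if (inherits(object, "mlp_fit")) object$model else object
  payload <- list(
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    input_scaler = model$input_scaler, output_scaler = model$output_scaler,
    input_names = model$input_names, output_names = model$output_names,
    n_hidden = model$n_hidden
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$W1 <- matrix(x$W1, x$n_hidden, length(x$input_names))
  x$W2 <- matrix(x$W2, length(x$output_names), x$n_hidden)
  x$input_scaler <- lapply(x$input_scaler, as.numeric)
  x$output_scaler <- lapply(x$output_scaler, as.numeric)
  structure(x, class = "neuroloop_mlp")
}
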
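# Shared fixtures, built once per suite run. The 65-bin noiseless protocol
# dataset and its response fits are reused by several test files; building
# them here keeps individual tests fast without caching anything on disk.

fixture_env <- new.env(parent = emptyenv())

default_plant <- function() plant_params()

protocol_dataset <- function() {
  if (is.null(fixture_env$dataset)) {
    fixture_env$dataset <- run_protocol(default_protocol(), default_plant(),
      seed = 101, noiseless = TRUE
    )
  }
  fixture_env$dataset
}

protocol_fits <- function() {
  if (is.null(fixture_env$fits)) {
    fixture_env$fits <- fit_responses(protocol_dataset())
  }
  fixture_env$fits
}

# small trained models on the protocol fits, shared across controller tests
forward_fit_small <- function() {
  if (is.null(fixture_env$fwd)) {
    fixture_env$fwd <- suppressWarnings(train_forward(
      protocol_fits(),
      train_config(n_hidden = 12, n_restarts = 4, max_iter = 60, seed = 11)
    ))
  }
  fixture_env$fwd
}

inverse_fit_small <- function() {
  if (is.null(fixture_env$inv)) {
    fixture_env$inv <- suppressWarnings(train_inverse(
      protocol_fits(),
      train_config(n_hidden = 12, n_restarts = 4, max_iter = 60, seed = 12)
    ))
  }
  fixture_env$inv
}

coef_cols <- c(paste0("poly_c", 0:7), "exp_a1", "exp_b1", "exp_a2", "exp_b2")
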
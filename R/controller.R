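# Closed-loop controller: inverse-model stimulus prediction, optional
# energy-constrained optimization, and the loop runner on the synthetic
# plant.

#' Predict stimulation parameters for target response coefficients
#'
#' Runs the inverse network on each target's 12 response coefficients and
#' clips the predicted (frequency, amplitude, pulse width) to the protocol
#' bounds; clipping is flagged per row. Train duration is fixed, not
#' predicted.
#'
#' @param inverse An inverse `mlp_fit` (or bare `neuroloop_mlp`).
#' @param targets Data frame with the 12 coefficient columns, one row per
#'   target.
#' @param bounds Named list of `c(min, max)` for `frequency`, `amplitude`,
#'   `pulse_width` (default: protocol envelope).
#' @param duration Fixed train duration, s.
#' @return Tibble with `frequency`, `amplitude`, `pulse_width`, `duration`
#'   and a logical `clipped` column.
#' @export
predict_stimulus <- function(inverse, targets, bounds = stim_ranges(),
                             duration = 2) {
  pred <- predict(inverse, targets)
  if (any(!is.finite(as.matrix(pred)))) {
    abort("inverse model produced non-finite stimulation parameters.")
  }
  clipped <- rep(FALSE, nrow(pred))
  for (nm in stimulus_input_names()) {
    lo <- bounds[[nm]][1]
    hi <- bounds[[nm]][2]
    clipped <- clipped | pred[[nm]] < lo | pred[[nm]] > hi
    pred[[nm]] <- pmin(pmax(pred[[nm]], lo), hi)
  }
  pred$duration <- duration
  pred$clipped <- clipped
  pred
}

#' Stimulation energy proxy
#'
#' `amplitude^2 * pulse_width * frequency`, proportional to delivered power
#' for constant-current pulses into a fixed impedance (duration is fixed by
#' the protocol and drops out).
#'
#' @param stim Data frame with `frequency`, `amplitude`, `pulse_width`.
#' @return Energy proxy per row (uA^2 * ms * Hz).
#' @export
stimulus_energy <- function(stim) {
  stim$amplitude^2 * stim$pulse_width * stim$frequency
}

#' Minimum-energy stimulus matching a target response
#'
#' Resolves the redundancy of the stimulus-response map by constrained
#' optimization: minimize the energy proxy `amplitude^2 * pulse_width *
#' frequency` subject to the forward model reproducing the target
#' coefficients within `tolerance` (RMS on scaled outputs) and the stimulus
#' staying inside the protocol bounds. A dense lattice over the normalized
#' stimulus cube is screened in one batched forward pass, and the most
#' promising candidates are refined by penalized L-BFGS-B local search
#' (grid-seeded multistart, so nonconvexity is handled); among all
#' candidates evaluated, the feasible one of least energy is returned, or
#' the minimum-residual candidate flagged infeasible if none meets the
#' tolerance.
#'
#' @param forward A forward `mlp_fit`/`neuroloop_mlp`, or a function taking
#'   a one-row stimulus tibble and returning a numeric coefficient vector
#'   (used with a plain numeric `target`).
#' @param target One-row data frame of the 12 coefficient columns, or a
#'   numeric vector when `forward` is a function.
#' @param bounds Named list of `c(min, max)` per stimulus parameter.
#' @param tolerance Feasibility threshold on the scaled RMS residual. The
#'   default matches the forward model's typical validation accuracy;
#'   looser values let the optimizer undershoot targets to save energy.
#' @param duration Fixed train duration, s.
#' @param n_grid Lattice points per dimension for the batched pre-screen.
#' @param n_polish Number of lattice candidates refined by local search.
#' @param extra_starts Optional data frame of additional start stimuli (e.g.
#'   an inverse-model prediction).
#' @return One-row tibble: stimulus, `energy`, `residual`, `feasible`.
#' @export
optimize_stimulus <- function(forward, target, bounds = stim_ranges(),
                              tolerance = 0.02, duration = 2, n_grid = 9,
                              n_polish = 3, extra_starts = NULL) {
  nms <- stimulus_input_names()
  lo <- vapply(nms, function(nm) bounds[[nm]][1], numeric(1))
  hi <- vapply(nms, function(nm) bounds[[nm]][2], numeric(1))

  if (is.function(forward)) {
    tvec <- as.numeric(target)
    resid_fn <- function(stim) {
      vapply(seq_len(nrow(stim)), function(i) {
        sqrt(mean((as.numeric(forward(stim[i, , drop = FALSE])) - tvec)^2))
      }, numeric(1))
    }
  } else {
    model <- if (inherits(forward, "mlp_fit")) forward$model else forward
    tmat <- as.matrix(as.data.frame(target)[, model$output_names,
      drop = FALSE
    ])
    ts <- drop(scale_to_unit(tmat, model$output_scaler))
    resid_fn <- function(stim) {
      ps <- scale_to_unit(
        as.matrix(stim[, model$input_names, drop = FALSE]),
        model$input_scaler
      )
      Y <- mlp_eval_scaled(model, ps)$Y
      sqrt(rowMeans((Y - matrix(ts, nrow(Y), length(ts), byrow = TRUE))^2))
    }
  }

  e_max <- hi[2]^2 * hi[3] * hi[1] # energy at the upper corner
  to_stim <- function(Z) {
    Z <- pmin(pmax(Z, 0), 1)
    S <- sweep(sweep(Z, 2, hi - lo, `*`), 2, lo, `+`)
    tibble::tibble(
      frequency = S[, 1], amplitude = S[, 2], pulse_width = S[, 3],
      duration = duration
    )
  }

  # batched lattice pre-screen over the stimulus cube
  g <- seq(0, 1, length.out = n_grid)
  Z <- as.matrix(expand.grid(g, g, g))
  if (!is.null(extra_starts)) {
    zs <- t(vapply(
      seq_len(nrow(extra_starts)),
      function(i) {
        (as.numeric(extra_starts[i, nms]) - lo) / (hi - lo)
      },
      numeric(3)
    ))
    Z <- rbind(Z, pmin(pmax(zs, 0), 1))
  }
  stim_all <- to_stim(Z)
  ev <- tibble::tibble(
    stim_all,
    energy = stimulus_energy(stim_all),
    residual = resid_fn(stim_all)
  )

  # local polish from the most promising lattice candidates: the
  # least-energy feasible point, the least-residual point, and the best
  # supplied starts
  penalized <- function(z) {
    stim <- to_stim(matrix(z, 1))
    stimulus_energy(stim) / e_max +
      1e4 * max(0, resid_fn(stim) - tolerance)^2
  }
  feas0 <- ev$residual <= tolerance
  picks <- unique(c(
    if (any(feas0)) which(feas0)[which.min(ev$energy[feas0])],
    which.min(ev$residual),
    if (!is.null(extra_starts)) nrow(Z) - seq_len(nrow(extra_starts)) + 1
  ))
  picks <- utils::head(picks, n_polish)
  polished <- purrr::map(picks, function(i) {
    opt <- tryCatch(
      optim(Z[i, ], penalized,
        method = "L-BFGS-B", lower = 0, upper = 1,
        control = list(maxit = 60)
      ),
      error = function(e) NULL
    )
    if (is.null(opt)) {
      return(NULL)
    }
    stim <- to_stim(matrix(opt$par, 1))
    tibble::tibble(stim,
      energy = stimulus_energy(stim), residual = resid_fn(stim)
    )
  })
  ev <- dplyr::bind_rows(ev, purrr::compact(polished))

  feas <- ev$residual <= tolerance
  best <- if (any(feas)) {
    which(feas)[which.min(ev$energy[feas])]
  } else {
    which.min(ev$residual)
  }
  out <- ev[best, ]
  out$feasible <- any(feas)
  out
}

#' Run the closed loop on the synthetic plant
#'
#' For each target response: predict the stimulus with the inverse model (or
#' the energy-constrained optimizer on the forward model), apply it to the
#' plant, and score the achieved dopamine trace against the trace
#' reconstructed from the target coefficients. Plant drift, when enabled, is
#' applied per trial; all randomness derives from the master seed.
#'
#' @param targets Tibble of target responses: the 12 coefficient columns
#'   plus `t_peak` and `stim_onset` (the layout of [fit_responses()] /
#'   [sample_targets()]).
#' @param plant A [plant_params()] object.
#' @param inverse An inverse `mlp_fit` (required unless `use_optimizer`).
#' @param forward A forward `mlp_fit` (required when `use_optimizer = TRUE`).
#' @param use_optimizer Resolve each target by [optimize_stimulus()] instead
#'   of the inverse network.
#' @param seed Master seed; per-target child seeds drive measurement noise.
#' @param noiseless Run the plant without measurement noise.
#' @param duration Fixed train duration, s.
#' @param tolerance Feasibility tolerance for the optimizer path.
#' @return A `closed_loop_result` tibble: one row per target with the
#'   predicted stimulus, `target_peak`, `achieved_peak`, `rms_error`,
#'   bookkeeping columns (`seed`, `drift_index`, `clipped`/`feasible`,
#'   `error`) and list-columns `achieved_trace`, `target_trace`.
#' @export
run_closed_loop <- function(targets, plant = plant_params(), inverse = NULL,
                            forward = NULL, use_optimizer = FALSE, seed = 1,
                            noiseless = FALSE, duration = 2,
                            tolerance = 0.02) {
  if (use_optimizer && is.null(forward)) {
    abort("`forward` model required when use_optimizer = TRUE.")
  }
  if (!use_optimizer && is.null(inverse)) {
    abort("`inverse` model required when use_optimizer = FALSE.")
  }
  n <- nrow(targets)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    row <- targets[i, , drop = FALSE]
    res <- tryCatch(
      {
        if (use_optimizer) {
          extra <- if (!is.null(inverse)) {
            predict_stimulus(inverse, row, duration = duration)
          }
          stim <- optimize_stimulus(forward, row,
            tolerance = tolerance,
            duration = duration, extra_starts = extra
          )
          stim$clipped <- FALSE
        } else {
          stim <- predict_stimulus(inverse, row, duration = duration)
          stim$energy <- stimulus_energy(stim)
          stim$residual <- NA_real_
          stim$feasible <- NA
        }
        p_i <- apply_drift(plant, i - 1)
        achieved <- simulate_response(
          stim[, c("frequency", "amplitude", "pulse_width", "duration")],
          p_i,
          seed = derive_seed(seed, i), noiseless = noiseless
        )
        target_trace <- reconstruct_response(row, achieved$time_s)
        tibble::tibble(
          target_id = i,
          frequency = stim$frequency, amplitude = stim$amplitude,
          pulse_width = stim$pulse_width, duration = stim$duration,
          clipped = stim$clipped, feasible = stim$feasible,
          energy = stim$energy,
          target_peak = trace_peak(target_trace),
          achieved_peak = trace_peak(achieved),
          rms_error = rms_error(achieved, target_trace),
          seed = derive_seed(seed, i), drift_index = i - 1,
          error = NA_character_,
          achieved_trace = list(achieved), target_trace = list(target_trace)
        )
      },
      error = function(e) {
        tibble::tibble(
          target_id = i, frequency = NA_real_, amplitude = NA_real_,
          pulse_width = NA_real_, duration = duration, clipped = NA,
          feasible = NA, energy = NA_real_, target_peak = NA_real_,
          achieved_peak = NA_real_, rms_error = NA_real_,
          seed = derive_seed(seed, i), drift_index = i - 1,
          error = conditionMessage(e),
          achieved_trace = list(NULL), target_trace = list(NULL)
        )
      }
    )
    out[[i]] <- res
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("closed_loop_result", class(res))
  res
}

#' Sample held-out target responses from the plant
#'
#' Draws stimuli uniformly within the protocol bounds (fixed duration),
#' simulates each noiselessly, and fits the 12-coefficient response model;
#' the resulting coefficient rows serve as closed-loop targets with known
#' generating stimuli (columns `true_frequency`, `true_amplitude`,
#' `true_pulse_width`).
#'
#' @param n Number of targets.
#' @param plant A [plant_params()] object.
#' @param seed RNG seed for the stimulus draw.
#' @param duration Fixed train duration, s.
#' @return Tibble of targets in [fit_responses()] layout.
#' @export
sample_targets <- function(n, plant = plant_params(), seed = 1,
                           duration = 2) {
  r <- stim_ranges()
  stim <- with_seed(seed, tibble::tibble(
    frequency = stats::runif(n, r$frequency[1], r$frequency[2]),
    amplitude = stats::runif(n, r$amplitude[1], r$amplitude[2]),
    pulse_width = stats::runif(n, r$pulse_width[1], r$pulse_width[2]),
    duration = duration
  ))
  ds <- run_protocol(stim, plant, seed = seed, noiseless = TRUE)
  fits <- fit_responses(ds)
  dplyr::rename(fits,
    true_frequency = "frequency", true_amplitude = "amplitude",
    true_pulse_width = "pulse_width"
  )
}
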
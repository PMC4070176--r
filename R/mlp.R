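# Two-layer feedforward network (tanh hidden layer, linear output layer)
# trained by full-batch Levenberg-Marquardt on the complete weight vector,
# with per-dimension affine scaling of inputs and outputs to [-1, 1].

#' Training configuration for the feedforward models
#'
#' @param n_hidden Hidden-layer width. The documented defaults are 150 for
#'   the forward (stimulus-to-response) model and 600 for the inverse
#'   (response-to-stimulus) model; with a 65-sample protocol dataset those
#'   widths are heavily overparameterized, and a warning is emitted when the
#'   weight count exceeds the number of training residuals. Tests and the
#'   shipped examples use 10-30 hidden units.
#' @param n_restarts Number of random weight initializations; the restart
#'   with the lowest validation (generalization) error is selected.
#' @param train_fraction Fraction of the dataset used for training; the
#'   remainder is the validation split.
#' @param lambda0,lm_up,lm_down Levenberg-Marquardt damping schedule.
#' @param max_iter Maximum LM iterations per restart.
#' @param tol LM convergence tolerance.
#' @param patience Validation-based early stopping: a restart's training
#'   stops once its validation error has not improved for this many
#'   accepted LM iterations, and the weights from the best validation
#'   point are kept (the standard guard against overfitting when weights
#'   are plentiful relative to samples). `Inf` disables it.
#' @param seed Master seed; restart initializations and the train/validation
#'   split derive child seeds from it.
#' @return A `train_config` list.
#' @export
train_config <- function(n_hidden = 150, n_restarts = 10,
                         train_fraction = 0.8, lambda0 = 1e-3, lm_up = 10,
                         lm_down = 10, max_iter = 150, tol = 1e-9,
                         patience = 8, seed = 1) {
  stopifnot(
    n_hidden >= 1, n_restarts >= 1,
    train_fraction > 0, train_fraction < 1, lm_up > 1, lm_down > 1
  )
  structure(
    list(
      n_hidden = as.integer(n_hidden), n_restarts = as.integer(n_restarts),
      train_fraction = train_fraction, lambda0 = lambda0, lm_up = lm_up,
      lm_down = lm_down, max_iter = as.integer(max_iter), tol = tol,
      patience = patience, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

# ---- scalers ----------------------------------------------------------------

make_scaler <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  span <- hi - lo
  span[span == 0] <- 1 # constant column maps to 0
  list(lo = lo, span = span)
}

scale_to_unit <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$lo, `-`), 2, scaler$span / 2, `/`) - 1
}

unscale_from_unit <- function(Xs, scaler) {
  sweep(sweep(Xs + 1, 2, scaler$span / 2, `*`), 2, scaler$lo, `+`)
}

# ---- weight packing ---------------------------------------------------------

mlp_dims <- function(n_in, n_hidden, n_out) {
  c(
    W1 = n_hidden * n_in, b1 = n_hidden,
    W2 = n_out * n_hidden, b2 = n_out
  )
}

unpack_weights <- function(theta, n_in, n_hidden, n_out) {
  d <- mlp_dims(n_in, n_hidden, n_out)
  stopifnot(length(theta) == sum(d))
  i <- 0
  W1 <- matrix(theta[i + seq_len(d[1])], n_hidden, n_in)
  i <- i + d[1]
  b1 <- theta[i + seq_len(d[2])]
  i <- i + d[2]
  W2 <- matrix(theta[i + seq_len(d[3])], n_out, n_hidden)
  i <- i + d[3]
  b2 <- theta[i + seq_len(d[4])]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

pack_weights <- function(w) c(w$W1, w$b1, w$W2, w$b2)

# Nguyen-Widrow initialization: hidden-unit weight vectors are drawn as
# random directions scaled to a common magnitude and the biases staggered
# so the units' active (non-saturated) regions tile the [-1, 1] input cube.
init_weights <- function(n_in, n_hidden, n_out, seed) {
  with_seed(seed, {
    beta <- 0.7 * n_hidden^(1 / n_in)
    W1 <- matrix(stats::runif(n_hidden * n_in, -1, 1), n_hidden, n_in)
    norms <- sqrt(rowSums(W1^2))
    W1 <- W1 * (beta / pmax(norms, 1e-12))
    b1 <- beta * seq(-1, 1, length.out = n_hidden) *
      sign(stats::runif(n_hidden, -1, 1))
    list(
      W1 = W1,
      b1 = b1,
      W2 = matrix(
        stats::runif(n_out * n_hidden, -1, 1) / sqrt(n_hidden),
        n_out, n_hidden
      ),
      b2 = rep(0, n_out)
    )
  })
}

# forward pass on scaled inputs: rows are samples
mlp_eval_scaled <- function(w, Xs) {
  H <- tanh(Xs %*% t(w$W1) + matrix(w$b1, nrow(Xs), length(w$b1),
    byrow = TRUE
  ))
  Y <- H %*% t(w$W2) + matrix(w$b2, nrow(Xs), length(w$b2), byrow = TRUE)
  list(H = H, Y = Y)
}

# Jacobian of the stacked residual vector vec(Y - T) (column-major over
# outputs) with respect to the packed weight vector.
mlp_jacobian <- function(w, Xs, H) {
  n <- nrow(Xs)
  n_in <- ncol(Xs)
  n_hidden <- length(w$b1)
  n_out <- length(w$b2)
  d <- mlp_dims(n_in, n_hidden, n_out)
  P <- sum(d)
  J <- matrix(0, n * n_out, P)
  Hp <- 1 - H^2 # tanh'
  o_W1 <- 0
  o_b1 <- d[1]
  o_W2 <- d[1] + d[2]
  o_b2 <- d[1] + d[2] + d[3]
  for (k in seq_len(n_out)) {
    rows <- (k - 1) * n + seq_len(n)
    Dk <- Hp * matrix(w$W2[k, ], n, n_hidden, byrow = TRUE)
    for (i in seq_len(n_in)) {
      cols <- o_W1 + (i - 1) * n_hidden + seq_len(n_hidden)
      J[rows, cols] <- Dk * Xs[, i]
    }
    J[rows, o_b1 + seq_len(n_hidden)] <- Dk
    for (j in seq_len(n_hidden)) {
      J[rows, o_W2 + (j - 1) * n_out + k] <- H[, j]
    }
    J[rows, o_b2 + k] <- 1
  }
  J
}

#' Split a dataset into training and validation subsets
#'
#' Seeded uniform shuffle; the first `round(n * train_fraction)` shuffled
#' rows form the training set, the remainder the validation set. The split
#' is disjoint, exhaustive and reproducible for a fixed seed.
#'
#' @param data A data frame.
#' @param train_fraction Fraction in (0, 1) (default 0.8).
#' @param seed Shuffle seed.
#' @return List with `train` and `validation` tibbles; the chosen row
#'   indices are attached as attribute `train_idx`.
#' @examples
#' sp <- split_dataset(data.frame(x = 1:65), 0.8, seed = 1)
#' nrow(sp$train) # 52
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 1) {
  n <- nrow(data)
  if (n < 5) abort("dataset too small to split (need >= 5 rows).")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).")
  }
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(n * train_fraction)
  n_train <- min(max(n_train, 1), n - 1)
  train_idx <- sort(idx[seq_len(n_train)])
  val_idx <- sort(idx[-seq_len(n_train)])
  structure(
    list(
      train = tibble::as_tibble(data[train_idx, , drop = FALSE]),
      validation = tibble::as_tibble(data[val_idx, , drop = FALSE])
    ),
    train_idx = train_idx
  )
}

rmse_scaled <- function(w, Xs, Ts) {
  sqrt(mean((mlp_eval_scaled(w, Xs)$Y - Ts)^2))
}

train_one_restart <- function(Xs, Ts, n_hidden, config, seed,
                              Xs_va = NULL, Ts_va = NULL) {
  n_in <- ncol(Xs)
  n_out <- ncol(Ts)
  w0 <- init_weights(n_in, n_hidden, n_out, seed)

  # validation-based early stopping: keep the weights from the iteration
  # with the best validation error, stop after `patience` accepted
  # iterations without improvement
  best <- new.env(parent = emptyenv())
  best$rmse <- Inf
  best$theta <- pack_weights(w0)
  best$since <- 0L
  cb <- NULL
  patience <- config$patience %||% Inf
  if (!is.null(Xs_va) && is.finite(patience)) {
    cb <- function(iter, theta, cost) {
      w <- unpack_weights(theta, n_in, n_hidden, n_out)
      v <- rmse_scaled(w, Xs_va, Ts_va)
      if (v < best$rmse) {
        best$rmse <- v
        best$theta <- theta
        best$since <- 0L
      } else {
        best$since <- best$since + 1L
      }
      best$since >= patience
    }
  }

  fit <- levenberg_marquardt(
    residual_fn = function(theta) {
      w <- unpack_weights(theta, n_in, n_hidden, n_out)
      as.vector(mlp_eval_scaled(w, Xs)$Y - Ts)
    },
    jacobian_fn = function(theta) {
      w <- unpack_weights(theta, n_in, n_hidden, n_out)
      mlp_jacobian(w, Xs, mlp_eval_scaled(w, Xs)$H)
    },
    init_params = pack_weights(w0),
    lambda0 = config$lambda0, lm_up = config$lm_up,
    lm_down = config$lm_down, max_iter = config$max_iter, tol = config$tol,
    callback = cb
  )
  theta <- if (!is.null(cb) && is.finite(best$rmse)) best$theta else fit$par
  list(
    weights = unpack_weights(theta, n_in, n_hidden, n_out),
    iterations = fit$iterations, converged = fit$converged,
    cost = fit$cost
  )
}

train_mlp <- function(data, input_names, output_names, config, direction) {
  keep <- stats::complete.cases(data[, c(input_names, output_names)])
  if ("fit_flag" %in% names(data)) {
    keep <- keep & (is.na(data$fit_flag) |
      data$fit_flag == "single_exponential_fallback")
  }
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 20) abort("need at least 20 complete training pairs.")

  sp <- split_dataset(data, config$train_fraction, derive_seed(config$seed, 0))
  X_tr <- as.matrix(sp$train[, input_names])
  T_tr <- as.matrix(sp$train[, output_names])
  X_va <- as.matrix(sp$validation[, input_names])
  T_va <- as.matrix(sp$validation[, output_names])

  in_scaler <- make_scaler(X_tr)
  out_scaler <- make_scaler(T_tr)
  Xs_tr <- scale_to_unit(X_tr, in_scaler)
  Ts_tr <- scale_to_unit(T_tr, out_scaler)
  Xs_va <- scale_to_unit(X_va, in_scaler)
  Ts_va <- scale_to_unit(T_va, out_scaler)

  n_params <- sum(mlp_dims(
    length(input_names), config$n_hidden,
    length(output_names)
  ))
  n_resid <- nrow(Xs_tr) * length(output_names)
  if (n_params > n_resid) {
    warn(sprintf(
      paste0(
        "network has %d weights but only %d training residuals; ",
        "expect overfitting (consider a smaller n_hidden)."
      ),
      n_params, n_resid
    ))
  }

  restarts <- purrr::map(seq_len(config$n_restarts), function(r) {
    res <- tryCatch(
      train_one_restart(
        Xs_tr, Ts_tr, config$n_hidden, config,
        derive_seed(config$seed, r), Xs_va, Ts_va
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      list(
        weights = NULL, iterations = NA_integer_, converged = FALSE,
        error = conditionMessage(res),
        train_rmse = NA_real_, val_rmse = NA_real_
      )
    } else {
      res$train_rmse <- rmse_scaled(res$weights, Xs_tr, Ts_tr)
      res$val_rmse <- rmse_scaled(res$weights, Xs_va, Ts_va)
      res$error <- NA_character_
      res
    }
  })

  report <- tibble::tibble(
    restart = seq_len(config$n_restarts),
    seed = vapply(
      seq_len(config$n_restarts),
      function(r) derive_seed(config$seed, r), integer(1)
    ),
    train_rmse = vapply(restarts, function(r) r$train_rmse, numeric(1)),
    val_rmse = vapply(restarts, function(r) r$val_rmse, numeric(1)),
    iterations = vapply(
      restarts,
      function(r) as.integer(r$iterations %||% NA_integer_), integer(1)
    ),
    converged = vapply(restarts, function(r) isTRUE(r$converged), logical(1)),
    error = vapply(restarts, function(r) r$error, character(1))
  )
  ok <- which(is.finite(report$val_rmse))
  if (!length(ok)) {
    abort(paste0(
      "all training restarts failed:\n",
      paste(sprintf(
        "  restart %d: %s", report$restart,
        ifelse(is.na(report$error), "non-finite validation error",
          report$error
        )
      ), collapse = "\n")
    ))
  }
  best <- ok[which.min(report$val_rmse[ok])] # ties: lowest restart index
  report$selected <- report$restart == best

  model <- structure(
    list(
      W1 = restarts[[best]]$weights$W1, b1 = restarts[[best]]$weights$b1,
      W2 = restarts[[best]]$weights$W2, b2 = restarts[[best]]$weights$b2,
      input_scaler = in_scaler, output_scaler = out_scaler,
      input_names = input_names, output_names = output_names,
      n_hidden = config$n_hidden
    ),
    class = "neuroloop_mlp"
  )
  structure(
    list(
      model = model, report = report, config = config, split = sp,
      direction = direction
    ),
    class = "mlp_fit"
  )
}

stimulus_input_names <- function() c("frequency", "amplitude", "pulse_width")

#' Train the forward (system) model: stimulus to response coefficients
#'
#' A two-layer feedforward network (tanh hidden layer, linear output) maps
#' the three stimulation parameters (frequency, amplitude, pulse width) to
#' the 12 response-model coefficients. The dataset is split 80/20 into
#' training and validation; `n_restarts` networks are trained from
#' independent random initializations by full-batch Levenberg-Marquardt, and
#' the restart with the lowest validation (generalization) error is
#' selected, ties broken by the lowest restart index. Rows flagged as having
#' no evoked response are excluded.
#'
#' @param data Coefficient table from [fit_responses()] (stimulus columns
#'   plus the 12 coefficient columns).
#' @param config A [train_config()]; the documented hidden-width default is
#'   150.
#' @return An `mlp_fit`: the selected `neuroloop_mlp` model plus the
#'   per-restart training report ([tidy.mlp_fit()]) and the data split.
#' @export
train_forward <- function(data, config = train_config(n_hidden = 150)) {
  train_mlp(data, stimulus_input_names(), coef_names(), config, "forward")
}

#' Train the inverse (predictive) model: response coefficients to stimulus
#'
#' Same machinery as [train_forward()] with inputs and outputs swapped: the
#' 12 response coefficients map to the three stimulation parameters
#' (frequency, amplitude, pulse width); stimulus train duration is fixed by
#' the protocol, not predicted.
#'
#' @inheritParams train_forward
#' @param config A [train_config()]; the documented hidden-width default is
#'   600.
#' @return An `mlp_fit`.
#' @export
train_inverse <- function(data, config = train_config(n_hidden = 600)) {
  train_mlp(data, coef_names(), stimulus_input_names(), config, "inverse")
}

#' Predict with a fitted feedforward model
#'
#' @param object A `neuroloop_mlp` or `mlp_fit`.
#' @param newdata Data frame containing the model's input columns.
#' @param ... Ignored.
#' @return A tibble of predicted outputs, one row per input row.
#' @export
predict.neuroloop_mlp <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$input_names, drop = FALSE])
  Xs <- scale_to_unit(X, object$input_scaler)
  Ys <- mlp_eval_scaled(object, Xs)$Y
  Y <- unscale_from_unit(Ys, object$output_scaler)
  colnames(Y) <- object$output_names
  tibble::as_tibble(Y)
}

#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
print.mlp_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<mlp_fit: %s> %d -> %d, %d hidden; %d restarts, selected #%d (val RMSE %.4g)\n",
    x$direction, length(x$model$input_names), length(x$model$output_names),
    x$model$n_hidden, nrow(x$report), g$selected_restart, g$val_rmse
  ))
  invisible(x)
}

#' Per-restart training report of a fitted model
#'
#' @param x An `mlp_fit`.
#' @param ... Ignored.
#' @return Tibble with one row per restart: seeds, train/validation RMSE (on
#'   scaled values), iteration counts, convergence and selection flags.
#' @method tidy mlp_fit
#' @export
tidy.mlp_fit <- function(x, ...) x$report

#' One-row summary of a fitted model
#'
#' @param x An `mlp_fit`.
#' @param ... Ignored.
#' @return One-row tibble: direction, dimensions, selected restart,
#'   train/validation RMSE, training/validation sizes.
#' @method glance mlp_fit
#' @export
glance.mlp_fit <- function(x, ...) {
  sel <- which(x$report$selected)
  tibble::tibble(
    direction = x$direction,
    n_hidden = x$model$n_hidden,
    n_restarts = nrow(x$report),
    selected_restart = sel,
    train_rmse = x$report$train_rmse[sel],
    val_rmse = x$report$val_rmse[sel],
    n_train = nrow(x$split$train),
    n_validation = nrow(x$split$validation)
  )
}

#' Goodness of fit of a model on a dataset
#'
#' Computes, on scaled (`[-1, 1]`) values so outputs are comparable, the
#' per-output R-squared and RMSE and the aggregate R-squared
#' `1 - SS_res / SS_tot` pooled over all outputs. Outputs with zero variance
#' in the evaluation data are reported as NA and excluded from the pool.
#'
#' @param object A `neuroloop_mlp` or `mlp_fit`.
#' @param data Data frame with the model's input and output columns.
#' @return List with `aggregate_r_squared`, `per_output` (tibble of
#'   `output`, `r_squared`, `rmse`, `rmse_scaled`), and `n`.
#' @export
evaluate_model <- function(object, data) {
  model <- if (inherits(object, "mlp_fit")) object$model else object
  keep <- stats::complete.cases(
    data[, c(model$input_names, model$output_names)]
  )
  data <- data[keep, , drop = FALSE]
  if (!nrow(data)) abort("no complete rows to evaluate on.")
  Yhat <- as.matrix(predict(model, data))
  Yobs <- as.matrix(as.data.frame(data)[, model$output_names, drop = FALSE])
  Ys_hat <- scale_to_unit(Yhat, model$output_scaler)
  Ys_obs <- scale_to_unit(Yobs, model$output_scaler)
  res2 <- (Ys_hat - Ys_obs)^2
  ctr2 <- sweep(Ys_obs, 2, colMeans(Ys_obs))^2
  per_ss_tot <- colSums(ctr2)
  per_r2 <- ifelse(per_ss_tot > 0, 1 - colSums(res2) / per_ss_tot, NA_real_)
  pool <- per_ss_tot > 0
  aggregate <- 1 - sum(res2[, pool]) / sum(ctr2[, pool])
  list(
    aggregate_r_squared = aggregate,
    per_output = tibble::tibble(
      output = model$output_names,
      r_squared = unname(per_r2),
      rmse = sqrt(colMeans((Yhat - Yobs)^2)),
      rmse_scaled = sqrt(colMeans(res2))
    ),
    n = nrow(data)
  )
}
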
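#' Levenberg-Marquardt nonlinear least squares
#'
#' Damped Gauss-Newton minimization of `0.5 * sum(residual_fn(p)^2)`. At each
#' iteration the step solves `(J'J + lambda I) delta = -J'r`; accepted steps
#' (cost decreases) divide the damping `lambda` by `lm_down`, rejected steps
#' multiply it by `lm_up` and are retried. As `lambda -> 0` the step is
#' Gauss-Newton; as `lambda -> Inf` it approaches a small gradient-descent
#' step. Used both for biexponential decay fitting and for training the
#' feedforward networks.
#'
#' @param residual_fn Function `p -> residual vector`.
#' @param jacobian_fn Function `p -> Jacobian matrix` (n_residuals x
#'   n_params) of the residuals. If NULL, a forward-difference Jacobian is
#'   used.
#' @param init_params Numeric start vector.
#' @param lambda0 Initial damping.
#' @param lm_up,lm_down Damping multipliers on rejected / accepted steps
#'   (> 1).
#' @param max_iter Maximum accepted iterations.
#' @param tol Convergence threshold on gradient infinity-norm, relative step
#'   size and relative cost decrease.
#' @param lambda_max Damping at which a still-rejected step aborts.
#' @param callback Optional function called after every accepted iteration
#'   with `(iteration, params, cost)`; returning `TRUE` stops the
#'   optimization early (reason `"callback"`). Used e.g. for
#'   validation-based early stopping when training networks.
#' @return A list with `par`, `cost` (0.5*SSR), `initial_cost`, `iterations`,
#'   `converged`, `reason`, and the per-iteration `trace` tibble.
#' @examples
#' # linear least squares: converges to the closed-form solution
#' A <- cbind(1, 1:5)
#' y <- c(1.1, 1.9, 3.2, 3.9, 5.1)
#' fit <- levenberg_marquardt(
#'   function(p) drop(A %*% p) - y,
#'   function(p) A, c(0, 0)
#' )
#' all.equal(fit$par, drop(solve(crossprod(A), crossprod(A, y))))
#' @export
levenberg_marquardt <- function(residual_fn, jacobian_fn = NULL, init_params,
                                lambda0 = 1e-3, lm_up = 10, lm_down = 10,
                                max_iter = 200, tol = 1e-10,
                                lambda_max = 1e12, callback = NULL) {
  stopifnot(is.numeric(init_params), lm_up > 1, lm_down > 1, max_iter >= 1)
  p <- as.numeric(init_params)
  if (is.null(jacobian_fn)) {
    jacobian_fn <- function(pp) num_jacobian(residual_fn, pp)
  }
  r <- residual_fn(p)
  if (any(!is.finite(r))) abort("residuals not finite at the start point.")
  cost <- 0.5 * sum(r^2)
  initial_cost <- cost
  lambda <- lambda0
  iters <- 0L
  reason <- "max_iter"
  converged <- FALSE
  tr <- vector("list", max_iter)

  for (it in seq_len(max_iter)) {
    J <- jacobian_fn(p)
    if (length(r) != nrow(J) || length(p) != ncol(J)) {
      abort("residual/Jacobian dimensions inconsistent.")
    }
    g <- drop(crossprod(J, r))
    if (max(abs(g)) < tol) {
      converged <- TRUE
      reason <- "gradient"
      break
    }
    H <- crossprod(J)
    accepted <- FALSE
    repeat {
      step <- tryCatch(
        solve(H + diag(lambda, ncol(H)), -g),
        error = function(e) NULL
      )
      if (is.null(step)) {
        if (lambda >= lambda_max) {
          abort(sprintf(
            "normal equations singular at damping %g; aborting.", lambda
          ))
        }
        lambda <- lambda * lm_up
        next
      }
      p_new <- p + drop(step)
      r_new <- residual_fn(p_new)
      cost_new <- if (any(!is.finite(r_new))) Inf else 0.5 * sum(r_new^2)
      if (cost_new <= cost) {
        accepted <- TRUE
        step_rel <- sqrt(sum(step^2)) / (sqrt(sum(p^2)) + tol)
        cost_rel <- (cost - cost_new) / max(cost, .Machine$double.xmin)
        p <- p_new
        r <- r_new
        cost <- cost_new
        lambda <- max(lambda / lm_down, 1e-16)
        iters <- iters + 1L
        tr[[it]] <- c(iter = iters, cost = cost, lambda = lambda)
        if (step_rel < tol || cost_rel < tol) {
          converged <- TRUE
          reason <- if (step_rel < tol) "step" else "cost"
        }
        if (!converged && !is.null(callback) &&
          isTRUE(callback(iters, p, cost))) {
          converged <- TRUE
          reason <- "callback"
        }
        break
      }
      lambda <- lambda * lm_up
      if (lambda > lambda_max) {
        converged <- TRUE # cannot improve: local minimum to tolerance
        reason <- "lambda_max"
        break
      }
    }
    if (converged || !accepted) break
  }

  trace <- do.call(rbind, tr[!vapply(tr, is.null, logical(1))])
  list(
    par = p, cost = cost, initial_cost = initial_cost,
    iterations = iters, converged = converged, reason = reason,
    trace = if (is.null(trace)) {
      tibble::tibble(iter = integer(), cost = numeric(), lambda = numeric())
    } else {
      tibble::as_tibble(as.data.frame(trace))
    }
  )
}

num_jacobian <- function(fn, p, eps = 1e-7) {
  r0 <- fn(p)
  J <- matrix(0, length(r0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(1, abs(p[j]))
    pj <- p
    pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - r0) / h
  }
  J
}
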
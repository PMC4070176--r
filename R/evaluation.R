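# Controller-efficacy metrics: RMS trace error, achieved-vs-target
# regression (slope/offset/R^2), and report plots.

#' RMS error between two dopamine traces
#'
#' Root mean squared difference on the `actual` trace's time grid; the
#' `desired` trace is resampled onto that grid by linear interpolation when
#' the grids differ. Errors if the time supports do not overlap.
#'
#' @param actual,desired `dopamine_trace` objects (or data frames with
#'   `time_s`, `concentration_uM`).
#' @return RMS error, uM.
#' @export
rms_error <- function(actual, desired) {
  ta <- actual$time_s
  td <- desired$time_s
  overlap <- ta >= min(td) & ta <= max(td)
  if (!any(overlap)) abort("traces have disjoint time supports.")
  d <- if (isTRUE(all.equal(ta, td))) {
    desired$concentration_uM
  } else {
    approx(td, desired$concentration_uM, xout = ta[overlap])$y
  }
  a <- if (isTRUE(all.equal(ta, td))) {
    actual$concentration_uM
  } else {
    actual$concentration_uM[overlap]
  }
  sqrt(mean((a - d)^2))
}

#' Achieved-versus-target linear regression
#'
#' Ordinary least squares of achieved on target values with the squared
#' Pearson correlation as R-squared; a perfect controller gives slope 1,
#' offset 0, R-squared 1, while systematic gain or bias errors show up in
#' the slope and offset.
#'
#' @param actual Achieved values, uM.
#' @param target Target values, uM.
#' @return A `regression_report` tibble: `slope`, `offset`, `r_squared`,
#'   `n`.
#' @examples
#' regression_analysis(c(1, 2, 3), c(1, 2, 3))
#' @export
regression_analysis <- function(actual, target) {
  actual <- as.numeric(actual)
  target <- as.numeric(target)
  ok <- is.finite(actual) & is.finite(target)
  actual <- actual[ok]
  target <- target[ok]
  if (length(actual) < 2) abort("need at least 2 finite pairs.")
  if (var(target) == 0) abort("target values have zero variance.")
  fit <- lm(actual ~ target)
  r2 <- if (var(actual) == 0) 0 else cor(actual, target)^2
  structure(
    tibble::tibble(
      slope = unname(coef(fit)[2]), offset = unname(coef(fit)[1]),
      r_squared = r2, n = length(actual)
    ),
    class = c("regression_report", "tbl_df", "tbl", "data.frame")
  )
}

#' Summarize a closed-loop run
#'
#' Regresses achieved on target dopamine either per target peak (`"peak"`,
#' the headline comparison) or pooling every trace sample (`"pointwise"`),
#' and assembles a per-target summary table; failed targets are dropped
#' (at least 2 successes required).
#'
#' @param results A `closed_loop_result` from [run_closed_loop()].
#' @param mode `"peak"` or `"pointwise"`.
#' @return A `closed_loop_report` list: `regression`
#'   (a [regression_analysis()] report), `summary` (per-target tibble),
#'   `mode`, and `points` (the regressed pairs).
#' @export
report_closed_loop <- function(results, mode = c("peak", "pointwise")) {
  mode <- match.arg(mode)
  ok <- is.na(results$error) & is.finite(results$rms_error)
  if (sum(ok) < 2) abort("need at least 2 successful closed-loop results.")
  res <- results[ok, ]
  points <- if (mode == "peak") {
    tibble::tibble(
      target_id = res$target_id,
      target = res$target_peak, achieved = res$achieved_peak
    )
  } else {
    purrr::map2_dfr(
      res$target_id, seq_len(nrow(res)),
      function(id, i) {
        tibble::tibble(
          target_id = id,
          target = res$target_trace[[i]]$concentration_uM,
          achieved = res$achieved_trace[[i]]$concentration_uM
        )
      }
    )
  }
  structure(
    list(
      regression = regression_analysis(points$achieved, points$target),
      summary = dplyr::select(
        res, "target_id", "frequency", "amplitude", "pulse_width",
        "target_peak", "achieved_peak", "rms_error", "clipped", "energy"
      ),
      mode = mode, points = points,
      results = res
    ),
    class = "closed_loop_report"
  )
}

#' @export
print.closed_loop_report <- function(x, ...) {
  r <- x$regression
  cat(sprintf(
    paste0(
      "<closed_loop_report> mode = %s, n = %d\n",
      "  achieved = %.3f * target + %.4f uM, R^2 = %.4f\n",
      "  mean RMS trace error %.4g uM\n"
    ),
    x$mode, r$n, r$slope, r$offset, r$r_squared, mean(x$summary$rms_error)
  ))
  invisible(x)
}

#' Scatter of achieved versus target dopamine with the fitted regression
#'
#' @param object A `closed_loop_report`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot closed_loop_report
#' @export
autoplot.closed_loop_report <- function(object, ...) {
  r <- object$regression
  ggplot2::ggplot(object$points, ggplot2::aes(.data$target, .data$achieved)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_abline(
      slope = r$slope, intercept = r$offset,
      colour = "firebrick"
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = expression("Target dopamine (" * mu * "M)"),
      y = expression("Achieved dopamine (" * mu * "M)"),
      title = sprintf(
        "Closed-loop control (%s): R² = %.3f, slope = %.2f",
        object$mode, r$r_squared, r$slope
      )
    )
}

#' Overlay of achieved and target dopamine traces per target
#'
#' @param report A `closed_loop_report`.
#' @param max_targets Plot at most this many targets.
#' @return A ggplot faceted by target.
#' @export
plot_closed_loop_traces <- function(report, max_targets = 6) {
  res <- report$results
  ids <- utils::head(res$target_id, max_targets)
  df <- purrr::map_dfr(which(res$target_id %in% ids), function(i) {
    dplyr::bind_rows(
      tibble::tibble(
        target_id = res$target_id[i], kind = "achieved",
        time_s = res$achieved_trace[[i]]$time_s,
        concentration_uM = res$achieved_trace[[i]]$concentration_uM
      ),
      tibble::tibble(
        target_id = res$target_id[i], kind = "target",
        time_s = res$target_trace[[i]]$time_s,
        concentration_uM = res$target_trace[[i]]$concentration_uM
      )
    )
  })
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$time_s, .data$concentration_uM,
      linetype = .data$kind, colour = .data$kind
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~target_id, scales = "free_y") +
    ggplot2::scale_linetype_manual(values = c(achieved = 1, target = 3)) +
    ggplot2::labs(
      x = "Time (s)", y = expression("Dopamine (" * mu * "M)"),
      title = "Achieved (solid) vs target (dotted) responses"
    )
}

#' Dose-response summary of a protocol dataset
#'
#' Peak evoked dopamine against each varied stimulus parameter, the
#' characterization sweep view of the dataset.
#'
#' @param dataset Output of [run_protocol()].
#' @return A tibble with `bin_index`, stimulus columns and `peak_uM`.
#' @export
dose_response <- function(dataset) {
  dplyr::mutate(
    dplyr::select(
      dataset, "bin_index", "frequency", "amplitude",
      "pulse_width", "duration"
    ),
    peak_uM = vapply(dataset$trace, trace_peak, numeric(1))
  )
}
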
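test_that("segmentation splits a response at its evoked peak", {
  tr <- simulate_response(stimulus_tbl(100, 300, 2, 2), default_plant(),
    noiseless = TRUE
  )
  seg <- segment_response(tr)
  # release stops at stimulus offset, uptake takes over: the peak sits at
  # the offset sample (within one 10-Hz sample)
  expect_equal(seg$t_peak, attr(tr, "stim_offset"), tolerance = 0.1 + 1e-9)
  expect_gt(nrow(seg$rise), 1)
  expect_gt(nrow(seg$decay), 1)
  expect_equal(seg$c_peak, trace_peak(tr))

  # triangular fixture splits exactly at the apex
  tri <- neuroloop:::new_trace(
    seq(0, 2, by = 0.1),
    c(seq(0, 1, by = 0.1), seq(0.9, 0, by = -0.1)), 0, 1
  )
  seg2 <- segment_response(tri)
  expect_equal(seg2$t_peak, 1)
  expect_equal(seg2$c_peak, 1)

  flat <- neuroloop:::new_trace(seq(0, 2, by = 0.1), rep(0, 21), 0, 1)
  expect_error(segment_response(flat), "no evoked response")
})

test_that("a constructed polynomial-rise/biexponential-decay trace is recovered", {
  # decay with known coefficients; rise is a smooth ramp to the peak value
  t <- seq(0, 20, by = 0.1)
  onset <- 5
  t_peak <- 7
  a <- c(1, 0.5)
  b <- c(-0.5, -0.05)
  conc <- numeric(length(t))
  rise <- t >= onset & t <= t_peak
  s <- (t[rise] - onset) / (t_peak - onset)
  conc[rise] <- sum(a) * s^2 * (3 - 2 * s) # smoothstep to a1 + a2
  dec <- t > t_peak
  u <- t[dec] - t_peak
  conc[dec] <- a[1] * exp(b[1] * u) + a[2] * exp(b[2] * u)
  tr <- neuroloop:::new_trace(t, conc, onset, t_peak)

  fit <- fit_response(tr)
  expect_length(coef(fit), 12)
  got <- fit$exp_coeffs
  # compare as (amplitude, rate) pairs sorted by rate, recovery within 1%
  ord_got <- order(got[c(2, 4)])
  ord_true <- order(b)
  expect_equal(unname(got[c(1, 3)][ord_got]), a[ord_true], tolerance = 0.01)
  expect_equal(unname(got[c(2, 4)][ord_got]), b[ord_true], tolerance = 0.01)
})

test_that("every noiseless protocol trace fits to within 5% of its peak", {
  fits <- protocol_fits()
  expect_equal(nrow(fits), 65)
  expect_true(all(is.na(fits$fit_flag)))
  expect_length(intersect(coef_cols, names(fits)), 12)
  expect_true(all(fits$fit_rmse <= 0.05 * fits$c_peak))
  # physical decays: rates within [-10, 0]
  expect_true(all(fits$exp_b1 <= 0 & fits$exp_b1 >= -10))
  expect_true(all(fits$exp_b2 <= 0 & fits$exp_b2 >= -10))
  # dominant amplitude positive, continuity at the peak
  expect_true(all(fits$exp_a1 > 0))
  expect_equal(fits$exp_a1 + fits$exp_a2, fits$c_peak, tolerance = 0.1)
})

test_that("fitting is deterministic and reconstruction matches the fit", {
  tr <- simulate_response(stimulus_tbl(60, 350, 2, 2), default_plant(),
    noiseless = TRUE
  )
  f1 <- fit_response(tr)
  f2 <- fit_response(tr)
  expect_identical(coef(f1), coef(f2))
  recon <- reconstruct_response(f1, tr$time_s)
  expect_equal(
    sqrt(mean((recon$concentration_uM - tr$concentration_uM)^2)),
    f1$fit_rmse,
    tolerance = 1e-12
  )
  expect_lte(f1$fit_rmse, 0.05 * f1$c_peak)
})

test_that("reconstruction evaluates the stored polynomial exactly", {
  fits <- protocol_fits()
  row <- fits[10, ]
  params <- as_response_params(row)
  # independent route: convert the Chebyshev coefficients to power-basis
  # coefficients and evaluate by Horner's rule
  pw <- neuroloop:::cheb_to_power(params$poly_coeffs)
  horner <- function(s) {
    acc <- pw[8]
    for (k in 7:1) acc <- acc * s + pw[k]
    acc
  }
  s_pts <- c(0.15, 0.5, 0.85)
  t_pts <- params$stim_onset + s_pts * (params$t_peak - params$stim_onset)
  recon <- reconstruct_response(params, t_pts)
  expect_equal(recon$concentration_uM, pmax(0, horner(s_pts)),
    tolerance = 1e-9
  )
})

test_that("zero coefficients reconstruct to a zero trace", {
  zero <- structure(
    list(
      poly_coeffs = stats::setNames(rep(0, 8), paste0("poly_c", 0:7)),
      exp_coeffs = stats::setNames(rep(0, 4), c(
        "exp_a1", "exp_b1",
        "exp_a2", "exp_b2"
      )),
      t_peak = 7, c_peak = 0, stim_onset = 5, fit_rmse = 0,
      flag = NA_character_
    ),
    class = "response_params"
  )
  tr <- reconstruct_response(zero, seq(0, 20, by = 0.1))
  expect_true(all(tr$concentration_uM == 0))
})

test_that("noisy traces still round-trip within 15% on clear responses", {
  p <- default_plant()
  ds <- run_protocol(default_protocol()[c(5, 14, 25, 40, 60), ], p, seed = 77)
  fits <- fit_responses(ds, noise_sd = p$noise_sd)
  clear <- fits$c_peak >= 10 * p$noise_sd
  expect_true(any(clear))
  expect_true(all(fits$fit_rmse[clear] <= 0.15 * fits$c_peak[clear]))
})

test_that("tidy and glance expose the 12 coefficients and fit metadata", {
  tr <- simulate_response(stimulus_tbl(100, 300, 2, 2), default_plant(),
    noiseless = TRUE
  )
  fit <- fit_response(tr)
  td <- tidy(fit)
  expect_equal(nrow(td), 12)
  expect_equal(sum(td$component == "polynomial"), 8)
  expect_equal(sum(td$component == "exponential"), 4)
  g <- glance(fit)
  expect_equal(g$c_peak, fit$c_peak)
  expect_false(g$flagged)
})
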
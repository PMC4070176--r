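test_that("recruitment is a logistic function of charge per pulse", {
  p <- default_plant()
  # sigmoid midpoint: charge exactly recruit_mid recruits half the fibers
  for (pw in c(0.5, 1, 2)) {
    expect_equal(recruitment(p$recruit_mid / pw, pw, p), 0.5)
  }
  # frozen value from direct evaluation of 1/(1+exp(-0.01*(300*2 - 400)))
  expect_equal(recruitment(300, 2.0, p), 0.8807970779778823, tolerance = 1e-12)
  expect_error(recruitment(-10, 2, p), "positive")
  expect_error(recruitment(100, 0, p), "positive")
})

test_that("recruitment increases with amplitude and pulse width for any plant", {
  withr::with_seed(42, {
    for (i in 1:20) {
      p <- plant_params(
        recruit_mid = runif(1, 50, 800),
        recruit_slope = runif(1, 0.002, 0.05)
      )
      expect_gt(recruitment(450, 2.0, p), recruitment(100, 2.0, p))
      a <- runif(1, 100, 400)
      expect_gt(recruitment(a, 2.0, p), recruitment(a, 0.5, p))
    }
  })
})

test_that("frequency modulation is 1 at the peak and unimodal around it", {
  p <- default_plant()
  expect_equal(frequency_modulation(p$freq_peak, p), 1)
  f <- seq(20, 200, by = 1)
  m <- frequency_modulation(f, p)
  expect_true(all(diff(m[f <= p$freq_peak]) > 0))
  expect_true(all(diff(m[f >= p$freq_peak]) < 0))
  expect_error(frequency_modulation(0, p), "positive")
})

test_that("simulated release-rate curve peaks where the brute-force scan says", {
  p <- default_plant()
  f <- seq(20, 200, by = 1)
  release_rate <- f * frequency_modulation(f, p)
  expect_equal(f[which.max(release_rate)], 108) # continuous argmax > 100 Hz
  grid <- seq(20, 200, by = 20)
  expect_equal(grid[which.max(grid * frequency_modulation(grid, p))], 100)
})

test_that("a stimulus that recruits nothing evokes a flat trace", {
  p <- plant_params(recruit_mid = 1e7) # recruitment ~ 0 at protocol charges
  tr <- simulate_response(stimulus_tbl(100, 100, 0.1, 2), p, noiseless = TRUE)
  expect_lt(max(tr$concentration_uM), 1e-12)
})

test_that("trace grid is the 10-Hz scan grid covering the bin", {
  tr <- simulate_response(stimulus_tbl(100, 300, 2, 2), default_plant(),
    noiseless = TRUE
  )
  expect_equal(nrow(tr), 201)
  expect_equal(diff(tr$time_s), rep(0.1, 200), tolerance = 1e-9)
  expect_equal(attr(tr, "stim_onset"), 5)
  expect_equal(attr(tr, "stim_offset"), 7)
  expect_true(all(tr$concentration_uM >= 0))
})

test_that("coarse integrator matches a 10x finer Euler solution within 1%", {
  p <- default_plant()
  stims <- list(
    list(frequency = 100, amplitude = 300, pulse_width = 2, duration = 2),
    list(frequency = 60, amplitude = 450, pulse_width = 2, duration = 2),
    list(frequency = 20, amplitude = 250, pulse_width = 2, duration = 2),
    list(frequency = 100, amplitude = 300, pulse_width = 0.1, duration = 2),
    list(frequency = 60, amplitude = 300, pulse_width = 2, duration = 8)
  )
  for (stim in stims) {
    coarse <- trace_peak(simulate_response(stim, p, noiseless = TRUE))
    fine <- euler_fine_peak(stim, p)
    expect_equal(coarse, fine, tolerance = 0.01)
  }
})

test_that("peak dopamine rises monotonically with amplitude and pulse width", {
  p <- default_plant()
  peaks_a <- vapply(seq(100, 450, by = 50), function(a) {
    trace_peak(simulate_response(stimulus_tbl(60, a, 2, 2), p,
      noiseless = TRUE
    ))
  }, numeric(1))
  expect_true(all(diff(peaks_a) >= 0))
  peaks_pw <- vapply(seq(0.2, 2, by = 0.3), function(pw) {
    trace_peak(simulate_response(stimulus_tbl(100, 300, pw, 2), p,
      noiseless = TRUE
    ))
  }, numeric(1))
  expect_true(all(diff(peaks_pw) >= 0))
})

test_that("concentration decays monotonically to baseline after the train", {
  tr <- simulate_response(stimulus_tbl(100, 350, 2, 2), default_plant(),
    noiseless = TRUE
  )
  tail_c <- tr$concentration_uM[tr$time_s > attr(tr, "stim_offset")]
  expect_true(all(diff(tail_c) <= 1e-12))
  expect_lt(tail_c[length(tail_c)], 1e-3)
})

test_that("noisy simulation is reproducible from its seed", {
  p <- default_plant()
  s <- stimulus_tbl(100, 300, 2, 2)
  a <- simulate_response(s, p, seed = 7)
  b <- simulate_response(s, p, seed = 7)
  c <- simulate_response(s, p, seed = 8)
  expect_identical(a$concentration_uM, b$concentration_uM)
  expect_false(identical(a$concentration_uM, c$concentration_uM))
  # noiseless output ignores the seed entirely
  expect_identical(
    simulate_response(s, p, seed = 1, noiseless = TRUE)$concentration_uM,
    simulate_response(s, p, seed = 99, noiseless = TRUE)$concentration_uM
  )
})

test_that("drift scales release and uptake geometrically per trial", {
  p <- plant_params(drift_rate = 0)
  expect_identical(apply_drift(p, 10), p)
  p2 <- plant_params(drift_rate = 0.01)
  d <- apply_drift(p2, 10)
  expect_equal(d$release_per_pulse, p2$release_per_pulse * 1.01^10)
  expect_equal(d$Vmax, p2$Vmax * 1.01^10)
  p3 <- plant_params(drift_rate = -0.5)
  d3 <- apply_drift(p3, 40)
  expect_gt(d3$release_per_pulse, 0)
  expect_lt(d3$release_per_pulse, 1e-10)
})

test_that("stimulus validation enforces the protocol envelope", {
  expect_error(stimulus_tbl(10, 300, 2, 2), "frequency")
  expect_error(stimulus_tbl(100, 500, 2, 2), "amplitude")
  expect_error(stimulus_tbl(100, 300, 3, 2), "pulse_width")
  expect_silent(stimulus_tbl(20, 100, 0.1, 0.5))
})
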
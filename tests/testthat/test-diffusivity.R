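test_that("the diagonal series equals its closed form at zero and the oracle elsewhere", {
  expect_equal(psi_model(0), 512 / 960, tolerance = 1e-9)
  expect_equal(psi_model(0.1), oracle_psi(0.1), tolerance = 1e-12)
  expect_equal(psi_model(0.1), 0.25402, tolerance = 1e-4)
  expect_equal(psi_model(c(0.05, 0.5, 2)),
               vapply(c(0.05, 0.5, 2), oracle_psi, numeric(1)),
               tolerance = 1e-12)
  expect_error(psi_model(-0.1), "nonnegative")
})

test_that("the series is strictly decreasing in tau*", {
  tau <- seq(0, 2, by = 0.02)
  expect_true(all(diff(psi_model(tau)) < 0))
})

test_that("inversion round-trips the series to 1e-6 over tau* in [0, 2]", {
  expect_equal(invert_psi(psi_model(0)), 0)
  expect_equal(invert_psi(0.25402), 0.1, tolerance = 1e-4)
  set.seed(5)
  x <- stats::runif(100, 0, 2)
  back <- vapply(psi_model(x), invert_psi, numeric(1))
  expect_lt(max(abs(back - x)), 1e-6)
  expect_error(invert_psi(0.9), "psi_model")
  expect_error(invert_psi(0), "psi_model")
})

test_that("psi_from_kinetics maps uptake to [eps, 1] with clip warnings", {
  k <- kinetic_series("x", c(0, 10, 20, 30), c(0, 0.218, 0.436, 0.48))
  expect_warning(p <- psi_from_kinetics(k, Ye = 0.436), "clipped")
  expect_equal(p$psi[1], 1)
  expect_equal(p$psi[2], 0.5)
  expect_equal(p$psi[3], 1e-9)      # Y = Ye clips to eps
  expect_identical(attr(p, "n_clipped"), 2L)
  expect_error(psi_from_kinetics(k, Ye = -1), "positive")
})

test_that("characteristic length contracts with the cube root of volume", {
  expect_equal(characteristic_length(1, 0.00609), 0.00609)
  expect_equal(characteristic_length(0.512, 2), 1.6)
  expect_equal(characteristic_length(0.125, 0.00609), 0.003045)
  expect_error(characteristic_length(0, 1), "positive")
})

test_that("modified slope method recovers D on the noiseless grid", {
  for (D in c(1, 2, 4) * 1e-10) {
    for (sf in c(1, 0.75, 0.5)) {
      cfg <- simulation_config(D_true = D, shrink_final = sf)
      kin <- generate_kinetics(cfg, Y_e = 0.436)
      est <- modified_slope_method(psi_from_kinetics(kin, 0.436),
                                   generate_shrinkage(cfg), cfg$L0)
      expect_lt(abs(est$D_avg / D - 1), 0.05)
      expect_true(all(est$D_stepwise > 0))
      expect_true(all(diff(est$tau_star) > 0))
      expect_gt(est$r_squared, 0.99)
    }
  }
})

test_that("modified slope method reports exclusions and refuses flat input", {
  cfg <- simulation_config()
  kin <- generate_kinetics(cfg, Y_e = 0.436)
  psi <- psi_from_kinetics(kin, 0.436)
  est <- modified_slope_method(psi, generate_shrinkage(cfg), cfg$L0)
  expect_gt(est$n_excluded_early, 0)   # early points sit above 8/15

  flat <- psi_series(c(0, 10, 20, 30), rep(0.4, 4))
  expect_error(
    suppressWarnings(
      modified_slope_method(flat, generate_shrinkage(cfg), cfg$L0)),
    "3 usable")
})

test_that("nonmonotone psi points are dropped with a warning", {
  cfg <- simulation_config(shrink_final = 1)
  kin <- generate_kinetics(cfg, Y_e = 0.436)
  psi <- psi_from_kinetics(kin, 0.436)
  bump <- which(psi$psi < psi_model(0))[2]
  psi$psi[bump] <- psi$psi[bump - 1] + 0.01  # noise spike above running min
  expect_warning(
    est <- modified_slope_method(psi, generate_shrinkage(cfg), cfg$L0),
    "nonmonotone")
  expect_identical(est$n_dropped_nonmonotone, 1L)
  expect_lt(abs(est$D_avg / cfg$D_true - 1), 0.05)
})

test_that("time-unit rescaling leaves the estimate consistent", {
  cfg <- simulation_config(shrink_final = 0.75)
  kin <- generate_kinetics(cfg, Y_e = 0.436)
  psi_s <- psi_from_kinetics(kin, 0.436)
  shr <- generate_shrinkage(cfg)
  est_s <- modified_slope_method(psi_s, shr, cfg$L0)

  psi_min <- psi_series(psi_s$times / 60, psi_s$psi, psi_s$substance)
  shr_min <- shrinkage_series(shr$times / 60, shr$v_ratio)
  est_min <- modified_slope_method(psi_min, shr_min, cfg$L0)
  # D in m^2/min is exactly 60 times D in m^2/s
  expect_equal(est_min$D_avg / (est_s$D_avg * 60), 1, tolerance = 1e-9)
})

test_that("non-shrinkage slope method is exact on a constructed line", {
  L0 <- 0.00609; D <- 2e-10
  t <- c(1e4, 2e4, 3e4, 4e4)
  s <- 3 * pi^2 * D / (4 * L0^2)
  psi <- psi_series(t, exp(log(512 / pi^6) - s * t))
  est <- slope_method_no_shrink(psi, L0)
  expect_equal(est$D_avg / D, 1, tolerance = 1e-10)
  expect_equal(est$r_squared, 1)

  # doubling psi shifts the intercept only: identical D
  psi2 <- psi_series(t, pmin(1 - 1e-12, 2 * psi$psi))
  expect_equal(slope_method_no_shrink(psi2, L0)$D_avg / est$D_avg, 1,
               tolerance = 1e-9)
})

test_that("late-time points of the noiseless series recover D within 1%", {
  L0 <- 0.00609; D <- 2e-10
  tau <- seq(0.1, 0.3, by = 0.05)
  t <- tau * L0^2 / D
  psi <- psi_series(t, psi_model(tau))
  est <- slope_method_no_shrink(psi, L0)
  expect_lt(abs(est$D_avg / D - 1), 0.01)
})

test_that("overestimation ratio is 1 without shrinkage and > 1 with it", {
  cfg1 <- simulation_config(shrink_final = 1)
  kin1 <- generate_kinetics(cfg1, Y_e = 0.436)
  p1 <- psi_from_kinetics(kin1, 0.436)
  e1 <- overestimation_ratio(slope_method_no_shrink(p1, cfg1$L0),
                             modified_slope_method(p1, generate_shrinkage(cfg1),
                                                   cfg1$L0))
  expect_equal(e1, 1, tolerance = 0.03)

  cfg2 <- simulation_config(shrink_final = 0.5)
  kin2 <- generate_kinetics(cfg2, Y_e = 0.436)
  p2 <- psi_from_kinetics(kin2, 0.436)
  e2 <- overestimation_ratio(slope_method_no_shrink(p2, cfg2$L0),
                             modified_slope_method(p2, generate_shrinkage(cfg2),
                                                   cfg2$L0))
  expect_gt(e2, 1)
})

test_that("noisy replicates keep the median recovery error within 10%", {
  errs <- vapply(1:20, function(s) {
    cfg <- simulation_config(shrink_final = 0.75, seed = s)
    kin <- generate_kinetics(cfg, Y_e = 0.436, noise_rel = 0.01)
    est <- suppressWarnings(
      modified_slope_method(psi_from_kinetics(kin, 0.436),
                            generate_shrinkage(cfg), cfg$L0))
    abs(est$D_avg / cfg$D_true - 1)
  }, numeric(1))
  expect_lte(stats::median(errs), 0.10)
})
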
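# Nonlinear least-squares estimation: initialization, recovery, diagnostics.

test_that("initialization follows the median/quantile rules with shapes at 1", {
  d <- reference_fixture("nls", simulation_design(noise_sd_ln = 0.02, seed = 3))
  init <- init_from_data(d)
  expect_identical(init$nu1, 1)
  expect_identical(init$nu2, 1)
  expect_identical(init$k, 1)
  # symmetric 9-point design on [-15, -11]: the median is -13
  expect_identical(init$x_i, -13)
  expect_identical(init$y_i, median(seq(-8, -1, length.out = 8)))
  # amplitude starts at the 0.95 quantile of observed ln FI: between the
  # inflection-pair value and the upper asymptote of the generating surface
  d0 <- reference_fixture("nls", simulation_design(noise_sd_ln = 0))
  init0 <- init_from_data(d0)
  expect_identical(init0$lnC, quantile(log(d0$fi), 0.95, names = FALSE))
  upper <- 9.75 + log1p(0.08) / 0.08 + log1p(0.99) / 0.99
  expect_gt(init0$lnC, 9.75)
  expect_lt(init0$lnC, upper)

  # deterministic: same data, same start
  expect_identical(init_from_data(d), init)

  # a skewed design falls back to the half-rise quantile, still bracketed
  p <- reference_params("nls")
  skew <- simulation_design(x_grid = c(-15, -14.8, -14.6, -14.4, -13, -11),
                            noise_sd_ln = 0, seed = 1)
  init_skew <- init_from_data(simulate_dataset(p, skew))
  expect_true(init_skew$x_i %in% skew$x_grid)

  one_x <- simulate_dataset(p, simulation_design(x_grid = -13, noise_sd_ln = 0))
  expect_error(init_from_data(one_x), "'x'")
})

test_that("noiseless surfaces refit to the generating parameters within 1e-3", {
  for (row in c("nls", "bayes")) {
    truth <- ref_row(row)
    d <- reference_fixture(row, simulation_design(noise_sd_ln = 0))
    fit <- fit_nls(d)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$estimates[names(truth)] - truth)), 1e-3)
    expect_lt(fit$residual_rmse, 1e-6)
  }
})

test_that("degenerate and noisy data produce honest flags and residual scales", {
  # constant response: no inflection identifiable, no exception
  flat <- titration_dataset(x = rep(seq(-15, -11, 1), 4),
                            y = rep(c(-5, -4, -3, -2), each = 5),
                            fi = rep(100, 20))
  f_flat <- fit_nls(flat)
  expect_false(f_flat$converged)
  expect_match(f_flat$reason, "no inflection")

  # known noise shows up as residual RMSE near its true scale
  d <- reference_fixture("nls", simulation_design(noise_sd_ln = 0.05, seed = 7))
  f <- fit_nls(d)
  expect_true(f$converged)
  expect_gt(f$residual_rmse, 0.03)
  expect_lt(f$residual_rmse, 0.08)
  expect_true(all(is.finite(f$uncertainty$se)))
})

test_that("parameter recovery is accurate across replicated noisy datasets", {
  # 50 seeds at the study noise level; precision is parameter-dependent:
  # locations and amplitude are recovered to well under 2%, the serum-axis
  # asymmetry to ~5%, while the antigen-axis asymmetry (0.08, near the
  # Gompertz boundary) is sampling-limited to roughly twice that.
  gen <- reference_params("nls")
  truth <- ref_row("nls")
  errs <- t(vapply(1:50, function(s) {
    d <- simulate_dataset(gen, simulation_design(noise_sd_ln = 0.05, seed = 1000 + s))
    abs(fit_nls(d)$estimates[names(truth)] - truth) / abs(truth)
  }, numeric(5)))
  med <- apply(errs, 2, median)
  expect_lt(med[["lnC"]], 0.02)
  expect_lt(med[["x_i"]], 0.02)
  expect_lt(med[["y_i"]], 0.02)
  expect_lt(med[["nu2"]], 0.05)
  expect_lt(med[["nu1"]], 0.15)
})

test_that("rescaling FI shifts lnC by the log factor and nothing else", {
  d <- reference_fixture("nls", simulation_design(noise_sd_ln = 0.05, seed = 21))
  f1 <- fit_nls(d)
  scaled <- titration_dataset(x = d$x, y = d$y, fi = 10 * d$fi,
                              replicate = d$replicate)
  f2 <- fit_nls(scaled)
  expect_equal(f2$estimates[["lnC"]], f1$estimates[["lnC"]] + log(10),
               tolerance = 1e-6)
  others <- c("nu1", "x_i", "nu2", "y_i", "k")
  expect_equal(f2$estimates[others], f1$estimates[others], tolerance = 1e-6)
})

test_that("freeing k2 on shared-rate data recovers both rates in agreement", {
  d <- reference_fixture("nls", simulation_design(noise_sd_ln = 0.05, seed = 31))
  f <- fit_nls(d, free_k2 = TRUE)
  expect_true(f$converged)
  joint_se <- sqrt(f$uncertainty$se[["k"]]^2 + f$uncertainty$se[["k2"]]^2)
  expect_lt(abs(f$estimates[["k"]] - f$estimates[["k2"]]), 2 * joint_se)
})

test_that("single-axis fits recover curves and flag unidentifiable designs", {
  p <- fig_params()
  truth <- c(A = 8000, nu = 0.5, k = 1, x_i = -13)

  d <- single_axis_fixture(p, grid = seq(-15, -11, length.out = 9),
                           noise_sd_ln = 0, seed = 1)
  f <- fit_single(d)
  expect_true(f$converged)
  expect_lt(max(abs(f$estimates[names(truth)] - truth) / abs(truth)), 1e-4)

  # left-asymptote-only data: the upper limit is not identifiable
  d_left <- single_axis_fixture(p, grid = seq(-28, -23, length.out = 8),
                                noise_sd_ln = 0, seed = 2)
  expect_false(fit_single(d_left)$converged)

  # fixing nu = 1 reduces to a logistic fit: an explicit logistic refit agrees
  pl <- richards_params(A = 8000, nu = 1, k = 1, x_i = -13)
  d_log <- single_axis_fixture(pl, grid = seq(-16, -10, length.out = 11),
                               noise_sd_ln = 0, seed = 3)
  f_fix <- fit_single(d_log, nu_fixed = 1)
  expect_true(f_fix$converged)
  expect_lt(max(abs(f_fix$estimates[c("A", "k", "x_i")] - c(8000, 1, -13)) /
                  c(8000, 1, 13)), 1e-8)

  # a 2-D dataset is refused with a pointer to the 2-D fitter
  d2 <- reference_fixture("nls", simulation_design(noise_sd_ln = 0))
  expect_error(fit_single(d2), "fit_nls")

  # a serum-axis (y) titration works the same way
  dy <- single_axis_fixture(p, grid = seq(-15, -11, length.out = 9),
                            axis = "y", noise_sd_ln = 0, seed = 4)
  fy <- fit_single(dy)
  expect_true(fy$converged)
  expect_equal(fy$estimates[["x_i"]], -13, tolerance = 1e-4)
})

test_that("baseline (5PL) fitting recovers an additive offset", {
  p5 <- richards_params(A = 8000, nu = 0.5, k = 1, x_i = -13, c0 = 300)
  d <- single_axis_fixture(p5, grid = seq(-17, -10, length.out = 15),
                           noise_sd_ln = 0, seed = 6, replicates = 2L)
  f <- fit_single(d, baseline = TRUE)
  expect_true(f$converged)
  expect_equal(f$estimates[["c0"]], 300, tolerance = 0.02 * 300)
  expect_equal(f$estimates[["A"]], 8000, tolerance = 0.02 * 8000)
})

test_that("goodness summaries: zero self-fit, order invariance, noise response", {
  p <- reference_params("nls")
  d0 <- reference_fixture("nls", simulation_design(noise_sd_ln = 0))
  g0 <- goodness(d0, p)
  expect_equal(g0$rmse, 0, tolerance = 1e-12)

  d <- reference_fixture("nls", simulation_design(x_grid = seq(-15, -11, length.out = 20),
                                                  y_grid = seq(-8, -1, length.out = 20),
                                                  replicates = 5L,
                                                  noise_sd_ln = 0.1, seed = 9))
  g <- goodness(d, p)
  expect_equal(g$rmse, 0.1, tolerance = 0.05)

  shuffled <- d[sample(nrow(d)), ]
  class(shuffled) <- class(d)
  expect_equal(goodness(shuffled, p)$rmse, g$rmse, tolerance = 1e-12)
})
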
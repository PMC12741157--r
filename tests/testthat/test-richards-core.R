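# Closed-form sigmoid family: values, parametrizations, limits, derivatives.

test_that("logistic curve: midpoint, shift-parameter equivalence, arithmetic value", {
  p <- logistic_params(A = 8000, k = 1, x_c = -13)
  expect_equal(logistic_value(-13, p), 4000)

  # b = exp(k * x_c) and the centered form are the same curve
  set.seed(1)
  xs <- runif(20, -20, -6)
  pb <- logistic_params(A = 8000, k = 1, b = exp(1 * -13))
  expect_equal(logistic_value(xs, pb), 8000 / (1 + exp(-(xs - -13))))

  # direct arithmetic oracle four rate units right of the inflection
  expect_equal(logistic_value(-9, p), 8000 / (1 + exp(-4)), tolerance = 1e-12)
  expect_equal(logistic_value(-9, p), 7856.1, tolerance = 1e-4)

  expect_error(logistic_params(A = -1, k = 1, x_c = 0), "positive")
  expect_error(logistic_params(A = 1, k = 0, x_c = 0), "positive")
})

test_that("Richards curve: inflection value, logistic special case, asymptotes", {
  p <- fig_params()
  # at the inflection: A * (1 + nu)^(-1/nu) = 8000 * 1.5^-2
  expect_equal(richards_value(-13, p), 8000 * 1.5^-2, tolerance = 1e-12)
  expect_equal(richards_value(-13, p), 3555.56, tolerance = 1e-5)

  # nu = 1 is the logistic curve, pointwise
  set.seed(2)
  xs <- runif(20, -20, -6)
  p1 <- richards_params(A = 8000, nu = 1, k = 1, x_i = -13)
  pl <- logistic_params(A = 8000, k = 1, x_c = -13)
  expect_equal(richards_value(xs, p1), logistic_value(xs, pl), tolerance = 1e-12)

  # asymptotes far beyond the transition
  expect_equal(richards_value(p$x_i + 50 / p$k, p), p$A, tolerance = 1e-10)
  expect_lt(richards_value(p$x_i - 50 / p$k, p), 1e-10 * p$A)

  expect_error(richards_params(A = 8000, nu = -0.5, k = 1, x_i = -13), "positive")
})

test_that("d-form and nu-form are the same curve (d = nu + 1), pointwise to 1e-12", {
  set.seed(3)
  xs <- seq(-18, -8, length.out = 41)
  for (p in random_richards(10)) {
    expect_equal(richards_value_d(xs, A = p$A, d = p$nu + 1, k = p$k, x_i = p$x_i),
                 richards_value(xs, p), tolerance = 1e-12)
  }
  expect_error(richards_value_d(0, A = 1, d = 0.5, k = 1, x_i = 0), "exceed 1")
})

test_that("log Richards curve: substitution value, left-asymptote slope, exp identity", {
  p <- fig_params()
  expect_equal(log_richards_value(-13, p), log(8000) - 2 * log(1.5), tolerance = 1e-12)

  # finite-difference slope far left approaches k/nu = 2
  h <- 1e-4
  x_far <- p$x_i - 40
  slope <- (log_richards_value(x_far + h, p) - log_richards_value(x_far - h, p)) / (2 * h)
  expect_equal(slope, p$k / p$nu, tolerance = 1e-6)

  set.seed(4)
  xs <- runif(20, -20, -6)
  expect_equal(exp(log_richards_value(xs, p)), richards_value(xs, p), tolerance = 1e-12)
})

test_that("normalized Richards curve: unity at inflection, upper limit, multiplier identity", {
  set.seed(5)
  for (p in random_richards(8, seed = 5)) {
    expect_equal(normalized_richards_value(p$x_i, p), 1, tolerance = 1e-12)
    xs <- runif(10, p$x_i - 5, p$x_i + 5)
    expect_equal(richards_value(xs, p),
                 p$A * (1 + p$nu)^(-1 / p$nu) * normalized_richards_value(xs, p),
                 tolerance = 1e-12)
  }
  p1 <- richards_params(A = 5, nu = 1, k = 2, x_i = 0)
  expect_equal(normalized_richards_value(50, p1), 2, tolerance = 1e-10)
})

test_that("inflection rate value: landmark at d = 2, limits 1/e and 1, monotone", {
  expect_identical(inflection_ratio(2), 0.5)
  expect_equal(inflection_ratio(1 + 1e-8), exp(-1), tolerance = 1e-6)
  expect_equal(inflection_ratio(1e8), 1, tolerance = 2e-6)

  d_grid <- exp(seq(log(1.0001), log(1e8), length.out = 200))
  vals <- inflection_ratio(d_grid)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > exp(-1) & vals < 1))
  expect_error(inflection_ratio(1), "exceed 1")
  expect_error(inflection_ratio(0.3), "exceed 1")
})

test_that("Gompertz curve is the d -> 1 limit of the Richards family", {
  expect_equal(gompertz_value(-13, A = 8000, k = 1, x_i = -13), 8000 / exp(1),
               tolerance = 1e-12)
  expect_equal(gompertz_value(40, A = 8000, k = 1, x_i = -13), 8000, tolerance = 1e-6)

  xs <- seq(-18, -8, length.out = 100)
  near_limit <- richards_value_d(xs, A = 8000, d = 1 + 1e-7, k = 1, x_i = -13)
  expect_lt(max(abs(near_limit - gompertz_value(xs, A = 8000, k = 1, x_i = -13))),
            1e-4 * 8000)

  # the dedicated small-nu branch agrees with the Gompertz form
  p_tiny <- richards_params(A = 8000, nu = 1e-9, k = 1, x_i = -13)
  expect_equal(richards_value(xs, p_tiny),
               gompertz_value(xs, A = 8000, k = 1, x_i = -13), tolerance = 1e-12)
  expect_error(gompertz_value(0, A = 0, k = 1, x_i = 0), "positive")
})

test_that("growth rates: product identity, left asymptote, logistic midpoint slope", {
  p <- fig_params()
  set.seed(6)
  xs <- runif(20, -18, -8)
  g <- growth_rates(xs, p)
  expect_equal(g$absolute, richards_value(xs, p) * g$relative, tolerance = 1e-10)

  # relative rate decreasing, approaching k/nu on the far left
  ord <- order(xs)
  expect_true(all(diff(g$relative[ord]) < 0))
  expect_equal(growth_rates(p$x_i - 40 / p$k, p)$relative, p$k / p$nu,
               tolerance = 1e-6)

  # logistic case: absolute rate at the inflection is k*A/4
  p1 <- richards_params(A = 8000, nu = 1, k = 1, x_i = -13)
  expect_equal(growth_rates(-13, p1)$absolute, 1 * 8000 / 4, tolerance = 1e-10)

  # absolute rate is maximal at the inflection
  grid <- seq(p$x_i - 3, p$x_i + 3, length.out = 121)
  ga <- growth_rates(grid, p)$absolute
  expect_equal(grid[which.max(ga)], p$x_i, tolerance = 0.06)
})

test_that("the closed form solves the Richards ODE to discretization error", {
  p <- fig_params()
  set.seed(7)
  xs <- runif(20, -16, -10)
  expect_lt(max(abs(ode_residual(xs, p, step = 1e-4))), 1e-6 * p$A)

  # logistic case at the inflection: dL/dx = k L (1 - L/A)
  p1 <- richards_params(A = 8000, nu = 1, k = 1, x_i = -13)
  expect_lt(abs(ode_residual(-13, p1, step = 1e-4)), 1e-6 * p1$A)

  # central differences are second order: halving the step quarters the error
  x0 <- -12.3
  r1 <- abs(ode_residual(x0, p, step = 2e-3))
  r2 <- abs(ode_residual(x0, p, step = 1e-3))
  expect_equal(r1 / r2, 4, tolerance = 0.2)
})

test_that("family invariants: inflection location, k-invariance at x_i, pure shift", {
  # numerically located inflection (zero of the second difference) sits at x_i
  for (p in random_richards(6, seed = 8)) {
    f <- function(x) richards_value(x, p)
    d2 <- function(x) (f(x + 1e-3) - 2 * f(x) + f(x - 1e-3)) / 1e-6
    root <- uniroot(d2, interval = c(p$x_i - 3 / p$k, p$x_i + 3 / p$k), tol = 1e-10)$root
    expect_equal(root, p$x_i, tolerance = 1e-4)
  }

  # with A and nu fixed, R(x_i) does not depend on k
  vals <- vapply(c(0.25, 0.5, 1, 2, 4), function(k)
    richards_value(-13, richards_params(A = 8000, nu = 0.5, k = k, x_i = -13)), 0)
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)

  # moving x_i is exactly a horizontal shift
  p <- fig_params()
  xs <- seq(-16, -10, length.out = 25)
  delta <- 0.7
  p_shift <- richards_params(A = p$A, nu = p$nu, k = p$k, x_i = p$x_i + delta)
  expect_identical(richards_value(xs, p_shift), richards_value(xs - delta, p))
})

test_that("baseline offset: 4PL/5PL reduce to the plain forms at c0 = 0", {
  xs <- seq(-16, -10, length.out = 11)
  p4 <- logistic_params(A = 8000, k = 1, x_c = -13, c0 = 150)
  p0 <- logistic_params(A = 8000, k = 1, x_c = -13)
  expect_equal(logistic_value(xs, p4), logistic_value(xs, p0) + 150)
  p5 <- richards_params(A = 8000, nu = 0.5, k = 1, x_i = -13, c0 = 150)
  expect_equal(richards_value(xs, p5), richards_value(xs, fig_params()) + 150)
  expect_error(richards_params(A = 1, nu = 1, k = 1, x_i = 0, c0 = -2), "c0")
})

test_that("parameter config round-trips through the flat key-value format", {
  p <- richards_params(A = 8000, nu = 0.5, k = 1, x_i = -13, c0 = 2.5)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_params_config(p, path)
  q <- read_params_config(path)
  expect_equal(q[c("A", "nu", "k", "x_i", "c0")], p[c("A", "nu", "k", "x_i", "c0")])

  dp <- double_richards_params(lnC = 9.75, nu1 = 0.08, nu2 = 0.99, k = 1,
                               x_i = -12.92, y_i = -2.97)
  write_params_config(dp, path)
  dq <- read_params_config(path)
  expect_equal(dq[c("lnC", "nu1", "nu2", "k", "x_i", "y_i")],
               dp[c("lnC", "nu1", "nu2", "k", "x_i", "y_i")])
})
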
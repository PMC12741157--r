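# Nonlinear least-squares fitting of the single and double Richards models on
# the ln FI scale. Positivity of nu1, nu2 and k is enforced by fitting their
# logs; standard errors on the natural scale come from the delta method
# applied to the final Jacobian.

# ---- internal parameter vector <-> model objects -----------------------------

theta_names_2d <- function(free_k2) {
  c("lnC", "log_nu1", "x_i", "log_nu2", "y_i", "log_k",
    if (free_k2) "log_k2")
}

theta_to_params_2d <- function(theta) {
  free_k2 <- "log_k2" %in% names(theta)
  double_richards_params(
    lnC = theta[["lnC"]], nu1 = exp(theta[["log_nu1"]]),
    nu2 = exp(theta[["log_nu2"]]), k = exp(theta[["log_k"]]),
    x_i = theta[["x_i"]], y_i = theta[["y_i"]],
    k2 = if (free_k2) exp(theta[["log_k2"]]) else NULL,
    normalized = TRUE)
}

params_to_theta_2d <- function(p, free_k2 = FALSE) {
  th <- c(lnC = p$lnC, log_nu1 = log(p$nu1), x_i = p$x_i,
          log_nu2 = log(p$nu2), y_i = p$y_i, log_k = log(p$k))
  if (free_k2) th <- c(th, log_k2 = log(p$k2))
  th
}

model_mu_2d <- function(theta, x, y) {
  k <- exp(theta[["log_k"]])
  k2 <- if ("log_k2" %in% names(theta)) exp(theta[["log_k2"]]) else k
  theta[["lnC"]] +
    log_norm_factor(x, theta[["x_i"]], exp(theta[["log_nu1"]]), k) +
    log_norm_factor(y, theta[["y_i"]], exp(theta[["log_nu2"]]), k2)
}

# ---- data-driven initialization ---------------------------------------------

# Axis-marginal initialization: median of the distinct design values when the
# design is near-symmetric (|sample skewness| <= 1), otherwise the design value
# whose marginal mean ln FI is nearest the half-rise between the marginal
# extremes.
init_axis_center <- function(vals, lnfi, axis) {
  u <- sort(unique(vals))
  if (length(u) < 2L)
    stop_domain("axis '%s' has fewer than 2 distinct values; cannot initialize a titration fit", axis)
  if (abs(sample_skewness(u)) <= 1) return(stats::median(u))
  marg <- vapply(u, function(v) mean(lnfi[vals == v]), 0)
  half <- min(marg) + 0.5 * (max(marg) - min(marg))
  u[which.min(abs(marg - half))]
}

#' Data-driven starting values for the double Richards fit
#'
#' Builds the starting parameter set the nonlinear fitters use. Central
#' parameters come from medians or relevant quantiles depending on the
#' skewness of the design variables — the inflection abscissas start at the
#' median of the distinct axis values when the axis design is near-symmetric
#' (absolute sample skewness at most 1) and otherwise at the design value
#' closest to the half-rise of the axis-marginal mean ln FI — while both shape
#' parameters start at 1 (the symmetric logistic), the log amplitude at the
#' 0.95 quantile of observed ln FI, and the rate at 1. An alternative
#' derivative-based rule is available behind `rule = "derivative"`: each
#' inflection starts at the axis value with the largest first difference of
#' marginal mean ln FI.
#'
#' @param data A [titration_dataset()] with at least two distinct values on
#'   each axis.
#' @param rule `"quantile"` (default) or `"derivative"`.
#' @return A [double_richards_params()] starting set.
#' @export
init_from_data <- function(data, rule = c("quantile", "derivative")) {
  stopifnot(inherits(data, "titration_dataset"))
  rule <- match.arg(rule)
  d <- fitting_records(data, quiet = TRUE)
  if (nrow(d) == 0L) stop_domain("no records with positive fi")
  lnfi <- log(d$fi)
  center <- function(vals, axis) {
    if (rule == "quantile") return(init_axis_center(vals, lnfi, axis))
    u <- sort(unique(vals))
    if (length(u) < 2L)
      stop_domain("axis '%s' has fewer than 2 distinct values; cannot initialize a titration fit", axis)
    marg <- vapply(u, function(v) mean(lnfi[vals == v]), 0)
    u[which.max(c(diff(marg) / diff(u), -Inf))]
  }
  double_richards_params(
    lnC = stats::quantile(lnfi, 0.95, names = FALSE),
    nu1 = 1, nu2 = 1, k = 1,
    x_i = center(d$x, "x"), y_i = center(d$y, "y"),
    normalized = TRUE)
}

# ---- shared NLS machinery ----------------------------------------------------

run_nlslm <- function(theta0, resid_fn, maxiter = 200L) {
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = 1e-12, ptol = 1e-12))
  theta <- stats::setNames(unlist(fit$par), names(theta0))
  r <- fit$fvec
  n <- length(r); p_free <- length(theta)
  # J'J from a central-difference Jacobian at the solution (the solver's own
  # Gauss-Newton matrix is unreliable at zero-residual optima)
  J <- vapply(seq_len(p_free), function(j) {
    h <- 1e-6 * (1 + abs(theta[j]))
    tp <- tm <- theta; tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (resid_fn(tp) - resid_fn(tm)) / (2 * h)
  }, numeric(n))
  hess <- crossprod(J)
  ev <- tryCatch(eigen(hess, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) rep(NA_real_, p_free))
  cond <- if (all(is.finite(ev)) && min(ev) > 0) max(ev) / min(ev) else Inf
  identifiable <- is.finite(cond) && cond < 1e14
  sigma2 <- sum(r^2) / max(1, n - p_free)
  se <- rep(NA_real_, p_free)
  if (identifiable) {
    vc <- tryCatch(sigma2 * solve(hess), error = function(e) NULL)
    if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  }
  # info codes 1-3 are tolerance-met terminations; 4 (residuals orthogonal to
  # the Jacobian columns) is the usual exit at an exact-interpolation optimum
  list(theta = theta, se = stats::setNames(se, names(theta)),
       rss = sum(r^2), rmse = sqrt(mean(r^2)), niter = fit$niter,
       info = fit$info, message = fit$message,
       converged = fit$info %in% 1:4 && identifiable,
       identifiable = identifiable, condition = cond, n = n)
}

new_fit_result <- function(params, method, estimates, uncertainty, converged,
                           reason, diagnostics, residual_rmse, draws = NULL,
                           model = "double_richards") {
  structure(list(params = params, method = method, estimates = estimates,
                 uncertainty = uncertainty, converged = converged,
                 reason = reason, diagnostics = diagnostics,
                 residual_rmse = residual_rmse, draws = draws, model = model),
            class = "richards_fit")
}

#' @export
print.richards_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s)%s\n", x$model, x$method,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (!is.null(x$reason) && !x$converged) cat("  reason:", x$reason, "\n")
  tab <- data.frame(estimate = x$estimates)
  if (x$method == "nls" && !is.null(x$uncertainty$se))
    tab$std_error <- x$uncertainty$se[rownames(tab)]
  if (x$method == "bayes" && !is.null(x$uncertainty$ci)) {
    tab$q2.5 <- x$uncertainty$ci["2.5%", rownames(tab)]
    tab$q97.5 <- x$uncertainty$ci["97.5%", rownames(tab)]
  }
  print(round(tab, 4))
  cat(sprintf("  residual RMSE (ln FI scale): %.4g\n", x$residual_rmse))
  invisible(x)
}

# ---- the 2-D fitter ----------------------------------------------------------

#' Fit the double Richards model by nonlinear least squares
#'
#' Minimizes the sum of squared residuals of observed ln FI against the
#' normalized double Richards log surface using the Levenberg-Marquardt
#' algorithm. Positivity of the asymmetries and rate is enforced by an
#' internal log reparametrization. The result carries an honest convergence
#' flag: failure to converge within the iteration budget, a rank-deficient
#' final Jacobian (unidentifiable parameters), or a degenerate constant
#' response all yield `converged = FALSE` with the best iterate retained —
#' never an exception.
#'
#' @param data A [titration_dataset()] with at least 2 distinct values on
#'   each axis.
#' @param init Starting [double_richards_params()]; defaults to
#'   [init_from_data()].
#' @param free_k2 Fit a separate serum-axis rate `k2` instead of the
#'   shared-rate default.
#' @param maxiter Levenberg-Marquardt iteration budget.
#' @return An object of class `richards_fit` with elements `params`
#'   (fitted [double_richards_params()]), `estimates` (named vector: `lnC`,
#'   `nu1`, `x_i`, `nu2`, `y_i`, `k`, and `k2` if freed), `uncertainty$se`
#'   (delta-method standard errors), `converged`, `diagnostics` (iterations,
#'   residual norm, Jacobian condition) and `residual_rmse` on the ln FI
#'   scale.
#' @export
fit_nls <- function(data, init = NULL, free_k2 = FALSE, maxiter = 200L) {
  stopifnot(inherits(data, "titration_dataset"))
  d <- fitting_records(data)
  if (nrow(d) == 0L) stop_domain("no records with positive fi")
  if (length(unique(d$x)) < 2L) stop_domain("axis 'x' has fewer than 2 distinct values")
  if (length(unique(d$y)) < 2L) stop_domain("axis 'y' has fewer than 2 distinct values")
  lnfi <- log(d$fi)
  if (stats::sd(lnfi) < 1e-10) {
    p0 <- if (is.null(init)) NULL else init
    return(new_fit_result(p0, "nls", estimates = NULL,
                          uncertainty = list(se = NULL), converged = FALSE,
                          reason = "no inflection identifiable: response is constant",
                          diagnostics = list(), residual_rmse = 0))
  }
  if (is.null(init)) init <- init_from_data(data)
  stopifnot(inherits(init, "double_richards_params"))
  theta0 <- params_to_theta_2d(normalize_amplitude(init, TRUE), free_k2 = free_k2)
  resid_fn <- function(th) {
    th <- stats::setNames(unlist(th), names(theta0))
    lnfi - model_mu_2d(th, d$x, d$y)
  }
  sol <- run_nlslm(theta0, resid_fn, maxiter)
  params <- theta_to_params_2d(sol$theta)
  est <- c(lnC = params$lnC, nu1 = params$nu1, x_i = params$x_i,
           nu2 = params$nu2, y_i = params$y_i, k = params$k)
  se <- c(lnC = sol$se[["lnC"]], nu1 = params$nu1 * sol$se[["log_nu1"]],
          x_i = sol$se[["x_i"]], nu2 = params$nu2 * sol$se[["log_nu2"]],
          y_i = sol$se[["y_i"]], k = params$k * sol$se[["log_k"]])
  if (free_k2) {
    est <- c(est, k2 = params$k2)
    se <- c(se, k2 = params$k2 * sol$se[["log_k2"]])
  }
  reason <- if (sol$converged) NULL
  else if (!sol$identifiable) "rank-deficient Jacobian: parameters not identifiable from this design"
  else sprintf("Levenberg-Marquardt stopped without convergence (info %d: %s)", sol$info, sol$message)
  new_fit_result(params, "nls", est, list(se = se), sol$converged, reason,
                 diagnostics = list(niter = sol$niter, rss = sol$rss,
                                    info = sol$info, condition = sol$condition,
                                    n = sol$n),
                 residual_rmse = sol$rmse)
}

# ---- the 1-D fitter ----------------------------------------------------------

#' Fit a single Richards titration curve
#'
#' For data in which only one axis varies (serum-only or antigen-only
#' titration), fits the log Richards curve
#' \eqn{\ln FI = \ln A - (1/\nu)\ln(1 + \nu e^{-k(z - z_i)})} on the varying
#' axis by Levenberg-Marquardt, optionally with an additive baseline `c0`
#' (the 5PL form) or with the asymmetry fixed (e.g. `nu_fixed = 1` for a
#' logistic fit). Same convergence contract as [fit_nls()].
#'
#' @param data A [titration_dataset()] with exactly one varying axis.
#' @param init Optional starting [richards_params()]; a data-driven start is
#'   built otherwise.
#' @param nu_fixed Optional fixed asymmetry value (> 0); when given, `nu` is
#'   not estimated.
#' @param baseline Estimate an additive baseline `c0 >= 0` (5PL).
#' @param maxiter Iteration budget.
#' @return A `richards_fit` with `estimates` `A`, `nu`, `k`, `x_i` (plus
#'   `c0` when `baseline = TRUE`); `params` is a [richards_params()].
#' @export
fit_single <- function(data, init = NULL, nu_fixed = NULL, baseline = FALSE,
                       maxiter = 200L) {
  stopifnot(inherits(data, "titration_dataset"))
  d <- fitting_records(data)
  if (nrow(d) == 0L) stop_domain("no records with positive fi")
  x_varies <- length(unique(d$x)) > 1L
  y_varies <- length(unique(d$y)) > 1L
  if (x_varies && y_varies)
    stop_domain("both axes vary: use fit_nls() for two-dimensional titration data")
  if (!x_varies && !y_varies)
    stop_domain("neither axis varies; nothing to fit")
  z <- if (x_varies) d$x else d$y
  lnfi <- log(d$fi)
  if (stats::sd(lnfi) < 1e-10)
    return(new_fit_result(init, "nls", NULL, list(se = NULL), FALSE,
                          "no inflection identifiable: response is constant",
                          list(), 0, model = "richards"))
  if (!is.null(nu_fixed)) check_positive(nu_fixed, "nu_fixed")
  if (is.null(init)) {
    u <- sort(unique(z))
    init <- richards_params(A = exp(stats::quantile(lnfi, 0.95, names = FALSE)),
                            nu = if (is.null(nu_fixed)) 1 else nu_fixed,
                            k = 1, x_i = init_axis_center(z, lnfi, if (x_varies) "x" else "y"))
  }
  stopifnot(inherits(init, "richards_params"))
  free_nu <- is.null(nu_fixed)
  theta0 <- c(lnA = log(init$A),
              if (free_nu) c(log_nu = log(init$nu)),
              log_k = log(init$k), x_i = init$x_i,
              if (baseline) c(log_c0 = log(max(init$c0, 1e-3 * init$A))))
  mu_fn <- function(th) {
    A <- exp(th[["lnA"]])
    nu <- if (free_nu) exp(th[["log_nu"]]) else nu_fixed
    k <- exp(th[["log_k"]])
    lr <- if (nu < NU_GOMPERTZ_SWITCH) -exp(-k * (z - th[["x_i"]]))
    else -log1pexp(log(nu) - k * (z - th[["x_i"]])) / nu
    if (baseline) log(exp(th[["log_c0"]]) + A * exp(lr)) else th[["lnA"]] + lr
  }
  resid_fn <- function(th) {
    th <- stats::setNames(unlist(th), names(theta0))
    lnfi - mu_fn(th)
  }
  sol <- run_nlslm(theta0, resid_fn, maxiter)
  A <- exp(sol$theta[["lnA"]])
  nu <- if (free_nu) exp(sol$theta[["log_nu"]]) else nu_fixed
  k <- exp(sol$theta[["log_k"]])
  c0 <- if (baseline) exp(sol$theta[["log_c0"]]) else 0
  params <- richards_params(A = A, nu = nu, k = k, x_i = sol$theta[["x_i"]], c0 = c0)
  est <- c(A = A, nu = nu, k = k, x_i = sol$theta[["x_i"]])
  se <- c(A = A * sol$se[["lnA"]],
          nu = if (free_nu) nu * sol$se[["log_nu"]] else 0,
          k = k * sol$se[["log_k"]], x_i = sol$se[["x_i"]])
  if (baseline) {
    est <- c(est, c0 = c0)
    se <- c(se, c0 = c0 * sol$se[["log_c0"]])
  }
  reason <- if (sol$converged) NULL
  else if (!sol$identifiable) "rank-deficient Jacobian: upper limit or shape not identifiable from this design"
  else sprintf("Levenberg-Marquardt stopped without convergence (info %d: %s)", sol$info, sol$message)
  new_fit_result(params, "nls", est, list(se = se), sol$converged, reason,
                 diagnostics = list(niter = sol$niter, rss = sol$rss,
                                    info = sol$info, condition = sol$condition,
                                    n = sol$n, axis = if (x_varies) "x" else "y"),
                 residual_rmse = sol$rmse, model = "richards")
}

# ---- residual summaries ------------------------------------------------------

#' Residual summaries on the ln FI scale
#'
#' RMSE, mean residual and per-axis residual trends (least-squares slope of
#' residual against each axis) of a dataset under given parameters.
#'
#' @param data A [titration_dataset()].
#' @param params A [double_richards_params()] or [richards_params()] (the
#'   varying axis is detected for the latter).
#' @return A list with `rmse`, `mean_residual`, `trend_x`, `trend_y`, `n`.
#' @export
goodness <- function(data, params) {
  stopifnot(inherits(data, "titration_dataset"))
  d <- fitting_records(data, quiet = TRUE)
  lnfi <- log(d$fi)
  mu <- if (inherits(params, "double_richards_params")) {
    log_double_normalized(d$x, d$y, params)
  } else if (inherits(params, "richards_params")) {
    z <- if (length(unique(d$x)) > 1L) d$x else d$y
    log(richards_value(z, params))
  } else stop_domain("'params' must be Richards or double Richards parameters")
  r <- lnfi - mu
  slope <- function(v) if (stats::var(v) > 0) stats::cov(v, r) / stats::var(v) else 0
  list(rmse = sqrt(mean(r^2)), mean_residual = mean(r),
       trend_x = slope(d$x), trend_y = slope(d$y), n = length(r))
}
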
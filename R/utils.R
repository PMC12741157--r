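# Internal numeric helpers shared across the package.

# log(1 + exp(u)) without overflow for large u or cancellation for small u.
log1pexp <- function(u) {
  out <- u
  lo <- u <= 18
  out[lo] <- log1p(exp(u[lo]))
  mid <- u > 18 & u < 33.3
  out[mid] <- u[mid] + exp(-u[mid])
  out
}

# Moment-based sample skewness (biased form; only the |skewness| <= 1 cut matters).
sample_skewness <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 3L) return(0)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) return(0)
  mean((v - m)^3) / s^3
}

stop_domain <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    stop_domain("parameter '%s' must be a single positive finite number", name)
  invisible(value)
}

check_real <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop_domain("parameter '%s' must be a single finite number", name)
  invisible(value)
}

# Asymmetry values below this switch evaluation to the Gompertz limit form,
# avoiding catastrophic cancellation in (.)^(-1/nu).
NU_GOMPERTZ_SWITCH <- 1e-6
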
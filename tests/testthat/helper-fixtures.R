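# Shared fixtures, built in code.

# The reference single-curve parameter set used throughout the curve tests:
# A = 8000, nu = 0.5, k = 1, x_i = -13, on the ln-concentration range [-15, -11].
fig_params <- function() richards_params(A = 8000, nu = 0.5, k = 1, x_i = -13)

# The two built-in reference rows of the normalized double Richards model.
ref_row <- function(which = "nls") {
  if (which == "nls") c(lnC = 9.75, nu1 = 0.08, x_i = -12.92, nu2 = 0.99, y_i = -2.97)
  else c(lnC = 9.77, nu1 = 0.09, x_i = -12.93, nu2 = 1.00, y_i = -2.93)
}

# Random valid Richards parameter draws for property-style loops.
random_richards <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    richards_params(A = exp(runif(1, 2, 10)), nu = exp(runif(1, -2.3, 1.6)),
                    k = exp(runif(1, -1.4, 1.4)), x_i = runif(1, -16, -8)))
}
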
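# Independent oracles used across the suite.

# Brute-force (weighted) normal equations: slope of w on x with intercept
# and optional extra covariate columns, solved directly.
ne_slope <- function(x, w, weights = NULL, covars = NULL) {
  X <- cbind(1, x)
  if (!is.null(covars)) X <- cbind(X, covars)
  if (is.null(weights)) weights <- rep(1, length(x))
  A <- t(X) %*% (X * weights)
  unname(drop(solve(A, t(X) %*% (weights * w))))[2L]
}

# Adaptive-quadrature integral over the real line.
quad <- function(f, lower = -Inf, upper = Inf) {
  stats::integrate(f, lower, upper, rel.tol = 1e-11,
                   abs.tol = 1e-13)$value
}

probit_m <- function(alpha, bw, bx) outcome_model("probit", alpha, bw, bx)
linear_m <- function(alpha, bw, bx) outcome_model("linear", alpha, bw, bx)

# A reproducible case-control fixture with both strata.
fixture_sample <- function(n = 40L, seed = 42L) {
  set.seed(seed)
  x <- rnorm(n)
  w <- 0.5 * x + rnorm(n, sd = sqrt(0.75))
  y <- rep(0:1, length.out = n)
  cc_sample(x, w, y)
}
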
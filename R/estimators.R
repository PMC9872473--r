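# Weighted least-squares slope with classical and sandwich standard errors.
# Coefficients come from stats::lm.wfit (the standard QR least-squares
# routine); the two SE formulas are computed directly from its output.
wls_slope <- function(X, w, weights = NULL) {
  n <- nrow(X)
  if (n < 3L)
    stop("need at least 3 observations for a slope fit", call. = FALSE)
  fit <- if (is.null(weights)) stats::lm.fit(X, w) else stats::lm.wfit(X, w, weights)
  if (fit$rank < ncol(X))
    stop("degenerate design: regressors are collinear (is Var(x) = 0?)",
         call. = FALSE)
  k <- ncol(X)
  e <- fit$residuals
  if (is.null(weights)) {
    XtXinv <- chol2inv(chol(crossprod(X)))
    sigma2 <- sum(e^2) / (n - k)
    se <- sqrt(sigma2 * diag(XtXinv))
    list(coef = fit$coefficients, se = se, se_sandwich = NULL, n = n)
  } else {
    Xw <- X * weights
    XtXinv <- chol2inv(chol(crossprod(X, Xw)))
    meat <- crossprod(X * (weights * e))
    V <- XtXinv %*% meat %*% XtXinv
    list(coef = fit$coefficients, se = sqrt(diag(V)),
         se_sandwich = sqrt(diag(V)), n = n)
  }
}

subset_idx <- function(sample, subset) {
  switch(subset,
         all = seq_len(nrow(sample)),
         cases = which(sample$y == 1L),
         controls = which(sample$y == 0L))
}

#' Ordinary least-squares slope of W on X on a stratum
#'
#' Fits the simple linear regression of `w` on `x` (with intercept) over the
#' full sample, cases only, or controls only, with the classical
#' large-sample standard error. Under case-control sampling the stratified
#' fits are downward biased whenever W carries its own effect on case
#' status; see [reconstruct_slope()].
#'
#' @param sample A [cc_sample()].
#' @param subset `"all"`, `"cases"`, or `"controls"`.
#' @return A one-row data frame (class `"cc_estimate"`) with columns
#'   `method`, `estimate`, `stderr`, `n_used`.
#' @export
#' @examples
#' s <- cc_sample(x = rnorm(20), w = rnorm(20), y = rep(0:1, 10))
#' ols_slope(s, "controls")
ols_slope <- function(sample, subset = c("all", "cases", "controls")) {
  subset <- match.arg(subset)
  idx <- subset_idx(sample, subset)
  if (length(idx) < 3L)
    stop(sprintf("subset '%s' has fewer than 3 observations", subset),
         call. = FALSE)
  x <- sample$x[idx]
  if (stats::var(x) == 0)
    stop("degenerate design: Var(x) = 0 on the requested subset", call. = FALSE)
  f <- wls_slope(cbind(1, x), sample$w[idx])
  label <- switch(subset, all = "pooled", cases = "cases_only",
                  controls = "controls_only")
  new_estimate(label, f$coef[2L], f$se[2L], f$n)
}

#' Slope of W on X adjusting for case-control status
#'
#' Coefficient of `x` in the least-squares fit of `w` on `(x, y)`; the
#' within-stratum slope pooled across strata by their x-variation.
#'
#' @inheritParams ols_slope
#' @return A `"cc_estimate"` row with method `"adjusted"`.
#' @export
adjusted_slope <- function(sample) {
  if (attr(sample, "n_cases") == 0L || attr(sample, "n_controls") == 0L)
    stop("adjusted fit requires both cases and controls", call. = FALSE)
  f <- wls_slope(cbind(1, sample$x, sample$y), sample$w)
  new_estimate("adjusted", f$coef[2L], f$se[2L], f$n)
}

#' Pooled slope of W on X ignoring case-control status
#'
#' The naive fit over everyone, as if the sample were a random draw from the
#' population. In the reference simulations this estimator is remarkably
#' stable, with only a small upward bias when cases are rare.
#'
#' @inheritParams ols_slope
#' @return A `"cc_estimate"` row with method `"pooled"`.
#' @export
pooled_slope <- function(sample) {
  ols_slope(sample, "all")
}

#' Inverse-probability-weighted slope of W on X
#'
#' Weighted least squares with weights proportional to
#' `pi / f1` for cases and `(1 - pi) / f0` for controls, where `f1`, `f0`
#' are the sample stratum fractions - i.e. reweighting the sample back to a
#' population with case proportion `pi`. When the realized population
#' stratum counts are known (as in simulation), `pop_counts = c(N1, N0)`
#' uses the exact selection probabilities `n1/N1`, `n0/N0` instead. Weights
#' are normalized to sum to one; the slope is invariant to any positive
#' rescaling of the weights. The standard error is heteroscedasticity-robust
#' (sandwich).
#'
#' @inheritParams ols_slope
#' @param pi Assumed population case proportion, in (0, 1).
#' @param pop_counts Optional integer pair `c(N1, N0)` of population stratum
#'   sizes; overrides `pi`.
#' @return A `"cc_estimate"` row with method `"ipw"`.
#' @export
ipw_slope <- function(sample, pi = NULL, pop_counts = NULL) {
  n1 <- attr(sample, "n_cases"); n0 <- attr(sample, "n_controls")
  if (n1 == 0L || n0 == 0L)
    stop("IPW requires both cases and controls", call. = FALSE)
  if (!is.null(pop_counts)) {
    stopifnot(length(pop_counts) == 2L, all(pop_counts >= c(n1, n0)))
    w_case <- pop_counts[1L] / n1
    w_ctrl <- pop_counts[2L] / n0
  } else {
    if (is.null(pi) || !is.numeric(pi) || pi <= 0 || pi >= 1)
      stop("pi must be supplied in (0, 1) unless pop_counts is given",
           call. = FALSE)
    n <- n1 + n0
    w_case <- pi / (n1 / n)
    w_ctrl <- (1 - pi) / (n0 / n)
  }
  wt <- ifelse(sample$y == 1L, w_case, w_ctrl)
  wt <- wt / sum(wt)
  f <- wls_slope(cbind(1, sample$x), sample$w, weights = wt)
  new_estimate("ipw", f$coef[2L], f$se[2L], f$n)
}

#' Between-groups slope from stratum mean differences
#'
#' `(mean(w | cases) - mean(w | controls)) / (mean(x | cases) -
#' mean(x | controls))`. Valid as an estimate of `beta_WX` when case status
#' is conditionally independent of W given X. Its variance is computed
#' conditionally on x as `sigma^2_{W.X} (1/n1 + 1/n0) / (xbar1 - xbar0)^2`,
#' with the residual variance pooled across strata.
#'
#' @inheritParams ols_slope
#' @param tol Relative guard on the denominator: an error is raised when
#'   `|xbar1 - xbar0| < tol * sd(x)`.
#' @return A `"cc_estimate"` row with method `"between_groups"`.
#' @export
between_groups_slope <- function(sample, tol = 1e-8) {
  n1 <- attr(sample, "n_cases"); n0 <- attr(sample, "n_controls")
  if (n1 == 0L || n0 == 0L)
    stop("between-groups estimate requires both strata", call. = FALSE)
  x1 <- sample$x[sample$y == 1L]; x0 <- sample$x[sample$y == 0L]
  w1 <- sample$w[sample$y == 1L]; w0 <- sample$w[sample$y == 0L]
  dx <- mean(x1) - mean(x0)
  if (abs(dx) < tol * stats::sd(sample$x))
    stop("stratum means of x are too close: between-groups ratio unstable",
         call. = FALSE)
  est <- (mean(w1) - mean(w0)) / dx
  # pooled residual variance about the within-stratum regressions
  s2 <- pooled_resid_var(sample)
  se <- sqrt(s2 * (1 / n1 + 1 / n0)) / abs(dx)
  new_estimate("between_groups", est, se, n1 + n0)
}

# Residual variance of w about x pooled across the two strata (residuals of
# the fit of w on x and stratum indicator; df = n - 3).
pooled_resid_var <- function(sample) {
  fit <- stats::lm.fit(cbind(1, sample$x, sample$y), sample$w)
  sum(fit$residuals^2) / (nrow(sample) - 3L)
}

#' Combined estimator for the conditionally independent case
#'
#' When case status is conditionally independent of W given X there are
#' three asymptotically independent sources of information on `beta_WX`:
#' the within-cases slope, the within-controls slope, and the
#' between-groups ratio of stratum mean differences. The combined estimate
#' is their inverse-variance weighted mean, with combined variance
#' `1 / sum(1 / v_i)`. A consistency statistic (the maximum absolute
#' pairwise standardized difference between components) is attached for the
#' informal check that the three agree; the caller asserts the
#' conditional-independence regime.
#'
#' @inheritParams ols_slope
#' @return A `"cc_estimate"` row with method `"combined"`; attributes
#'   `components` (the three component estimates) and `consistency`
#'   (max |b_i - b_j| / sqrt(v_i + v_j)).
#' @export
combined_ci_estimator <- function(sample) {
  comp <- rbind(ols_slope(sample, "cases"),
                ols_slope(sample, "controls"),
                between_groups_slope(sample))
  b <- comp$estimate; v <- comp$stderr^2
  wts <- 1 / v
  est <- sum(wts * b) / sum(wts)
  var_c <- 1 / sum(wts)
  pairs <- utils::combn(3L, 2L)
  z <- abs(b[pairs[1L, ]] - b[pairs[2L, ]]) /
    sqrt(v[pairs[1L, ]] + v[pairs[2L, ]])
  out <- new_estimate("combined", est, sqrt(var_c), nrow(sample))
  attr(out, "components") <- comp
  attr(out, "consistency") <- max(z)
  out
}

#' Reconstruct the population slope of W on X from a case-control sample
#'
#' Inverts a selection-bias formula to recover the population regression
#' coefficient `beta_WX` from a stratum slope estimate, given an externally
#' supplied population case proportion `pi` (which cannot be estimated from
#' the case-control sample itself). The recipe:
#' \enumerate{
#'   \item Nuisance coefficients `(beta_YW_X, beta_YX_W)` from a logistic fit
#'     of `y` on `(w, x)` over the whole sample (slope coefficients are
#'     invariant under case-control sampling), optionally rescaled to the
#'     probit scale by `scale` (default 1; `1/1.6` is the conventional
#'     logistic-to-probit factor);
#'   \item `sigma^2_{W.X}` from the residual variance of `w` on `x` in the
#'     stratum named by `sigma_source` (default controls, which approximate
#'     the population when cases are rare);
#'   \item `alpha = -gamma * qnorm(pi)` via [alpha_from_pi()], with `gamma`
#'     recomputed from the running solution since `beta_YX` depends on the
#'     unknown `beta_WX`;
#'   \item solve `b_target = beta* + correction(beta*)` for `beta*` by a
#'     damped fixed-point iteration, where `b_target` is the slope named by
#'     `target` and the correction is either the rare-case linear
#'     approximation (`correction = "mills"`, see [slope_rare_approx()]:
#'     `(beta_YX_W + beta_YW_X beta*) sigma alpha / tau^2`) or the exact
#'     selection-model slope displacement (`correction = "slope"`, see
#'     [slope_exact()]).
#' }
#' `"mills"` round-trips [slope_rare_approx()] exactly when the true
#' nuisances are supplied, but - inheriting that formula's sign - moves the
#' estimate downward and so cannot de-bias the downward-biased cases-only
#' slope; `"slope"` corrects in the empirically right direction and is what
#' the simulation harness reports. The standard error is delta-method,
#' treating the nuisance parameters as fixed.
#'
#' @inheritParams ols_slope
#' @param pi Population case proportion, in (0, 1). Required.
#' @param correction `"mills"` or `"slope"`; see Details.
#' @param scale Multiplier applied to the logistic nuisance coefficients
#'   (default 1; use `1/1.6` to map to the probit scale).
#' @param sigma_source `"controls"` or `"pooled"`: stratum whose residual
#'   variance estimates `sigma^2_{W.X}`.
#' @param target `"cases"` or `"controls"`: stratum slope to be corrected.
#' @param nuisance Optional list with elements `beta_YW_X`, `beta_YX_W`
#'   (already on the probit scale) replacing the logistic fit.
#' @return A `"cc_estimate"` row with method `"reconstructed"`; attribute
#'   `details` carries the nuisance values, `alpha`, `tau2` and the target
#'   slope actually corrected.
#' @export
reconstruct_slope <- function(sample, pi,
                              correction = c("mills", "slope"),
                              scale = 1,
                              sigma_source = c("controls", "pooled"),
                              target = c("cases", "controls"),
                              nuisance = NULL) {
  correction <- match.arg(correction)
  sigma_source <- match.arg(sigma_source)
  target <- match.arg(target)
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1)
    stop("pi must be a single number in (0, 1)", call. = FALSE)

  if (is.null(nuisance)) {
    gf <- stats::glm.fit(cbind(1, sample$w, sample$x), sample$y,
                         family = stats::binomial())
    b_w <- gf$coefficients[2L] * scale
    b_x <- gf$coefficients[3L] * scale
  } else {
    b_w <- nuisance$beta_YW_X
    b_x <- nuisance$beta_YX_W
  }

  s2 <- if (sigma_source == "controls") {
    idx <- sample$y == 0L
    fit <- stats::lm.fit(cbind(1, sample$x[idx]), sample$w[idx])
    sum(fit$residuals^2) / (sum(idx) - 2L)
  } else pooled_resid_var(sample)

  if (!is.null(nuisance) && !is.null(nuisance$sigma2_W_given_X))
    s2 <- nuisance$sigma2_W_given_X

  tgt <- ols_slope(sample, target)
  sol <- invert_slope_correction(tgt$estimate, pi, b_w, b_x, s2,
                                 correction = correction)
  se <- tgt$stderr / abs(sol$unit_coef)

  out <- new_estimate("reconstructed", sol$beta, se, nrow(sample))
  attr(out, "details") <- c(sol[c("beta_YW_X", "beta_YX_W",
                                  "sigma2_W_given_X", "alpha", "tau2",
                                  "beta_YX")],
                            list(target_slope = tgt$estimate,
                                 correction = correction))
  out
}

#' Invert a selection-bias slope correction
#'
#' Solves `b_target = beta* + correction(beta*)` for the population slope
#' `beta*`, the algebraic core of [reconstruct_slope()]. The correction term
#' depends on `beta*` through the marginal coefficient
#' `beta_YX = beta_YX_W + beta_YW_X beta*` and through
#' `alpha = -gamma * qnorm(pi)`; the solution is found by iterating the
#' exact linear solve at the current `alpha` to a fixed point. For
#' `correction = "mills"` this is the exact algebraic inverse of
#' [slope_rare_approx()]: feeding that formula's output back with the true
#' nuisance parameters recovers `beta*` to machine precision.
#'
#' @param b_target Observed stratum slope to be corrected.
#' @param pi Population case proportion, in (0, 1).
#' @param beta_YW_X,beta_YX_W Nuisance coefficients on the probit scale.
#' @param sigma2_W_given_X Residual variance of W given X.
#' @param correction `"mills"` (rare-case linear form, gamma in its
#'   conventional form) or `"slope"` (exact selection-model slope
#'   displacement, gamma in its marginal form).
#' @return List with `beta` (the solution), `alpha`, `tau2`, `beta_YX`,
#'   `unit_coef` (the coefficient of `beta*` in the final linear solve, used
#'   for the delta-method standard error), and the nuisance values.
#' @export
invert_slope_correction <- function(b_target, pi, beta_YW_X, beta_YX_W,
                                    sigma2_W_given_X,
                                    correction = c("mills", "slope")) {
  correction <- match.arg(correction)
  b_w <- beta_YW_X; b_x <- beta_YX_W; s2 <- sigma2_W_given_X
  tau2 <- 1 + b_w^2 * s2
  beta <- b_target
  alpha <- NA_real_; cpart <- NA_real_
  for (it in seq_len(200L)) {
    byx <- b_x + b_w * beta
    gamma <- if (correction == "mills") sqrt(1 + tau2 + byx^2)
             else sqrt(tau2 + byx^2)
    alpha <- alpha_from_pi(pi, gamma)
    cpart <- if (correction == "mills")
      sqrt(s2) * alpha / tau2
    else
      s2 * b_w / tau2 * mills_lambda_prime(-alpha / sqrt(tau2))
    denom <- 1 + b_w * cpart
    if (abs(denom) < 1e-10)
      stop("reconstruction has no solution: unit coefficient of beta* ",
           "vanishes", call. = FALSE)
    beta_new <- (b_target - b_x * cpart) / denom
    done <- abs(beta_new - beta) < 1e-14
    beta <- beta_new
    if (done) break
  }
  if (alpha <= 0)
    warning("alpha <= 0: rare-case correction regime violated", call. = FALSE)
  list(beta = beta, alpha = alpha, tau2 = tau2,
       beta_YX = b_x + b_w * beta, unit_coef = 1 + b_w * cpart,
       beta_YW_X = b_w, beta_YX_W = b_x, sigma2_W_given_X = s2)
}
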
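#' Marginal coefficient of X in the outcome model
#'
#' Collapses the two partial coefficients into the marginal coefficient of X
#' on Y using the population regression of W on X:
#' `beta_YX = beta_YX_W + beta_YW_X * beta_WX`.
#'
#' @param model An [outcome_model()].
#' @param pop A [population_joint()].
#' @return The marginal coefficient `beta_YX` (numeric scalar).
#' @export
marginal_beta_yx <- function(model, pop) {
  model$beta_YX_W + model$beta_YW_X * pop$beta_WX
}

#' Derived probit-model quantities tau, gamma and the marginal case probability
#'
#' For the probit outcome model, `tau^2 = 1 + beta_YW_X^2 * sigma^2_{W.X}` is
#' the variance inflation from marginalizing over W given X, and the marginal
#' case probability is `P(Y = 1) = pnorm(-alpha / gamma)`. Two conventions for
#' `gamma^2` are offered:
#' \describe{
#'   \item{`"standard"`}{`gamma^2 = 1 + tau^2 + beta_YX^2` (the conventional
#'     definition used by the selection formulas in this package).}
#'   \item{`"marginal"`}{`gamma^2 = tau^2 + beta_YX^2 * var_X`, the value for
#'     which `pnorm(-alpha / gamma)` is exactly the marginal probability when
#'     X is normal; the standard form carries an extra unit term.}
#' }
#'
#' @inheritParams marginal_beta_yx
#' @param gamma2_form `"standard"` or `"marginal"`; see Details.
#' @return A list with elements `beta_YX`, `tau2`, `tau`, `gamma2`, `gamma`,
#'   `pi` (the marginal case probability `pnorm(-alpha / gamma)`).
#' @export
#' @examples
#' m <- outcome_model("probit", alpha = 2, beta_YW_X = 1, beta_YX_W = 1)
#' p <- population_joint(0.5, 0.75)
#' tau_gamma(m, p)
tau_gamma <- function(model, pop, gamma2_form = c("standard", "marginal")) {
  gamma2_form <- match.arg(gamma2_form)
  if (model$link != "probit")
    stop("tau and gamma are defined for the probit link only", call. = FALSE)
  beta_YX <- marginal_beta_yx(model, pop)
  tau2 <- 1 + model$beta_YW_X^2 * pop$sigma2_W_given_X
  gamma2 <- switch(gamma2_form,
                   standard = 1 + tau2 + beta_YX^2,
                   marginal = tau2 + beta_YX^2 * pop$var_X)
  gamma <- sqrt(gamma2)
  list(beta_YX = beta_YX, tau2 = tau2, tau = sqrt(tau2),
       gamma2 = gamma2, gamma = gamma,
       pi = stats::pnorm(-model$alpha / gamma))
}

#' Inverse Mills-type ratio lambda(z) = phi(z) / Phi(z)
#'
#' The mean-shift factor of a normal variate conditioned on a probit
#' selection event. Evaluated in log space so it is finite and accurate for
#' strongly negative arguments (at least to `z = -40`), where the naive
#' ratio underflows. Strictly positive, strictly decreasing, and
#' `lambda(z) ~ -z` as `z -> -Inf`.
#'
#' @param z Numeric vector.
#' @return `dnorm(z) / pnorm(z)`, elementwise.
#' @export
#' @examples
#' mills_lambda(0)      # sqrt(2 / pi)
#' mills_lambda(-10)    # close to 10
mills_lambda <- function(z) {
  exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
}

# derivative of mills_lambda; always in (-1, 0)
mills_lambda_prime <- function(z) {
  l <- mills_lambda(z)
  -l * (z + l)
}

# Shared guts: evaluate the linear-in-probability factors for stratum y.
lp_factors <- function(w, x, y, model, pop) {
  if (model$link != "linear")
    stop("linear-in-probability operation requires link = 'linear'", call. = FALSE)
  m <- if (y == 1) model else controls_model(model, "linear")
  num <- m$alpha + m$beta_YX_W * x + m$beta_YW_X * w
  den <- m$alpha + marginal_beta_yx(m, pop) * x
  list(num = num, den = den)
}

#' Conditional density of W given X within a stratum, linear model
#'
#' Under the linear-in-probability outcome model the density of W given
#' `X = x` among cases is the population conditional density tilted by the
#' selection factor:
#' `f(w | x, y=1) = f(w | x) * (alpha + beta_YX_W x + beta_YW_X w) /
#' (alpha + beta_YX x)`. For controls replace `alpha` by `1 - alpha` and
#' reverse the signs of the regression coefficients. The linear model is
#' meaningful only where the probability factor lies in (0, 1); a negative
#' factor at the evaluation point is a hard error, never silently clipped.
#'
#' @param w,x Evaluation point (scalars; `w` may be a vector).
#' @param y Stratum: 1 for cases, 0 for controls.
#' @inheritParams marginal_beta_yx
#' @param base_density Function of `(w, x)` giving the population conditional
#'   density of W given X. Default: normal with mean `beta_WX * x` and
#'   variance `sigma2_W_given_X`.
#' @return Density value(s).
#' @export
lp_cond_density <- function(w, x, y, model, pop, base_density = NULL) {
  stopifnot(y %in% c(0, 1))
  if (is.null(base_density))
    base_density <- function(w, x)
      stats::dnorm(w, pop$beta_WX * x, sqrt(pop$sigma2_W_given_X))
  fac <- lp_factors(w, x, y, model, pop)
  if (any(fac$num < 0) || fac$den <= 0)
    stop("linear-in-probability factor negative at the evaluation point; ",
         "the model is invalid there", call. = FALSE)
  base_density(w, x) * fac$num / fac$den
}

#' Conditional mean of W given X within a stratum, linear model
#'
#' The selection-displaced conditional mean under the linear-in-probability
#' model: `beta_WX * x + beta_YW_X * sigma^2_{W.X} / (alpha + beta_YX * x)`
#' for cases, with the usual control substitution. Same slope as the
#' population line, displaced intercept.
#'
#' @inheritParams lp_cond_density
#' @return The conditional mean (numeric scalar).
#' @export
lp_cond_mean <- function(x, y, model, pop) {
  stopifnot(y %in% c(0, 1))
  if (model$link != "linear")
    stop("linear-in-probability operation requires link = 'linear'", call. = FALSE)
  m <- if (y == 1) model else controls_model(model, "linear")
  den <- m$alpha + marginal_beta_yx(m, pop) * x
  if (den <= 0)
    stop("stratum probability at x is not positive; model invalid there",
         call. = FALSE)
  pop$beta_WX * x + m$beta_YW_X * pop$sigma2_W_given_X / den
}

#' Case probability given X under the probit model
#'
#' Integrating the probit outcome model over the normal conditional law of W
#' given X gives `P(Y = 1 | X = x) = pnorm((-alpha + beta_YX * x) / tau)`.
#'
#' @param x Covariate value(s).
#' @inheritParams marginal_beta_yx
#' @return Probability value(s).
#' @export
probit_prob_given_x <- function(x, model, pop) {
  tg <- tau_gamma(model, pop)
  stats::pnorm((-model$alpha + tg$beta_YX * x) / tg$tau)
}

#' Marginal case probability under the probit model
#'
#' `P(Y = 1) = pnorm(-alpha / gamma)`; see [tau_gamma()] for the two
#' conventions for gamma.
#'
#' @inheritParams tau_gamma
#' @return Probability (scalar).
#' @export
probit_marginal_prob <- function(model, pop, gamma2_form = "standard") {
  tau_gamma(model, pop, gamma2_form)$pi
}

#' Probit intercept matching a given marginal case probability
#'
#' Inverts `P(Y = 1) = pnorm(-alpha / gamma)`: `alpha = -gamma * qnorm(pi)`.
#' Round-trips through [probit_marginal_prob()] to machine precision.
#'
#' @param pi Marginal case probability, in (0, 1).
#' @param gamma Scale factor gamma (> 0), e.g. from [tau_gamma()].
#' @return The intercept alpha.
#' @export
alpha_from_pi <- function(pi, gamma) {
  if (!is.numeric(pi) || any(pi <= 0) || any(pi >= 1))
    stop("pi must lie strictly in (0, 1)", call. = FALSE)
  stopifnot(gamma > 0)
  -gamma * stats::qnorm(pi)
}

#' Conditional density of W given X within a stratum, probit model
#'
#' For cases,
#' `f(w | x, 1) = f(w | x) * pnorm(-alpha + beta_YW_X w + beta_YX_W x) /
#' pnorm((-alpha + beta_YX x) / tau)` with a normal base density; for
#' controls both normal probabilities are replaced by their complements.
#' All factors are combined in log space so extreme intercepts do not
#' underflow.
#'
#' @inheritParams lp_cond_density
#' @return Density value(s).
#' @export
probit_cond_density <- function(w, x, y, model, pop) {
  stopifnot(y %in% c(0, 1))
  if (model$link != "probit")
    stop("probit operation requires link = 'probit'", call. = FALSE)
  tg <- tau_gamma(model, pop)
  s <- sqrt(pop$sigma2_W_given_X)
  lower <- (y == 0)  # complements for the control stratum
  log_num <- stats::pnorm(-model$alpha + model$beta_YW_X * w + model$beta_YX_W * x,
                          lower.tail = !lower, log.p = TRUE)
  log_den <- stats::pnorm((-model$alpha + tg$beta_YX * x) / tg$tau,
                          lower.tail = !lower, log.p = TRUE)
  exp(stats::dnorm(w, pop$beta_WX * x, s, log = TRUE) + log_num - log_den)
}

#' First-order mean shift under probit selection
#'
#' Leading-order expansion of the stratum conditional mean for standardized
#' variables and small outcome coefficients:
#' `E(W | X = x, Y = 1) = beta_WX * x + lambda(-alpha) * beta_YW_X *
#' sigma^2_{W.X} + O(beta_Y^2)`. For controls the sign of `beta_YW_X` is
#' reversed and `alpha` replaced by `1 - alpha`. With rare cases
#' (`alpha > 0`) the case-stratum displacement is much larger than the
#' control-stratum one.
#'
#' @inheritParams lp_cond_density
#' @return The approximate conditional mean (numeric scalar).
#' @export
first_order_mean_shift <- function(x, y, model, pop) {
  stopifnot(y %in% c(0, 1))
  if (model$link != "probit")
    stop("probit operation requires link = 'probit'", call. = FALSE)
  m <- if (y == 1) model else controls_model(model, "expansion")
  pop$beta_WX * x + mills_lambda(-m$alpha) * m$beta_YW_X * pop$sigma2_W_given_X
}

#' Mills-ratio approximation to the stratum conditional mean
#'
#' The printed Mills-ratio form of the case-stratum conditional mean:
#' `E(W | X = x, Y = 1) ~ beta_WX * x + sigma_{W.X} * tau^{-1} * lambda(u)`
#' with `u = (-alpha + beta_YX * x) / tau`. For controls the signs of
#' `alpha` and `beta_YX` are reversed. Implemented verbatim; note it carries
#' no `beta_YW_X` factor in the shift term, unlike [first_order_mean_shift()]
#' and the exact mean [cond_mean_exact()] - the three agree only in special
#' regimes, and the exact form is the quadrature-verified reference.
#'
#' @inheritParams lp_cond_density
#' @return The approximate conditional mean (numeric scalar).
#' @export
cond_mean_mills <- function(x, y, model, pop) {
  stopifnot(y %in% c(0, 1))
  if (model$link != "probit")
    stop("probit operation requires link = 'probit'", call. = FALSE)
  m <- if (y == 1) model else controls_model(model, "negate")
  tg <- tau_gamma(m, pop)
  u <- (-m$alpha + tg$beta_YX * x) / tg$tau
  pop$beta_WX * x + sqrt(pop$sigma2_W_given_X) / tg$tau * mills_lambda(u)
}

#' Delta-method approximation to the stratum conditional mean
#'
#' Local linearization of the selection integral around the population
#' conditional mean of W:
#' `E(W | x, 1) ~ beta_WX * x * {pnorm(-alpha + beta_YX x) +
#' sigma^2_{W.X} beta_YW_X dnorm(-alpha + beta_YX x)} /
#' pnorm((-alpha + beta_YX x) / tau)`. For controls the arguments of the
#' normal probabilities change sign. Implemented verbatim; proportional to
#' `x` by construction, hence zero at `x = 0`.
#'
#' @inheritParams lp_cond_density
#' @return The approximate conditional mean (numeric scalar).
#' @export
cond_mean_delta <- function(x, y, model, pop) {
  stopifnot(y %in% c(0, 1))
  if (model$link != "probit")
    stop("probit operation requires link = 'probit'", call. = FALSE)
  tg <- tau_gamma(model, pop)
  arg <- -model$alpha + tg$beta_YX * x
  sgn <- if (y == 1) 1 else -1
  num <- stats::pnorm(sgn * arg) +
    pop$sigma2_W_given_X * model$beta_YW_X * stats::dnorm(arg)
  pop$beta_WX * x * num / stats::pnorm(sgn * arg / tg$tau)
}

#' Exact stratum conditional mean under probit selection
#'
#' The closed-form conditional mean of W given `X = x` in stratum `y` when
#' (X, W) is bivariate normal and selection is probit:
#' `E(W | x, 1) = beta_WX * x + sigma^2_{W.X} * beta_YW_X * tau^{-1} *
#' lambda(u)` with `u = (-alpha + beta_YX x) / tau`, and for controls
#' `E(W | x, 0) = beta_WX * x - sigma^2_{W.X} * beta_YW_X * tau^{-1} *
#' lambda(-u)`. Agrees with adaptive quadrature of [probit_cond_density()]
#' to full precision; serves as the reference the approximations are
#' judged against.
#'
#' @inheritParams lp_cond_density
#' @return The conditional mean (numeric scalar).
#' @export
cond_mean_exact <- function(x, y, model, pop) {
  stopifnot(y %in% c(0, 1))
  if (model$link != "probit")
    stop("probit operation requires link = 'probit'", call. = FALSE)
  tg <- tau_gamma(model, pop)
  u <- (-model$alpha + tg$beta_YX * x) / tg$tau
  shift <- pop$sigma2_W_given_X * model$beta_YW_X / tg$tau
  if (y == 1) pop$beta_WX * x + shift * mills_lambda(u)
  else pop$beta_WX * x - shift * mills_lambda(-u)
}

#' Case-stratum regression slope at x = 0, Mills-ratio form
#'
#' The printed nonlinear conditional mean summarized by its slope at
#' `x = 0`: `beta_WX + beta_YX * sigma_{W.X} * tau^{-1} * lambda(-alpha/tau)`.
#' Implemented verbatim; see [slope_exact()] for the derivative of the exact
#' conditional mean, which differs in sign of the correction.
#'
#' @inheritParams marginal_beta_yx
#' @return Slope (numeric scalar).
#' @export
slope_at_zero <- function(model, pop) {
  tg <- tau_gamma(model, pop)
  pop$beta_WX + tg$beta_YX * sqrt(pop$sigma2_W_given_X) / tg$tau *
    mills_lambda(-model$alpha / tg$tau)
}

#' Rare-case linear approximation to the case-stratum slope
#'
#' Replacing `lambda(z) ~ -z` (valid for strongly negative arguments, i.e.
#' rare cases with `alpha > 0`) in [slope_at_zero()] gives
#' `beta_WX + beta_YX * sigma_{W.X} * alpha / tau^2`. A warning is issued
#' when `alpha <= 0`, outside the approximation's regime.
#'
#' @inheritParams marginal_beta_yx
#' @return Slope (numeric scalar).
#' @export
slope_rare_approx <- function(model, pop) {
  if (model$alpha <= 0)
    warning("alpha <= 0: the rare-case (-z) approximation regime is violated",
            call. = FALSE)
  tg <- tau_gamma(model, pop)
  pop$beta_WX + tg$beta_YX * sqrt(pop$sigma2_W_given_X) * model$alpha / tg$tau2
}

#' Slope of the exact stratum conditional mean
#'
#' Differentiating [cond_mean_exact()] in `x` gives, for cases,
#' `beta_WX + sigma^2_{W.X} * beta_YW_X * beta_YX * tau^{-2} * lambda'(u)`
#' with `u = (-alpha + beta_YX x) / tau` and
#' `lambda'(z) = -lambda(z) (z + lambda(z)) < 0`: with all coefficients
#' positive and rare cases the case-stratum slope is *attenuated* relative
#' to `beta_WX`. This is the correction inverted by
#' `reconstruct_slope(correction = "slope")`.
#'
#' @param x Point at which the slope is evaluated (default 0).
#' @param y Stratum, 1 (cases) or 0 (controls).
#' @inheritParams marginal_beta_yx
#' @return Slope (numeric scalar).
#' @export
slope_exact <- function(model, pop, x = 0, y = 1) {
  stopifnot(y %in% c(0, 1))
  tg <- tau_gamma(model, pop)
  u <- (-model$alpha + tg$beta_YX * x) / tg$tau
  fac <- pop$sigma2_W_given_X * model$beta_YW_X * tg$beta_YX / tg$tau2
  if (y == 1) pop$beta_WX + fac * mills_lambda_prime(u)
  else pop$beta_WX + fac * mills_lambda_prime(-u)
}
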
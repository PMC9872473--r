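#' Population joint law of (X, W)
#'
#' Describes the originating population distribution of the two explanatory
#' variables through the least-squares regression of W on X. Both variables
#' are taken to have mean zero; for the normal-theory operations the implied
#' marginal variance of W is `beta_WX^2 * var_X + sigma2_W_given_X`.
#'
#' @param beta_WX Slope of the population least-squares regression of W on X.
#' @param sigma2_W_given_X Residual variance of W about that regression
#'   (strictly positive).
#' @param var_X Variance of X (strictly positive, default 1).
#' @return An object of class `"population_joint"`.
#' @seealso [standardized_population()] for the unit-variance construction
#'   used in the simulation design.
#' @export
#' @examples
#' population_joint(beta_WX = 0.5, sigma2_W_given_X = 0.75)
population_joint <- function(beta_WX, sigma2_W_given_X, var_X = 1) {
  stopifnot(is.numeric(beta_WX), length(beta_WX) == 1L, is.finite(beta_WX))
  if (!is.numeric(sigma2_W_given_X) || sigma2_W_given_X <= 0)
    stop("sigma2_W_given_X must be > 0", call. = FALSE)
  if (!is.numeric(var_X) || var_X <= 0)
    stop("var_X must be > 0", call. = FALSE)
  structure(
    list(beta_WX = as.numeric(beta_WX),
         sigma2_W_given_X = as.numeric(sigma2_W_given_X),
         var_X = as.numeric(var_X)),
    class = "population_joint")
}

#' Standardized population with unit-variance X and W
#'
#' Convenience constructor for the common standardized setting where
#' `Var(X) = Var(W) = 1`, so the residual variance is `1 - beta_WX^2`.
#'
#' @inheritParams population_joint
#' @return A `"population_joint"` object.
#' @export
standardized_population <- function(beta_WX) {
  if (abs(beta_WX) >= 1)
    stop("|beta_WX| must be < 1 for a standardized population", call. = FALSE)
  population_joint(beta_WX, 1 - beta_WX^2, 1)
}

#' @export
print.population_joint <- function(x, ...) {
  cat("Population joint law of (X, W):\n")
  cat(sprintf("  beta_WX = %g, sigma^2_{W.X} = %g, Var(X) = %g\n",
              x$beta_WX, x$sigma2_W_given_X, x$var_X))
  invisible(x)
}

#' Outcome model for case status given (W, X)
#'
#' Specifies `P(Y = 1 | W = w, X = x)` through a link function and three
#' coefficients. Sign convention, part of this type's contract:
#' \describe{
#'   \item{probit}{`P(Y=1|w,x) = pnorm(-alpha + beta_YW_X * w + beta_YX_W * x)`;
#'     the intercept enters with a minus sign, so rare cases correspond to
#'     `alpha > 0`.}
#'   \item{logistic}{`P(Y=1|w,x) = plogis(alpha + beta_YW_X * w + beta_YX_W * x)`.}
#'   \item{linear}{`P(Y=1|w,x) = alpha + beta_YW_X * w + beta_YX_W * x`,
#'     valid only where that expression lies in (0, 1); evaluations outside
#'     that range raise an error rather than being clipped.}
#' }
#'
#' @param link One of `"probit"`, `"logistic"`, `"linear"`.
#' @param alpha Intercept on the link's scale (see sign convention above).
#' @param beta_YW_X Partial coefficient of W given X.
#' @param beta_YX_W Partial coefficient of X given W.
#' @return An object of class `"outcome_model"`.
#' @export
#' @examples
#' outcome_model("probit", alpha = 2, beta_YW_X = 0.3, beta_YX_W = 0.2)
outcome_model <- function(link = c("probit", "logistic", "linear"),
                          alpha, beta_YW_X, beta_YX_W) {
  link <- match.arg(link)
  vals <- c(alpha, beta_YW_X, beta_YX_W)
  stopifnot(is.numeric(vals), length(vals) == 3L, all(is.finite(vals)))
  structure(
    list(link = link, alpha = as.numeric(alpha),
         beta_YW_X = as.numeric(beta_YW_X), beta_YX_W = as.numeric(beta_YX_W)),
    class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  pred <- if (x$link == "probit") "-alpha + b_w w + b_x x" else "alpha + b_w w + b_x x"
  cat(sprintf("Outcome model: %s link, predictor %s\n", x$link, pred))
  cat(sprintf("  alpha = %g, beta_YW.X = %g, beta_YX.W = %g\n",
              x$alpha, x$beta_YW_X, x$beta_YX_W))
  invisible(x)
}

#' Case-control sample of (x, w, y)
#'
#' Container for paired observations with binary case status, the unit of
#' estimation for all slope estimators. Cases are `y == 1`, controls
#' `y == 0`. Missing values are rejected: filtering is the reader's job
#' (see [read_sample()]).
#'
#' @param x,w Numeric vectors of equal length.
#' @param y Vector of 0/1 case indicators (logical accepted).
#' @return A data frame of class `c("cc_sample", "data.frame")` with columns
#'   `x`, `w`, `y` and attributes `n_cases`, `n_controls`.
#' @export
#' @examples
#' cc_sample(x = rnorm(6), w = rnorm(6), y = rep(0:1, 3))
cc_sample <- function(x, w, y) {
  x <- as.numeric(x); w <- as.numeric(w)
  if (is.logical(y)) y <- as.integer(y)
  n <- length(x)
  if (length(w) != n || length(y) != n)
    stop("x, w, y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(w) || anyNA(y))
    stop("cc_sample does not accept missing values", call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("y must be coded 0 (control) / 1 (case)", call. = FALSE)
  y <- as.integer(y)
  out <- data.frame(x = x, w = w, y = y)
  class(out) <- c("cc_sample", "data.frame")
  attr(out, "n_cases") <- sum(y == 1L)
  attr(out, "n_controls") <- sum(y == 0L)
  out
}

#' @export
print.cc_sample <- function(x, ...) {
  cat(sprintf("Case-control sample: %d cases, %d controls\n",
              attr(x, "n_cases"), attr(x, "n_controls")))
  NextMethod()
}

# One-row estimate record shared by every estimator.
new_estimate <- function(method, estimate, stderr, n_used) {
  out <- data.frame(method = method, estimate = as.numeric(estimate),
                    stderr = as.numeric(stderr), n_used = as.integer(n_used),
                    stringsAsFactors = FALSE)
  class(out) <- c("cc_estimate", "data.frame")
  out
}

# Stratum coefficient transformation. The control-stratum counterpart of each
# case formula is obtained from one of three flip rules, stated once here
# rather than re-derived per formula:
#   "linear":    alpha -> 1 - alpha, negate both partial coefficients
#                (linear-in-probability model; the marginal beta_YX flips with
#                them).
#   "expansion": alpha -> 1 - alpha, negate beta_YW_X only (the first-order
#                probit expansion rule, applied verbatim).
#   "negate":    negate alpha and both partial coefficients (the Mills-ratio
#                conditional-mean rule "reverse the signs of alpha, beta_YX";
#                flipping both partials flips the marginal beta_YX).
controls_model <- function(model, rule = c("linear", "expansion", "negate")) {
  rule <- match.arg(rule)
  m <- model
  if (rule == "linear") {
    m$alpha <- 1 - m$alpha
    m$beta_YW_X <- -m$beta_YW_X
    m$beta_YX_W <- -m$beta_YX_W
  } else if (rule == "expansion") {
    m$alpha <- 1 - m$alpha
    m$beta_YW_X <- -m$beta_YW_X
  } else {
    m$alpha <- -m$alpha
    m$beta_YW_X <- -m$beta_YW_X
    m$beta_YX_W <- -m$beta_YX_W
  }
  m
}
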
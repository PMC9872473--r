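#' Configuration for the case-control sampling simulation
#'
#' Describes one cell of the simulation design: a standardized bivariate
#' population of (X, W), a logistic outcome model, and a fixed-size
#' case-control draw. Defaults are the reference study conditions: a
#' population of 1e5, W built as `beta_WX * X + sqrt(1 - beta_WX^2) * Z`
#' with X and Z standard normal, case status Bernoulli with probability
#' `plogis(alpha + beta_YW_X W + beta_YX_W X)`, 2000 cases and 2000
#' controls drawn at random, and 250 replicates.
#'
#' `alpha_mode` controls how the logistic intercept is set from
#' `case_fraction` (the design label `L(alpha)`):
#' \describe{
#'   \item{`"naive"` (default)}{`alpha = qlogis(case_fraction)`: `L(alpha)`
#'     is literally the logistic function at the intercept. The realized
#'     population case fraction then exceeds `case_fraction` whenever the
#'     outcome coefficients are nonzero. This is the convention that
#'     reproduces the reference simulation results.}
#'   \item{`"calibrated"`}{`alpha` is root-found so the population-average
#'     case probability equals `case_fraction` exactly.}
#' }
#' `ipw_pi` picks the inverse-probability weights used by the harness:
#' `"nominal"` (default) weights by the design value `case_fraction`,
#' `"realized"` by the realized population case fraction, `"exact"` by the
#' exact selection probabilities `n1/N1`, `n0/N0`.
#'
#' @param beta_WX Population slope of W on X, with `|beta_WX| <= 1`.
#' @param beta_YW_X,beta_YX_W Logistic outcome coefficients of W and X.
#' @param case_fraction Design case proportion `L(alpha)`, in (0, 1).
#' @param n_population Population size per replicate.
#' @param n_cases,n_controls Case-control sample sizes.
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param covariate_dist `"normal"` or `"t10"` (X and Z drawn from a
#'   t-distribution with 10 degrees of freedom, variance 1.25).
#' @param standardize_t Scale t10 draws to unit variance (default FALSE:
#'   raw t10 draws, the literal reading of the sensitivity design).
#' @param alpha_mode `"naive"` or `"calibrated"`; see Details.
#' @param ipw_pi `"nominal"`, `"realized"`, or `"exact"`; see Details.
#' @param shortfall Policy when a replicate's population contains fewer
#'   cases (or controls) than requested: `"retry"` regenerates the
#'   population from fresh draws of the replicate's RNG stream (retries are
#'   counted and reported); `"truncate"` samples every available unit.
#' @param seed Integer root seed; all randomness flows from it.
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' sim_config(beta_WX = 0.5, beta_YW_X = 1, beta_YX_W = 1,
#'            case_fraction = 0.1, n_replicates = 10)
sim_config <- function(beta_WX = 0.5, beta_YW_X = 1, beta_YX_W = 1,
                       case_fraction = 0.1,
                       n_population = 1e5L,
                       n_cases = 2000L, n_controls = 2000L,
                       n_replicates = 250L,
                       covariate_dist = c("normal", "t10"),
                       standardize_t = FALSE,
                       alpha_mode = c("naive", "calibrated"),
                       ipw_pi = c("nominal", "realized", "exact"),
                       shortfall = c("retry", "truncate"),
                       seed = 1L) {
  covariate_dist <- match.arg(covariate_dist)
  alpha_mode <- match.arg(alpha_mode)
  ipw_pi <- match.arg(ipw_pi)
  shortfall <- match.arg(shortfall)
  if (abs(beta_WX) > 1)
    stop("|beta_WX| must be <= 1: the innovation scale sqrt(1 - beta_WX^2) ",
         "requires it", call. = FALSE)
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("case_fraction must lie strictly in (0, 1)", call. = FALSE)
  if (n_cases + n_controls > n_population)
    stop("n_cases + n_controls must not exceed n_population", call. = FALSE)
  structure(list(beta_WX = beta_WX, beta_YW_X = beta_YW_X,
                 beta_YX_W = beta_YX_W, case_fraction = case_fraction,
                 n_population = as.integer(n_population),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_replicates = as.integer(n_replicates),
                 covariate_dist = covariate_dist,
                 standardize_t = standardize_t,
                 alpha_mode = alpha_mode, ipw_pi = ipw_pi,
                 shortfall = shortfall, seed = as.integer(seed)),
            class = "sim_config")
}

# draw n innovations per the configured covariate distribution
draw_innovations <- function(n, cfg) {
  if (cfg$covariate_dist == "normal") stats::rnorm(n)
  else {
    z <- stats::rt(n, df = 10)
    if (isTRUE(cfg$standardize_t)) z / sqrt(10 / 8) else z  # Var(t10) = 1.25
  }
}

#' Generate a population of (x, w) pairs
#'
#' Draws `n_population` pairs with `W = beta_WX * X + sqrt(1 - beta_WX^2) *
#' Z`, X and Z i.i.d. standard normal (or t10 under the sensitivity
#' variant). Uses the current RNG state unless `seed` is given.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed set before drawing.
#' @return A data frame with columns `x`, `w`.
#' @export
generate_population <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- draw_innovations(cfg$n_population, cfg)
  z <- draw_innovations(cfg$n_population, cfg)
  data.frame(x = x, w = cfg$beta_WX * x + sqrt(1 - cfg$beta_WX^2) * z)
}

#' Assign case status to a population
#'
#' Bernoulli case indicators with logistic probabilities
#' `plogis(alpha + beta_YW_X w + beta_YX_W x)`, the intercept set per
#' `cfg$alpha_mode` (see [sim_config()]).
#'
#' @param population Data frame with columns `x`, `w`.
#' @param cfg A [sim_config()].
#' @return List with `y` (integer vector), `alpha` (intercept used), and
#'   `achieved` (realized population case fraction).
#' @export
assign_outcomes <- function(population, cfg) {
  eta <- cfg$beta_YW_X * population$w + cfg$beta_YX_W * population$x
  alpha <- if (cfg$alpha_mode == "naive") {
    stats::qlogis(cfg$case_fraction)
  } else {
    f <- function(a) mean(stats::plogis(a + eta)) - cfg$case_fraction
    lo <- -40; hi <- 40
    if (f(lo) > 0 || f(hi) < 0)
      stop("alpha calibration failed: root not bracketed in [-40, 40]",
           call. = FALSE)
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  y <- stats::rbinom(length(eta), 1L, stats::plogis(alpha + eta))
  list(y = as.integer(y), alpha = alpha, achieved = mean(y))
}

#' Draw a fixed-size case-control sample from a population
#'
#' Simple random sampling without replacement within each stratum.
#'
#' @param population Data frame with columns `x`, `w`.
#' @param y Integer 0/1 case indicators for the population.
#' @param n_cases,n_controls Stratum sample sizes.
#' @return A [cc_sample()]; attribute `pop_counts` carries the population
#'   stratum sizes `c(N1, N0)`.
#' @export
draw_case_control <- function(population, y, n_cases, n_controls) {
  ci <- which(y == 1L); ki <- which(y == 0L)
  if (length(ci) < n_cases || length(ki) < n_controls) {
    cnd <- structure(
      class = c("retroreg_shortfall", "error", "condition"),
      list(message = sprintf(
        "population has %d cases / %d controls; %d / %d requested",
        length(ci), length(ki), n_cases, n_controls), call = NULL))
    stop(cnd)
  }
  i1 <- if (length(ci) == n_cases) ci else sample(ci, n_cases)
  i0 <- if (length(ki) == n_controls) ki else sample(ki, n_controls)
  out <- cc_sample(x = c(population$x[i1], population$x[i0]),
                   w = c(population$w[i1], population$w[i0]),
                   y = rep(1:0, c(n_cases, n_controls)))
  attr(out, "pop_counts") <- c(length(ci), length(ki))
  attr(out, "indices") <- c(i1, i0)
  out
}

# Independent L'Ecuyer-CMRG RNG streams, one per replicate, spawned from the
# root seed. Restores the caller's RNG kind and state on exit of the
# consumer (see with_stream).
make_streams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

# Evaluate expr with the RNG positioned at `stream`, restoring state after.
with_stream <- function(stream, expr) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  assign(".Random.seed", stream, globalenv())
  expr
}

# The seven estimates computed on each replicate, as a named vector.
replicate_estimates <- function(population, y, sample, cfg, achieved) {
  pop_fit <- stats::lm.fit(cbind(1, population$x), population$w)
  pc <- attr(sample, "pop_counts")
  ipw <- switch(cfg$ipw_pi,
    nominal = ipw_slope(sample, pi = cfg$case_fraction),
    realized = ipw_slope(sample, pi = achieved),
    exact = ipw_slope(sample, pop_counts = pc))
  rec <- suppressWarnings(
    reconstruct_slope(sample, pi = achieved,
                      correction = "slope", scale = 1 / 1.6))
  c(population = unname(pop_fit$coefficients[2L]),
    controls_only = ols_slope(sample, "controls")$estimate,
    cases_only = ols_slope(sample, "cases")$estimate,
    adjusted = adjusted_slope(sample)$estimate,
    pooled = pooled_slope(sample)$estimate,
    ipw = ipw$estimate,
    reconstructed = rec$estimate)
}

#' Run the Monte-Carlo replicates for one configuration
#'
#' For each replicate: generate a fresh population, assign outcomes, draw
#' the case-control sample, and compute the seven slope estimates
#' (population, controls-only, cases-only, adjusted, pooled, IPW, and the
#' reconstructed estimate, the last using the exact-slope correction with
#' probit-rescaled nuisances and the realized population case fraction as
#' the known pi). Each replicate runs on its own RNG substream spawned from
#' `cfg$seed`, so results are bit-reproducible and any single replicate can
#' be re-run in isolation.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `"cc_sim"`: list with `summary` (data frame
#'   of per-method mean and empirical SD across replicates), `estimates`
#'   (replicate x method matrix), `achieved` (mean realized case fraction),
#'   `retries` (number of populations regenerated under the `"retry"`
#'   shortfall policy), and `config`.
#' @export
run_replicates <- function(cfg) {
  streams <- make_streams(cfg$seed, cfg$n_replicates)
  methods <- c("population", "controls_only", "cases_only", "adjusted",
               "pooled", "ipw", "reconstructed")
  est <- matrix(NA_real_, cfg$n_replicates, length(methods),
                dimnames = list(NULL, methods))
  achieved <- numeric(cfg$n_replicates)
  retries <- 0L
  for (r in seq_len(cfg$n_replicates)) {
    res <- with_stream(streams[[r]], {
      repeat {
        population <- generate_population(cfg)
        oc <- assign_outcomes(population, cfg)
        smp <- tryCatch(
          draw_case_control(population, oc$y, cfg$n_cases, cfg$n_controls),
          retroreg_shortfall = function(e) e)
        if (!inherits(smp, "retroreg_shortfall")) break
        if (cfg$shortfall == "truncate") {
          smp <- draw_case_control(
            population, oc$y,
            min(cfg$n_cases, sum(oc$y == 1L)),
            min(cfg$n_controls, sum(oc$y == 0L)))
          break
        }
        retries <- retries + 1L  # expr evaluates in this function's frame
      }
      list(est = replicate_estimates(population, oc$y, smp, cfg, oc$achieved),
           achieved = oc$achieved)
    })
    est[r, ] <- res$est
    achieved[r] <- res$achieved
  }
  summary <- data.frame(method = methods,
                        mean = colMeans(est),
                        sd = apply(est, 2L, stats::sd),
                        row.names = NULL)
  structure(list(summary = summary, estimates = est,
                 achieved = mean(achieved), retries = retries, config = cfg),
            class = "cc_sim")
}

#' @export
print.cc_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Case-control simulation: beta_WX = %g, beta_YW.X = %g, beta_YX.W = %g, L(alpha) = %g\n",
    cfg$beta_WX, cfg$beta_YW_X, cfg$beta_YX_W, cfg$case_fraction))
  cat(sprintf("%d replicates, achieved case fraction %.4f, %d retries\n",
              cfg$n_replicates, x$achieved, x$retries))
  print(transform(x$summary, mean = round(mean, 4), sd = round(sd, 4)))
  invisible(x)
}

#' Run the full simulation grid
#'
#' Runs the 16-configuration grid `beta_WX` in {0.5, 0.8} x `beta_YW_X` in
#' {0.5, 1} x `beta_YX_W` in {0.5, 1} x `L(alpha)` in {0.02, 0.1} and
#' returns one tidy row per configuration with the seven averaged
#' estimates. The reconstructed column (`bWX_star`) uses the package's
#' exact-slope correction and is reported for completeness but is not a
#' validated reproduction of the reference table's corresponding column,
#' whose operationalization is not fully specified.
#'
#' @param seed Integer root seed (each configuration derives its own
#'   subseed deterministically).
#' @param n_replicates Replicates per configuration (default 250).
#' @param ... Further arguments passed to [sim_config()] (e.g.
#'   `covariate_dist = "t10"`, `n_population`).
#' @return Data frame with parameter columns `bWX`, `bYW_X`, `bYX_W`,
#'   `L_alpha` and estimate columns `bWX_pop`, `bWX_0`, `bWX_1`, `bWX_Y`,
#'   `bWX_pool`, `bWX_IPW`, `bWX_star`, plus `achieved` and `retries`.
#' @export
table1_experiment <- function(seed = 1L, n_replicates = 250L, ...) {
  grid <- expand.grid(L_alpha = c(0.02, 0.1), bYX_W = c(0.5, 1),
                      bYW_X = c(0.5, 1), bWX = c(0.5, 0.8),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("bWX", "bYW_X", "bYX_W", "L_alpha")]
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- sim_config(beta_WX = g$bWX, beta_YW_X = g$bYW_X,
                      beta_YX_W = g$bYX_W, case_fraction = g$L_alpha,
                      n_replicates = n_replicates,
                      seed = as.integer((as.numeric(seed) * 1000 + i) %%
                                          2147483647), ...)
    sim <- run_replicates(cfg)
    m <- sim$summary$mean
    names(m) <- sim$summary$method
    rows[[i]] <- data.frame(
      g,
      bWX_pop = m[["population"]], bWX_0 = m[["controls_only"]],
      bWX_1 = m[["cases_only"]], bWX_Y = m[["adjusted"]],
      bWX_pool = m[["pooled"]], bWX_IPW = m[["ipw"]],
      bWX_star = m[["reconstructed"]],
      achieved = sim$achieved, retries = sim$retries)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
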
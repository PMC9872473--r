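#' A 2x2 probability table for two binary variables
#'
#' Joint probabilities `p_ij = P(W = i, X = j)` for `i, j` in `{0, 1}`,
#' stored as a named vector in the fixed cell order `w1x1, w1x0, w0x1,
#' w0x0`. The log odds ratio numerator is `p11 * p00` under this indexing;
#' serialized tables always carry these cell names so the orientation
#' cannot silently transpose.
#'
#' @param p11,p10,p01,p00 Cell probabilities `P(W=1,X=1)`, `P(W=1,X=0)`,
#'   `P(W=0,X=1)`, `P(W=0,X=0)`; nonnegative, summing to 1 within 1e-12.
#' @return A named numeric vector of class `"two_by_two"`.
#' @export
#' @examples
#' two_by_two(0.4, 0.1, 0.1, 0.4)
two_by_two <- function(p11, p10, p01, p00) {
  p <- c(w1x1 = unname(p11), w1x0 = unname(p10),
         w0x1 = unname(p01), w0x0 = unname(p00))
  if (any(!is.finite(p)) || any(p < 0))
    stop("cell probabilities must be finite and nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12)
    stop("cell probabilities must sum to 1 (within 1e-12)", call. = FALSE)
  structure(p, class = "two_by_two")
}

#' Stratified 2x2 tables for cases and controls
#'
#' The conditional laws `p_{ij|y}` of `(W, X)` within controls (`y = 0`)
#' and cases (`y = 1`), together with the population case probability `pi`
#' that mixes them back into the population table.
#'
#' @param controls,cases [two_by_two()] tables (plain length-4 vectors in
#'   the `w1x1, w1x0, w0x1, w0x0` order are accepted).
#' @param pi Population case probability, in [0, 1] (the endpoints give the
#'   pure stratum tables; the rare-case expansion is meant for small pi).
#' @return A list of class `"stratified_tables"`.
#' @export
stratified_tables <- function(controls, cases, pi) {
  as_t <- function(p) if (inherits(p, "two_by_two")) p
    else two_by_two(p[1L], p[2L], p[3L], p[4L])
  if (!is.numeric(pi) || length(pi) != 1L || pi < 0 || pi > 1)
    stop("pi must lie in [0, 1]", call. = FALSE)
  structure(list(controls = as_t(controls), cases = as_t(cases),
                 pi = as.numeric(pi)),
            class = "stratified_tables")
}

#' Mix stratum tables into the population 2x2 table
#'
#' Cellwise mixture `p_ij = (1 - pi) p_{ij|0} + pi p_{ij|1}`: the population
#' joint law recovered from the two conditional laws and the population
#' case probability.
#'
#' @param s A [stratified_tables()] object.
#' @return A [two_by_two()] table.
#' @export
#' @examples
#' s <- stratified_tables(c(.4, .1, .1, .4), c(.1, .4, .4, .1), pi = 0.3)
#' mix_population_table(s)
mix_population_table <- function(s) {
  p <- (1 - s$pi) * unclass(s$controls) + s$pi * unclass(s$cases)
  two_by_two(p[1L], p[2L], p[3L], p[4L])
}

#' Log odds ratio of a 2x2 probability table
#'
#' `psi = log((p11 * p00) / (p10 * p01))`; zero under independence. Zero
#' cells are a hard error - no continuity correction is ever applied to
#' probability tables (a documented half-count correction exists for count
#' inputs in [tables_from_counts()]).
#'
#' @param t A [two_by_two()] table.
#' @return The log odds ratio (numeric scalar).
#' @export
log_odds_ratio <- function(t) {
  p <- unclass(t)
  if (any(p == 0))
    stop("log odds ratio undefined: zero cell in probability table",
         call. = FALSE)
  log((p[["w1x1"]] * p[["w0x0"]]) / (p[["w1x0"]] * p[["w0x1"]]))
}

#' First-order rare-case approximation to the population log odds ratio
#'
#' For small `pi` the population log odds ratio expands about the
#' control-stratum value with error `O(pi^2)`:
#' `psi = psi0 + pi * (Dp11/p11|0 + Dp00/p00|0 - Dp10/p10|0 - Dp01/p01|0)`,
#' where `Dp_ij = p_{ij|1} - p_{ij|0}`. Because each stratum's
#' probabilities sum to one, `Dp11 + Dp00 - Dp10 - Dp01 = 0`; the
#' adjustment is largest when the diagonal differences share a sign.
#'
#' @param s A [stratified_tables()] object with strictly positive control
#'   cells.
#' @return A list with `psi` (the first-order value), `psi0` (control-
#'   stratum log odds ratio), and `adjustment` (the coefficient of `pi`).
#' @export
psi_first_order <- function(s) {
  p0 <- unclass(s$controls); p1 <- unclass(s$cases)
  if (any(p0 == 0))
    stop("first-order expansion undefined: zero cell in controls table",
         call. = FALSE)
  d <- p1 - p0
  sgn <- c(w1x1 = 1, w1x0 = -1, w0x1 = -1, w0x0 = 1)
  adj <- sum(sgn * d / p0)
  psi0 <- log_odds_ratio(s$controls)
  list(psi = psi0 + s$pi * adj, psi0 = psi0, adjustment = adj)
}

#' Stratified tables from stratum cell counts
#'
#' Maximum-likelihood cell proportions per stratum from observed counts in
#' the `w1x1, w1x0, w0x1, w0x0` order. The population case probability
#' `pi` cannot be estimated from case-control counts and must be supplied.
#' An optional Haldane-style correction adds half a count to every cell of
#' a stratum before normalizing; it applies to counts only, never to
#' probability tables.
#'
#' @param controls,cases Length-4 nonnegative integer count vectors.
#' @param pi Population case probability, in (0, 1).
#' @param haldane Add 0.5 to every cell before forming proportions.
#' @return A [stratified_tables()] object.
#' @export
#' @examples
#' tables_from_counts(c(40, 10, 10, 40), c(10, 40, 40, 10), pi = 0.05)
tables_from_counts <- function(controls, cases, pi, haldane = FALSE) {
  prop <- function(cnt, lab) {
    if (length(cnt) != 4L || any(cnt < 0) || any(cnt != round(cnt)))
      stop(sprintf("%s counts must be 4 nonnegative integers", lab),
           call. = FALSE)
    if (sum(cnt) == 0)
      stop(sprintf("empty %s stratum", lab), call. = FALSE)
    if (haldane) cnt <- cnt + 0.5
    p <- cnt / sum(cnt)
    two_by_two(p[1L], p[2L], p[3L], p[4L])
  }
  stratified_tables(prop(controls, "control"), prop(cases, "case"), pi)
}
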
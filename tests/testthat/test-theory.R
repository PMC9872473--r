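test_that("marginal coefficient and tau/gamma combine the partials correctly", {
  p <- population_joint(0.5, 0.75)
  expect_equal(marginal_beta_yx(probit_m(0, 1, 1), p), 1.5)
  expect_equal(marginal_beta_yx(probit_m(0, 0, 0.7), p), 0.7)
  expect_equal(marginal_beta_yx(probit_m(0, 1, 0.5), population_joint(0.8, 0.36)), 1.3)

  tg <- tau_gamma(probit_m(1, 1, 1), p)
  expect_equal(tg$tau2, 1.75)
  expect_equal(tg$gamma2, 1 + 1.75 + 1.5^2)  # = 5
  expect_equal(tau_gamma(probit_m(1, 0, 1), p)$tau2, 1)
  expect_equal(tau_gamma(probit_m(0, 1, 1), p)$pi, 0.5)
  expect_error(tau_gamma(outcome_model("logistic", 1, 1, 1), p), "probit")

  # marginal-form gamma makes pnorm(-alpha/gamma) the exact marginal case
  # probability under normal X: check against quadrature over x
  m <- probit_m(2, 0.6, 0.4)
  tgm <- tau_gamma(m, p, gamma2_form = "marginal")
  marg <- quad(function(x) dnorm(x) * probit_prob_given_x(x, m, p))
  expect_equal(tgm$pi, marg, tolerance = 1e-9)
})

test_that("Mills-type ratio is stable, monotone, and asymptotically -z", {
  expect_equal(mills_lambda(0), sqrt(2 / pi))
  # frozen from direct high-precision evaluation of dnorm/pnorm at z = -2
  expect_equal(mills_lambda(-2), 2.373215532822843, tolerance = 1e-12)
  expect_equal(mills_lambda(-10), 10.09809, tolerance = 1e-6)
  expect_true(mills_lambda(-10) / 10 > 1 && mills_lambda(-10) / 10 < 1.01)
  expect_true(is.finite(mills_lambda(-40)))
  expect_gt(mills_lambda(-40), 40)

  z <- seq(-40, 5, by = 0.5)
  l <- mills_lambda(z)
  expect_true(all(l > 0))
  expect_true(all(diff(l) < 0))                      # strictly decreasing
  expect_true(all(l[z < 0] > -z[z < 0]))             # lambda(z) > -z
  zc <- seq(-8, 4, by = 0.25)                         # identity on a safe range
  expect_equal(mills_lambda(zc) * pnorm(zc), dnorm(zc), tolerance = 1e-14)
})

test_that("linear-model conditional density tilts the base law and normalizes", {
  p <- population_joint(0.5, 0.75)
  # no W effect: selection factor constant in w, density unchanged
  m0 <- linear_m(0.3, 0, 0.1)
  wg <- seq(-3, 3, by = 0.5)
  for (y in 0:1)
    expect_equal(lp_cond_density(wg, 0.5, y, m0, p),
                 dnorm(wg, 0.25, sqrt(0.75)), tolerance = 1e-14)

  # normalization for both strata; the gentle W coefficient keeps the
  # probability factor positive over the effective support, where the
  # linear model is meaningful (integration over [-8, 8] carries the full
  # mass to well below the tolerance)
  m1 <- linear_m(0.5, 0.05, 0)
  for (y in 0:1)
    expect_equal(quad(function(w) lp_cond_density(w, 0, y, m1, p), -8, 8), 1,
                 tolerance = 1e-8)

  # point value against a quadrature-normalized oracle (independent of the
  # marginal-coefficient identity the implementation uses)
  m2 <- linear_m(0.3, 0.2, 0.1)
  x <- 0.5; w <- 0.4
  num <- function(w) dnorm(w, 0.25, sqrt(0.75)) * (0.3 + 0.1 * x + 0.2 * w)
  expect_equal(lp_cond_density(w, x, 1, m2, p), num(w) / quad(num),
               tolerance = 1e-8)

  # invalid region is an error, not a clipped value
  expect_error(lp_cond_density(-10, 0, 1, m2, p), "negative")
})

test_that("linear-model conditional mean matches quadrature and its reductions", {
  p <- population_joint(0.5, 0.75)
  expect_equal(lp_cond_mean(0.7, 1, linear_m(0.3, 0, 0.1), p), 0.35)
  expect_equal(lp_cond_mean(0, 1, linear_m(0.4, 0.2, 0.1), p),
               0.2 * 0.75 / 0.4)
  # worked value: beta_WX x + b_w sigma2 / (alpha + beta_YX x), with the
  # partials chosen so the marginal coefficient is 0.6
  m <- linear_m(0.3, 0.2, 0.5)
  expect_equal(lp_cond_mean(1, 1, m, p), 0.5 + 0.15 / 0.9)
  # against quadrature of the stratum density, both strata (parameters kept
  # inside the linear model's validity region over [-8, 8])
  mg <- linear_m(0.5, 0.05, 0.05)
  for (y in 0:1) {
    mean_q <- quad(function(w) w * lp_cond_density(w, 0.3, y, mg, p), -8, 8) /
      quad(function(w) lp_cond_density(w, 0.3, y, mg, p), -8, 8)
    expect_equal(lp_cond_mean(0.3, y, mg, p), mean_q, tolerance = 1e-8)
  }
  expect_error(lp_cond_mean(-5, 1, m, p), "not positive")
})

test_that("probit marginalization identity holds across a parameter grid", {
  grid <- expand.grid(alpha = c(0, 1, 2, 4), bw = c(0.1, 0.5, 1),
                      bx = c(0, 0.5), bwx = c(0.2, 0.7), x = c(-1, 0.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    m <- probit_m(g$alpha, g$bw, g$bx)
    p <- population_joint(g$bwx, 0.6)
    lhs <- quad(function(w) dnorm(w, g$bwx * g$x, sqrt(0.6)) *
                  pnorm(-g$alpha + g$bw * w + g$bx * g$x))
    expect_equal(probit_prob_given_x(g$x, m, p), lhs, tolerance = 1e-8)
  }
})

test_that("probit conditional density normalizes and vanishes with the W effect", {
  p <- population_joint(0.5, 0.75)
  m <- probit_m(1, 0.3, 0.2)
  for (y in 0:1)
    expect_equal(quad(function(w) probit_cond_density(w, 0.5, y, m, p)), 1,
                 tolerance = 1e-8)
  # harsher intercept: log-space evaluation keeps this finite and normalized
  mh <- probit_m(5, 0.5, 0.3)
  expect_equal(quad(function(w) probit_cond_density(w, 0, 1, mh, p)), 1,
               tolerance = 1e-8)

  # b_w = 0: equal to the base density pointwise, both strata
  m0 <- probit_m(1, 0, 0.4)
  wg <- seq(-4, 4, by = 0.25)
  for (y in 0:1)
    expect_lt(max(abs(probit_cond_density(wg, 0.5, y, m0, p) -
                        dnorm(wg, 0.25, sqrt(0.75)))), 1e-12)

  # point value against the quadrature-normalized oracle
  den <- quad(function(w) dnorm(w, 0, sqrt(0.75)) * pnorm(-1 + 0.3 * w))
  oracle <- dnorm(1, 0, sqrt(0.75)) * pnorm(-1 + 0.3 * 1) / den
  expect_equal(probit_cond_density(1, 0, 1, m, p), oracle, tolerance = 1e-8)
})

test_that("exact stratum mean matches quadrature; expansions behave to order", {
  p <- population_joint(0.5, 0.75)
  m <- probit_m(1, 0.3, 0.2)
  for (y in 0:1) {
    mq <- quad(function(w) w * probit_cond_density(w, 0.4, y, m, p))
    expect_equal(cond_mean_exact(0.4, y, m, p), mq, tolerance = 1e-9)
  }

  # first-order expansion: error is quadratic in the outcome coefficients
  # jointly, so halving both cuts the discrepancy against the exact mean
  # about fourfold (at x = 0 the quadratic term vanishes by symmetry and
  # the decay is cubic, i.e. even faster)
  disc <- sapply(c(0.1, 0.05), function(c) {
    mm <- probit_m(1.5, c * 1, c * 0.5)
    abs(first_order_mean_shift(0.8, 1, mm, p) - cond_mean_exact(0.8, 1, mm, p))
  })
  expect_equal(disc[1] / disc[2], 4, tolerance = 0.2)
  disc0 <- sapply(c(0.1, 0.05), function(bw) {
    mm <- probit_m(1.5, bw, 0.2)
    abs(first_order_mean_shift(0, 1, mm, p) - cond_mean_exact(0, 1, mm, p))
  })
  expect_gt(disc0[1] / disc0[2], 4)

  # rare-case asymmetry: case displacement positive and larger in magnitude
  # than the control displacement, for positive coefficients and pi < 0.5
  m2 <- probit_m(2, 0.5, 0.3)
  expect_lt(probit_marginal_prob(m2, p), 0.5)
  d1 <- first_order_mean_shift(0, 1, m2, p)
  d0 <- first_order_mean_shift(0, 0, m2, p)
  expect_gt(d1, 0)
  expect_lt(abs(d0), d1)
  e1 <- cond_mean_exact(0, 1, m2, p)
  e0 <- cond_mean_exact(0, 0, m2, p)
  expect_gt(e1, 0)
  expect_lt(abs(e0), e1)
})

test_that("Mills-ratio and delta-method mean formulas match direct substitution", {
  p <- population_joint(0.5, 0.75)
  m <- probit_m(1, 0.3, 0.2)
  byx <- 0.2 + 0.3 * 0.5
  tau <- sqrt(1 + 0.09 * 0.75)

  # independent re-evaluation of the printed expressions
  u <- (-1 + byx * 1) / tau
  expect_equal(cond_mean_mills(1, 1, m, p),
               0.5 + sqrt(0.75) / tau * dnorm(u) / pnorm(u), tolerance = 1e-12)
  u0 <- (1 - byx * 1) / tau  # controls: signs of alpha and beta_YX reversed
  expect_equal(cond_mean_mills(1, 0, m, p),
               0.5 + sqrt(0.75) / tau * dnorm(u0) / pnorm(u0), tolerance = 1e-12)

  arg <- -1 + byx * 1
  expect_equal(cond_mean_delta(1, 1, m, p),
               0.5 * (pnorm(arg) + 0.75 * 0.3 * dnorm(arg)) / pnorm(arg / tau),
               tolerance = 1e-12)
  expect_equal(cond_mean_delta(1, 0, m, p),
               0.5 * (pnorm(-arg) + 0.75 * 0.3 * dnorm(arg)) / pnorm(-arg / tau),
               tolerance = 1e-12)

  # structural reductions
  expect_equal(cond_mean_delta(0, 1, m, p), 0)           # proportional to x
  m0 <- probit_m(1, 0, 0.4)                               # b_w = 0 => tau = 1
  expect_equal(cond_mean_delta(0.8, 1, m0, p), 0.4)
  # nonlinearity of the Mills-ratio mean in x when beta_YX != 0
  d_right <- cond_mean_mills(1, 1, m, p) - cond_mean_mills(0, 1, m, p)
  d_left <- cond_mean_mills(0, 1, m, p) - cond_mean_mills(-1, 1, m, p)
  expect_gt(abs(d_right - d_left), 1e-6)
})

test_that("slope summaries: printed forms, rare-case limit, exact derivative", {
  p <- population_joint(0.5, 0.75)
  expect_equal(slope_at_zero(probit_m(2, 0, 0), p), 0.5)   # beta_YX = 0
  m_a0 <- probit_m(0, 1, 1)
  tg <- tau_gamma(m_a0, p)
  expect_equal(slope_at_zero(m_a0, p),
               0.5 + 1.5 * sqrt(0.75) / tg$tau * sqrt(2 / pi))

  m <- probit_m(2, 1, 1)
  expect_equal(slope_rare_approx(m, p), 0.5 + 1.5 * sqrt(0.75) * 2 / 1.75)
  expect_warning(slope_rare_approx(probit_m(-1, 1, 1), p), "regime")

  # -z underestimates lambda, so the linear form never exceeds the
  # Mills-ratio form when alpha > 0 and beta_YX > 0 ...
  expect_lt(slope_rare_approx(m, p), slope_at_zero(m, p))
  # ... and the two corrections agree asymptotically as alpha grows
  ratio <- sapply(c(10, 20), function(a) {
    ma <- probit_m(a, 1, 1)
    (slope_rare_approx(ma, p) - 0.5) / (slope_at_zero(ma, p) - 0.5)
  })
  expect_equal(ratio[2], 1, tolerance = 0.01)
  expect_gt(ratio[2], ratio[1])  # monotone approach

  # slope_exact is the derivative of the exact conditional mean
  h <- 1e-6
  for (y in 0:1) {
    num_deriv <- (cond_mean_exact(h, y, m, p) - cond_mean_exact(-h, y, m, p)) / (2 * h)
    expect_equal(slope_exact(m, p, x = 0, y = y), num_deriv, tolerance = 1e-7)
  }
  # attenuation: with positive coefficients the case-stratum slope is below
  # the population slope (the empirical bias direction)
  expect_lt(slope_exact(m, p), 0.5)
})

test_that("intercept/probability inversion round-trips", {
  expect_equal(alpha_from_pi(0.5, 3), 0)
  expect_equal(alpha_from_pi(0.02, sqrt(5)), -sqrt(5) * qnorm(0.02))
  p <- population_joint(0.5, 0.75)
  for (pi in seq(0.01, 0.99, by = 0.07)) {
    g <- tau_gamma(probit_m(1, 1, 1), p)$gamma
    a <- alpha_from_pi(pi, g)
    m <- probit_m(a, 1, 1)
    expect_equal(probit_marginal_prob(m, p), pi, tolerance = 1e-12)
  }
  expect_error(alpha_from_pi(0, 1), "strictly")
  expect_error(alpha_from_pi(1.2, 1), "strictly")
})
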
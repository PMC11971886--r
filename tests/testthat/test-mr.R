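test_that("Wald ratio propagates effect and first-order SE", {
  w <- wald_ratio(0.1, 0.02, 0.05, 0.01)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  w2 <- wald_ratio(-0.1, 0.02, 0.05, 0.01)
  expect_equal(w2$beta, -0.5)
  expect_equal(w2$se, 0.1)
  w3 <- wald_ratio(1, 0.05, 0.3, 0.2)  # unit exposure passes outcome through
  expect_equal(w3$beta, 0.3)
  expect_equal(w3$se, 0.2)
  expect_error(wald_ratio(0, 0.02, 0.05, 0.01), "beta_exp")
})

test_that("IVW is the precision-weighted mean with fixed-effect SE", {
  # weights 100 and 25: beta = (100*0.5 + 25*0.7)/125 = 0.54, se = 125^-0.5
  est <- ivw(c(0.5, 0.7), c(0.1, 0.2))
  expect_equal(est$beta, 0.54)
  expect_equal(est$se, 1 / sqrt(125))
  # single ratio reduces to the Wald ratio exactly
  w <- wald_ratio(0.1, 0.02, 0.05, 0.01)
  est1 <- ivw(w$beta, w$se)
  expect_identical(est1$beta, w$beta)
  expect_identical(est1$se, w$se)
  # equal SEs give the arithmetic mean
  expect_equal(ivw(c(0.2, 0.4, 0.9), rep(0.1, 3))$beta, 0.5)
  expect_error(ivw(numeric(0), numeric(0)), "at least one")
})

test_that("IVW and Egger match weighted-least-squares oracles to 1e-10", {
  for (seed in 1:5) {
    d <- withr::with_seed(seed, data.frame(
      bx = runif(5, 0.05, 0.3), by = rnorm(5, 0.1, 0.05),
      sy = runif(5, 0.01, 0.05)))
    # IVW of ratios == no-intercept WLS of by on bx with weights sy^-2
    r <- wald_ratio(d$bx, 0, d$by, d$sy)
    est <- ivw(r$beta, r$se)
    fit <- lm(by ~ 0 + bx, data = d, weights = d$sy^-2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
    s <- summary(fit)
    expect_equal(est$se, unname(s$coefficients[1, 2] / s$sigma),
                 tolerance = 1e-10)
    # Egger == intercept WLS, fixed-effect SEs
    eg <- mr_egger(d$bx, d$by, d$sy)
    fit2 <- lm(by ~ bx, data = d, weights = d$sy^-2)
    s2 <- summary(fit2)
    expect_equal(eg$intercept, unname(coef(fit2)[1]), tolerance = 1e-10)
    expect_equal(eg$slope, unname(coef(fit2)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept_se,
                 unname(s2$coefficients[1, 2] / s2$sigma), tolerance = 1e-10)
    expect_equal(eg$slope_se,
                 unname(s2$coefficients[2, 2] / s2$sigma), tolerance = 1e-10)
  }
})

test_that("Egger recovers exact lines and orients exposure effects", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  eg <- mr_egger(bx, 0.5 * bx, rep(0.02, 4))
  expect_equal(eg$slope, 0.5, tolerance = 1e-12)
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  eg2 <- mr_egger(bx, 0.1 + 0.5 * bx, rep(0.02, 4))
  expect_equal(eg2$slope, 0.5, tolerance = 1e-12)
  expect_equal(eg2$intercept, 0.1, tolerance = 1e-12)
  # sign orientation: flipping a pair leaves the fit unchanged
  eg3 <- mr_egger(c(-bx[1], bx[-1]), c(-(0.1 + 0.5 * bx)[1], (0.1 + 0.5 * bx)[-1]),
                  rep(0.02, 4))
  expect_equal(eg3$intercept, 0.1, tolerance = 1e-12)
  # under three instruments: flagged not applicable
  expect_false(mr_egger(bx[1:2], bx[1:2], rep(0.02, 2))$applicable)
})

test_that("Cochran's Q measures ratio dispersion", {
  q <- cochran_q(c(0.5, 0.7), c(0.1, 0.2))
  expect_equal(q$q, 100 * (0.5 - 0.54)^2 + 25 * (0.7 - 0.54)^2)  # 0.8
  expect_equal(q$df, 1L)
  q0 <- cochran_q(rep(0.3, 4), rep(0.1, 4))
  expect_equal(q0$q, 0)
  expect_equal(q0$pval, 1)
  # duplicating every SNP doubles the df bookkeeping to 2n - 1
  qd <- cochran_q(rep(c(0.5, 0.7), 2), rep(c(0.1, 0.2), 2))
  expect_equal(qd$df, 3L)
  expect_false(cochran_q(0.5, 0.1)$applicable)
})

test_that("log-odds effects convert to OR / CI / percent change", {
  o0 <- effect_to_or(0, 0.1)
  expect_equal(o0$or, 1)
  expect_equal(o0$pct_change, 0)
  expect_equal(o0$ci_low * o0$ci_high, 1, tolerance = 1e-12)  # log-symmetric
  o <- effect_to_or(log(1.62), 0.1092)
  expect_equal(o$or, 1.62)
  expect_equal(o$ci_low, 1.31, tolerance = 5e-3)
  expect_equal(o$ci_high, 2.01, tolerance = 5e-3)
  expect_equal(effect_to_or(log(0.66), 0.1)$pct_change, -34)
})

test_that("printed OR/CI triples invert to z and p", {
  p <- or_ci_to_p(1.62, 1.31, 2.01)
  expect_equal(p$z, 4.42, tolerance = 0.01)
  expect_equal(p$pval, 1.0e-5, tolerance = 0.15)
  expect_equal(or_ci_to_p(2.26, 1.82, 2.82)$z, 7.30, tolerance = 0.01)
  expect_equal(or_ci_to_p(2.26, 1.82, 2.82)$pval, 2.9e-13, tolerance = 0.05)
  o1 <- or_ci_to_p(1, exp(-0.1), exp(0.1))
  expect_equal(o1$z, 0)
  expect_equal(o1$pval, 1)
  expect_error(or_ci_to_p(1.2, 1.3, 1.4), "ci_low")
  # mutual inverse with effect_to_or to 1e-10
  for (seed in 1:5) {
    b <- withr::with_seed(seed, rnorm(1, 0, 0.5))
    s <- withr::with_seed(seed + 50, runif(1, 0.02, 0.3))
    o <- effect_to_or(b, s)
    back <- or_ci_to_p(o$or, o$ci_low, o$ci_high)
    expect_equal(back$se_log, s, tolerance = 1e-10)
    expect_equal(back$z, b / s, tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.05)),
               c(0.004, 0.02, 0.08 / 3, 0.05))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.04, 0.001, 0.8, 0.2)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("the estimator hierarchy follows the instrument count", {
  h1 <- data.frame(beta_exp = 0.1, se_exp = 0.01, beta_out = 0.05,
                   se_out = 0.01)
  r1 <- mr_per_exposure(h1, "e", "o")
  expect_equal(r1$method, "wald_ratio")
  expect_equal(r1$beta, 0.5)
  expect_true(is.na(r1$q_stat))
  expect_equal(r1$or, exp(r1$beta))
  expect_true(r1$ci_low < r1$or && r1$or < r1$ci_high)

  h2 <- data.frame(beta_exp = c(0.1, 0.2), se_exp = 0.01,
                   beta_out = c(0.05, 0.09), se_out = 0.01)
  r2 <- mr_per_exposure(h2, "e", "o")
  expect_equal(r2$method, "ivw")
  expect_false(is.na(r2$q_stat))
  expect_true(is.na(r2$egger_intercept))  # n < 3

  h3 <- data.frame(beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
                   beta_out = c(0.05, 0.09, 0.16), se_out = 0.01)
  r3 <- mr_per_exposure(h3, "e", "o")
  expect_equal(r3$method, "ivw")
  expect_false(is.na(r3$egger_intercept))
  # IVW stays inside the ratio range (convexity)
  ratios <- h3$beta_out / h3$beta_exp
  expect_gte(r3$beta, min(ratios))
  expect_lte(r3$beta, max(ratios))
})
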
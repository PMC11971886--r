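# Two-sample MR estimators and supporting statistics: Wald ratio,
# fixed-effect IVW, MR-Egger, Cochran's Q, OR conversion, BH-FDR.

# clamped away from exact zero so p-values remain valid inputs downstream
two_sided_p <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

#' Wald ratio estimate for a single instrument
#'
#' The causal effect is the outcome effect divided by the exposure effect;
#' the standard error uses the first-order delta method,
#' `se = se_out / |beta_exp|`.
#'
#' @param beta_exp,se_exp Instrument effect on the exposure and its SE.
#' @param beta_out,se_out Instrument effect on the outcome and its SE.
#' @return List `beta`, `se`, `pval` (two-sided normal).
#' @examples
#' wald_ratio(0.1, 0.02, 0.05, 0.01)  # beta 0.5, se 0.1
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) {
    stop("Wald ratio undefined for beta_exp = 0", call. = FALSE)
  }
  beta <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  list(beta = beta, se = se, pval = two_sided_p(beta / se))
}

#' Fixed-effect inverse-variance-weighted estimate
#'
#' Precision-weighted mean of per-SNP ratio estimates: weights
#' `w_j = se_j^-2`, `beta = sum(w b) / sum(w)`, `se = sum(w)^-0.5`.
#' With a single SNP this reduces exactly to the Wald ratio.
#'
#' @param beta Per-SNP ratio estimates.
#' @param se Their standard errors (all > 0).
#' @return List `beta`, `se`, `pval`.
#' @examples
#' ivw(c(0.5, 0.7), c(0.1, 0.2))  # beta 0.54, se ~0.0894
#' @export
ivw <- function(beta, se) {
  if (length(beta) == 0L) stop("ivw needs at least one ratio", call. = FALSE)
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- se^-2
  b <- sum(w * beta) / sum(w)
  s <- sum(w)^-0.5
  list(beta = b, se = s, pval = two_sided_p(b / s))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept, weights `se_out^-2`. Pairs are first oriented so
#' all exposure effects are positive (flipping both signs where needed); a
#' non-zero intercept indicates directional pleiotropy. Standard errors are
#' fixed-effect (no residual-variance scaling), with two-sided normal
#' p-values, consistent with the fixed-effect IVW used for the headline
#' estimates. Requires at least three instruments; with fewer, all fields
#' are `NA` and `applicable` is `FALSE`.
#'
#' @param beta_exp Instrument effects on the exposure.
#' @param beta_out Instrument effects on the outcome.
#' @param se_out Standard errors of the outcome effects.
#' @return List `slope`, `slope_se`, `slope_pval`, `intercept`,
#'   `intercept_se`, `intercept_pval`, `applicable`.
#' @export
mr_egger <- function(beta_exp, beta_out, se_out) {
  stopifnot(length(beta_exp) == length(beta_out),
            length(beta_exp) == length(se_out))
  if (length(beta_exp) < 3L) {
    return(list(slope = NA_real_, slope_se = NA_real_, slope_pval = NA_real_,
                intercept = NA_real_, intercept_se = NA_real_,
                intercept_pval = NA_real_, applicable = FALSE))
  }
  flip <- sign(beta_exp)
  flip[flip == 0] <- 1
  x <- beta_exp * flip
  y <- beta_out * flip
  w <- se_out^-2
  # closed-form WLS with intercept
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  intercept <- (swxx * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  intercept_se <- sqrt(swxx / det)
  slope_se <- sqrt(sw / det)
  list(slope = slope, slope_se = slope_se,
       slope_pval = two_sided_p(slope / slope_se),
       intercept = intercept, intercept_se = intercept_se,
       intercept_pval = two_sided_p(intercept / intercept_se),
       applicable = TRUE)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (b_j - b_IVW)^2)` with IVW weights, df = n - 1, upper-tail
#' chi-square p-value. Requires at least two ratios.
#'
#' @inheritParams ivw
#' @return List `q`, `df`, `pval`, `applicable`.
#' @export
cochran_q <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  if (length(beta) < 2L) {
    return(list(q = NA_real_, df = NA_integer_, pval = NA_real_,
                applicable = FALSE))
  }
  w <- se^-2
  b <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - b)^2)
  df <- length(beta) - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE),
       applicable = TRUE)
}

#' Convert a log-odds effect to an odds ratio with confidence interval
#'
#' @param beta Effect on the log-odds scale (per SD of exposure).
#' @param se Standard error (> 0).
#' @param level Confidence level (default 0.95).
#' @return List `or`, `ci_low`, `ci_high`, `pval`, `pct_change` where
#'   `pct_change = 100 * (or - 1)` (a negative value is a percent risk
#'   reduction of magnitude `100 * (1 - or)`).
#' @examples
#' effect_to_or(log(1.62), 0.1092)
#' @export
effect_to_or <- function(beta, se, level = 0.95) {
  stopifnot(all(se > 0), level > 0, level < 1)
  z_crit <- stats::qnorm(1 - (1 - level) / 2)
  list(or = exp(beta),
       ci_low = exp(beta - z_crit * se),
       ci_high = exp(beta + z_crit * se),
       pval = two_sided_p(beta / se),
       pct_change = 100 * (exp(beta) - 1))
}

#' Recover z and p from a printed odds ratio and confidence interval
#'
#' Inverts [effect_to_or()]: `se = (log ci_high - log ci_low) / (2 z_level)`
#' and `z = log(or) / se`. Useful for consistency-checking published
#' OR (CI) p triples.
#'
#' @param or_ Odds ratio.
#' @param ci_low,ci_high Confidence bounds, `0 < ci_low < or_ < ci_high`.
#' @param level Confidence level of the interval (default 0.95).
#' @return List `z`, `se_log`, `pval`.
#' @examples
#' or_ci_to_p(1.62, 1.31, 2.01)  # z ~4.42, p ~1e-5
#' @export
or_ci_to_p <- function(or_, ci_low, ci_high, level = 0.95) {
  if (any(!(ci_low < or_ & or_ < ci_high & ci_low > 0))) {
    stop("require 0 < ci_low < or_ < ci_high", call. = FALSE)
  }
  z_crit <- stats::qnorm(1 - (1 - level) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z_crit)
  z <- log(or_) / se
  list(z = z, se_log = se, pval = two_sided_p(z))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; adjusted values are
#' capped at 1 and monotone in p-value rank.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Per-exposure MR estimate from harmonized instruments
#'
#' Applies the estimator hierarchy used for proteome-wide screens: a single
#' instrument gives the Wald ratio; two or more give the fixed-effect IVW
#' with Cochran's Q attached; three or more additionally attach the
#' MR-Egger intercept as a pleiotropy sensitivity analysis (the headline
#' estimate stays IVW). The effect is reported both on the log scale and as
#' an odds ratio with 95% CI.
#'
#' @param h A `harmonized` data frame (only kept/flipped rows are used), or
#'   any data frame with columns `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @param exposure_id,outcome_id Labels for the result row.
#' @return One-row data frame of class `mr_result`: `exposure`, `outcome`,
#'   `method`, `n_snp`, `beta`, `se`, `pval`, `or`, `ci_low`, `ci_high`,
#'   `q_stat`, `q_df`, `q_pval`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`.
#' @export
mr_per_exposure <- function(h, exposure_id = "exposure", outcome_id = "outcome") {
  if (inherits(h, "harmonized")) h <- harmonized_kept(h)
  if (nrow(h) == 0L) stop("no harmonized instruments for ", exposure_id,
                          call. = FALSE)
  ratios <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  n <- nrow(h)
  if (n == 1L) {
    method <- "wald_ratio"
    est <- list(beta = ratios$beta, se = ratios$se, pval = ratios$pval)
    q <- list(q = NA_real_, df = NA_integer_, pval = NA_real_)
    eg <- list(intercept = NA_real_, intercept_se = NA_real_,
               intercept_pval = NA_real_)
  } else {
    method <- "ivw"
    est <- ivw(ratios$beta, ratios$se)
    q <- cochran_q(ratios$beta, ratios$se)
    eg <- mr_egger(h$beta_exp, h$beta_out, h$se_out)
  }
  orci <- effect_to_or(est$beta, est$se)
  out <- data.frame(
    exposure = exposure_id, outcome = outcome_id, method = method,
    n_snp = n, beta = est$beta, se = est$se, pval = est$pval,
    or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
    q_stat = q$q, q_df = as.integer(q$df), q_pval = q$pval,
    egger_intercept = eg$intercept, egger_intercept_se = eg$intercept_se,
    egger_intercept_pval = eg$intercept_pval,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_result", "data.frame")
  out
}
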
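# Bayesian colocalization of two traits in one region: per-SNP Wakefield
# approximate Bayes factors and the posterior over the five sharing
# hypotheses, with the decision thresholds used for target prioritization.

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with variance `V = se^2` and a normal effect
#' prior with standard deviation `prior_sd` (variance `W`), the
#' approximate Bayes factor against the null is
#' `log ABF = 0.5 * (log(1 - r) + r z^2)` with `r = W / (V + W)` and
#' `z = beta / se`. It is strictly increasing in `z^2` and tends to 0 as
#' `prior_sd` tends to 0.
#'
#' @param beta,se Effect estimate and standard error (`se > 0`).
#' @param prior_sd Prior standard deviation of the true effect (> 0).
#' @return Log ABF (vectorized).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  if (any(prior_sd <= 0)) stop("prior_sd must be positive", call. = FALSE)
  v <- se^2
  w <- prior_sd^2
  r <- w / (v + w)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Assemble aligned per-SNP inputs for colocalization
#'
#' Both traits must supply estimates for the identical ordered SNP list
#' (e.g. after [harmonize()]). The effect prior defaults to SD 0.2 for
#' quantitative traits and 0.15 (log-odds scale) for case-control traits —
#' the conventional defaults of the enumeration-based colocalization
#' method. Prior SNP-level hypothesis probabilities default to
#' `p1 = p2 = 1e-4` and `p12 = 1e-5`.
#'
#' @param beta1,se1 Per-SNP estimates for trait 1.
#' @param beta2,se2 Per-SNP estimates for trait 2, same SNP order.
#' @param snp_ids Optional SNP identifiers.
#' @param type1,type2 `"quantitative"` or `"case_control"` per trait.
#' @param prior_sd1,prior_sd2 Effect-prior SDs; `NULL` picks the default
#'   for the trait type.
#' @param p1,p2,p12 Per-SNP prior probabilities that a SNP is causal for
#'   trait 1 only, trait 2 only, or both; must be positive with
#'   `p1 + p2 + p12 < 1`.
#' @return Object of class `coloc_input`.
#' @export
coloc_input <- function(beta1, se1, beta2, se2, snp_ids = NULL,
                        type1 = "quantitative", type2 = "quantitative",
                        prior_sd1 = NULL, prior_sd2 = NULL,
                        p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  n <- length(beta1)
  if (n == 0L) stop("colocalization needs at least one SNP", call. = FALSE)
  if (length(se1) != n || length(beta2) != n || length(se2) != n) {
    stop("trait 1 and trait 2 must cover the identical ordered SNP list",
         call. = FALSE)
  }
  if (any(se1 <= 0) || any(se2 <= 0)) stop("all se must be positive", call. = FALSE)
  type1 <- match.arg(type1, c("quantitative", "case_control"))
  type2 <- match.arg(type2, c("quantitative", "case_control"))
  default_sd <- c(quantitative = 0.2, case_control = 0.15)
  if (is.null(prior_sd1)) prior_sd1 <- unname(default_sd[type1])
  if (is.null(prior_sd2)) prior_sd2 <- unname(default_sd[type2])
  if (min(p1, p2, p12) <= 0 || p1 + p2 + p12 >= 1) {
    stop("priors must be positive with p1 + p2 + p12 < 1", call. = FALSE)
  }
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%d", seq_len(n))
  structure(
    list(snp_ids = as.character(snp_ids),
         beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
         type1 = type1, type2 = type2,
         prior_sd1 = prior_sd1, prior_sd2 = prior_sd2,
         p1 = p1, p2 = p2, p12 = p12),
    class = "coloc_input"
  )
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when equal
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Five-hypothesis colocalization posterior
#'
#' Enumerates, from per-SNP Wakefield log ABFs `L1` and `L2`, the evidence
#' for the five sharing hypotheses about a region: H0 neither trait has a
#' causal variant; H1/H2 only trait 1/2 does; H3 both do but at distinct
#' variants; H4 both share one causal variant. With `S1 = sum(exp(L1))`,
#' `S2 = sum(exp(L2))`, `S12 = sum(exp(L1 + L2))` the unnormalized masses
#' are 1, `p1 S1`, `p2 S2`, `p1 p2 (S1 S2 - S12)`, `p12 S12`; posteriors
#' are the normalized masses, computed with log-sum-exp stabilization.
#' With a single SNP the H3 cross-term vanishes exactly.
#'
#' @param input A [coloc_input()] object.
#' @return Object of class `coloc_result`: list with `pph0` ... `pph4`,
#'   `n_snps`, and `log_mass` (the five log evidence terms).
#' @export
coloc_abf <- function(input) {
  stopifnot(inherits(input, "coloc_input"))
  l1 <- wakefield_log_abf(input$beta1, input$se1, input$prior_sd1)
  l2 <- wakefield_log_abf(input$beta2, input$se2, input$prior_sd2)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  log_mass <- c(
    h0 = 0,
    h1 = log(input$p1) + ls1,
    h2 = log(input$p2) + ls2,
    h3 = log(input$p1) + log(input$p2) + logdiffexp(ls1 + ls2, ls12),
    h4 = log(input$p12) + ls12
  )
  post <- exp(log_mass - logsumexp(log_mass))
  post <- post / sum(post)
  structure(
    list(pph0 = post[["h0"]], pph1 = post[["h1"]], pph2 = post[["h2"]],
         pph3 = post[["h3"]], pph4 = post[["h4"]],
         n_snps = length(input$beta1), log_mass = log_mass),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result>", x$n_snps, "SNPs\n")
  probs <- c(PPH0 = x$pph0, PPH1 = x$pph1, PPH2 = x$pph2,
             PPH3 = x$pph3, PPH4 = x$pph4)
  print(round(probs, 4))
  invisible(x)
}

#' Colocalization decision rule
#'
#' A region pair is called colocalized when PPH4 exceeds `pph4_min`
#' (default 0.75) or when PPH3 + PPH4 exceeds `sum34_min` (default 0.8);
#' the reason records which clause fired.
#'
#' @param result A `coloc_result`.
#' @param pph4_min Threshold on PPH4.
#' @param sum34_min Threshold on PPH3 + PPH4.
#' @return List `decision` (`"colocalized"` / `"not_colocalized"`) and
#'   `reason`.
#' @export
coloc_decision <- function(result, pph4_min = 0.75, sum34_min = 0.8) {
  stopifnot(inherits(result, "coloc_result"))
  if (result$pph4 > pph4_min) {
    list(decision = "colocalized",
         reason = sprintf("pph4 %.3f > %.2f", result$pph4, pph4_min))
  } else if (result$pph3 + result$pph4 > sum34_min) {
    list(decision = "colocalized",
         reason = sprintf("pph3 + pph4 %.3f > %.2f",
                          result$pph3 + result$pph4, sum34_min))
  } else {
    list(decision = "not_colocalized",
         reason = sprintf("pph4 %.3f, pph3 + pph4 %.3f below thresholds",
                          result$pph4, result$pph3 + result$pph4))
  }
}
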
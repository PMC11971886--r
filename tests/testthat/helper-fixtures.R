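# Small in-code fixtures shared across test files.

make_records <- function(n = 3, chrom = "1", pos = NULL, ea = "A", oa = "G",
                         eaf = 0.3, beta = 0.1, se = 0.02, pval = NULL,
                         snp_id = NULL) {
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = n)
  if (is.null(snp_id)) snp_id <- sprintf("rs%03d", seq_len(n))
  beta <- rep_len(beta, n); se <- rep_len(se, n)
  if (is.null(pval)) {
    pval <- 2 * pnorm(-abs(beta / se))
  } else {
    # keep beta consistent with the requested p so validation stays quiet
    pval <- rep_len(pval, n)
    beta <- sign(beta) * qnorm(pval / 2, lower.tail = FALSE) * se
  }
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
             eaf = rep_len(eaf, n), beta = beta, se = se,
             pval = rep_len(pval, n), stringsAsFactors = FALSE)
}

make_sumstats <- function(..., trait_id = "trait", trait_type = "quantitative",
                          validate = TRUE) {
  sumstats(make_records(...), trait_id = trait_id, trait_type = trait_type,
           validate = validate)
}

# independent greedy-clump oracle: operates on a plain sorted data frame
oracle_clump <- function(df, r, r2_max, window_bp) {
  df <- df[order(df$pval, df$snp_id), ]
  kept <- character(0)
  while (nrow(df) > 0L) {
    lead <- df[1L, ]
    kept <- c(kept, lead$snp_id)
    df <- df[-1L, , drop = FALSE]
    if (nrow(df) > 0L) {
      drop <- df$chrom == lead$chrom &
        abs(df$pos - lead$pos) <= window_bp &
        r[df$snp_id, lead$snp_id]^2 >= r2_max
      df <- df[!drop, , drop = FALSE]
    }
  }
  kept
}
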
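# GWAS summary-statistics container, readers, and exposure/outcome
# harmonization to a common effect allele.

REQUIRED_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "beta", "se", "pval")
OPTIONAL_COLS <- c("eaf", "n")

#' GWAS summary statistics for one trait
#'
#' Builds a validated `sumstats` object from a data frame of per-SNP
#' association records. Rows violating the record invariants (non-positive
#' standard error, allele frequency outside \[0, 1\], identical alleles,
#' p-value outside (0, 1\]) are dropped with a message reporting the count.
#' When both `beta`/`se` and `pval` are supplied, records whose p-value
#' disagrees with the two-sided normal p implied by `|beta/se|` by more than
#' 10\% on the z scale trigger a warning but are kept.
#'
#' @param records Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`, and optionally
#'   `eaf` and `n`. Positions are 1-based base pairs. For binary traits
#'   `beta` is on the log-odds scale; for quantitative traits, in SD units.
#' @param trait_id Character label for the trait.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param n_case,n_control Case and control counts, required for
#'   `trait_type = "case_control"`.
#' @param validate Set `FALSE` to skip row filtering (e.g. for data already
#'   produced by this package).
#' @return An object of class `sumstats`: a list with elements `trait_id`,
#'   `trait_type`, `records` (the kept rows), `n_case`, `n_control`, and
#'   `n_dropped`.
#' @examples
#' rec <- data.frame(snp_id = "rs1", chrom = "1", pos = 100L,
#'                   effect_allele = "A", other_allele = "G",
#'                   eaf = 0.3, beta = 0.1, se = 0.02, pval = 5.7e-7)
#' ss <- sumstats(rec, trait_id = "PROT1", trait_type = "quantitative")
#' @export
sumstats <- function(records, trait_id, trait_type = c("quantitative", "case_control"),
                     n_case = NULL, n_control = NULL, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records)
  missing_cols <- setdiff(REQUIRED_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("summary statistics for '", trait_id, "' lack mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("summary statistics for '", trait_id, "' are empty", call. = FALSE)
  }
  if (trait_type == "case_control" && (is.null(n_case) || is.null(n_control))) {
    stop("case_control traits need n_case and n_control", call. = FALSE)
  }
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  if (!"n" %in% names(records)) records$n <- NA_real_
  records$eaf <- as.numeric(records$eaf)
  records$n <- as.numeric(records$n)
  records$chrom <- as.character(records$chrom)
  records$snp_id <- as.character(records$snp_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))

  n_dropped <- 0L
  if (validate) {
    ok <- is.finite(records$beta) & is.finite(records$se) & records$se > 0 &
      is.finite(records$pval) & records$pval > 0 & records$pval <= 1 &
      (is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)) &
      records$effect_allele != records$other_allele
    ok[is.na(ok)] <- FALSE
    n_dropped <- sum(!ok)
    if (n_dropped > 0L) {
      message("sumstats('", trait_id, "'): dropped ", n_dropped,
              " record(s) failing validation")
      records <- records[ok, , drop = FALSE]
    }
    if (nrow(records) == 0L) {
      stop("no valid records remain for '", trait_id, "'", call. = FALSE)
    }
    if (anyDuplicated(records$snp_id)) {
      stop("duplicate snp_id in '", trait_id, "'", call. = FALSE)
    }
    z <- abs(records$beta / records$se)
    z_from_p <- stats::qnorm(pmax(records$pval, 1e-300) / 2, lower.tail = FALSE)
    inconsistent <- z > 0 & is.finite(z_from_p) & z_from_p > 0 &
      abs(z - z_from_p) / pmax(z, z_from_p) > 0.10
    if (any(inconsistent)) {
      warning(sum(inconsistent), " record(s) in '", trait_id,
              "' have p-values inconsistent with |beta/se| beyond 10% ",
              "relative tolerance", call. = FALSE)
    }
  }
  rownames(records) <- NULL
  structure(
    list(trait_id = trait_id, trait_type = trait_type, records = records,
         n_case = n_case, n_control = n_control, n_dropped = n_dropped),
    class = "sumstats"
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat("<sumstats> trait:", x$trait_id, "(", x$trait_type, ")\n")
  cat("  records:", nrow(x$records), "SNPs on",
      length(unique(x$records$chrom)), "chromosome(s)\n")
  if (x$trait_type == "case_control") {
    cat("  cases:", x$n_case, " controls:", x$n_control, "\n")
  }
  invisible(x)
}

#' Number of records in a summary-statistics object
#' @param x A `sumstats` object.
#' @return Integer record count.
#' @export
n_records <- function(x) nrow(x$records)

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table with a header row and maps its
#' columns onto the canonical record fields. The delimiter is sniffed by
#' [data.table::fread()].
#'
#' @param path File path.
#' @param column_map Named character vector mapping canonical field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pval`, optionally `eaf`, `n`) to the column names used in the
#'   file. Fields absent from the map are assumed to use the canonical name.
#' @inheritParams sumstats
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = basename(path),
                          trait_type = c("quantitative", "case_control"),
                          n_case = NULL, n_control = NULL) {
  trait_type <- match.arg(trait_type)
  tab <- data.table::fread(path, data.table = FALSE)
  if (nrow(tab) == 0L) stop("empty summary-statistics table: ", path, call. = FALSE)
  wanted <- c(REQUIRED_COLS, OPTIONAL_COLS)
  map <- stats::setNames(wanted, wanted)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), wanted)
    if (length(unknown) > 0L) {
      stop("column_map has unknown field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  missing_req <- REQUIRED_COLS[!map[REQUIRED_COLS] %in% names(tab)]
  if (length(missing_req) > 0L) {
    stop("file ", path, " is missing mapped column(s) for: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  present <- wanted[map[wanted] %in% names(tab)]
  records <- tab[, map[present], drop = FALSE]
  names(records) <- present
  sumstats(records, trait_id = trait_id, trait_type = trait_type,
           n_case = n_case, n_control = n_control)
}

#' Write summary statistics as tab-delimited text
#'
#' The output uses the canonical column names and round-trips through
#' [read_sumstats()].
#'
#' @param x A `sumstats` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  data.table::fwrite(x$records, path, sep = "\t")
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) {
  out <- unname(COMPLEMENT[a])
  out[is.na(out)] <- NA_character_
  out
}

#' Classify a SNP's palindromic status
#'
#' A/T and C/G pairs read the same on both strands, so their orientation
#' cannot be resolved from allele labels alone. They can still be aligned
#' through the effect-allele frequency unless it is close to 0.5 (or
#' missing), in which case the SNP is ambiguous.
#'
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T).
#' @param eaf Effect-allele frequency, possibly `NA`.
#' @param ambiguity_band Half-width of the frequency band around 0.5 inside
#'   which a palindromic SNP is declared ambiguous (default 0.08).
#' @return One of `"not_palindromic"`, `"palindromic_resolvable"`,
#'   `"palindromic_ambiguous"` (vectorized).
#' @examples
#' is_palindromic("A", "G", 0.3)   # not_palindromic
#' is_palindromic("A", "T", 0.10)  # palindromic_resolvable
#' is_palindromic("C", "G", 0.49)  # palindromic_ambiguous
#' @export
is_palindromic <- function(effect_allele, other_allele, eaf = NA_real_,
                           ambiguity_band = 0.08) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  n <- max(length(effect_allele), length(other_allele), length(eaf))
  effect_allele <- rep_len(effect_allele, n)
  other_allele <- rep_len(other_allele, n)
  eaf <- rep_len(eaf, n)
  pal <- !is.na(effect_allele) & !is.na(other_allele) &
    effect_allele %in% names(COMPLEMENT) &
    other_allele == complement_allele(effect_allele)
  out <- rep("not_palindromic", n)
  ambiguous <- is.na(eaf) | abs(eaf - 0.5) < ambiguity_band
  out[pal & ambiguous] <- "palindromic_ambiguous"
  out[pal & !ambiguous] <- "palindromic_resolvable"
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two traits by `snp_id` and puts the outcome effect on the
#' exposure's effect allele. Outcome records whose alleles are in the
#' reverse orientation have their beta sign flipped and frequency
#' complemented (`action = "flipped"`); strand (complementary-base) label
#' differences are resolved the same way. Palindromic SNPs are aligned via
#' allele frequency when resolvable and dropped
#' (`action = "dropped_palindromic"`) when ambiguous and
#' `drop_ambiguous_palindromic` is set. Indels, multi-allelic sites, and
#' allele pairs that cannot be reconciled are dropped
#' (`action = "dropped_incompatible"`). Dropped rows carry no estimates.
#'
#' Harmonization is idempotent: re-harmonizing the exposure against the
#' harmonized outcome leaves every kept record unchanged.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param drop_ambiguous_palindromic Drop palindromic SNPs with frequency
#'   near 0.5 (default `TRUE`).
#' @param ambiguity_band Passed to [is_palindromic()].
#' @return A data frame of class `harmonized` with one row per intersected
#'   SNP: `snp_id`, `effect_allele`, `other_allele` (exposure orientation),
#'   `eaf_exp`, `beta_exp`, `se_exp`, `pval_exp`, `eaf_out`, `beta_out`,
#'   `se_out`, `pval_out`, `action`.
#' @export
harmonize <- function(exposure, outcome, drop_ambiguous_palindromic = TRUE,
                      ambiguity_band = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$records
  ou <- outcome$records
  common <- intersect(ex$snp_id, ou$snp_id)
  if (length(common) == 0L) {
    warning("no SNPs shared between '", exposure$trait_id, "' and '",
            outcome$trait_id, "'", call. = FALSE)
  }
  ex <- ex[match(common, ex$snp_id), , drop = FALSE]
  ou <- ou[match(common, ou$snp_id), , drop = FALSE]
  n <- length(common)

  out <- data.frame(
    snp_id = common, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf_exp = ex$eaf, beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval,
    eaf_out = rep(NA_real_, n), beta_out = rep(NA_real_, n),
    se_out = rep(NA_real_, n), pval_out = rep(NA_real_, n),
    action = rep("dropped_incompatible", n),
    stringsAsFactors = FALSE
  )

  bases <- names(COMPLEMENT)
  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (!all(c(ea_x, oa_x, ea_y, oa_y) %in% bases)) next  # indel/multi-base
    pal <- ea_x == complement_allele(oa_x)

    if (!pal) {
      if (ea_y == ea_x && oa_y == oa_x) {
        action <- "kept"
      } else if (ea_y == oa_x && oa_y == ea_x) {
        action <- "flipped"
      } else if (ea_y == complement_allele(ea_x) && oa_y == complement_allele(oa_x)) {
        action <- "kept"      # strand label difference only
      } else if (ea_y == complement_allele(oa_x) && oa_y == complement_allele(ea_x)) {
        action <- "flipped"
      } else {
        next
      }
    } else {
      # palindromic: allele labels cannot distinguish strand from swap
      same_set <- (ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x)
      if (!same_set) next
      flag <- is_palindromic(ea_x, oa_x, ex$eaf[i], ambiguity_band)
      out_ambiguous <- is.na(ou$eaf[i]) || abs(ou$eaf[i] - 0.5) < ambiguity_band
      if (flag == "palindromic_ambiguous" || out_ambiguous) {
        if (drop_ambiguous_palindromic) {
          out$action[i] <- "dropped_palindromic"
          next
        }
        action <- if (ea_y == ea_x) "kept" else "flipped"
      } else {
        # align by frequency: the outcome effect allele is the exposure
        # effect allele iff their (label-aligned) frequencies sit on the
        # same side of 0.5
        eaf_y_lab <- if (ea_y == ea_x) ou$eaf[i] else 1 - ou$eaf[i]
        same_side <- (ex$eaf[i] < 0.5) == (eaf_y_lab < 0.5)
        label_action <- if (ea_y == ea_x) "kept" else "flipped"
        action <- if (same_side) label_action else
          if (label_action == "kept") "flipped" else "kept"
      }
    }

    out$action[i] <- action
    if (action == "kept") {
      out$beta_out[i] <- ou$beta[i]
      out$eaf_out[i] <- ou$eaf[i]
    } else {
      out$beta_out[i] <- -ou$beta[i]
      out$eaf_out[i] <- 1 - ou$eaf[i]
    }
    out$se_out[i] <- ou$se[i]
    out$pval_out[i] <- ou$pval[i]
  }
  class(out) <- c("harmonized", "data.frame")
  out
}

#' Kept rows of a harmonization table
#' @param h A `harmonized` data frame.
#' @return The subset of rows with action `kept` or `flipped`.
#' @export
harmonized_kept <- function(h) {
  h[h$action %in% c("kept", "flipped"), , drop = FALSE]
}

#' Convert harmonized outcome records back into a `sumstats` object
#'
#' Useful for audits (e.g. verifying harmonization idempotence): kept and
#' flipped rows become outcome records expressed on the exposure's effect
#' allele.
#'
#' @param h A `harmonized` data frame.
#' @param outcome The original outcome `sumstats` (supplies trait metadata).
#' @return A `sumstats` object.
#' @export
harmonized_outcome <- function(h, outcome) {
  k <- harmonized_kept(h)
  rec <- data.frame(
    snp_id = k$snp_id, chrom = k$chrom, pos = k$pos,
    effect_allele = k$effect_allele, other_allele = k$other_allele,
    eaf = k$eaf_out, beta = k$beta_out, se = k$se_out, pval = k$pval_out,
    stringsAsFactors = FALSE
  )
  sumstats(rec, trait_id = outcome$trait_id, trait_type = outcome$trait_type,
           n_case = outcome$n_case, n_control = outcome$n_control,
           validate = FALSE)
}

#' Write a harmonization audit table
#' @param h A `harmonized` data frame.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  data.table::fwrite(as.data.frame(h), path, sep = "\t")
  invisible(path)
}
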
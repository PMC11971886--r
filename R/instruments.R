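# Instrument selection for one exposure: cis-window restriction,
# genome-wide-significance filter, greedy LD clumping, weak-instrument gate.

#' Gene annotation table
#'
#' @param gene_id Character vector of gene identifiers (unique).
#' @param chrom Chromosome of each gene.
#' @param tss Transcription start site, 1-based base pairs (> 0).
#' @return Data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, tss) {
  stopifnot(length(gene_id) == length(chrom), length(gene_id) == length(tss))
  if (anyDuplicated(gene_id)) stop("gene_id must be unique", call. = FALSE)
  if (any(tss <= 0)) stop("tss must be positive", call. = FALSE)
  structure(
    data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
               tss = as.integer(tss), stringsAsFactors = FALSE),
    class = c("gene_annotation", "data.frame")
  )
}

#' Read a gene annotation table
#'
#' Expects delimited text with columns `gene_id`, `chrom`, `tss`.
#' @param path File path.
#' @return A `gene_annotation` data frame.
#' @export
read_gene_annotation <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE)
  need <- c("gene_id", "chrom", "tss")
  if (!all(need %in% names(tab))) {
    stop("gene annotation must have columns gene_id, chrom, tss", call. = FALSE)
  }
  gene_annotation(tab$gene_id, tab$chrom, tab$tss)
}

lookup_gene <- function(annotation, gene_id) {
  i <- match(gene_id, annotation$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id, call. = FALSE)
  annotation[i, , drop = FALSE]
}

#' LD correlation matrix for a set of SNPs
#'
#' @param r Square matrix of pairwise correlations in \[-1, 1\].
#' @param snp_ids SNP identifiers, one per row/column of `r`.
#' @param tol Numerical tolerance for the symmetry, unit-diagonal, and
#'   positive-semidefiniteness checks (default 1e-8).
#' @return Object of class `ld_matrix`: list with `snp_ids` and `r`.
#' @export
ld_matrix <- function(r, snp_ids, tol = 1e-8) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r), length(snp_ids) == nrow(r))
  if (max(abs(r - t(r))) > tol) stop("LD matrix is not symmetric", call. = FALSE)
  if (max(abs(diag(r) - 1)) > tol) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (any(abs(r) > 1 + tol)) stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  ev_min <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -tol) {
    stop("LD matrix is not positive semidefinite (min eigenvalue ",
         format(ev_min), ")", call. = FALSE)
  }
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r = r), class = "ld_matrix")
}

#' Read an LD matrix from delimited text
#'
#' Expects a square numeric matrix whose header row holds the SNP ids.
#' @param path File path.
#' @return An `ld_matrix` object.
#' @export
read_ld_matrix <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE)
  ld_matrix(as.matrix(tab), snp_ids = names(tab))
}

#' Write an LD matrix as delimited text
#' @param ld An `ld_matrix` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  data.table::fwrite(as.data.frame(ld$r), path, sep = "\t")
  invisible(path)
}

# Pairwise r between candidate SNPs; `ld` may be one ld_matrix or a list of
# block ld_matrix objects (zero correlation across blocks). Errors on SNPs
# absent from every block.
ld_submatrix <- function(ld, snp_ids) {
  if (inherits(ld, "ld_matrix")) ld <- list(ld)
  all_ids <- unlist(lapply(ld, `[[`, "snp_ids"))
  missing <- setdiff(snp_ids, all_ids)
  if (length(missing) > 0L) {
    stop("SNP(s) missing from the LD matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  r <- matrix(0, length(snp_ids), length(snp_ids),
              dimnames = list(snp_ids, snp_ids))
  diag(r) <- 1
  for (block in ld) {
    here <- intersect(snp_ids, block$snp_ids)
    if (length(here) > 1L) r[here, here] <- block$r[here, here]
  }
  r
}

#' Restrict summary statistics to a gene's cis window
#'
#' Keeps records on the gene's chromosome with position within
#' `window_bp` of the transcription start site; the window is closed
#' (a SNP exactly `window_bp` away is kept).
#'
#' @param x A `sumstats` object.
#' @param gene One row of a [gene_annotation()] table, or a gene id plus
#'   `annotation`.
#' @param window_bp Half-width of the cis window in base pairs
#'   (default 1 Mb).
#' @param annotation Optional `gene_annotation` used when `gene` is an id.
#' @return A `sumstats` object with the cis records.
#' @export
cis_filter <- function(x, gene, window_bp = 1e6, annotation = NULL) {
  stopifnot(inherits(x, "sumstats"), window_bp > 0)
  if (is.character(gene)) gene <- lookup_gene(annotation, gene)
  keep <- x$records$chrom == gene$chrom &
    abs(x$records$pos - gene$tss) <= window_bp
  out <- x
  out$records <- x$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Keep genome-wide (or preset) significant records
#'
#' The inequality is strict: a record at exactly `p_max` is excluded.
#'
#' @param x A `sumstats` object.
#' @param p_max Significance threshold in (0, 1), e.g. 5e-8 for pQTLs.
#' @return Filtered `sumstats`.
#' @export
significance_filter <- function(x, p_max = 5e-8) {
  stopifnot(inherits(x, "sumstats"), p_max > 0, p_max < 1)
  out <- x
  out$records <- x$records[x$records$pval < p_max, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Single-SNP instrument-strength F statistic
#'
#' The per-SNP F is the squared z statistic, `(beta/se)^2`; F > 10 is the
#' conventional weak-instrument gate.
#'
#' @param beta,se Effect estimate and its standard error (`se > 0`).
#' @return F values (vectorized).
#' @examples
#' f_statistic(0.1, 0.02)  # 25
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  (beta / se)^2
}

#' Greedy LD clumping of candidate instruments
#'
#' PLINK-style greedy clumping: repeatedly keep the remaining SNP with the
#' smallest p-value (ties broken by lexicographic `snp_id`) and discard all
#' remaining SNPs within `window_kb` of it whose squared correlation with
#' it is at least `r2_max`. SNPs on different chromosomes are never clumped
#' together. The kept set is invariant to the input row order.
#'
#' @param x A `sumstats` object of candidate SNPs.
#' @param ld An `ld_matrix`, or a list of block `ld_matrix` objects with
#'   zero cross-block correlation. Every candidate must appear in `ld`.
#' @param r2_max Squared-correlation threshold in (0, 1); kept pairs within
#'   the window satisfy `r^2 < r2_max`.
#' @param window_kb Clump distance window in kilobases (1 kb = 1000 bp).
#' @return List with `kept` (a `sumstats` of retained SNPs, in kept order)
#'   and `log` (data frame `snp_id`, `reason` of `selected`/`clumped_out`).
#' @export
ld_clump <- function(x, ld, r2_max = 0.1, window_kb = 10000) {
  stopifnot(inherits(x, "sumstats"), r2_max > 0, r2_max < 1, window_kb > 0)
  rec <- x$records
  if (nrow(rec) == 0L) {
    out <- x
    return(list(kept = out,
                log = data.frame(snp_id = character(), reason = character())))
  }
  r <- ld_submatrix(ld, rec$snp_id)
  ord <- order(rec$pval, rec$snp_id)
  remaining <- rec$snp_id[ord]
  pos <- stats::setNames(rec$pos, rec$snp_id)
  chrom <- stats::setNames(rec$chrom, rec$snp_id)
  kept <- character(0)
  reason <- stats::setNames(rep("clumped_out", nrow(rec)), rec$snp_id)
  window_bp <- window_kb * 1000
  while (length(remaining) > 0L) {
    lead <- remaining[1L]
    kept <- c(kept, lead)
    reason[lead] <- "selected"
    remaining <- remaining[-1L]
    if (length(remaining) > 0L) {
      near <- chrom[remaining] == chrom[lead] &
        abs(pos[remaining] - pos[lead]) <= window_bp
      correlated <- r[remaining, lead]^2 >= r2_max
      remaining <- remaining[!(near & correlated)]
    }
  }
  out <- x
  out$records <- rec[match(kept, rec$snp_id), , drop = FALSE]
  rownames(out$records) <- NULL
  list(kept = out,
       log = data.frame(snp_id = rec$snp_id, reason = unname(reason[rec$snp_id]),
                        stringsAsFactors = FALSE))
}

#' Threshold presets for instrument selection
#'
#' `pqtl`: cis-pQTL instruments — p < 5e-8, r^2 < 0.1, 10,000 kb clump
#' window, cis window +/- 1 Mb of the TSS, F > 10. `lifestyle`: lifestyle
#' exposures — p < 1e-5, r^2 < 0.001, 10,000 kb, genome-wide (no cis
#' window), F > 10.
#'
#' @param name `"pqtl"` or `"lifestyle"`.
#' @return Named list: `window_bp` (NA = no cis restriction), `p_max`,
#'   `r2_max`, `clump_window_kb`, `f_min`.
#' @export
instrument_preset <- function(name = c("pqtl", "lifestyle")) {
  name <- match.arg(name)
  switch(name,
    pqtl = list(window_bp = 1e6, p_max = 5e-8, r2_max = 0.1,
                clump_window_kb = 10000, f_min = 10),
    lifestyle = list(window_bp = NA_real_, p_max = 1e-5, r2_max = 0.001,
                     clump_window_kb = 10000, f_min = 10)
  )
}

#' Select instrumental variables for one exposure
#'
#' Applies, in order: the cis-window restriction (skipped when `gene` is
#' `NULL` or the preset has no window), the significance filter, greedy LD
#' clumping, and the weak-instrument F gate. The selection log assigns each
#' input SNP exactly one reason: `cis_fail`, `pval_fail`, `clumped_out`,
#' `weak_instrument`, or `selected`.
#'
#' @param x A `sumstats` object (the exposure GWAS, or its region).
#' @param gene A `gene_annotation` row or gene id (with `annotation`), or
#'   `NULL` for genome-wide selection (e.g. reverse MR, lifestyle traits).
#' @param ld An `ld_matrix` or list of block matrices covering all
#'   candidates that survive the p-value filter.
#' @param cfg Threshold list as from [instrument_preset()]; individual
#'   entries can be overridden via `...`.
#' @param annotation Optional `gene_annotation` for id lookup.
#' @param ... Named overrides of `cfg` entries.
#' @return Object of class `instrument_set`: list with `exposure_id`,
#'   `selected` (records data frame), `f_stats`, and `selection_log`.
#' @export
select_instruments <- function(x, gene = NULL, ld, cfg = instrument_preset("pqtl"),
                               annotation = NULL, ...) {
  stopifnot(inherits(x, "sumstats"))
  dots <- list(...)
  cfg[names(dots)] <- dots
  log <- stats::setNames(rep(NA_character_, nrow(x$records)), x$records$snp_id)

  stage <- x
  if (!is.null(gene) && !is.na(cfg$window_bp)) {
    stage <- cis_filter(stage, gene, window_bp = cfg$window_bp,
                        annotation = annotation)
    log[setdiff(names(log), stage$records$snp_id)] <- "cis_fail"
  }
  sig <- significance_filter(stage, p_max = cfg$p_max)
  log[setdiff(stage$records$snp_id, sig$records$snp_id)] <- "pval_fail"

  if (nrow(sig$records) > 0L) {
    cl <- ld_clump(sig, ld, r2_max = cfg$r2_max, window_kb = cfg$clump_window_kb)
    log[cl$log$snp_id] <- cl$log$reason
    f <- f_statistic(cl$kept$records$beta, cl$kept$records$se)
    weak <- f <= cfg$f_min
    log[cl$kept$records$snp_id[weak]] <- "weak_instrument"
    selected <- cl$kept$records[!weak, , drop = FALSE]
    f_stats <- stats::setNames(f[!weak], selected$snp_id)
  } else {
    selected <- sig$records
    f_stats <- stats::setNames(numeric(0), character(0))
  }
  rownames(selected) <- NULL
  structure(
    list(exposure_id = x$trait_id, selected = selected, f_stats = f_stats,
         selection_log = data.frame(snp_id = names(log), reason = unname(log),
                                    stringsAsFactors = FALSE)),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set>", x$exposure_id, ":", nrow(x$selected),
      "instrument(s) of", nrow(x$selection_log), "input SNP(s)\n")
  if (nrow(x$selected) > 0L) {
    cat("  F range:", paste(signif(range(x$f_stats), 4), collapse = " - "), "\n")
  }
  invisible(x)
}

#' Turn an instrument set back into a `sumstats` object
#' @param instr An `instrument_set`.
#' @param template The exposure `sumstats` the set was selected from
#'   (supplies trait metadata).
#' @return A `sumstats` holding only the selected instruments.
#' @export
instruments_as_sumstats <- function(instr, template) {
  stopifnot(inherits(instr, "instrument_set"), nrow(instr$selected) > 0L)
  ss <- template
  ss$records <- instr$selected
  ss
}
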
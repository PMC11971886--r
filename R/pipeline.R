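# Orchestration of the full screen: proteome-wide forward MR -> FDR ->
# colocalization follow-up -> reverse MR -> lifestyle MR, plus report
# writing. Stage ordering is enforced: colocalization and reverse MR only
# ever see FDR survivors.

#' Run configuration for the MR/colocalization pipeline
#'
#' @param preset Instrument preset for protein exposures
#'   (see [instrument_preset()]).
#' @param lifestyle_preset Preset for lifestyle exposures.
#' @param fdr_threshold FDR significance threshold (default 0.05).
#' @param pph4_min,sum34_min Colocalization decision thresholds
#'   (defaults 0.75 and 0.8).
#' @param p1,p2,p12 Colocalization priors.
#' @param prior_sd_quant,prior_sd_cc Wakefield effect-prior SDs for
#'   quantitative and case-control traits.
#' @param drop_ambiguous_palindromic,ambiguity_band Harmonization options.
#' @param reverse_family Which proteins form the reverse-MR FDR family:
#'   `"provided"` uses exactly the protein list passed to
#'   [run_reverse_mr()] (the colocalization survivors in [run_study()]).
#' @param seed Integer seed echoed into the report manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(preset = "pqtl", lifestyle_preset = "lifestyle",
                       fdr_threshold = 0.05, pph4_min = 0.75, sum34_min = 0.8,
                       p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       prior_sd_quant = 0.2, prior_sd_cc = 0.15,
                       drop_ambiguous_palindromic = TRUE, ambiguity_band = 0.08,
                       reverse_family = "provided", seed = 1) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            pph4_min > 0, pph4_min < 1, sum34_min > 0, sum34_min < 1)
  structure(
    list(preset = instrument_preset(preset),
         lifestyle_preset = instrument_preset(lifestyle_preset),
         fdr_threshold = fdr_threshold, pph4_min = pph4_min,
         sum34_min = sum34_min, p1 = p1, p2 = p2, p12 = p12,
         prior_sd_quant = prior_sd_quant, prior_sd_cc = prior_sd_cc,
         drop_ambiguous_palindromic = drop_ambiguous_palindromic,
         ambiguity_band = ambiguity_band, reverse_family = reverse_family,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

prior_sd_for <- function(cfg, trait_type) {
  if (trait_type == "case_control") cfg$prior_sd_cc else cfg$prior_sd_quant
}

# restrict a sumstats object to the given snp_ids using a prebuilt
# snp_id -> row-index map (avoids rehashing a large table per exposure)
subset_by_index <- function(ss, idx_map, snp_ids) {
  rows <- idx_map[snp_ids]
  rows <- rows[!is.na(rows)]
  out <- ss
  out$records <- ss$records[rows, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

mr_one_exposure <- function(exposure_ss, gene, ld, outcome, cfg,
                            preset = cfg$preset, outcome_index = NULL) {
  instr <- select_instruments(exposure_ss, gene = gene, ld = ld, cfg = preset)
  if (nrow(instr$selected) == 0L) {
    return(list(result = NULL, instruments = instr,
                skip_reason = paste0("no instruments (",
                  paste(sort(unique(instr$selection_log$reason)),
                        collapse = "/"), ")")))
  }
  if (!is.null(outcome_index)) {
    outcome <- subset_by_index(outcome, outcome_index, instr$selected$snp_id)
  }
  h <- harmonize(instruments_as_sumstats(instr, exposure_ss), outcome,
                 drop_ambiguous_palindromic = cfg$drop_ambiguous_palindromic,
                 ambiguity_band = cfg$ambiguity_band)
  kept <- harmonized_kept(h)
  if (nrow(kept) == 0L) {
    return(list(result = NULL, instruments = instr,
                skip_reason = "no instruments survived harmonization"))
  }
  list(result = mr_per_exposure(kept, exposure_id = exposure_ss$trait_id,
                                outcome_id = outcome$trait_id),
       instruments = instr, skip_reason = NULL)
}

#' Forward MR across all exposures with FDR prioritization
#'
#' For every exposure: instrument selection, harmonization against the
#' outcome, and the per-exposure MR estimate; then Benjamini-Hochberg FDR
#' across the family of exposures that yielded at least one instrument.
#' Exposures without usable instruments are excluded from the FDR family
#' and logged.
#'
#' @param study An `mr_study` (from [simulate_mr_study()] or
#'   [load_study()]).
#' @param cfg A [run_config()].
#' @return List of class `forward_mr`: `results` (MR table with
#'   `pval_fdr` and `significant`), `skipped` (data frame of excluded
#'   exposures with reasons), `survivors` (FDR-significant exposure ids).
#' @export
run_forward_mr <- function(study, cfg = run_config()) {
  stopifnot(inherits(study, "mr_study"), inherits(cfg, "run_config"))
  rows <- list()
  skipped <- list()
  outcome_index <- stats::setNames(seq_len(nrow(study$outcome$records)),
                                   study$outcome$records$snp_id)
  for (id in names(study$exposures)) {
    ld_here <- if (!is.null(study$ld[[id]])) study$ld[[id]] else study$ld
    fit <- mr_one_exposure(study$exposures[[id]],
                           gene = lookup_gene(study$annotation, id),
                           ld = ld_here, outcome = study$outcome, cfg = cfg,
                           outcome_index = outcome_index)
    if (is.null(fit$result)) {
      skipped[[id]] <- data.frame(exposure = id, reason = fit$skip_reason,
                                  stringsAsFactors = FALSE)
    } else {
      rows[[id]] <- fit$result
    }
  }
  if (length(rows) == 0L) {
    stop("no exposure yielded instruments (", length(skipped), " skipped)",
         call. = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results$pval_fdr <- bh_fdr(results$pval)
  results$significant <- results$pval_fdr < cfg$fdr_threshold
  structure(
    list(results = results,
         skipped = if (length(skipped)) do.call(rbind, c(skipped,
             make.row.names = FALSE)) else
           data.frame(exposure = character(), reason = character()),
         survivors = results$exposure[results$significant]),
    class = "forward_mr"
  )
}

#' Colocalization follow-up of FDR survivors
#'
#' For each surviving protein, aligns its cis-region summary statistics
#' with the outcome's statistics over the same region (via [harmonize()])
#' and runs the five-hypothesis colocalization with the configured priors
#' and decision thresholds. Survivors whose region cannot be aligned are
#' skipped with a logged reason, not an error.
#'
#' @param study An `mr_study`.
#' @param survivors Character vector of exposure ids (normally
#'   `forward$survivors`).
#' @param cfg A [run_config()].
#' @return Data frame of class `coloc_table`: one row per survivor with
#'   `exposure`, `n_snps`, `pph0` ... `pph4`, `decision`, `reason`.
#' @export
run_coloc_followup <- function(study, survivors, cfg = run_config()) {
  stopifnot(inherits(study, "mr_study"))
  outcome_index <- stats::setNames(seq_len(nrow(study$outcome$records)),
                                   study$outcome$records$snp_id)
  rows <- lapply(survivors, function(id) {
    gene <- lookup_gene(study$annotation, id)
    region <- cis_filter(study$exposures[[id]], gene,
                         window_bp = cfg$preset$window_bp)
    if (nrow(region$records) == 0L) {
      return(data.frame(exposure = id, n_snps = 0L, pph0 = NA_real_,
                        pph1 = NA_real_, pph2 = NA_real_, pph3 = NA_real_,
                        pph4 = NA_real_, decision = "skipped",
                        reason = "no regional data", stringsAsFactors = FALSE))
    }
    out_sub <- subset_by_index(study$outcome, outcome_index,
                               region$records$snp_id)
    h <- harmonized_kept(harmonize(region, out_sub,
        drop_ambiguous_palindromic = cfg$drop_ambiguous_palindromic,
        ambiguity_band = cfg$ambiguity_band))
    if (nrow(h) == 0L) {
      return(data.frame(exposure = id, n_snps = 0L, pph0 = NA_real_,
                        pph1 = NA_real_, pph2 = NA_real_, pph3 = NA_real_,
                        pph4 = NA_real_, decision = "skipped",
                        reason = "no aligned outcome data",
                        stringsAsFactors = FALSE))
    }
    inp <- coloc_input(h$beta_exp, h$se_exp, h$beta_out, h$se_out,
                       snp_ids = h$snp_id,
                       type1 = study$exposures[[id]]$trait_type,
                       type2 = study$outcome$trait_type,
                       prior_sd1 = prior_sd_for(cfg, study$exposures[[id]]$trait_type),
                       prior_sd2 = prior_sd_for(cfg, study$outcome$trait_type),
                       p1 = cfg$p1, p2 = cfg$p2, p12 = cfg$p12)
    res <- coloc_abf(inp)
    dec <- coloc_decision(res, pph4_min = cfg$pph4_min,
                          sum34_min = cfg$sum34_min)
    data.frame(exposure = id, n_snps = res$n_snps, pph0 = res$pph0,
               pph1 = res$pph1, pph2 = res$pph2, pph3 = res$pph3,
               pph4 = res$pph4, decision = dec$decision, reason = dec$reason,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(exposure = character(), n_snps = integer(), pph0 = numeric(),
               pph1 = numeric(), pph2 = numeric(), pph3 = numeric(),
               pph4 = numeric(), decision = character(), reason = character())
  class(out) <- c("coloc_table", "data.frame")
  out
}

#' Reverse-direction MR: outcome as exposure
#'
#' Selects instruments for the outcome trait genome-wide (the protein
#' preset's significance, clumping, and F thresholds, but no cis window),
#' then estimates the outcome's effect on each listed protein, with BH-FDR
#' across the protein family. Proteins sharing no SNPs with the outcome
#' instruments get a not-applicable row.
#'
#' @param study An `mr_study`.
#' @param proteins Character vector of protein exposure ids to test.
#' @param cfg A [run_config()].
#' @return Data frame of class `reverse_mr_table` (same MR columns, plus
#'   `pval_fdr`, `significant`, `note`).
#' @export
run_reverse_mr <- function(study, proteins, cfg = run_config()) {
  stopifnot(inherits(study, "mr_study"))
  preset <- cfg$preset
  preset$window_bp <- NA_real_   # genome-wide: no cis restriction
  instr <- select_instruments(study$outcome, gene = NULL, ld = study$ld,
                              cfg = preset)
  na_row <- function(id, note) {
    data.frame(exposure = study$outcome$trait_id, outcome = id,
               method = NA_character_, n_snp = 0L, beta = NA_real_,
               se = NA_real_, pval = NA_real_, or = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, q_stat = NA_real_,
               q_df = NA_integer_, q_pval = NA_real_,
               egger_intercept = NA_real_, egger_intercept_se = NA_real_,
               egger_intercept_pval = NA_real_, note = note,
               stringsAsFactors = FALSE)
  }
  if (nrow(instr$selected) == 0L) {
    out <- do.call(rbind, lapply(proteins, na_row,
                                 note = "no genome-wide outcome instruments"))
  } else {
    out_ss <- instruments_as_sumstats(instr, study$outcome)
    rows <- lapply(proteins, function(id) {
      h <- harmonized_kept(harmonize(out_ss, study$exposures[[id]],
          drop_ambiguous_palindromic = cfg$drop_ambiguous_palindromic,
          ambiguity_band = cfg$ambiguity_band))
      if (nrow(h) == 0L) return(na_row(id, "no overlapping instruments"))
      res <- mr_per_exposure(h, exposure_id = study$outcome$trait_id,
                             outcome_id = id)
      res$note <- ""
      res
    })
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  tested <- !is.na(out$pval)
  out$pval_fdr <- NA_real_
  out$pval_fdr[tested] <- bh_fdr(out$pval[tested])
  out$significant <- !is.na(out$pval_fdr) & out$pval_fdr < cfg$fdr_threshold
  class(out) <- c("reverse_mr_table", "data.frame")
  out
}

#' Lifestyle-exposure MR on protein outcomes
#'
#' Runs MR of each lifestyle exposure on the protein outcome(s) using the
#' lifestyle instrument preset (p < 1e-5, r^2 < 0.001, 10,000 kb,
#' genome-wide). Headline significance uses the nominal p-value; a BH-FDR
#' column is reported alongside for reference but does not drive the flag.
#'
#' @param lifestyle_study An `mr_study` whose outcome is a protein (see
#'   [simulate_lifestyle_study()]), or a list of such studies (one per
#'   protein outcome).
#' @param cfg A [run_config()].
#' @param alpha Nominal significance level for the headline flag
#'   (default 0.05).
#' @return Data frame of class `lifestyle_mr_table`.
#' @export
run_lifestyle_mr <- function(lifestyle_study, cfg = run_config(), alpha = 0.05) {
  if (inherits(lifestyle_study, "mr_study")) {
    studies <- list(lifestyle_study)
  } else {
    studies <- lifestyle_study
  }
  rows <- list()
  for (study in studies) {
    stopifnot(inherits(study, "mr_study"))
    outcome_index <- stats::setNames(seq_len(nrow(study$outcome$records)),
                                     study$outcome$records$snp_id)
    for (id in names(study$exposures)) {
      ld_here <- if (!is.null(study$ld[[id]])) study$ld[[id]] else study$ld
      fit <- mr_one_exposure(study$exposures[[id]], gene = NULL,
                             ld = ld_here, outcome = study$outcome,
                             cfg = cfg, preset = cfg$lifestyle_preset,
                             outcome_index = outcome_index)
      if (!is.null(fit$result)) rows[[paste(id, study$outcome$trait_id)]] <- fit$result
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(exposure = character(), outcome = character(),
                      method = character(), n_snp = integer(),
                      beta = numeric(), se = numeric(), pval = numeric())
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$pval_fdr <- bh_fdr(out$pval)
    out$significant_nominal <- out$pval < alpha
  }
  class(out) <- c("lifestyle_mr_table", "data.frame")
  out
}

#' Run the complete study and (optionally) write the report
#'
#' Executes the stages in their designed order: forward MR with FDR, then
#' colocalization of the FDR survivors, then reverse MR of the
#' colocalization-validated proteins, then (if a lifestyle study is given)
#' lifestyle MR. When `output_dir` is set the report is written with
#' [write_report()].
#'
#' @param study An `mr_study`.
#' @param cfg A [run_config()].
#' @param lifestyle_study Optional lifestyle `mr_study` (or list of them).
#' @param output_dir Optional directory for the on-disk report.
#' @return List of class `study_report`: `forward`, `coloc`, `reverse`,
#'   `lifestyle` (NULL when not run), `config`.
#' @export
run_study <- function(study, cfg = run_config(), lifestyle_study = NULL,
                      output_dir = NULL) {
  forward <- run_forward_mr(study, cfg)
  coloc_tab <- run_coloc_followup(study, forward$survivors, cfg)
  validated <- coloc_tab$exposure[coloc_tab$decision == "colocalized"]
  reverse <- if (length(validated) > 0L) {
    run_reverse_mr(study, validated, cfg)
  } else NULL
  lifestyle <- if (!is.null(lifestyle_study)) {
    run_lifestyle_mr(lifestyle_study, cfg)
  } else NULL
  report <- structure(
    list(forward = forward, coloc = coloc_tab, reverse = reverse,
         lifestyle = lifestyle, config = cfg),
    class = "study_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  forward MR:", nrow(x$forward$results), "exposure(s),",
      length(x$forward$survivors), "FDR-significant\n")
  cat("  colocalized:", sum(x$coloc$decision == "colocalized"), "of",
      nrow(x$coloc), "\n")
  if (!is.null(x$reverse)) {
    cat("  reverse MR significant:", sum(x$reverse$significant), "of",
        nrow(x$reverse), "\n")
  }
  if (!is.null(x$lifestyle) && nrow(x$lifestyle) > 0L) {
    cat("  lifestyle MR nominally significant:",
        sum(x$lifestyle$significant_nominal), "of", nrow(x$lifestyle), "\n")
  }
  invisible(x)
}

#' Write the study report to disk
#'
#' Emits one tab-delimited table per stage that ran
#' (`forward_mr.tsv`, `coloc.tsv`, `reverse_mr.tsv`, `lifestyle_mr.tsv`,
#' `skipped_exposures.tsv`) plus a key-value `manifest.txt` echoing the
#' seed, thresholds, and row counts; stages that did not run are marked
#' `not_run` in the manifest. Re-running with the same seed reproduces
#' every file byte-identically.
#'
#' @param report A `study_report` from [run_study()].
#' @param output_dir Directory to write into (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  stopifnot(inherits(report, "study_report"))
  ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  }
  wr <- function(tab, name) {
    data.table::fwrite(as.data.frame(tab), file.path(output_dir, name),
                       sep = "\t")
  }
  wr(report$forward$results, "forward_mr.tsv")
  wr(report$forward$skipped, "skipped_exposures.tsv")
  wr(report$coloc, "coloc.tsv")
  if (!is.null(report$reverse)) wr(report$reverse, "reverse_mr.tsv")
  if (!is.null(report$lifestyle)) wr(report$lifestyle, "lifestyle_mr.tsv")

  cfg <- report$config
  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("pqtlmr"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("fdr_threshold: %g", cfg$fdr_threshold),
    sprintf("pph4_min: %g", cfg$pph4_min),
    sprintf("sum34_min: %g", cfg$sum34_min),
    sprintf("coloc_priors: p1=%g p2=%g p12=%g", cfg$p1, cfg$p2, cfg$p12),
    sprintf("instrument_preset: p_max=%g r2_max=%g clump_window_kb=%g f_min=%g",
            cfg$preset$p_max, cfg$preset$r2_max, cfg$preset$clump_window_kb,
            cfg$preset$f_min),
    sprintf("n_exposures_tested: %d", nrow(report$forward$results)),
    sprintf("n_exposures_skipped: %d", nrow(report$forward$skipped)),
    sprintf("n_fdr_significant: %d", length(report$forward$survivors)),
    sprintf("n_colocalized: %d", sum(report$coloc$decision == "colocalized")),
    if (is.null(report$reverse)) "reverse_mr: not_run" else
      sprintf("n_reverse_significant: %d", sum(report$reverse$significant)),
    if (is.null(report$lifestyle)) "lifestyle_mr: not_run" else
      sprintf("n_lifestyle_rows: %d", nrow(report$lifestyle))
  )
  writeLines(manifest, file.path(output_dir, "manifest.txt"))
  invisible(output_dir)
}

#' Load a study from files listed in a YAML config
#'
#' The config must name: `exposures` (list of `id:`/`path:` entries, or a
#' named map id -> path), `outcome` (`path`, `trait_type`, optional
#' `n_case`/`n_control`), `annotation` (path), and `ld` (named map region
#' id -> LD-matrix path). All tables use the package's delimited-text
#' dialects.
#'
#' @param path Path to the YAML config.
#' @return An `mr_study`.
#' @export
load_study <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  exposures <- list()
  for (nm in names(cfg$exposures)) {
    exposures[[nm]] <- read_sumstats(resolve(cfg$exposures[[nm]]),
                                     trait_id = nm)
  }
  out_cfg <- cfg$outcome
  outcome <- read_sumstats(resolve(out_cfg$path),
                           trait_id = if (is.null(out_cfg$trait_id)) "outcome"
                             else out_cfg$trait_id,
                           trait_type = out_cfg$trait_type,
                           n_case = out_cfg$n_case,
                           n_control = out_cfg$n_control)
  annotation <- read_gene_annotation(resolve(cfg$annotation))
  ld <- lapply(cfg$ld, function(p) read_ld_matrix(resolve(p)))
  truth <- data.frame(exposure_id = names(exposures),
                      causal = NA, theta = NA_real_,
                      causal_snps = NA_character_, stringsAsFactors = FALSE)
  structure(
    list(exposures = exposures, outcome = outcome, annotation = annotation,
         ld = ld, truth = truth,
         params = list(source = path)),
    class = "mr_study"
  )
}
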
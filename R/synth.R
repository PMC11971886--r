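# Synthetic GWAS summary statistics with known truth. Regional z-scores are
# drawn directly from their asymptotic sampling distribution,
#   z ~ MVN(sqrt(n) * R %*% b, R),
# where R is the LD correlation matrix and b the joint (per-SD-genotype)
# causal effect vector — no individual-level genotypes are simulated.
# Quantitative traits use se = 1/sqrt(n); case-control traits use the
# effective sample size n_eff = 4 / (1/n_case + 1/n_control) with betas
# interpreted on the log-odds scale.

# --- seeding ---------------------------------------------------------------
# All randomness flows from one integer seed; child seeds are derived
# arithmetically so module-level reproducibility holds regardless of call
# order. Child seeds stay below 2^31 - 1.
child_seed <- function(seed, index) {
  as.integer((as.double(seed %% 2147483647L) * 1000003 + index * 7919) %% 2147483629)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- LD --------------------------------------------------------------------

#' AR(1) LD correlation matrix
#'
#' `r[i, j] = rho^|i - j|`; symmetric and positive definite for
#' `0 <= rho < 1`, a standard stand-in for the decay of linkage
#' disequilibrium with distance along a region.
#'
#' @param n_snps Number of SNPs.
#' @param rho Adjacent-SNP correlation in \[0, 1).
#' @param snp_ids Optional SNP identifiers.
#' @return An [ld_matrix()] object.
#' @export
ar1_ld <- function(n_snps, rho, snp_ids = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%04d", seq_len(n_snps))
  idx <- seq_len(n_snps)
  r <- rho^abs(outer(idx, idx, "-"))
  ld_matrix(r, snp_ids)
}

# non-palindromic ordered allele pairs (effect, other)
ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "C", "A", "C", "T",
                         "G", "A", "G", "T", "T", "G", "T", "C"),
                       ncol = 2, byrow = TRUE)

# shared per-region SNP metadata: ids, positions, alleles, frequencies
region_frame <- function(n_snps, chrom, region_tag, maf_range, start = 1e6,
                         spacing = 1000) {
  pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), n_snps, replace = TRUE), ,
                       drop = FALSE]
  data.frame(
    snp_id = sprintf("rs%s_%04d", region_tag, seq_len(n_snps)),
    chrom = as.character(chrom),
    pos = as.integer(start + (seq_len(n_snps) - 1L) * spacing),
    effect_allele = pair[, 1], other_allele = pair[, 2],
    eaf = stats::runif(n_snps, maf_range[1], maf_range[2]),
    stringsAsFactors = FALSE
  )
}

effective_n <- function(n_case, n_control) 4 / (1 / n_case + 1 / n_control)

# draw one trait's records over a region frame given joint effects b
draw_trait <- function(frame, chol_u, b, n_equiv) {
  n_snps <- nrow(frame)
  mu <- sqrt(n_equiv) * drop(crossprod(chol_u, chol_u %*% b))  # R %*% b via U'U
  z <- mu + drop(crossprod(chol_u, stats::rnorm(n_snps)))
  se <- 1 / sqrt(n_equiv)
  rec <- frame
  rec$beta <- z * se
  rec$se <- se
  rec$pval <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
  rec$n <- n_equiv
  rec
}

# --- Scenario --------------------------------------------------------------

#' Define a two-trait regional simulation scenario
#'
#' Encapsulates the generative truth for one region shared by two GWAS:
#' AR(1) LD, causal configuration for each trait, trait types and sample
#' sizes, and the seed. The `sharing` modes place causal variants as:
#' `shared` — one variant causal for both traits (trait-2 joint effect
#' `theta * effect1` unless `effect2` is given); `distinct` — one causal
#' variant per trait at well-separated positions; `exposure_only` — trait 1
#' only; `null` — neither.
#'
#' @param sharing One of `"shared"`, `"distinct"`, `"null"`,
#'   `"exposure_only"`.
#' @param n_snps Number of SNPs in the region.
#' @param ld_rho AR(1) LD parameter in \[0, 1).
#' @param maf_range Range the effect-allele frequencies are drawn from,
#'   within (0, 0.5\].
#' @param causal_index Index of trait 1's causal SNP (default: region
#'   centre; for `distinct`, the first quarter).
#' @param causal_index2 Index of trait 2's causal SNP under `distinct`
#'   (default: third quarter, separated enough that r^2 < 0.3).
#' @param effect1 Trait-1 joint causal effect, per SD of genotype (for a
#'   quantitative trait, `effect1^2` is the variance explained).
#' @param effect2 Trait-2 joint effect; defaults to `theta * effect1`
#'   (shared) or `effect1` (distinct).
#' @param theta Causal effect of trait 1 on trait 2 used to derive
#'   `effect2` under `shared`.
#' @param trait1_type,trait2_type `"quantitative"` or `"case_control"`.
#' @param n1 Trait-1 sample size (quantitative).
#' @param n2 Trait-2 sample size (quantitative).
#' @param n1_case,n1_control,n2_case,n2_control Case/control sizes for
#'   case-control traits.
#' @param pleiotropy_sd SD of extra direct effects added to trait 2 at
#'   trait 1's causal indices.
#' @param seed Integer seed; identical scenarios reproduce identical data.
#' @return Object of class `scenario`.
#' @export
scenario <- function(sharing = c("shared", "distinct", "null", "exposure_only"),
                     n_snps = 200, ld_rho = 0.9, maf_range = c(0.05, 0.5),
                     causal_index = NULL, causal_index2 = NULL,
                     effect1 = 0.1, effect2 = NULL, theta = 1,
                     trait1_type = "quantitative", trait2_type = "quantitative",
                     n1 = 10000, n2 = 10000,
                     n1_case = NULL, n1_control = NULL,
                     n2_case = NULL, n2_control = NULL,
                     pleiotropy_sd = 0, seed = 1) {
  sharing <- match.arg(sharing)
  stopifnot(n_snps >= 1, ld_rho >= 0, ld_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            is.finite(theta), pleiotropy_sd >= 0)
  if (is.null(causal_index)) {
    causal_index <- if (sharing == "distinct") max(1L, round(n_snps / 4)) else
      max(1L, round(n_snps / 2))
  }
  if (sharing == "distinct" && is.null(causal_index2)) {
    causal_index2 <- min(n_snps, round(3 * n_snps / 4))
  }
  if (causal_index < 1 || causal_index > n_snps ||
      (!is.null(causal_index2) && (causal_index2 < 1 || causal_index2 > n_snps))) {
    stop("causal indices out of range", call. = FALSE)
  }
  if (is.null(effect2)) {
    effect2 <- if (sharing == "shared") theta * effect1 else effect1
  }
  structure(
    list(sharing = sharing, n_snps = as.integer(n_snps), ld_rho = ld_rho,
         maf_range = maf_range, causal_index = as.integer(causal_index),
         causal_index2 = if (is.null(causal_index2)) NA_integer_ else
           as.integer(causal_index2),
         effect1 = effect1, effect2 = effect2, theta = theta,
         trait1_type = trait1_type, trait2_type = trait2_type,
         n1 = n1, n2 = n2, n1_case = n1_case, n1_control = n1_control,
         n2_case = n2_case, n2_control = n2_control,
         pleiotropy_sd = pleiotropy_sd, seed = as.integer(seed)),
    class = "scenario"
  )
}

#' Read a scenario from a key-value (YAML) config file
#' @param path Path to a YAML file whose keys are [scenario()] arguments.
#' @return A `scenario` object.
#' @export
read_scenario <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$maf_range)) args$maf_range <- as.numeric(args$maf_range)
  do.call(scenario, args)
}

#' Simulate two GWAS over one region from a scenario
#'
#' Draws both traits' summary statistics from the multivariate-normal
#' sampling distribution of z-scores implied by the scenario (see the
#' package vignette for the model). SNP metadata (ids, positions spaced
#' 1 kb apart so the region fits inside one clump window, alleles,
#' frequencies) is shared between the traits. The same scenario always
#' reproduces identical output.
#'
#' @param sc A [scenario()] object.
#' @return List with `trait1` and `trait2` (`sumstats`) and `truth` (list:
#'   `ld`, joint effect vectors `b1`, `b2`, marginal effects
#'   `marginal1 = R b1`, `marginal2`, causal indices, and the scenario).
#' @export
simulate_region <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  with_seed(sc$seed, {
    frame <- region_frame(sc$n_snps, chrom = "1", region_tag = "sim",
                          maf_range = sc$maf_range)
    ld <- ar1_ld(sc$n_snps, sc$ld_rho, snp_ids = frame$snp_id)
    chol_u <- chol(ld$r)

    b1 <- numeric(sc$n_snps)
    b2 <- numeric(sc$n_snps)
    if (sc$sharing %in% c("shared", "distinct", "exposure_only")) {
      b1[sc$causal_index] <- sc$effect1
    }
    if (sc$sharing == "shared") {
      b2[sc$causal_index] <- sc$effect2
    } else if (sc$sharing == "distinct") {
      b2[sc$causal_index2] <- sc$effect2
    }
    if (sc$pleiotropy_sd > 0 && any(b1 != 0)) {
      idx <- which(b1 != 0)
      b2[idx] <- b2[idx] + stats::rnorm(length(idx), 0, sc$pleiotropy_sd)
    }

    n1_equiv <- if (sc$trait1_type == "case_control")
      effective_n(sc$n1_case, sc$n1_control) else sc$n1
    n2_equiv <- if (sc$trait2_type == "case_control")
      effective_n(sc$n2_case, sc$n2_control) else sc$n2

    rec1 <- draw_trait(frame, chol_u, b1, n1_equiv)
    rec2 <- draw_trait(frame, chol_u, b2, n2_equiv)
    trait1 <- sumstats(rec1, trait_id = "trait1", trait_type = sc$trait1_type,
                       n_case = sc$n1_case, n_control = sc$n1_control,
                       validate = FALSE)
    trait2 <- sumstats(rec2, trait_id = "trait2", trait_type = sc$trait2_type,
                       n_case = sc$n2_case, n_control = sc$n2_control,
                       validate = FALSE)
    truth <- list(ld = ld, b1 = b1, b2 = b2,
                  marginal1 = unname(drop(ld$r %*% b1)),
                  marginal2 = unname(drop(ld$r %*% b2)),
                  causal_index = sc$causal_index,
                  causal_index2 = sc$causal_index2, scenario = sc)
    list(trait1 = trait1, trait2 = trait2, truth = truth)
  })
}

# --- Whole-study generator -------------------------------------------------

#' Simulate a proteome-style two-sample MR study
#'
#' Generates a collection of exposure GWAS (one cis region each, with 1 or
#' 2 well-separated causal pQTLs), a single outcome GWAS spanning every
#' exposure region plus optional outcome-specific loci, the gene
#' annotation, and per-region LD — the complete input set for the forward,
#' colocalization, reverse, and lifestyle pipeline stages, with the truth
#' recorded. Defaults mirror a plasma-proteome screen: exposures measured
#' in 35,559 individuals and a binary outcome with 11,755 cases and
#' 441,978 controls.
#'
#' Outcome joint effects at an exposure's causal SNPs are
#' `theta * b_exposure` for truly causal exposures (plus optional
#' pleiotropy noise) and pleiotropy-only otherwise, so the outcome signal
#' in a causal protein's region shares that protein's causal variants.
#' Outcome-specific loci carry outcome-only causal variants; every
#' exposure GWAS also covers those loci (null for the protein unless
#' `theta_reverse` is non-zero), which is what reverse MR instruments
#' harmonize against.
#'
#' @param n_exposures Number of protein exposures.
#' @param frac_causal Fraction of exposures with a true causal effect on
#'   the outcome.
#' @param theta True causal effect (log-odds of outcome per SD of protein)
#'   for causal exposures.
#' @param instruments_per_exposure 1 or 2 independent causal pQTLs per
#'   exposure.
#' @param n_exp Exposure GWAS sample size.
#' @param outcome_type `"case_control"` (default) or `"quantitative"`.
#' @param n_case,n_control Outcome case/control counts (case-control).
#' @param n_out Outcome sample size (quantitative).
#' @param n_outcome_loci Number of outcome-specific loci (for reverse MR).
#' @param outcome_locus_effect Joint effect at each outcome-specific locus.
#' @param theta_reverse True causal effect of the outcome on every protein
#'   (propagates outcome-locus effects into the protein GWAS; 0 = purely
#'   forward-causal study).
#' @param n_snps_region SNPs per region.
#' @param ld_rho AR(1) LD parameter within each region (default 0.4,
#'   emulating a provider-pruned pQTL panel: greedy clumping at r^2 < 0.1
#'   then removes essentially every correlated genome-wide-significant
#'   neighbour of a lead pQTL, so the selected instruments are the 1-2
#'   nearly independent signals per protein the generator intends).
#' @param instrument_effect Joint effect of each causal pQTL on its
#'   protein, per SD of genotype (default 0.08, ~0.6% variance explained —
#'   comfortably genome-wide significant at the default exposure sample
#'   size).
#' @param maf_range Effect-allele frequency range.
#' @param pleiotropy_sd SD of direct instrument-to-outcome effects.
#' @param seed Integer seed.
#' @return Object of class `mr_study`: list with `exposures` (named list
#'   of `sumstats`), `outcome` (`sumstats`), `annotation`
#'   (`gene_annotation`), `ld` (named list of `ld_matrix`, one per
#'   region), `truth` (data frame: `exposure_id`, `causal`, `theta`,
#'   `causal_snps`), and `params`.
#' @export
simulate_mr_study <- function(n_exposures, frac_causal = 0, theta = 0,
                              instruments_per_exposure = 2,
                              n_exp = 35559,
                              outcome_type = c("case_control", "quantitative"),
                              n_case = 11755, n_control = 441978,
                              n_out = 50000,
                              n_outcome_loci = 0, outcome_locus_effect = 0.07,
                              theta_reverse = 0,
                              n_snps_region = 60, ld_rho = 0.4,
                              maf_range = c(0.05, 0.5),
                              instrument_effect = 0.08,
                              pleiotropy_sd = 0, seed = 1) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(n_exposures >= 1, frac_causal >= 0, frac_causal <= 1,
            instruments_per_exposure %in% c(1L, 2L), n_snps_region >= 20)
  n_out_equiv <- if (outcome_type == "case_control")
    effective_n(n_case, n_control) else n_out

  # one Cholesky factor serves every region (same n_snps and rho)
  proto_ld <- ar1_ld(n_snps_region, ld_rho)
  chol_u <- chol(proto_ld$r)

  causal_flags <- with_seed(child_seed(seed, 0L), {
    n_causal <- round(frac_causal * n_exposures)
    flags <- rep(FALSE, n_exposures)
    flags[sample.int(n_exposures, n_causal)] <- TRUE
    flags
  })

  exposures <- vector("list", n_exposures)
  exposure_ids <- sprintf("PROT%04d", seq_len(n_exposures))
  ld_list <- list()
  outcome_records <- vector("list", n_exposures + n_outcome_loci)
  annotation_rows <- vector("list", n_exposures)
  causal_snps <- character(n_exposures)

  # outcome-specific loci (generated first so exposures can cover them)
  locus_frames <- list()
  locus_b <- list()
  if (n_outcome_loci > 0) {
    for (l in seq_len(n_outcome_loci)) {
      lf <- with_seed(child_seed(seed, 500000L + l), {
        frame <- region_frame(n_snps_region,
                              chrom = as.character(n_exposures + l),
                              region_tag = sprintf("OL%02d", l),
                              maf_range = maf_range)
        b <- numeric(n_snps_region)
        b[round(n_snps_region / 2)] <- outcome_locus_effect
        out_rec <- draw_trait(frame, chol_u, b, n_out_equiv)
        list(frame = frame, b = b, out_rec = out_rec)
      })
      locus_frames[[l]] <- lf$frame
      locus_b[[l]] <- lf$b
      outcome_records[[n_exposures + l]] <- lf$out_rec
      ld_list[[sprintf("OL%02d", l)]] <-
        ld_matrix(proto_ld$r, lf$frame$snp_id)
    }
  }

  for (e in seq_len(n_exposures)) {
    sim <- with_seed(child_seed(seed, e), {
      frame <- region_frame(n_snps_region, chrom = as.character(e),
                            region_tag = sprintf("%04d", e),
                            maf_range = maf_range)
      # well-separated causal indices so clumped instruments are nearly
      # independent (AR(1) correlation decays below 0.05 at this distance)
      m <- n_snps_region
      if (instruments_per_exposure == 1L) {
        idx <- sample(seq(round(0.4 * m), round(0.6 * m)), 1L)
      } else {
        idx <- c(sample(seq(max(2L, round(m / 12)), round(m / 4)), 1L),
                 sample(seq(round(3 * m / 4), m - 1L), 1L))
      }
      b_exp <- numeric(n_snps_region)
      b_exp[idx] <- instrument_effect
      theta_e <- if (causal_flags[e]) theta else 0
      b_out <- theta_e * b_exp
      if (pleiotropy_sd > 0) {
        b_out[idx] <- b_out[idx] + stats::rnorm(length(idx), 0, pleiotropy_sd)
      }
      exp_rec <- draw_trait(frame, chol_u, b_exp, n_exp)
      out_rec <- draw_trait(frame, chol_u, b_out, n_out_equiv)
      # protein coverage of outcome-specific loci (reverse-causal path)
      locus_rec <- NULL
      if (n_outcome_loci > 0) {
        locus_rec <- do.call(rbind, lapply(seq_len(n_outcome_loci), function(l) {
          draw_trait(locus_frames[[l]], chol_u, theta_reverse * locus_b[[l]],
                     n_exp)
        }))
      }
      list(frame = frame, idx = idx, exp_rec = exp_rec, out_rec = out_rec,
           locus_rec = locus_rec)
    })
    rec <- if (is.null(sim$locus_rec)) sim$exp_rec else
      as.data.frame(data.table::rbindlist(list(sim$exp_rec, sim$locus_rec)))
    exposures[[e]] <- sumstats(rec, trait_id = exposure_ids[e],
                               trait_type = "quantitative", validate = FALSE)
    outcome_records[[e]] <- sim$out_rec
    ld_list[[exposure_ids[e]]] <- ld_matrix(proto_ld$r, sim$frame$snp_id)
    annotation_rows[[e]] <- data.frame(
      gene_id = exposure_ids[e], chrom = as.character(e),
      tss = as.integer(1e6 + floor(n_snps_region / 2) * 1000),
      stringsAsFactors = FALSE
    )
    causal_snps[e] <- paste(sim$frame$snp_id[sim$idx], collapse = ",")
  }

  names(exposures) <- exposure_ids
  ann <- do.call(rbind, annotation_rows)
  annotation <- gene_annotation(ann$gene_id, ann$chrom, ann$tss)
  outcome <- sumstats(as.data.frame(data.table::rbindlist(outcome_records)),
                      trait_id = "outcome",
                      trait_type = outcome_type,
                      n_case = if (outcome_type == "case_control") n_case,
                      n_control = if (outcome_type == "case_control") n_control,
                      validate = FALSE)
  truth <- data.frame(
    exposure_id = exposure_ids, causal = causal_flags,
    theta = ifelse(causal_flags, theta, 0), causal_snps = causal_snps,
    stringsAsFactors = FALSE
  )
  structure(
    list(exposures = exposures, outcome = outcome, annotation = annotation,
         ld = ld_list, truth = truth,
         params = list(n_exposures = n_exposures, frac_causal = frac_causal,
                       theta = theta,
                       instruments_per_exposure = instruments_per_exposure,
                       n_exp = n_exp, outcome_type = outcome_type,
                       n_case = n_case, n_control = n_control, n_out = n_out,
                       n_outcome_loci = n_outcome_loci,
                       outcome_locus_effect = outcome_locus_effect,
                       theta_reverse = theta_reverse,
                       n_snps_region = n_snps_region, ld_rho = ld_rho,
                       maf_range = maf_range,
                       instrument_effect = instrument_effect,
                       pleiotropy_sd = pleiotropy_sd, seed = seed)),
    class = "mr_study"
  )
}

#' @export
print.mr_study <- function(x, ...) {
  cat("<mr_study>", length(x$exposures), "exposure(s),",
      sum(x$truth$causal), "truly causal (theta =", x$params$theta, ")\n")
  cat("  outcome:", x$params$outcome_type, "|",
      x$params$n_outcome_loci, "outcome-specific locus/loci\n")
  invisible(x)
}

#' Simulate a lifestyle-exposure MR study
#'
#' Convenience wrapper around [simulate_mr_study()] emulating lifestyle
#' exposures (large-cohort quantitative GWAS with instruments of modest
#' strength that pass the lifestyle preset's p < 1e-5 but typically not
#' genome-wide significance) acting on a quantitative protein outcome.
#'
#' @param n_lifestyle Number of lifestyle exposures.
#' @param theta True effect of each causal lifestyle exposure on the
#'   protein (SD per SD).
#' @param frac_causal Fraction of lifestyle exposures truly affecting the
#'   protein.
#' @param n_lifestyle_gwas Lifestyle GWAS sample size (default 450,000,
#'   biobank scale).
#' @param n_protein Protein GWAS sample size.
#' @param instrument_effect Joint instrument effect (default 0.0073,
#'   placing instrument p-values between 1e-5 and 5e-8 on average).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [simulate_mr_study()].
#' @return An `mr_study` whose outcome is the (quantitative) protein.
#' @export
simulate_lifestyle_study <- function(n_lifestyle, theta = -0.3,
                                     frac_causal = 1,
                                     n_lifestyle_gwas = 450000,
                                     n_protein = 35559,
                                     instrument_effect = 0.0073,
                                     seed = 1, ...) {
  study <- simulate_mr_study(
    n_exposures = n_lifestyle, frac_causal = frac_causal, theta = theta,
    n_exp = n_lifestyle_gwas, outcome_type = "quantitative",
    n_out = n_protein, instrument_effect = instrument_effect, seed = seed, ...
  )
  names(study$exposures) <- sub("^PROT", "LIFE", names(study$exposures))
  study$truth$exposure_id <- sub("^PROT", "LIFE", study$truth$exposure_id)
  study$annotation$gene_id <- sub("^PROT", "LIFE", study$annotation$gene_id)
  names(study$ld) <- sub("^PROT", "LIFE", names(study$ld))
  for (i in seq_along(study$exposures)) {
    study$exposures[[i]]$trait_id <- names(study$exposures)[i]
  }
  study$outcome$trait_id <- "protein"
  study
}

#' Randomly flip the reported orientation of records
#'
#' Swaps effect/other alleles, negates beta, and complements the frequency
#' for a random subset of records — the estimates are unchanged in
#' substance, only reported on the opposite allele. Used to exercise
#' harmonization: a pipeline run on flipped data must reproduce the
#' original estimates.
#'
#' @param x A `sumstats` object.
#' @param fraction Fraction of records to flip (default 1 = all).
#' @param seed Integer seed for choosing the subset.
#' @return The modified `sumstats`.
#' @export
flip_orientation <- function(x, fraction = 1, seed = 1) {
  stopifnot(inherits(x, "sumstats"), fraction >= 0, fraction <= 1)
  rec <- x$records
  idx <- with_seed(seed, which(stats::runif(nrow(rec)) < fraction))
  ea <- rec$effect_allele[idx]
  rec$effect_allele[idx] <- rec$other_allele[idx]
  rec$other_allele[idx] <- ea
  rec$beta[idx] <- -rec$beta[idx]
  rec$eaf[idx] <- 1 - rec$eaf[idx]
  x$records <- rec
  x
}
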
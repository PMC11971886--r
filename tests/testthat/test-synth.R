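test_that("AR(1) LD matrix has the defining structure", {
  id <- ar1_ld(5, 0)
  expect_equal(id$r, diag(5), ignore_attr = TRUE)
  ld <- ar1_ld(10, 0.7)
  expect_equal(ld$r[1, 3], 0.49)
  expect_equal(ld$r, t(ld$r), ignore_attr = TRUE)
  ev <- eigen(ar1_ld(50, 0.9)$r, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(ar1_ld(5, 1), "rho")
})

test_that("identical scenarios reproduce bit-identical data", {
  sc <- scenario(sharing = "shared", n_snps = 50, seed = 42)
  a <- simulate_region(sc)
  b <- simulate_region(scenario(sharing = "shared", n_snps = 50, seed = 42))
  expect_identical(a$trait1$records, b$trait1$records)
  expect_identical(a$trait2$records, b$trait2$records)
  c <- simulate_region(scenario(sharing = "shared", n_snps = 50, seed = 43))
  expect_false(identical(a$trait1$records, c$trait1$records))

  st1 <- simulate_mr_study(n_exposures = 3, frac_causal = 1, theta = 0.3,
                           seed = 7)
  st2 <- simulate_mr_study(n_exposures = 3, frac_causal = 1, theta = 0.3,
                           seed = 7)
  expect_identical(st1$outcome$records, st2$outcome$records)
  expect_identical(st1$exposures[[2]]$records, st2$exposures[[2]]$records)
})

test_that("null z-scores are standard normal per SNP (moment matching)", {
  n_rep <- 400
  zs <- sapply(seq_len(n_rep), function(i) {
    sim <- simulate_region(scenario(sharing = "null", n_snps = 40,
                                    ld_rho = 0.3, n1 = 1e4, seed = 3000 + i))
    sim$trait1$records$beta / sim$trait1$records$se
  })
  # pooled over 40 x 400 draws (MC bounds account for within-region LD)
  expect_equal(mean(zs), 0, tolerance = 0.06)
  expect_equal(stats::var(as.vector(zs)), 1, tolerance = 0.05)
  # per-SNP means stay within Monte-Carlo bounds
  m <- rowMeans(zs)
  expect_true(all(abs(m) < 5 / sqrt(n_rep)))
})

test_that("the causal SNP's expected z equals sqrt(n) times its effect", {
  n_rep <- 300
  zc <- sapply(seq_len(n_rep), function(i) {
    sim <- simulate_region(scenario(sharing = "shared", n_snps = 40,
                                    effect1 = 0.1, theta = 1, n1 = 1e4,
                                    n2 = 1e4, seed = 4000 + i))
    ci <- sim$truth$causal_index
    sim$trait1$records$beta[ci] / sim$trait1$records$se[ci]
  })
  expect_equal(mean(zc), sqrt(1e4) * 0.1, tolerance = 3 / sqrt(n_rep) * 2)
})

test_that("marginal effects equal LD times joint effects (exact at rho 0)", {
  sim <- simulate_region(scenario(sharing = "shared", n_snps = 30, ld_rho = 0,
                                  effect1 = 0.12, theta = 0.5, seed = 5))
  expect_equal(sim$truth$marginal1, sim$truth$b1)
  expect_equal(sim$truth$marginal2, sim$truth$b2)
  sim2 <- simulate_region(scenario(sharing = "shared", n_snps = 30,
                                   ld_rho = 0.8, effect1 = 0.12, seed = 5))
  expect_equal(sim2$truth$marginal1,
               unname(drop(sim2$truth$ld$r %*% sim2$truth$b1)))
})

test_that("generated records satisfy the container invariants by construction", {
  st <- simulate_mr_study(n_exposures = 4, frac_causal = 0.5, theta = 0.5,
                          n_outcome_loci = 1, seed = 13)
  for (ss in c(st$exposures, list(st$outcome))) {
    rec <- ss$records
    expect_true(all(rec$se > 0))
    expect_true(all(rec$eaf > 0 & rec$eaf < 1))
    expect_false(anyDuplicated(rec$snp_id) > 0)
    z <- abs(rec$beta / rec$se)
    z_p <- qnorm(pmax(rec$pval, 1e-300) / 2, lower.tail = FALSE)
    expect_true(all(abs(z - z_p) / pmax(z, z_p, 1) < 0.1))
    # revalidation through the constructor is silent
    expect_silent(sumstats(rec, ss$trait_id, ss$trait_type,
                           n_case = ss$n_case, n_control = ss$n_control))
  }
  # case-control effective sample size is recorded in the n column
  expect_equal(unique(st$outcome$records$n),
               4 / (1 / 11755 + 1 / 441978))
})

test_that("scenario configs load from key-value files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("sharing: distinct", "n_snps: 80", "ld_rho: 0.85",
               "effect1: 0.12", "n1: 20000", "seed: 9"), path)
  sc <- read_scenario(path)
  expect_s3_class(sc, "scenario")
  expect_equal(sc$n_snps, 80L)
  expect_equal(sc$ld_rho, 0.85)
  expect_equal(sc$causal_index, 20L)
  expect_equal(sc$causal_index2, 60L)
  # r^2 between the two default causal positions is below 0.3
  expect_lt(sc$ld_rho^(2 * (sc$causal_index2 - sc$causal_index)), 0.3)
})

test_that("summary statistics round-trip through the text dialect", {
  sim <- simulate_region(scenario(sharing = "shared", n_snps = 20, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(sim$trait1, path)
  back <- read_sumstats(path, trait_id = "trait1")
  expect_equal(back$records$beta, sim$trait1$records$beta, tolerance = 1e-12)
  expect_equal(back$records$snp_id, sim$trait1$records$snp_id)
  expect_equal(back$records$eaf, sim$trait1$records$eaf, tolerance = 1e-12)
})

test_that("orientation corruption only changes the reported allele", {
  st <- simulate_mr_study(n_exposures = 1, frac_causal = 1, theta = 0.4,
                          seed = 19)
  flipped <- flip_orientation(st$outcome, fraction = 0.5, seed = 4)
  changed <- flipped$records$beta != st$outcome$records$beta
  expect_true(any(changed) && !all(changed))
  expect_equal(flipped$records$beta[changed],
               -st$outcome$records$beta[changed])
  expect_equal(flipped$records$effect_allele[changed],
               st$outcome$records$other_allele[changed])
  expect_equal(flipped$records$pval, st$outcome$records$pval)
})
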
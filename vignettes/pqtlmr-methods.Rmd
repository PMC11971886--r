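---
title: "Methods: proteome-wide MR and colocalization with pqtlmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR and colocalization with pqtlmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlmr)
```

## The analysis pqtlmr implements

`pqtlmr` implements a drug-target prioritization design that is now standard
in genetic epidemiology: plasma proteins, instrumented by their cis protein
quantitative trait loci (cis-pQTLs), are screened for causal effects on a
disease outcome by two-sample Mendelian randomization (MR); the
FDR-significant hits are validated by Bayesian colocalization of the protein
and disease association signals in the cis region; reverse-direction MR
checks that the association is not driven by reverse causation; and a final
MR pass asks which lifestyle exposures move the validated protein levels.
The pipeline operates purely on GWAS summary statistics: per-SNP effect
estimates, standard errors, allele information, and p-values for each trait.

Because the real data sets such screens use (large proteogenomic cohorts,
biobank disease endpoints) are access-controlled, the package ships a fully
seeded generator of synthetic summary statistics with known causal truth, so
every stage — and the pipeline end to end — is testable on a laptop.

## Instrument selection

For a protein with transcription start site (TSS) `t` on chromosome `c`,
candidate instruments must satisfy four criteria, applied in order by
`select_instruments()`:

1. **cis window** — position within ±1 Mb of `t` on chromosome `c`
   (closed interval; `cis_filter()`);
2. **genome-wide significance** — `p < 5e-8`, strict (`significance_filter()`);
3. **LD independence** — greedy PLINK-style clumping (`ld_clump()`): the
   remaining SNP with the smallest p-value (ties broken by lexicographic
   SNP id, which makes the result invariant to input row order) is kept and
   all SNPs within 10,000 kb of it with `r^2 >= 0.1` are removed, until no
   candidates remain;
4. **instrument strength** — per-SNP `F = (beta/se)^2 > 10`, the
   conventional weak-instrument gate.

A `lifestyle` preset (`p < 1e-5`, `r^2 < 0.001`, 10,000 kb, no cis window)
serves exposures whose GWAS rarely reach genome-wide significance. Every
input SNP receives exactly one reason code (`cis_fail`, `pval_fail`,
`clumped_out`, `weak_instrument`, `selected`), so selection is auditable.

## Harmonization

Exposure and outcome records are matched by SNP id and the outcome effect is
re-expressed on the exposure's effect allele: reversed allele pairs flip the
sign of `beta` and complement the frequency; complementary-base labels are
treated as strand notation. Palindromic SNPs (A/T, C/G) confound strand with
orientation; they are aligned through the effect-allele frequency when both
traits' frequencies are far from 0.5 and dropped as ambiguous when either
lies within 0.08 of 0.5 (the conventional band; configurable). Indels and
irreconcilable pairs are dropped. Harmonization is idempotent and invariant
to the reported orientation of the input — both properties are tested.

## MR estimators

With harmonized instrument effects `(b_xj, b_yj)` and outcome standard
errors `s_yj`:

* **Wald ratio** (single instrument): `theta_j = b_yj / b_xj`, with the
  first-order delta-method standard error `s_yj / |b_xj|`.
* **IVW** (two or more): the fixed-effect precision-weighted mean of the
  per-SNP ratios, `w_j = se_j^-2`, `theta = sum(w theta_j) / sum(w)`,
  `se = sum(w)^-1/2`. Equivalent to no-intercept weighted least squares of
  `b_y` on `b_x`, which is the independent oracle used in the tests.
* **Cochran's Q** accompanies IVW (`df = n - 1`); with the 1–2 instruments
  typical of cis-pQTL exposures it is rarely informative, which is why the
  fixed-effect (not multiplicative random-effect) IVW is the headline
  estimator: a residual variance cannot be estimated from 1–2 ratios.
* **MR-Egger** (three or more): weighted least squares with a free
  intercept after orienting all exposure effects positive; a non-zero
  intercept flags directional pleiotropy. Standard errors are fixed-effect
  (no residual scaling), consistent with the IVW convention above; note
  that some implementations scale Egger standard errors by the residual
  variance, which is a different (random-effect) convention.

P-values use the normal reference throughout, the standard two-sample-MR
convention. Effects are reported per SD of protein level and exponentiated
to odds ratios with 95% CIs; `or_ci_to_p()` inverts a printed OR/CI triple
back to `z` and `p` (used for consistency checks against published
results). Multiple testing across the proteome uses Benjamini–Hochberg FDR
(`stats::p.adjust`) at threshold 0.05.

## Bayesian colocalization

For each SNP and trait, the Wakefield approximate Bayes factor against the
null is computed in closed form from the estimate, its variance `V`, and a
normal effect prior with variance `W`:

    log ABF = 0.5 * [ log(1 - r) + r z^2 ],   r = W / (V + W),  z = beta/se

with prior SD 0.2 for quantitative traits and 0.15 (log-odds scale) for
case-control traits. Under the single-causal-variant assumption the
evidence for the five region hypotheses (H0 none, H1/H2 one trait only,
H3 both at distinct variants, H4 shared variant) is assembled from the
per-SNP sums `S1`, `S2`, `S12`:

    H0: 1, H1: p1*S1, H2: p2*S2, H3: p1*p2*(S1*S2 - S12), H4: p12*S12

normalized with log-sum-exp stabilization; the H3 cross-term vanishes
algebraically for a single-SNP region. SNP-level priors default to
`p1 = p2 = 1e-4`, `p12 = 1e-5`, the defaults of the published
enumeration-based colocalization method. A region pair is called
colocalized when `PPH4 > 0.75` or `PPH3 + PPH4 > 0.8`; the decision rule is
applied per analyzed region, and both thresholds are configurable. No sdY
rescaling is applied to case-control traits beyond the prior-SD switch.

The combined `PPH3 + PPH4` clause matters in practice: when a region holds
*two* causal variants that both traits share, the single-causal-variant
enumeration must attribute each trait's evidence to one variant, and
sampling noise decides whether the two traits agree (mass on H4) or split
across the pair (mass on H3). The combined threshold absorbs this
instability, which is visible in the package's own two-instrument
simulations.

```{r coloc-demo}
sim <- simulate_region(scenario(sharing = "shared", n_snps = 200,
                                ld_rho = 0.9, effect1 = 0.1, theta = 1,
                                n1 = 1e4, n2 = 1e4, seed = 7))
res <- coloc_abf(coloc_input(sim$trait1$records$beta, sim$trait1$records$se,
                             sim$trait2$records$beta, sim$trait2$records$se))
res
coloc_decision(res)$decision
```

## The synthetic-data generator

Summary statistics are drawn directly from the asymptotic sampling
distribution of GWAS z-scores: for a region with LD correlation matrix `R`
(AR(1), `r[i,j] = rho^|i-j|`) and joint causal effects `b` (per SD of
genotype),

    z ~ MVN( sqrt(n) * R b,  R ),   beta = z / sqrt(n),  se = 1 / sqrt(n)

for quantitative traits; case-control traits use the effective sample size
`n_eff = 4 / (1/n_case + 1/n_control)` with betas read on the log-odds
scale. No individual-level genotypes are simulated — this is sufficient for
every downstream stage and orders of magnitude faster. All randomness flows
from one integer seed through arithmetic seed-splitting, so identical
configurations reproduce identical data regardless of call order.

`simulate_mr_study()` emulates the proteome screen: its defaults are the
study conditions the pipeline is designed for — exposures measured in
35,559 individuals, a binary outcome with 11,755 cases and 441,978
controls, 1–2 causal cis-pQTLs per protein each explaining ~0.6% of protein
variance (`instrument_effect = 0.08`, comfortably genome-wide significant),
and a true causal effect `theta` (log-odds per SD) for a chosen fraction of
proteins. Outcome effects at a causal protein's pQTLs are `theta * b` plus
optional pleiotropy noise, so the outcome signal in such a region shares
the protein's causal variants — exactly the configuration colocalization
should confirm. Optional outcome-specific loci carry disease-only signals;
the protein GWAS cover them (null, unless a reverse effect
`theta_reverse` is injected), which is what reverse MR instruments
harmonize against.

Within exposure regions the generator uses `ld_rho = 0.4`, emulating a
provider-pruned pQTL panel: at higher LD an AR(1) region places SNPs just
under the `r^2 < 0.1` clump threshold that are still genome-wide
significant, so selection retains winner's-cursed shadows of the lead
signal (3–5 "instruments" per protein) whose overestimated exposure effects
bias ratios toward the null and invalidate the nominal calibration of the
estimator. With a pruned panel, selection recovers the intended 1–2 nearly
independent instruments per protein. The coloc-oriented `scenario()`
generator keeps `ld_rho = 0.9`: dense local LD is precisely what
colocalization must see through.

What the generator does **not** emulate: real human LD (blocky, long-range,
population-specific) rather than AR(1); allele-frequency-dependent standard
errors (the standardized-genotype model makes `se` constant within a
trait); aptamer measurement error and cross-reactivity; sample overlap
between exposure and outcome GWAS; case-control ascertainment beyond the
effective-sample-size approximation. Tests passing on this generator
therefore validate the statistical machinery and its calibration under the
stated model, not robustness to those real-data complications.

## Numerical choices

* Two-sided p-values are clamped at `1e-300` so downstream `log`/FDR steps
  never receive an exact zero.
* Colocalization masses are combined in log space (log-sum-exp /
  log-diff-exp); posteriors sum to 1 within 1e-9 by construction.
* LD matrices are validated symmetric, unit-diagonal, and positive
  semidefinite within 1e-8.
* Clumping ties on p-value break by lexicographic SNP id; selection is
  therefore deterministic and row-order invariant.
* The p/z consistency check on input records warns (does not fail) beyond
  10% relative disagreement on the z scale, since published tables are
  rounded.
* `beta_exp = 0` makes the Wald ratio undefined and is an error; zero
  exposure effects cannot pass the significance filter in practice.

## Design decisions on open points

* **Reverse-MR instruments** are selected genome-wide with the pQTL
  significance/clumping/F thresholds but no cis window; the FDR family for
  reverse MR is the protein list passed in (the colocalization-validated
  set in `run_study()`), both configurable.
* **Lifestyle results** are flagged at nominal p; an FDR column is emitted
  alongside for reference but does not drive the flag, mirroring how such
  exploratory lifestyle passes are conventionally reported.
* **Palindromic ambiguity band** 0.08; matching is by SNP id only
  (positional matching is unnecessary for single-panel synthetic data and
  out of scope).
* **Multi-window tiling** of large regions is not implemented; the decision
  rule applies to the analyzed region as a whole.

## Test and calibration problem sizes

The package's property suites use: a 2,000-exposure null screen for type-I
error (expected rejection 4–6% at alpha 0.05); 500-replicate recovery runs
at theta in {-0.5, 0, 0.3, 0.8} (mean IVW estimate within 2 Monte-Carlo SE
of truth); 500-replicate coverage at n = 50,000 per sample (93–97% CI
coverage, evaluated at theta = 0.1); and 60-region discrimination suites
for colocalization. These sizes give Monte-Carlo error well inside the
asserted bands while keeping the default test run fast.

## Known limitations

* The first-order Wald/IVW standard error omits the exposure-side variance
  term `theta^2 * se_x^2`; at `theta = 0.3` this shades 95% CI coverage to
  roughly 94%, and more for larger effects — a property of the estimator,
  not of the implementation.
* With a strong forward effect the outcome becomes genome-wide significant
  inside causal protein cis regions, and reverse MR (which applies no
  Steiger-type directionality filter, as in the design it follows) will
  select instruments there and report the inverse effect. The reverse-null
  demonstrations therefore use moderate forward effects, matching the
  premise that disease instruments do not overlap protein cis signals.
* Fixed-effect IVW and the normal reference understate uncertainty under
  real heterogeneity; with 1–2 instruments per exposure no heterogeneity
  model is estimable, which is the regime this pipeline targets.
* The single-causal-variant assumption of the colocalization model is
  violated by multi-signal regions; conditioning/masking or SuSiE-style
  extensions are out of scope.
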
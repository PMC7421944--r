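---
title: "Models and methods behind gwasoverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gwasoverlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`gwasoverlap` implements the statistical chain of a two-trait
imaging-genetics analysis: per-variant association with covariates, LD
clumping into genomic risk loci, conditional and conjunctional false
discovery rates for cross-trait discovery, SNP heritability and genetic
correlation, and covariate-adjusted case-control contrasts.  This vignette
explains the models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.  It states no empirical
result beyond what the package's tests and `scripts/acceptance.R` compute.

## The synthetic study

All tests run on synthetic data whose structure mirrors what the downstream
estimators assume.  `simulation_config()` fixes the study conditions:

* `m_snps = 20000` variants in AR(1) LD blocks of `block_size = 40`
  (`block_rho = 0.8`), allele frequencies uniform on the post-QC range
  `[0.05, 0.5]`;
* GWAS sample sizes `n1 = n2 = 27000`, the scale of a large single-cohort
  discovery sample;
* a four-component causal mixture per variant — trait-A-only (`pi_a`),
  trait-B-only (`pi_b`), shared (`pi_shared`), null — with defaults
  `0.003 / 0.003 / 0.001`, i.e. a sparse polygenic architecture with a
  modest shared component;
* `sign_concordance = 0.7`: a shared causal variant carries same-sign
  effects in both traits with probability 0.7, the mixed-direction pattern
  that motivates conjunctional-FDR analysis in the first place;
* target heritabilities `h2_a = 0.48`, `h2_b = 0.27`, spanning the range
  reported for brainstem volumes.

**Genotypes.** Each haplotype gets a latent Gaussian vector with AR(1)
correlation `rho^|i-j|` inside a block; the allele is called when the
latent value is below the frequency quantile.  This thresholded-copula
construction gives Hardy–Weinberg marginals, controllable LD, and always
positive-definite block correlation.  `block_rho` may be a range, in which
case each block draws its own rho uniformly — real genomes have strongly
heterogeneous LD, and a single global rho leaves the LD-score distribution
almost degenerate, making LD-score regression unidentifiable at desk scale.
The LDSC and GREML experiments therefore use `block_rho = c(0.2, 0.95)`.

**Summary statistics.** Z-scores are drawn block-wise from the standard
infinitesimal-noise approximation `z ~ N(sqrt(N) R beta, R)`.  `R` is the
*dosage-scale* block correlation, computed analytically from the copula via
the Mehler (tetrachoric) series — thresholding attenuates the latent
correlation, and using the latent matrix here would make the simulated z
inconsistent with the r² any genotype panel measures (the tests verify the
series against a brute-force haplotype simulation).  Per-causal effect
variance is `h2 / (m · pi)`, so realized heritability matches the target in
expectation.  A shared causal variant's trait-B effect is the trait-A
effect rescaled to trait B's per-causal scale and sign-flipped with
probability `1 - sign_concordance`; the correlation of shared effects is
therefore exactly `2·sign_concordance - 1`, which gives the rg-recovery
tests an analytic truth.

The variant map (frequencies, positions, blocks, alleles) depends only on
the config seed, never on the sample size, so biobank-scale summary
statistics and a small LD reference panel from the same config are always
aligned.  `simulate_sumstats_pair(config, seed =)` redraws effects and
noise on a fixed map for replicate designs.

**What the generator does not emulate:** realistic human LD maps,
imputation uncertainty (an INFO column is passed through but not
generated), population structure, relatedness, or the X chromosome.
Passing tests therefore demonstrate the estimators' correctness under their
own assumptions, not robustness to confounding in real cohorts.

**Clinical cohorts.** Five volumes per subject: four regions built from
sex, age, age², ICV and site effects plus Gaussian noise, and a whole
volume equal to the sum of the regions plus independent noise — so
contrasts with and without the whole volume as covariate genuinely differ.
Diagnosis offsets are injected in residual-SD units, making the injected
value the true covariate-adjusted Cohen's d.

## Association and QC

`run_gwas()` residualizes phenotype and dosages on the covariates and
regresses residual on residual (Frisch–Waugh–Lovell), with the degrees of
freedom of the full model; the tests assert exact equality with per-variant
`lm()` fits.  QC applies the conventional thresholds — INFO < 0.5,
MAF < 0.05, missingness > 5%, exact Hardy–Weinberg p < 1e-6 — as strict
inequalities in that fixed order, one reason code per removed variant.  The
HWE test is the exact conditional test computed with the stable recurrence
over heterozygote counts; the test-suite oracle recomputes it by direct
enumeration with log-factorials.

## Locus definition

Greedy-by-ascending-p clumping with a `(chromosome, position)` tie-break,
the FUMA/PLINK convention: independence requires r² < 0.6 within a 1 Mb
window (so r² = 0.6 exactly is *dependent*, matching the candidate rule
r² ≥ 0.6); leads require r² < 0.1; loci merge when leads are closer than
250 kb.  Two dialect choices are fixed and documented: the window is the
physical distance between variant positions, and after lead-distance
merging any loci whose candidate spans still overlap are collapsed, so the
per-trait loci are pairwise disjoint.  Cross-trait unique regions merge
per-trait loci by interval overlap (≥ 1 bp); the merging rule behind
published "unique region" counts is not standardized, so alternatives
(e.g. lead distance) would change counts slightly.  On-disk BED exports are
0-based half-open; everything internal is 1-based inclusive.

## Conditional and conjunctional FDR

The estimator is the stratified empirical one: with
`S(p2) = {j : p2_j ≤ p2}`,

    cFDR(p1 | p2) = p1 · |S(p2)| / #{ j ∈ S(p2) : p1_j ≤ p1 }

with the null proportion fixed at 1 — conservative by construction — and
values clipped to `[p1, 1]`.  Ties are counted with `≤` exactly as
written.  Two evaluation modes:

* `prune_iter = 1`: evaluated exactly at every variant's own `(p1, p2)`
  with an O(m log m) dominance-counting sweep; this reduces to the
  counting formula, and to the unconditional empirical FDR `p1·m/rank(p1)`
  when the conditioning trait is constant.
* `prune_iter > 1` with LD blocks: a lookup table on a `-log10` grid
  (primary axis 0–7.3 step 0.1; conditioning knots at the conventional
  cutoffs 1, 0.1, 0.01, 0.001 plus half-decade knots) is built per random
  pruning iteration (one variant per block), averaged, forced monotone
  non-increasing along both axes, and bilinearly interpolated in `-log10`
  space.  Empty strata inherit the next coarser knot's values with a
  warning.  Default 20 iterations.

The conjunctional FDR is the maximum of the two reciprocal conditional
FDRs — symmetric in trait order by construction.  Inflation control
(`lambda = median(z²)/0.455`, deflation never applied) runs after region
exclusion and before FDR construction; the MHC and 8p23.1 regions are
excluded at their fixed hg19 coordinates with inclusive bounds, and further
regions (e.g. MAPT, APOE) are caller-supplied.  Shared loci are called by
running the clumping machinery on the conjFDR values; each locus' lead is
its minimum-conjFDR variant and the effect direction is `sign(z1·z2)` at
the lead.  A conjFDR-0.05 report is expected to contain about 5% false
loci, whose directions are arbitrary — the direction-concordance tests
therefore condition on truly shared loci.

Conditional Q–Q curves report `-log10` of each stratum's empirical CDF at
nominal `-log10 p` knots: the null follows the identity diagonal and
enrichment deflects curves below it, successively further for stricter
conditioning strata.

## Heritability and genetic correlation

`compute_grm()` is the GCTA single-component GRM with in-sample allele
frequencies.  `greml()` eigendecomposes the GRM once and runs
average-information REML in the rotated basis (O(n²) per iteration), with
an EM step whenever an AI step would leave the parameter space or decrease
the restricted likelihood; components are clamped at 1e-8, convergence is
a log-likelihood change below 1e-6 (max 100 iterations), and SEs come from
the inverse AI matrix (delta method for h²).  With an identity GRM the fit
collapses to the usual residual-variance estimate, which the tests check
against the closed form.

`ld_scores()` sums bias-adjusted r² (`r² - (1-r²)/(n_ref-2)`) over a 1 Mb
window.  `ldsc_h2()` regresses χ² on ℓ with weights `1/max(ℓ,1)` (optional
two-step intercept from the χ² < 30 subset); full iterative
heteroskedasticity weights are deliberately out of scope.  `ldsc_rg()`
regresses `z1·z2` on ℓ with the same weights and converts via
`rg = gencov / sqrt(h2_1 h2_2)`; SEs are a block jackknife over contiguous
blocks (200, auto-reduced to about one block per 100 variants).  Because
the sampling attenuation of estimated LD scores hits the cross-trait and
the two single-trait slopes alike, it largely cancels in rg.

Problem sizes for these experiments — chosen once as desk-scale conditions
under which the estimators are informative — are n = 2000, M = 5000 with
500 causal variants for GREML recovery (25 phenotype replicates), and
m = 20000, N = 30000 with a dense architecture (causal fraction 0.15–0.3)
for the LDSC recovery and rg grids.  Sparse architectures at this m leave
the LD-score regression dominated by a few hundred high-χ² variants; the
estimates stay unbiased but their spread makes single-fit checks
uninformative, which is why the rg checks average a handful of replicates.

## Clinical contrasts

Each diagnosis is contrasted against the controls sharing a scanner site,
with site as a fixed effect when more than one is involved.  Cohen's d is
taken from the group t statistic, `d = t(n1+n2)/(sqrt(n1 n2) sqrt(df))` —
the paper-trail for adjusted models rarely states the conversion, and the
t-based one is unit-free and standard.  The full matrix is one
whole-volume test plus four regional tests with and without the whole
volume as covariate per diagnosis — 99 tests for eleven diagnoses — and
Benjamini–Hochberg q-values are pooled over the whole matrix
(`stats::p.adjust`; the test suite carries an independent step-up oracle).

## Numerical choices and degenerate inputs

* p-values are floored at 1e-300 so `-log10 p` stays finite; z and
  beta/se must agree in sign where both are present.
* Constant dosage columns yield NA association rows with a reason code
  rather than errors; rank-deficient covariates name the collinear
  columns.
* Allele harmonization flips z for swapped pairs (directly or after
  reverse complement) and drops strand-ambiguous (A/T, C/G) and
  mismatched variants with logged reasons; the generator never emits
  ambiguous pairs.
* The Mehler series for the dosage correlation is truncated at 12 terms
  (the truncation error is far below the 0.5% diagonal shrinkage applied
  for Cholesky stability).
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state.

## Known limitations

The conditional-FDR estimator is conservative (null proportion 1), so its
realized false discovery proportion sits well below the nominal level; no
attempt is made to estimate the null proportion or fit a bivariate mixture
likelihood.  LDSC weights are simplified; sample-overlap intercepts are
reported but not modeled.  Relatedness handling is an input mask, not a
kinship estimate.  The PLINK reader loads dosages densely into memory,
which is appropriate for the package's desk-scale reference panels but not
for biobank-scale genotype files.
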
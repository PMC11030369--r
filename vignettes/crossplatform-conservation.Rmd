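---
title: "Cross-platform conservation testing for serum proteomics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform conservation testing for serum proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossprot)
```

This vignette is the package's own account of the statistical methods it
implements, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The scientific setting

Two serum proteomics studies of extreme old age are combined: a TMT
LC-MS/MS study of 50 subjects — 9 centenarians, 17 centenarians' offspring,
24 controls without familial longevity — arranged in 5 pools of 10 labeled
channels (plus an 11th pooled-reference channel), each pool run in
triplicate, giving 150 sample profiles in 15 runs; and an aptamer-array
(RFU) study of 224 subjects of which those 50 are a subset. The inferential
goal is not the union of per-platform hits but the set of proteins whose
cohort association is *conserved* across the two assays, which differ in
chemistry, dynamic range, and failure modes.

## 2. Per-platform models

**MS differential model.** After preprocessing (section 4), each protein's
log2 abundance is modeled as `expr ~ cohort + year + gender` with
centenarians the reference level, so a positive coefficient means higher
expression in the named younger cohort. Because each subject contributes
three replicate profiles, estimation uses generalized estimating equations
with subject as the cluster and an exchangeable working correlation; the
global cohort test is a 2-df Wald test on the two cohort coefficients using
the sandwich covariance.

Two small-sample choices depart from textbook GEE defaults, deliberately.
With ~50 clusters the plain sandwich estimator is biased downward and the
chi-square reference is too light-tailed: in our null simulations the plain
Wald test rejected about twice the nominal 5%. The package therefore
defaults to the Mancl–DeRouen bias-corrected sandwich (cluster scores
premultiplied by `(I − H_i)^{-1}`) with an `F(2, K − p)` reference, which
simulation shows is near nominal; `sandwich = "robust"` and
`reference = "chisq"` restore the asymptotic versions. A working-model
likelihood-ratio variant of the global test (`test = "working-lrt"`) is
provided because the source literature for this design describes the global
test as a likelihood-ratio chi-square even though GEE defines no
likelihood; the Wald form is the default.

**Aptamer differential model.** The same mean model fit by OLS per aptamer
on the subjects with unmasked values, tested by the global F statistic on 2
and n − 5 denominator degrees of freedom (45 when all 50 subjects are
usable: intercept, two cohort terms, year, gender).

## 3. The conserved-association test

Let `p_MS` and `p_Soma` be a shared feature's per-platform global p-values.
Under independence, `max(p_MS, p_Soma)` has null CDF `t²`, so
`max(·)²` is again uniform. Shared samples break independence. The package
models the dependence through an *effective number of studies*:

* transform each study's per-pair p-value to a signed normal score
  `z = sign(β_control) · Φ⁻¹(1 − p/2)`;
* estimate `r = cor(z_MS, z_Soma)` across shared pairs (pairs with a
  missing p or a zero coefficient are excluded);
* set `k_eff = 2 − r²`, the two-study eigenvalue (Nyholt-style) form: the
  2×2 score correlation matrix has eigenvalues `1 ± r`, and
  `1 + (1 − Var(λ)/2) = 2 − r²`. Limits behave correctly: duplicated
  studies give `r = 1, k_eff = 1`; independent studies give `k_eff → 2`.
  At `r = 0.48` the formula gives 1.77, the magnitude expected for a
  50-subject study nested in a 224-subject one.

Then `p_cons = max(p_MS, p_Soma)^k_eff`. The exact functional linking
score dependence to the max-p exponent is not uniquely determined by
theory; `2 − r²` was adopted because (a) it has the right limits, and
(b) the acceptance suite validates it *by calibration*: under two null
studies sharing 50% of subjects, the realized `p_cons` with the estimated
`k_eff` passes KS uniformity, while forcing `k_eff = 2` under strong
dependence is demonstrably anti-conservative. The exponent is a numerical
approximation — the true null CDF of the max of two correlated two-sided
p-values is not exactly a power law — but numerical integration shows the
sup-CDF deviation is below 0.01 for score correlations up to ≈ 0.3 and
about 0.03 at 0.5, within KS tolerance at the tested scale. `k_eff` can
also be supplied directly when an external estimate exists.

**Pooled FDR.** One BH correction is applied over the concatenation of the
shared pairs' `p_cons` and the nominal p-values of platform-unique features
(e.g. 353 pairs + 132 MS-only proteins + 4,050 aptamer-only aptamers =
4,535 adjusted features). The unique features widen the correction to the
full tested feature space while each contributes its own evidence; the
mixed protein/aptamer granularity of the unique sets follows the source
convention. A protein with k aptamers contributes k pairs; protein-level
report tables keep the pair with the smallest pooled q.

**Conservation classes.** Among significant pairs, *full* conservation
requires sign agreement of both the control−centenarian and
offspring−centenarian coefficients across platforms; *partial* requires
exactly one (direction taken from the agreeing comparison); *discordant*
pairs are excluded from the signature. Zero coefficients count as
mismatches. Classification is reported at both 1% and 5% FDR tiers by
convention; the threshold is a plain argument.

## 4. MS preprocessing: parameters and conventions

* **Depleted proteins** (default list of 12 gene symbols, `ALBU` … `TRFE`):
  residual peptides of depletion-column targets are removed first.
* **Missingness QC**: per peptide, logistic GEE of the missingness
  indicator on cohort + year + gender, clustered by subject; Bonferroni at
  0.05. A flagged peptide would indicate informative missingness. The step
  is diagnostic — flags are reported, not auto-removed. Peptides with no
  missingness variation are skipped; separation (e.g. a peptide missing in
  exactly one cohort) is reported as untestable rather than producing a
  meaningless Wald p. QC runs on unimputed data, before filtering.
* **The three 20% filters** (all "at least", so boundaries are removed):
  missing in ≥ 20% of profiles (30/150); missing-in-run — absent from all
  sample channels of a run — in ≥ 20% of runs (3/15); missing-in-pool —
  missing-in-run for all replicates of a pool — in ≥ 20% of pools (1/5).
  "Batch" means LC-MS/MS run (15), "pool" the 5 sample pools; a peptide is
  missing-in-run when absent from all 10 sample channels, the physically
  coherent reading since identification is per run.
* **Imputation**: missing cells are drawn from Uniform(0, m_b) with m_b the
  run's minimum observed intensity; draws are strictly positive almost
  surely so downstream log2 is finite. A run with no observed intensity is
  a hard error (no bound exists).
* **Aggregation**: protein = sum of its peptides' raw intensities per
  profile (mass-conserving, verified exactly in tests).
* **Normalization**: each profile divided by its 10% trimmed mean, then
  log2. "10% trimmed" means 10% of observations per tail
  (`floor(0.1 n)` each side), the dominant convention; `total_trim = TRUE`
  switches to 10% overall. The result is invariant to any multiplicative
  profile factor. Ratio normalization has a compositional side effect: when
  many proteins carry real effects, a small common shift can appear in all
  features' cohort coefficients; it cancels in cross-platform sign
  comparisons and is visible in the recovery tests only as a
  sign-aligned-magnitude criterion.
* **Batch correction**: parametric empirical-Bayes location/scale
  adjustment (ComBat-style) with run as batch. Cohort, gender, and year are
  protected in the design by default — the source design is silent on
  covariate protection, and protecting them avoids erasing signal;
  `protect_covariates = FALSE` disables. EB shrinkage deliberately does not
  remove per-feature batch-mean sampling noise (only `eb = FALSE` matches
  batch means exactly). Correcting 15 small batches also leaves mild
  within-run dependence; the end-to-end null stays KS-uniform, but
  rejection at the 5% level can run ~2-3 points high on fully preprocessed
  null data. This is a property of per-run correction at 10 samples/run,
  not of the test stage.

## 5. Aptamer preprocessing

Log2 transform, then per aptamer mask values beyond 3 standard deviations
of the 5% trimmed mean. The source convention fixes the center but not the
spread estimator; the ordinary (untrimmed) SD is the default and a
trimmed-SD variant is a flag. Aptamers with fewer than 5 observed values
are left unmasked with a warning. Under a Gaussian null the masking rate is
≈ P(|Z| > 3) ≈ 0.3%. Annotation updating is a user-supplied remap/drop
table, not a web-service call.

## 6. Transcriptome module

Counts are filtered (keep genes with ≥ 10 CPM in ≥ 3% of samples),
normalized by median-of-ratios size factors (reference genes = nonzero in
all samples), and log2(x/s + 1)-transformed. Each gene is fit with
`y = Xβ + g + ε`, `cov(g) = σ_g² K`, `cov(ε) = σ_e² I`, where K is the
kinship matrix; the one-time eigendecomposition of K rotates the problem so
REML profiling of `δ = σ_g²/σ_e²` is a 1-D optimization per gene (bounds
`e^±12`, flagged when hit). Age is the predictor of interest; its Wald t
(df = n − p) and BH FDR are reported. Variance components are re-estimated
per gene — matching the stated per-transcript model — rather than shared.
With K = I the fit reduces exactly to OLS.

Concordance with the protein signature uses (a) one-sided hypergeometric
over-representation — one-sided is the deliberate choice because it
reproduces both published example p-values (0.0002 and 0.808) where a
two-sided test does not — and (b) correlation of effect sizes after
negating proteomic betas so positive means higher at older age (the
proteomic contrasts compare younger cohorts *to* centenarians). Pearson is
the default, Spearman a flag; the source does not state which was used.

## 7. The synthetic world

The generator emulates: the exact pooled TMT design (pools, channels,
triplicates, a pooled reference channel that downstream stages ignore);
log-normal intensities with protein/peptide baselines; subject-level
biological deviations **shared between platforms for shared subjects**
(this is what makes `k_eff < 2` real in the synthetic world); run-level
batch shifts (SD 0.3 log2 by default); intensity-dependent missingness
`logit P(miss) = a − b·(latent log2)` (defaults a = 10, b = 0.6, giving
heavier missingness for low-abundance peptides, plus a 2% whole-run
identification failure rate — real TMT data loses the majority of peptides
to such filters); a 224-subject aptamer study containing the 50 MS subjects
with platform noise equal in SD to the biological variation (per-sample
cross-platform correlation ≈ 0.5, consistent with the moderate concordance
reported between MS and aptamer assays); multi-aptamer proteins; rare gross
RFU outliers; and, for the transcriptome, negative-binomial counts with
library-size variation and block-diagonal kinship (0.5/0.25 relatedness
within families, guaranteed PSD by construction).

Default effect structure: 10% of proteins are conserved (same-sign 1.0 log2
effect on both contrasts and both platforms, random sign per protein); 5%
carry an MS-only and 5% an aptamer-only effect (nulls for the conservation
test that stress the max-p logic); the rest are null. Cohort-to-pool
assignment is randomized by default with a stratified option, since the
real pool compositions are not public.

What it does **not** emulate — and hence what a green test does not
establish: spectrum-level artifacts (isotope impurity, ratio compression,
co-isolation), aptamer cross-reactivity, plate/hybridization effects,
realistic protein-protein abundance correlation, or non-Gaussian biological
tails. Recovery metrics on this world certify the pipeline's statistical
logic, not assay chemistry.

Determinism: every generator is a pure function of (config, seed); each
derives a fixed sub-stream from the base seed, so regenerating any one
artifact never perturbs another.

## 8. Numerical choices and degenerate inputs

* Signed scores cap p at `1e-300` and use the upper-tail `qnorm` form to
  avoid overflow at very small p.
* `estimate_effective_studies` refuses fewer than 30 usable pairs and asks
  for a manual `k_eff` instead of returning a noisy estimate.
* BH is implemented directly (sort, `p·n/rank`, cumulative minimum);
  NAs are excluded from `n` and propagated.
* GEE: exchangeable `α` is moment-estimated and clamped inside the valid
  range for the largest cluster; separation is detected by diverging linear
  predictors and reported as an error, which callers record as
  "untestable".
* Imputation draws are bounded by each run's minimum; a zero trimmed mean
  in normalization is an error naming the profile.
* The LMM t-test uses df = n − p rather than a normal reference; at the
  package's target sample sizes this keeps null p-values uniform.

## 9. Known limitations

The `k_eff` estimator on real (non-null) data absorbs signal-induced
correlation as well as sample sharing, making `p_cons` mildly conservative
when many features carry true shared effects; the acceptance calibration
is therefore run under the null, and recovery under signal is tested
separately. The pooled-FDR convention mixes protein- and aptamer-level
entries for the unique sets, mirroring the source bookkeeping rather than
resolving its granularity. The max-p exponent form is an approximation
(section 3). The generator's default parameter values are fixed choices of
a stated world; they were selected for realism, not fitted to data.
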
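---
title: "Methods: liver biomarkers, GDM risk, and two-sample Mendelian randomization"
author: "gdmliver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: liver biomarkers, GDM risk, and two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical machinery of `gdmliver`: the models
of both analysis arms, the assumptions behind them, the tunable parameters
and their defaults, what the synthetic generators do and do not emulate,
and the numerical and design choices that were genuinely open.

## The scientific setting

Gestational diabetes mellitus (GDM) is glucose intolerance first recognised
in pregnancy, diagnosed from a 75 g oral glucose tolerance test (OGTT) at
24-28 weeks: fasting glucose >= 5.1 mmol/L, 1-h post-load >= 10 mmol/L, or
2-h post-load >= 8.5 mmol/L (inclusive thresholds; one-step criteria).
Subtypes follow from which components are elevated: isolated impaired
fasting glucose (i-IFG, fasting only), isolated impaired glucose tolerance
(i-IGT, post-load only), and b-GDM (both). Liver function is measured in
early pregnancy (8-14 weeks) by ALT, AST, GGT and ALP (all U/L), the
AST/ALT ratio, and the hepatic steatosis index
HSI = 8 ALT/AST + BMI + 2 (female), a non-invasive fatty-liver screen.

The package asks two linked questions. Observationally: are higher
early-pregnancy liver indices associated with later GDM and its subtypes,
and do they interact with lipids? Causally: do genetically predicted liver
enzymes raise GDM risk, assessed by two-sample Mendelian randomization (MR)
on GWAS summary statistics?

## Cohort arm

**Filtering.** `apply_inclusion_exclusion()` drops records in a fixed
order -- missing liver tests, missing OGTT, a disqualifying medical history
(hypertensive disorders, diabetes, heart, hepatobiliary or kidney disease),
then abnormally elevated enzymes (ALT > 90, AST > 80, GGT > 90,
ALP > 240 U/L; strictly greater). First-matching-reason attribution makes
the attrition log reproducible regardless of overlapping reasons. A second,
stricter screen (`clinical_range_filter()`: ALT > 45, AST > 40, GGT > 45,
ALP > 120 U/L) is reserved for sensitivity reruns.

**Quartile models.** Each liver index is cut at its sample 25/50/75th
percentiles (`quartile_bin()`, type-7 interpolated quantiles; values tied
with a cut fall in the lower bin, which keeps integer-valued enzyme bins
non-overlapping). `fit_quartile_logistic()` fits a maximum-likelihood
logistic model of GDM on the quartile factor plus maternal age, BMI,
education (ordinal codes 1-4), gravidity, parity, weight gain before the
OGTT, gestational age at measurement, and smoking and alcohol status
(three-level factors keeping "unknown" as its own level). BMI enters as a
continuous term, except for HSI -- whose formula already contains BMI --
where the four-category version (<18.5, 18.5-23.9, 24.0-27.9, >= 28) is
used instead. Confidence intervals are Wald on the log-odds scale, so the
reported `p < 0.05` and "95% CI excludes 1" agree by construction. The
trend test refits the model with the per-quartile median assigned as a
continuous score and reads the Wald p-value of that term. A quartile with
zero cases (quasi-separation) is reported with an infinite CI and a flag
rather than an error.

**Splines and piecewise fits.** `fit_rcs()` screens each index against
each continuous glucose channel with a 4-knot restricted cubic spline
(truncated-power basis, linear beyond the boundary knots; knots at the
5/35/65/95th percentiles, the standard 4-knot schedule). Nonlinearity is
the exact F-test of the two nonlinear basis terms against the linear
model. If `p >= 0.05` the linear model is retained; otherwise
`fit_piecewise()` fits a continuous single-breakpoint (hinge) model, with
the breakpoint profiled over an 81-point grid of the 10th-90th exposure
percentiles by residual sum of squares. A profile whose minimum sits on
the grid edge falls back to the linear fit with a warning -- the data do
not support an interior breakpoint.

**Subtypes and interaction.** `fit_subtype_multinomial()` fits an ML
multinomial logit (via `nnet::multinom`) of subtype against the same
design, with non-GDM as the reference; a subtype with an empty quartile
cell is omitted with a warning. `crossover_interaction()` dichotomises a
liver index and a lipid at their sample medians (the cut is configurable;
medians are the balance-preserving default since no conventional clinical
cut exists for these pairs), fits both mains, their product and the
covariates, and reports the four joint-category odds ratios against the
low/low cell plus the Wald p-value of the product term. Only the
multiplicative scale is reported.

## MR arm

Instruments are biallelic SNPs at genome-wide significance (p < 5e-8,
strict) with MAF > 0.01 (strict), minus a user-supplied exclusion list of
known-pleiotropic variants (the offline stand-in for a GWAS Catalog
screen). `clump()` prunes linkage disequilibrium greedily: lowest p-value
first (ties broken by rsid), discarding neighbours within 10,000 kb whose
r^2 > 0.001 with the index; pairs absent from the user's r^2 table count
as independent, with a warning. `harmonize()` aligns outcome effects to
the exposure's effect allele, flipping swapped alleles, dropping
palindromic (A/T, C/G) SNPs outright -- allele frequency cannot settle
strand reliably near 0.5 -- and logging every action. Instrument strength
is summarised by per-SNP F = (beta/se)^2 with a warning at mean F <= 10.

Estimators, all written against the same harmonized container:

* `wald_ratio()`: beta_out/beta_exp with first-order delta SE
  (se_out/|beta_exp|); exposure-side noise is monitored through F rather
  than propagated, matching the outcome-variance weighting below.
* `ivw()`: inverse-variance weighted mean of the ratios, identical to the
  zero-intercept weighted regression of beta_out on beta_exp with weights
  1/se_out^2. The default SE is multiplicative random effects --
  fixed-effect SE times max(1, sqrt(Q/(m-1))) -- which widens under
  heterogeneity and never narrows; the fixed-effect SE is also returned.
  Random effects is the default because liver-enzyme instruments are
  numerous and heterogeneous in practice.
* `cochran_q()`: Q against chi-square with m-1 df.
* `mr_egger()`: weighted regression with a free intercept after orienting
  beta_exp >= 0; the intercept tests directional pleiotropy; t reference
  with m-2 df and residual scale floored at 1.
* `weighted_median()`: ratio at cumulative weight 0.5 (weights =
  inverse-variance of each ratio, normalised; linear interpolation);
  SE by seeded parametric bootstrap, 1000 draws by default.
* `mr_presso()`: leave-one-out weighted residual sum of squares against a
  seeded parametric null (default 10,000 draws, empirical p floored at
  1/n_sim), per-SNP outlier p-values with Bonferroni correction,
  IVW on the non-outliers as the corrected estimate, and a distortion
  test against random same-size removals.
* `mvmr()`: zero-intercept multivariable WLS of outcome effects on the
  exposure-effect matrix (typically an enzyme plus BMI), isolating direct
  effects; an all-zero exposure column is dropped with a warning (the
  remaining estimates equal their univariable counterparts), while
  genuine collinearity is an error.

Effects for the binary outcome are per-allele log odds ratios; all
reports exponentiate to ORs.

## Synthetic generators

`simulate_cohort()` draws covariates (age truncated-normal 18-45;
log-normal BMI centred at 21.2 kg/m^2; education/gravidity/parity/smoking/
alcohol at frequencies typical of a hospital pregnancy cohort), then eight
correlated log-normal biomarkers (ALT, AST, GGT, ALP, TG, TC, LDL-C,
HDL-C) with medians matching early-pregnancy reference values. The three
glucose channels are linear predictors on the standardized log-biomarkers
plus age and BMI effects plus independent noise, on each channel's own SD
scale (fasting 4.4 +/- 0.45, 1-h 7.6 +/- 1.5, 2-h 6.6 +/- 1.3 mmol/L). A
single shared intercept shift is then calibrated by bisection so the
realized GDM prevalence (through `diagnose_gdm()`, after rounding to the
0.1 mmol/L measurement resolution) hits the configured target -- 18.2% by
default, the prevalence scale of the cohorts this design emulates. The
default biomarker effect matrix is zero: the published literature reports
odds ratios, not generative effect sizes, so the default pins only the
structural anchors and analyses that need signal set effects explicitly
(per SD of log-biomarker, in channel SDs).

Because subtype labels compete -- raising post-load glucose moves some
women who would have been i-IFG into b-GDM -- a generator with purely
post-load effects induces a small *protective*-looking i-IFG artifact at
large n. The end-to-end subtype check therefore asserts "no elevated
i-IFG risk" (OR near or below 1) rather than an exact null.

`simulate_gwas_pair()` generates summary statistics directly (no
individual-level genotypes): maf ~ Uniform(0.1, 0.4); instrument effects
half-normal with scale 0.03, giving mean F near 100 at n_exp = 300,000 --
the strength scale reported for liver-enzyme instruments. The half-normal
(exposure-increasing) orientation matters: with sign-symmetric effects,
directional pleiotropy cancels out of IVW and the Egger-vs-IVW contrast
has nothing to detect. Standard errors follow the 1/sqrt(2 maf (1-maf) n)
large-sample form, observed effects are normal around truth, pleiotropy
adds direct effects alpha (balanced or directional) to an invalid
fraction, and the outcome effect is theta * gamma + alpha plus noise.
Palindromic allele pairs are injected at a configurable fraction, and SNPs
are laid out in LD blocks (exchangeable within-block r^2, blocks separated
beyond the clumping window) so the clumper has real structure to prune.

What the generators do *not* emulate: real LD beyond block-exchangeable
r^2, winner's-curse in instrument selection, sample overlap between the
two GWAS, assay error and non-log-normal biomarker tails, seasonal or
site effects, and informative missingness. Passing tests therefore show
the estimators and filters implement their definitions and are calibrated
under this generative family -- not that real-data biases are absent.

## Numerical choices and problem sizes

* Quantiles are type-7 (linear interpolation) everywhere.
* Bisection for the prevalence intercept runs on [-3, 3] channel SDs to a
  1e-9 bracket; an unattainable target is an error, and a realized miss
  beyond +/- 0.01 warns (only reachable with extreme configs).
* Wald CIs use z = 1.96 except MR-Egger (t, m-2 df).
* The weighted-median bootstrap and all MR-PRESSO draws run under a
  private seeded RNG state that does not disturb the caller's stream.
* Ties in clumping are broken lexicographically by rsid so output is
  deterministic across platforms.
* Simulation sizes used by the test-suite and the acceptance script were
  chosen as the package's own study conditions: 500 replicates for
  estimator recovery and for each type-I calibration (quartile-trend at
  n = 5,000, spline screen at n = 2,000, interaction at n = 10,000,
  Cochran Q at m = 50), 200 replicates for the robust-estimator
  comparisons and the MR-PRESSO null, 60 spike-in runs, and n = 20,000
  for the subtype-pattern demonstration.

## Known limitations

* The exposure-side uncertainty is not propagated into the Wald-ratio SE
  (first-order convention); with mean F near 100 the omitted term is
  below a percent of the variance.
* MR-PRESSO's distortion null uses random same-size removals of observed
  SNPs, a pragmatic simulated null; with very few SNPs its resolution is
  limited.
* The multinomial subtype model treats subtypes as unordered; no shared
  random effect links the three glucose channels.
* The baseline descriptive table uses rank-sum and chi-square tests only,
  mirroring the usual presentation; no normality switching is attempted.
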
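# gdmliver

Early-pregnancy liver biomarkers and the risk of gestational diabetes
mellitus (GDM): a prospective-cohort modelling toolkit and a two-sample
Mendelian-randomization (MR) engine, with seeded synthetic generators so
every stage runs and calibrates offline.

The package is written for perinatal epidemiologists and genetic
epidemiologists who want the full analysis chain — from raw participant and
GWAS summary-statistic tables to quartile odds-ratio tables, spline
dose–response screens, subtype models and the MR estimator suite — as
tested, reusable R functions rather than one-off scripts.

## What it computes

**Cohort arm.** Participants screened at 8–14 gestational weeks are
filtered (missing tests, disqualifying history, abnormally elevated enzymes
ALT > 90 / AST > 80 / GGT > 90 / ALP > 240 U/L), GDM is diagnosed from the
75 g OGTT (FBG ≥ 5.1, 1-h ≥ 10, 2-h ≥ 8.5 mmol/L, inclusive) and subtyped
(i-IFG / i-IGT / b-GDM). For each liver function index
(ALT, AST, GGT, ALP, AST/ALT, HSI = 8·ALT/AST + BMI + 2):

- adjusted quartile logistic models with Wald CIs and a median-assigned
  trend test (`fit_quartile_logistic`),
- 4-knot restricted-cubic-spline nonlinearity screens against each glucose
  channel, with a continuous single-breakpoint piecewise follow-up when
  nonlinear (`fit_rcs`, `fit_piecewise`),
- multinomial subtype models, reference non-GDM (`fit_subtype_multinomial`),
- overweight-stratified (BMI ≥ 24 kg/m²) and clinical-range sensitivity
  reruns, and median-split crossover interaction with lipids
  (`crossover_interaction`).

**MR arm.** From exposure/outcome GWAS summary statistics: instrument
selection (p < 5e-8, MAF > 0.01, pleiotropy exclusion list), greedy LD
clumping (r² = 0.001, 10,000 kb), allele harmonization with palindromic-SNP
removal, F-statistics, and the estimators — Wald ratio, IVW (multiplicative
random effects by default), Cochran's Q, MR-Egger, weighted median
(seeded bootstrap SE), MR-PRESSO (global, outlier and distortion tests) and
multivariable MR for BMI-conditional effects.

**Generators.** `simulate_cohort()` and `simulate_gwas_pair()` emulate both
arms' inputs with recorded ground truth (`truth_report()` tabulates bias,
RMSE, coverage and power), calibrating the realized GDM prevalence to
18.2% by default.

## Worked example

```r
library(gdmliver)
ef <- matrix(0, 8, 3); ef[1, 2:3] <- 0.2       # ALT raises post-load glucose
cs <- simulate_cohort(cohort_sim_config(n = 8000, seed = 42, effects = ef))
g  <- simulate_gwas_pair(gwas_sim_config(m_snps = 150, seed = 42,
                                         theta = 0.25,
                                         fraction_palindromic = 0.1))
cfg <- run_config(arm = "both", cohort = cs$records,
                  exposure = list(alt = g$exposure), outcome = g$outcome,
                  ld = g$ld, lfi = c("alt", "hsi"), lipids = "tg",
                  presso_n_sim = 1000)
res <- run_pipeline(cfg)
print(res)
print(res$cohort$quartile$alt)
```

```
Cohort arm: 8000 analytic participants, 1456 GDM (18.2%); 0 excluded
MR arm report:
 exposure                              method n_snps               or        p
      alt IVW (multiplicative random effects)     68 1.29 (1.25-1.33) 3.80e-57
      alt                            MR-Egger     68 1.30 (1.18-1.43) 4.84e-07
      alt                     Weighted median     68 1.28 (1.22-1.34) 1.31e-28
Quartile logistic model: GDM ~ alt
 contrast               or        p n_cases n_total
 Q2 vs Q1 1.19 (0.99-1.42) 6.49e-02     315    2001
 Q3 vs Q1 1.46 (1.22-1.74) 2.51e-05     379    2001
 Q4 vs Q1 2.05 (1.73-2.43) 1.15e-16     477    1995
P for trend (median-assigned): 4.19e-19
```

Reading the output: the generator gave ALT a true effect on the post-load
glucose channels and a true causal log-OR of 0.25 (OR ≈ 1.28) on the
simulated outcome. The cohort arm recovers a monotone quartile gradient
(Q4 vs Q1 OR 2.05, trend p ≈ 4e-19) at the calibrated 18.2% prevalence;
the MR arm recovers the causal OR with all three estimators (IVW 1.29
against the true 1.28 ≈ exp(0.25)) from the 68 instruments that survive
genome-wide-significance selection, clumping and harmonization of the 150
simulated SNPs.

Real summary-statistics files are accepted in the declared tab-delimited
format (`rsid, chr, pos, effect_allele, other_allele, eaf, beta, se, pval,
n`) via `read_sumstats()`, cohort tables via `read_cohort()`; a thin
command-line wrapper lives at `inst/cli/gdmliver.R`.

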
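# benefitscore

Tumor mutational burden (TMB) predicts benefit from immune checkpoint
inhibition (ICI) in melanoma, but imperfectly: a large mutation load only
helps the immune system when the resulting neoantigens are shared across
the tumor, and high intratumoral heterogeneity undercuts that. This
package implements a per-tumor **benefit score** that integrates the two
signals,

```
benefit score = TMB / MATH        (MATH replaced by 1 when it equals 0)
```

where TMB is the count of nonsynonymous somatic mutations and MATH
(mutant-allele tumor heterogeneity) is

```
MATH = 100 * 1.4826 * median(|VAF_i - median(VAF)|) / median(VAF)
```

computed on the tumor's variant allele fractions. A high score means a
high mutational load, low heterogeneity, or both — the profile expected to
respond to ICI.

The package is aimed at analysts working with MAF-style somatic mutation
tables plus clinical follow-up, and provides the full evaluation pipeline
around the score:

- **Mutation filtering** — VAF ≥ 0.05, coverage > 30 reads, standard MAF
  nonsynonymous classes (`read_maf()`, `apply_quality_filters()`,
  `select_nonsynonymous()`).
- **Scores** — TMB, MATH, benefit score per sample (`score_cohort()`),
  and clonal TMB from cancer-cell-fraction (CCF) annotations under either
  published clonality rule: lower 95% CCF bound > 0.95, or CCF = 1 /
  P(clonal) > P(subclonal) (`compute_clonal_tmb()`).
- **Survival stratification** — the maximally selected log-rank statistic
  over all admissible marker cutpoints (`find_optimal_cutpoint()`), with
  both the naive log-rank p and a selection-adjusted p (the naive p at a
  data-chosen cutpoint is anti-conservative), Kaplan–Meier coordinates,
  and multivariate Cox hazard ratios (`cox_fit()`, Efron ties).
- **Associations** — Spearman correlations between markers and two-tailed
  Wilcoxon contrasts of immune-cell fractions between and within score
  groups (`spearman_corr()`, `immune_contrast_table()`).
- **Synthetic cohorts** — a generator with known clonal architecture,
  binomial read sampling (`E[VAF] = purity × CCF / 2`), score-linked
  exponential survival and Dirichlet immune compositions, used by the test
  suite for oracle, calibration and recovery checks (`simulate_cohort()`).

## Worked example

```r
library(benefitscore)

cohort <- simulate_cohort(simulation_config(), seed = 7)
scores <- score_cohort(cohort$mutations)
head(scores[, c("sample_id", "tmb", "math", "benefit_score", "valid")], 4)
#>   sample_id tmb     math benefit_score valid
#> 1     S0001 511 48.21041     10.599371  TRUE
#> 2     S0002 112 13.47818      8.309726  TRUE
#> 3     S0003 395 46.42485      8.508375  TRUE
#> 4     S0004 281 10.74885     26.142332  TRUE

report <- run_analysis(analysis_config(
  cohort$mutations, cohort$survival,
  clonal = cohort$clonal_annotations, immune = cohort$immune_fractions,
  markers = c("tmb", "math", "benefit_score"),
  covariates = c("age", "sex", "stage")))
report
#> Benefit-score analysis: 99 samples scored, 1 excluded
#>   Spearman rho(TMB, MATH) = -0.130 (p = 0.201)
#>   Spearman rho(benefit score, clonal TMB) = 0.950 (p = 8.44e-51)
#>          marker  threshold n_high n_low chi_square      naive_p  adjusted_p
#> 1           tmb 150.500000     46    53   8.753473 3.090130e-03 0.064511309
#> 2          math  21.678275     50    49  11.485683 7.013434e-04 0.018897361
#> 3 benefit_score   8.257581     40    59  16.969026 3.799464e-05 0.001484439
#>   hr_high_vs_low hr_ci_low hr_ci_high
#> 1      0.4786373 0.2906746   0.788145
#> 2      2.3605356 1.4164315   3.933920
#> 3      0.3372426 0.1964578   0.578916
```

Reading this: TMB and MATH are essentially uncorrelated (rho = −0.13), so
the ratio adds information; one sample was excluded because MATH cannot be
estimated from too few mutations; the benefit score separates survival
more sharply (naive log-rank p = 3.8e−05, univariate HR high vs low =
0.34) than TMB alone (p = 3.1e−03, HR = 0.48), and the advantage survives
the selection-adjusted p. The multivariate Cox model confirms the score's
independence from clinical covariates:

```r
print(report$cox)
#> Cox proportional hazards fit (Efron ties): n = 99, events = 67
#>            term    hr        ci95 p_value
#>             age 0.990 0.970-1.010 0.32278
#>         sexMale 1.075 0.659-1.753 0.77322
#>         stageIV 0.991 0.570-1.724 0.97410
#>  score_grouplow 2.134 1.291-3.525 0.00309
```

i.e. a low benefit score roughly doubles the hazard of death after
adjusting for age, sex and stage.

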
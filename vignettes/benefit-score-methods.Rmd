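---
title: "Methods: the benefit score and its evaluation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the benefit score and its evaluation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benefitscore)
```

## The statistic

Checkpoint-inhibitor benefit tracks the supply of *clonal* neoantigens: a
tumor helps the immune system when it carries many mutations and those
mutations are shared across its cell population. Raw tumor mutational
burden (TMB) captures the first property; mutant-allele tumor
heterogeneity (MATH) captures the opposite of the second. The benefit
score integrates them as a ratio:

$$
\mathrm{score} = \frac{\mathrm{TMB}}{\mathrm{MATH}}, \qquad
\mathrm{MATH} = 100 \cdot \frac{1.4826 \cdot
\operatorname{median}_i\,\bigl|v_i - \operatorname{median}(v)\bigr|}
{\operatorname{median}(v)},
$$

where $v_i$ are the tumor's variant allele fractions (VAFs) after quality
filtering. The constant 1.4826 makes the median absolute deviation a
consistent estimator of the standard deviation under normality; MATH is
therefore a robust coefficient of variation of the VAF distribution,
scaled to percent. When every retained VAF is identical MATH is exactly 0,
and the score substitutes 1 for the denominator so the ratio stays
defined; the `math_substituted` flag records when this happened.

Assumptions worth keeping in view: MATH reads heterogeneity off a single
sample's VAF marginal, so it conflates subclonal structure with purity and
copy-number effects; and TMB is used as a raw count, not per megabase,
because every comparison the pipeline makes is within one cohort captured
with one exome footprint.

## Mutation filtering

Records with allelic fraction below 0.05 or with coverage of 30 reads or
fewer are excluded before any score is computed. Coverage is defined as
`t_alt_count + t_ref_count`, the only read-count fields universally
present in MAF exports. The boundary semantics are deliberate and tested:
VAF exactly 0.05 is retained (the cut is strict below), coverage exactly
30 is excluded (the cut is inclusive), and zero-coverage records are
dropped at parse time because their VAF is undefined.

TMB counts the *nonsynonymous* subset — by default the standard
protein-altering MAF classes (missense, nonsense, nonstop, splice site,
frame-shift and in-frame indels, translation start site). MATH, by
contrast, is computed on **all** quality-filtered VAFs, matching the
convention of MATH implementations that operate on the full MAF; a
`math_on = "nonsynonymous"` switch is available because the two choices
can disagree on sparse tumors. Both filters are applied before TMB
counting as well as before MATH; whether an upstream analysis applied them
to TMB is rarely documented, so `tmb_after_quality_filter = FALSE`
preserves the alternative for sensitivity analysis.

MATH needs a minimum number of VAFs to be meaningful; the package requires
5 (`min_mutations_for_math`), the smallest count at which a median/MAD
pair is not determined by one or two reads. Samples below the minimum are
kept in the score table with `valid = FALSE` and excluded from
stratification, with the exclusion count reported — cohort headline *n*s
depend on these drops, so they are never silent.

## Clonal TMB

Two clonality rules are implemented because published CCF annotations come
in two shapes. With PyClone-style posteriors, a mutation is clonal when
the lower bound of its 95% CCF interval exceeds 0.95 (strict inequality —
"exceeds" is read literally). With ABSOLUTE-style annotations, a mutation
is clonal when its CCF point estimate equals 1 (within $10^{-9}$, a pure
floating-point guard) or when the annotated probability of being clonal
exceeds that of being subclonal. Clonal TMB is the count of clonal calls
among the sample's quality-filtered nonsynonymous mutations, so it can
never exceed TMB — an invariant the tests assert.

## Survival stratification

Continuous markers are dichotomised at the cutpoint maximising the
absolute standardized two-group log-rank statistic. Candidate thresholds
are midpoints between consecutive distinct marker values (stable under
floating-point jitter of the observed values); a split is admissible when
both groups hold at least `ceil(minprop * n)` subjects, with
`minprop = 0.1`, the default of the widely used cutpoint selector this
reproduces; ties in the maximal statistic resolve to the smallest
threshold, for determinism; and "high" means strictly greater than the
threshold, consistent with midpoint candidates.

The log-rank statistic uses the hypergeometric variance at each distinct
event time. Its p-value at the *selected* cutpoint is biased low — the
threshold was chosen to maximise exactly that statistic — so the package
reports two numbers side by side: the naive log-rank p (what most applied
papers print) and a selection-adjusted p from the Brownian-bridge
approximation to the distribution of the maximally selected statistic over
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = $ `minprop`. The test suite
quantifies the bias directly: on 500 null cohorts (no survival–group
association) the naive p rejects at the 0.05 level about 40% of the time,
while the log-rank test on pre-specified groups holds its nominal 5%
size. Conclusions about marker performance should rest on the adjusted
column, or on validation cohorts.

Kaplan–Meier curves come from the product-limit estimator, and
multivariate verification uses Cox partial likelihood with the Efron tie
correction — the robust default when many tied times are present.
Covariates with no variation are dropped with a warning rather than
producing a silent NA coefficient, and convergence problems are surfaced
through a flag plus diagnostics. The score group enters the model with the
*high* group as reference, so the tabulated hazard ratio for the low group
reads directly as "excess hazard of a low benefit score".

## Correlations and immune contrasts

Marker correlations are Spearman throughout (monotone association, no
linearity assumption; average ranks under ties). "Two-tailed Wilcoxon" is
disambiguated by the data structure: between-group comparisons of
pre-treatment fractions use the rank-sum test, within-group pre-to-on
treatment changes use the signed-rank test on per-patient differences —
the change during treatment is a paired quantity, so the paired test is
the faithful reading. Exact distributions are used whenever sample sizes
permit and no ties interfere, the normal approximation with continuity
correction otherwise. Unadjusted p-values are primary, as is conventional
for small immune-profiling panels; a Benjamini–Hochberg column is emitted
alongside (per contrast family), clearly labelled, for readers who prefer
it.

## The synthetic-cohort generator

`simulate_cohort()` produces cohorts with the statistical structure the
analysis assumes, plus the ground truth needed for recovery tests:

- **Clonal architecture**: each tumor has a truncal clone at CCF 1 and 0–3
  subclones with CCFs uniform on (0.1, 0.8); mutations are assigned to
  clones uniformly.
- **Reads**: site depth is Poisson (mean 150, a typical exome), and alt
  reads are binomial with success probability `purity × CCF / 2` — a
  diploid, copy-neutral model, the simplest under which MATH and
  clonality behave as the analysis assumes.
- **Mutation load**: negative binomial (default mean 120, size 1.2),
  spanning roughly 10–1000 mutations per tumor, matching the orders of
  magnitude seen in melanoma exomes; 75% of simulated mutations are
  nonsynonymous.
- **The latent benefit group**: half the patients are "high" types, with
  3× the mutation mean and at most 2 clones; "low" types draw from the
  full 1–4 clone range. Survival is exponential with hazard
  `baseline × exp(group_log_hr × I(low))` (defaults 0.03/month and 0.7,
  i.e. a high-vs-low hazard ratio of ≈0.5) under uniform censoring on
  6–48 months. Linking survival to the latent *group* rather than to the
  continuous score gives an unambiguous generative hazard ratio for
  calibration.
- **CCF annotations**: true clone CCFs plus Gaussian noise (sd 0.03),
  lower bounds 0.02–0.08 below the point estimate, and a logistic map from
  CCF to clonality probabilities — enough structure for both clonality
  rules to be exercised realistically.
- **Immune fractions**: Dirichlet compositions (rows sum to 1 exactly) at
  two timepoints, with the high group receiving a positive NK-cell shift
  and negative M2-macrophage shift at baseline and a CD8 concentration
  boost on treatment.

One seed fans out to four independent per-stage generators (mutations,
clonality, survival, immune), so a stage rerun in isolation reproduces its
output.

What the generator does *not* emulate: copy-number variation and its
distortion of VAFs, sequencing error, purity estimation error, dependence
between mutation load and clinical covariates, and non-proportional
hazards. Tests passing on these cohorts therefore validate the
*computational pipeline* — filters, scores, cutpoint scan, calibration of
the tests — not the biological claim that the score predicts ICI benefit
in real patients.

## Numerical choices and degenerate inputs

MATH on fewer than 5 VAFs, or with median VAF 0, is `NA`, and propagates
to an `NA` score. A cutpoint scan with all marker values identical, a
log-rank test with zero events, a signed-rank test with all differences
zero, and a Spearman correlation against a constant vector all raise
informative errors rather than returning numbers. CCF equality with 1
uses a $10^{-9}$ tolerance; clonality and filter thresholds are strict or
inclusive exactly as documented above, and all are configurable.

## Problem sizes in the test suite

The test suite chooses sizes where each property is informative and the
whole suite stays quick: 1,000 random VAF vectors for the MATH oracle; 100
random instances of up to 200 subjects for cutpoint-scan/brute-force
equivalence; 10,000-replicate permutation checks on fixtures of 100
subjects (log-rank) and 12 per side (rank-sum); 500 cohorts of 80 patients
for null calibration; and 100 cohorts of 400 patients for hazard-ratio
recovery. Survival-only checks use lighter mutation loads than the
generator's defaults, since the mutation table does not enter those
statistics.

## Known limitations

Single-region MATH is a noisy proxy for heterogeneity, and the score
inherits that noise. The adjusted cutpoint p-value is an asymptotic
approximation, conservative at small n. The Cox table assumes
proportional hazards; no diagnostics beyond convergence are built in. The
pipeline analyses one cohort at a time by design — cutpoints are
data-dependent and should never be pooled across differently captured
cohorts — and a joint model of benefit score with clonal TMB is provided
only as a simple bivariate Cox fit, since the two markers are strongly
correlated by construction and their joint effect is not separately
identifiable at typical cohort sizes.
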
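---
title: "Robust normative modelling of NODDI microstructure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust normative modelling of NODDI microstructure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noddinorms)
```

## The problem

In the AT(N) biomarker framework for Alzheimer's disease, amyloid (A) and
tau (T) positivity are routinely dichotomized from CSF assays, but
neurodegeneration (N) has no comparably crisp definition: conventional
volumetry captures late-stage atrophy and confounds disease effects with
normal aging.  Microstructural diffusion MRI — here the NODDI model's
neurite density index (NDI) and orientation dispersion index (ODI),
extracted as bilateral means over disease-vulnerable gray-matter parcels
and white-matter tracts — is sensitive to earlier tissue change, but raw
values still drift with age and differ by sex.

`noddinorms` implements a *robust internal norms* approach, borrowed from
neuropsychological test norming, to turn ROI-level NODDI metrics into
age- and sex-adjusted z-scores whose reference distribution is anchored in
a biomarker-negative, cognitively unimpaired subgroup; and a downstream
inferential layer (nonparametric group comparisons and a Firth-penalized
logistic model-comparison suite) that asks whether those metrics carry
diagnostic information beyond CSF A/T status.

## The normative model

For each of the 24 metric-by-region cells (2 metrics x 12 regions), an
ordinary least squares regression is fitted on the normative set:

$$\widehat{y} = b_0 + b_{\mathrm{age}}\,(\mathrm{age} - \bar a) +
  b_{\mathrm{sex}}\,\mathrm{sex}, \qquad
  z = \frac{y - \widehat{y}}{\mathrm{RMSE}}$$

with sex coded 0 = male, 1 = female, and age centered at the mean age
$\bar a$ of the fitting set.  The procedure in `build_norms()` is:

1. the normative set is the cognitively unimpaired (CU), CSF A−T−
   participants;
2. all 24 regressions are fitted and initial z-scores computed on that set;
3. any normative participant with $z \le -1.5$ in *any* cell is removed
   (one pass, below-only);
4. the regressions are refit on the reduced set and the coefficients,
   RMSE and age-centering constant are frozen;
5. every participant — including the clinically impaired — is z-scored
   against the frozen model.

### Numerical and boundary choices

* **RMSE denominator.** Unspecified in the robust-norms literature we
  follow; the default is the residual degrees of freedom $n - 3$
  (intercept, age, sex), so the RMSE coincides with the regression's
  residual standard error.  A plain $n$ denominator is available
  (`norms_config(rmse_denominator = "n")`).  A direct consequence used by
  the test suite: on the final normative set the per-cell z-scores have
  mean exactly 0 (OLS residual identity) and standard deviation
  $\sqrt{(n-3)/(n-1)}$.
* **Exclusion boundary.** "1.5 or more SD below expected" is read as
  inclusive: $z \le -1.5$ flags.  The rule is one-sided; large positive
  values never trigger removal, even in tracts where disease *raises*
  ODI.
* **Age centering** is the mean age of the current fitting set and the
  final (reduced-set) value is frozen inside the serialized model, so
  applying saved norms to a new cohort is reproducible.
* **Single pass vs. iteration.** The procedure removes once and refits;
  `norms_config(iterate = TRUE)` repeats flag-and-refit to a fixed point
  for sensitivity analyses.  With the threshold set to `Inf` the
  procedure reduces exactly to a single-pass fit.
* The flag rule scans both metric families over all 12 regions by
  default; `norms_config(metrics = "NDI")` restricts it.

## A/T classification and sample selection

Amyloid positivity is `abeta42/abeta40 < 0.046` (strict) and tau
positivity `ptau >= 24.8` (inclusive), both configurable
(`cutoff_config()`); boundary semantics are taken literally from the
published cutoff definitions.  The joint amyloid rule is scale-invariant
in (Aβ42, Aβ40).  An optional secondary rule on raw Aβ42 exists behind
`cutoff_config(abeta42_cutoff = )` and is unconfigured by default.  The
analysis-sample filter keeps CU participants with A−T−/A+T−/A+T+ status
and impaired (MCI/AD) participants only when amyloid-positive; A−T+
participants fall outside the AD A/T continuum and are always excluded,
with every dropped row recorded in a reasoned ledger.

## Group comparisons

Per metric-by-region cell, `compare_groups()` runs a Kruskal–Wallis
omnibus test (tie-corrected, chi-square reference) across the group
levels, adjusts within-family with Benjamini–Hochberg FDR, and only for
cells passing the omnibus gate computes pairwise two-group
Kruskal–Wallis follow-ups with Cliff's delta effect sizes.  Design
choices that were genuinely open:

* **FDR procedure and family.** "FDR correction" does not pin down a
  method or family; the default is Benjamini–Hochberg within each
  metric-by-tissue-class block of six regions, matching the granularity
  at which results tables are usually presented.  Both the method
  (`method =` any `p.adjust` method) and the family (`"metric"`, `"all"`)
  are options rather than guesses about what was originally used.
* **Cliff's delta interval.** The variance is Cliff's unbiased
  consistent estimate, floored at $(1-d^2)/(n_x n_y - 1)$ (the estimate
  can otherwise go negative at extreme dominance), with a normal
  approximation truncated to $[-1, 1]$.  `delta = +1` collapses the
  interval.  The delta is oriented first-level-minus-second in the
  supplied level order, so "CU vs MCI/AD" is positive when CU scores
  higher.
* **Ties** take average ranks everywhere; a cell in which every pooled
  value is identical raises an explicit undefined-statistic error rather
  than returning `NaN`.
* Rank correlations between z-scores and CSF analyte levels use
  tie-aware ranks with the two-sided t approximation
  (`spearman_correlation()`).

## The Firth model suite

Ten logistic models predict clinical status (CU vs combined MCI/AD by
default; CU-vs-MCI and CU-vs-AD variants are configuration switches),
each controlling for age and sex: model 0 has no biomarker predictors;
model 1 adds CSF A/T status as a single ordinal covariate coded
1 = A−T−, 2 = A+T−, 3 = A+T+ (a dummy-coded variant sits behind
`suite_config(at_coding = "dummy")`); models 2–5 instead add the six
*raw* bilateral ROI means of one metric-by-tissue block; models 6–9
combine A/T status with each block.  With ~11 impaired cases, several
models separate the classes perfectly, so estimation uses Firth's
penalized likelihood

$$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det X^\top W X,$$

maximized by Newton steps on the modified score
$U^*(\beta) = X^\top\!\left(y - \mu + h\,(\tfrac12 - \mu)\right)$ with
hat diagonals $h$ and step-halving.  Convergence is declared at a
penalized-score max-norm below `1e-8`; the iteration cap defaults to 150
because near-separated fits on this design (raw age in years next to
fraction-scale ROI covariates) take roughly 70 iterations to drive the
score that low — a cap of 50 would flag spurious non-convergence.
Intercept-only fits have the closed form
$\hat p = (k + \tfrac12)/(n + 1)$, which the test suite checks for all
$k \le n \le 20$ alongside a grid-search oracle on separated data.

Model quality is reported as in-sample AUC (rank-sum definition, ties
one half) with a DeLong structural-components confidence interval,
AIC computed from the *penalized* log-likelihood with $k$ = all
coefficients including the intercept (an approximation, flagged here,
since the penalty is not a likelihood), and a penalized likelihood ratio
defined explicitly as $2(\ell^*_{\mathrm{model}} -
\ell^*_{\mathrm{reference}})$ with model 0 as the default reference.
Published tables of this design mix PLR signs without stating the
reference; this package defines the convention rather than
reverse-engineering one.  No cross-validation is performed — the AUC is
in-sample by design, matching the procedure being modelled — so AUC
values for the larger models should be read as optimistic.

## Voxel-level extraction

For gray matter, a GM-fraction map is synthesized as
`clamp(1 - WM - CSF, 0, 1)` (the raw subtraction can go negative where
the input fractions overlap; fractions are physically bounded, hence the
clamp), parcels are restricted to voxels with GM fraction at or above
0.7 — the boundary is inclusive and the threshold configurable — and
per-hemisphere means are averaged bilaterally.  For white matter, means
are weighted by tract probability over strictly positive-probability
voxels, which also avoids `0 * NaN` pathologies; left/right probability
maps are averaged after extraction.  The pseudo-T1 volume
(`0*CSF + 1*WM + 2*GM`, range [0, 2]) is provided as the registration
contrast; registration itself is out of scope and replaced by a
grid-equality check on all inputs.  Empty parcels or all-zero tracts
raise errors naming the region, never silent `NaN`s.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the study conditions at the published scale:
296 participants split CU 231/26/28, MCI 0/1/5, AD 0/1/4 over
A−T−/A+T−/A+T+; per-diagnosis age distributions (CU 65.1 ± 7.8,
MCI 71.8 ± 9.7, AD 71.4 ± 2.5 years, truncated to a plausible 45–95
study range) and female fractions (65%/83%/40%).  CSF analytes are
truncated log-normals conditional on the assigned cell — log-normality
keeps concentrations positive, truncation guarantees that
`classify_at()` reproduces the assigned cell with probability one.  ROI
values follow the linear generative model
`baseline + age_slope*(age - 65) + sex_effect*sex + shift*residual_sd +
noise`, clamped to (0, 1), with baselines and a residual SD of 0.03
chosen as field-plausible NODDI values and planted group shifts
expressed in residual-SD units so they map directly onto expected
z-score gaps.  The default shift pattern mirrors the published effect
directions, including the bidirectional white-matter ODI pattern
(uncinate and hippocampal cingulum higher, inferior longitudinal
fasciculus lower in MCI/AD) and a milder preclinical posterior ODI
decrease in CU A+T+.

Deliberate non-realism to keep in mind:

* **Residual noise is independent across cells.**  Real NODDI metrics
  are strongly correlated across regions within a person.  Under
  independence, the any-of-24-cells flag rule removes
  $1 - \Phi(1.5)^{24} \approx 80\%$ of a null normative sample — the
  test suite verifies exactly this prediction — whereas on correlated
  real data the same rule removes only a few percent.  Passing tests
  therefore validate the *rule*, not the real-data exclusion fraction.
* No scanner/site effects (the source data pooled two scanners), no
  longitudinal structure, no voxel-level realism in the cohort tables;
  the imaging phantom plants piecewise-constant ROI means in mirrored
  blobs and smooth tract profiles purely to exercise the extraction
  arithmetic.
* Two CU cell-count conventions circulate for the source cohort
  (231/26/28 in its demographics table, A+T− = 16 in its text); the
  generator defaults to the table and both are ordinary configuration
  fields — the discrepancy is surfaced, not reconciled.

## Problem sizes and runtime of the verification suite

The package's property checks run at sizes chosen to keep the full suite
around a minute while leaving comfortable statistical margins: normative
identities at n = 400; exclusion fidelity at 240 normative subjects with
10 planted outliers over 50 seeds; slope recovery at n = 200 over 200
replicates; 500 brute-force Cliff's delta cases and 200-case AUC/BH
oracle sweeps; DeLong coverage over 1000 null replicates at 100 per
class; type-I calibration over 2000 replicates of 3 x 30 subjects and 6
regions; and the model-suite ordering over 20 seeds of a ~200-person
cohort.

## Limitations

Beyond the generator's independence assumption above: the Wald intervals
for Firth coefficients are a convenience (profile-likelihood intervals
are out of scope); the AIC-on-penalized-likelihood convention makes AIC
values comparable within this package but not to plain-likelihood AICs;
and with ~11 impaired cases all impaired-group inferences — planted or
real — are dominated by small-sample noise, which is faithful to the
scale of the study being modelled and should temper interpretation of
any single run.
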
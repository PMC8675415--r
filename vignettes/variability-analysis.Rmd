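---
title: "Modelling sex differences in the variability of brain morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sex differences in the variability of brain morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainvar)
library(dplyr)
```

## The scientific question

For many human traits, males are reported to be more *variable* than
females, not only different on average.  brainvar implements a
mega-analytic pipeline for testing this on regional brain morphometry
pooled at the subject level across many imaging cohorts: 14 subcortical
volumes, 68 cortical surface areas and 68 cortical thicknesses on the
Desikan-Killiany parcellation, with cohorts covering different slices of
the 1–90 year age range.  The pipeline asks four questions per measure:

1. Do the sexes differ in **mean** (Cohen's *d*, pooled t-test, FDR)?
2. Do they differ in **variance** (permutation test of the variance
   ratio)?
3. **Where** along the distribution do they differ (shift function)?
4. Does the variance gap **change with age** (absolute-residual
   regression)?

and, across measures, whether the sexes differ in inter-regional
anatomical correlation (homogeneity).

## Covariate harmonization

Cohorts differ in age coverage, scanners and segmentation software, so
all analyses run on residuals from a two-step adjustment
(`adjust()`):

* **Stage 1** — OLS of each measure on cohort indicator contrasts and a
  cubic polynomial in age.  A single pooled model is used (no
  cohort-by-age interactions; a flag could add them, but the pooled fit
  is what makes a mega-analysis a mega-analysis).  Age is divided by 100
  before the polynomial expansion purely for numerical conditioning of
  the cubic design; coefficients are reported on that scale.
* **Stage 2** — a random-forest regression of the stage-1 residuals on
  scanner field strength and software version (one-hot categorical
  predictors), subtracting the forest's predictions.  The forest can
  absorb label interactions and non-additivity that a linear model would
  miss.  Hyperparameters default to 500 trees with a minimum node size
  of 50: large leaves deliberately restrict the forest to coarse label
  effects so it cannot soak up subject-level (including sex-linked)
  variance.  The forest seed is recorded in the output metadata.

Sex is **never** a covariate: the point of the residuals is that
sex-linked mean and variance structure survives adjustment.  When
scanner labels are nested within cohort — the common real-world design —
stage 1 has already removed them and stage 2 predicts approximately
nothing; the per-measure out-of-bag variance explained in
`attr(adjusted, "stage2_summary")` makes this visible rather than
hiding it.

Stage-1 residuals are exactly orthogonal to every design column (tested
at machine precision).  After the forest subtraction the residual mean
can drift from zero by a small amount (well under 1% of an SD); this is
inherent to non-projection adjustments and is common to both sexes, so
it cannot bias any sex contrast.

## The variance-ratio permutation test

For each measure, with residuals \(r_i = y_i - \hat y_i\), the test
statistic is Fisher's variance ratio
\(T = \mathrm{Var}_{males}/\mathrm{Var}_{females}\) (sample variances,
\(n-1\) denominator), log-transformed to symmetrize it around zero.
Significance comes from random permutation of the sex labels among the
residuals: with \(B\) permutations (default 10,000) the one-sided
p-value is the proportion of permuted statistics exceeding the observed
one, \(p = \sum_b I(T_b > T)/B\).  The default is two-sided on
\(|\log T|\), since greater *female* variance is a legitimate outcome
and is observed for some edges and measures; the one-sided variant is a
flag.  Ties are counted with a \(10^{-9}\) relative tolerance so that
analytically tied assignments (e.g. label complements with equal group
sizes) are handled identically regardless of floating-point noise, and
an exhaustive-enumeration mode replaces sampling when
\(\binom{n}{n_m}\) is small.  Add-one smoothing \((\#+1)/(B+1)\) is
available to bound p away from zero.

p-values are FDR-corrected (Benjamini–Hochberg via
`stats::p.adjust`) **within measure class** — the 14 subcortical
volumes, 68 areas and 68 thicknesses are separate reporting families.
Calibration and power are verified by simulation in the test suite:
type-I error at \(\alpha = 0.05\) lands in [0.03, 0.07] over 1,000 null
replicates, and power exceeds 0.95 at \(\log VR = 0.3\) with 1,000
subjects per sex.

## Shift functions

To see *where* the distributions differ, each group is mean-centered
and its deciles estimated; the decile distance
\(D(q) = Q_m(q) - Q_f(q)\) is reported with bootstrap standard errors
(stratified resampling within sex) and normal-approximation 95%
intervals \(D \pm 1.96\,SE\).  A positive slope of \(D\) in \(q\) —
males relatively smaller in the lower tail and larger in the upper
tail — means greater male spread.  Classification uses the sign pattern
of the deciles whose CI excludes zero; conflicting or absent evidence is
called `parallel`.

The default quantile estimator is Harrell–Davis: a smooth, efficient
L-estimator whose weights are Beta\(((n+1)q, (n+1)(1-q))\) masses over
the order-statistic cells.  The weight matrix depends only on \(n\) and
the probabilities, so bootstrap replicates reuse it and each replicate
costs one sort plus one matrix product — this is what keeps
100,000-subject shift functions in seconds.  A quantile-regression
forest estimator (age as the conditioning variable, leaf-pooled
quantiles averaged over the observed age distribution, large leaves for
stable tails) and the plain empirical estimator are available; the
forest mirrors an estimator sometimes used in this literature whose
conditioning set is rarely stated, which is why it is an option rather
than the default.  No simultaneous-coverage correction is applied
across the nine deciles; intervals are pointwise.

## Variance change across age

Whether the variance gap is stable over the lifespan is tested by
regressing the absolute residual \(|r_i|\) — a dispersion response:
\(E|r| = \sigma\sqrt{2/\pi}\) under normality — on an age term, sex,
and their product.  Model order 1 uses age; order 2 uses age² in both
the main and interaction terms (exactly that design, not a full
quadratic polynomial).  Sex is coded male = 1, so a positive sex
coefficient means greater male dispersion and a negative sex-by-age
coefficient means the male excess shrinks with age.  Age is z-scored by
default (raw years via a flag) — reported coefficient magnitudes
therefore refer to SD-of-age units, and recovery is validated by sign
and simulation rather than against any published coefficient table,
whose age scaling is not recoverable.  The residuals fed to this stage
are, by default, adjusted for age as well, so that \(|r|\) measures
spread and an age main effect reflects age-varying dispersion; a flag
reproduces the alternative reading in which age is left in the
measures.  Interaction p-values are FDR-corrected within class and
order.

## Anatomical correlation homogeneity

After sex-specific standardization (each measure centered and scaled to
unit variance within sex, removing all mean and variance sex
differences), Pearson correlation matrices \(M_{ij}\) and \(F_{ij}\)
are computed per sex over pairwise-complete rows and compared edge-wise
through the difference of their Fisher z-transforms.  Permutations
shuffle sex labels over whole subjects, preserving each subject's
cross-region profile — the exchangeability unit under the null of no
sex effect is the subject.  Two-sided p per edge is the proportion of
permuted \(|z|\) at or above the observed value; edges significant at
\(\alpha\) (uncorrected by default, as conventional for these maps; an
FDR flag exists) are counted by direction, and the two directional
counts are compared with a 1-df equal-proportions goodness-of-fit
chi-square, \(\chi^2 = \sum (O - E)^2/E\) with \(E = N/2\).  That
reconstruction — rather than a 2×2 independence test — is the only one
consistent with the reported statistics in this literature (counts
(2, 16) give 10.889; (478, 6) give 460.300), so it is what
`chisq_directional()` implements.  Correlations of exactly ±1 are
clipped to \(1 - 10^{-12}\) before the z-transform.

## The synthetic-cohort generator

Real pooled lifespan data of this kind are restricted, so
`simulate_cohorts()` generates tables with **known ground truth** for
every downstream stage.  Per subject and measure:

\[ y = base_c + f_c(age) + cohort + scanner + \Delta\,1[male]
      + \sigma_c\, s\, \epsilon \]

with a class-level cubic age trajectory, cohort offsets and
field-strength/software shifts drawn once per label and measure
(scanner labels ride on cohorts, reproducing the nesting that stresses
the two-step harmonization), a male mean shift scaled so the population
Cohen's d hits its target, noise correlated across regions with a
sex-specific compound-symmetry matrix (or user-supplied structure), and
a per-subject scale \(s = \exp((\log VR + slope \cdot z_{age})/2)\) for
males versus 1 for females, so the variance ratio equals
\(e^{\log VR}\) at the mean age and drifts with standardized age.
A scaled-t noise option stress-tests the permutation machinery under
heavy tails.

Default conditions were fixed once to emulate the study design this
pipeline targets: 20 cohorts totalling ~8,060 subjects with staggered
age windows inside 1–90 years; 52% female (the sex ratio implied by
reported counts, which disagrees slightly with a rounded abstract
percentage — we follow the counts); class targets d = 0.70 / 0.71 /
0.10 and log VR = 0.22 / 0.25 / 0.06 for volumes / area / thickness,
matching the reported per-class averages and ranges; variance-gap age
slopes −0.10 / −0.08 / 0 per SD of age (the reported interactions are
negative where present — gaps narrow with age); female-stronger
subcortical inter-regional correlation (0.50 vs 0.45) and male-stronger
thickness correlation (0.35 vs 0.30), mirroring the reported
directional asymmetries.  What the generator does **not** emulate:
realistic region-specific covariance estimated from atlases, spatially
heterogeneous effect maps within a class, non-uniform within-cohort age
densities, or outlier/QC-failure contamination.  Passing
parameter-recovery tests therefore demonstrates correctness of the
estimators under the stated generative family, not robustness to every
pathology of real consortium data.

## Numerical choices and problem sizes

* Harrell–Davis needs \(n \ge 10\) per group for deciles; smaller
  groups error with the minimum stated.
* Permutation p-values use tie tolerance \(10^{-9}\) (relative);
  exhaustive enumeration caps at 200,000 assignments.
* Per-measure permutation and bootstrap seeds are derived
  deterministically from the analysis seed plus a stable hash of the
  measure name, so results do not depend on measure order and the whole
  pipeline is bit-reproducible from one master seed (verified by test).
* Monte-Carlo suite sizes are the package's chosen reference scales:
  1,000 null replicates (B = 400 each) for type-I calibration, 200
  replicates at 1,000/sex for power, 100 replicates at 20,000 subjects
  for the age-interaction detection rate, 5,000/sex for
  parameter-recovery bands (±0.05), and 100,000/sex for closed-form
  shift-function checks.  B = 400 gives p-granularity 0.0025, ample for
  calibration at \(\alpha = 0.05\).

## Limitations

The pipeline is cross-sectional: age effects on dispersion are
between-subject statements, not trajectories.  The two-step adjustment
is the classical residualization approach, not an empirical-Bayes site
harmonization (ComBat-style) — deliberately, since the procedure itself
is part of what the package reproduces.  Shift-function CIs are
pointwise.  The directional chi-square conditions on the set of
significant edges; it is a description of asymmetry among detected
differences, not a test free of the selection step.
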
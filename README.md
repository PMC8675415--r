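# brainvar

Mega-analysis of **sex differences in the variability of regional brain
morphometry across the lifespan**: subject-level subcortical volumes,
cortical surface areas and thicknesses (Desikan–Killiany parcellation)
pooled over many imaging cohorts with heterogeneous age coverage.

Most sex-difference studies compare means; brainvar focuses on the
*spread* of the distributions and provides, per measure:

- **Harmonization** — two-step covariate adjustment: OLS on cohort
  indicators plus a cubic in age, then a random-forest regression on
  scanner field strength and segmentation-software version; residuals
  `r_i = y_i − ŷ_i` feed all downstream stages (sex is never adjusted
  out).
- **Mean tests** — Cohen's *d* (pooled SD; *d* > 0 = male larger) with
  Student t-tests and Benjamini–Hochberg FDR within measure class.
- **Variance-ratio tests** — Fisher's
  `T = Var_males / Var_females`, log-transformed, with significance by
  random permutation of sex labels (`p = Σ I(T_b > T)/B`, B = 10,000
  by default; two-sided on |log T| by default), FDR within class, plus
  the correlation of log VR with the *d* vector.
- **Shift functions** — after mean alignment, the decile distance
  `D(q) = Q_m(q) − Q_f(q)` (Harrell–Davis estimator) with stratified
  bootstrap SEs and 95% CIs; a positive slope in *q* is greater male
  spread at both tails.
- **Age interaction** — regression of |r| on age term × sex (linear
  and quadratic age), testing whether the variance gap changes over
  the lifespan.
- **Homogeneity** — sex-specific standardization, male and female
  inter-regional correlation matrices, per-edge Fisher-z differences
  with subject-level permutation, directional counts and a 1-df
  equal-proportions chi-square.
- A **synthetic multi-cohort generator** with known ground truth
  (configurable d, log VR, variance-gap age slope, sex-specific
  correlation structure, cohort/scanner offsets) so every stage is
  testable without restricted consortium data.

Everything is tibble-in / tibble-out with `tidy()` / `glance()`
methods and `autoplot()` figures, and the whole pipeline is
bit-reproducible from one master seed.

## Worked example

```r
library(brainvar)
library(dplyr)

co <- default_cohorts(6); co$n <- 400          # 6 cohorts, 2,400 subjects
cfg <- pipeline_config(
  sim  = sim_config(seed = 1, cohorts = co,
                    catalog = dk_catalog("subcortical_volume")),
  B = 1000, n_boot = 200, seed = 42)
bundle <- run_pipeline(cfg)

glance(bundle$variances)
#>   n_measures n_significant mean_log_vr     B sided alpha
#> 1         14            14       0.239  1000 two    0.05

tidy(bundle$variances) |>
  select(measure_id, n_m, n_f, T, log_vr, p_perm, q) |> head(5)
#>   measure_id           n_m   n_f     T log_vr p_perm       q
#> 1 lh_accumbens_vol    1193  1207  1.28  0.245  0     0
#> 2 lh_amygdala_vol     1193  1207  1.20  0.181  0.001 0.00108
#> 3 lh_caudate_vol      1193  1207  1.27  0.235  0     0
#> 4 lh_hippocampus_vol  1193  1207  1.25  0.226  0     0
#> 5 lh_pallidum_vol     1193  1207  1.24  0.219  0     0

bundle$vr_d
#>   measure_class          r    df     p
#> 1 subcortical_volume 0.301    12 0.296

glance(bundle$homogeneity$subcortical_volume)
#>   n_male_stronger n_female_stronger n_significant n_edges chi2 chi2_df   chi2_p
#> 1               0                24            24      91   24       1  9.63e-7
```

The generator was configured with greater male variance (class log VR
0.22) and female-stronger subcortical correlations, and the run
recovers exactly that: all 14 volumes show FDR-significant greater
male variance (mean log VR 0.239, n ≈ 1,200 per sex), the shift
functions classify 12 of 14 measures as `greater_male_variance`, and
all 24 significant correlation edges are stronger in females
(chi-square(1, N = 24) = 24.0).  `report_markdown(bundle)` renders the
same numbers as a readable per-class report and
`write_pipeline(bundle, dir)` writes the TSV/JSON bundle.

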
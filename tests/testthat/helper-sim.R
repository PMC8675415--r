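# Small simulation setups shared across tests.

# a few subcortical measures only
small_catalog <- function(p = 4) {
  head(dk_catalog("subcortical_volume"), p)
}

# pure-noise generator: no age trend, no cohort/scanner offsets, unit sigma,
# so the generated values ARE the residuals and empirical d / log VR can be
# read off directly.
noise_config <- function(seed, n, p = 2, sex_log_vr = 0, sex_d = 0,
                         vr_age_slope = 0, rho_m = 0, rho_f = 0,
                         female_fraction = 0.5, noise = "gaussian") {
  cohorts <- tibble::tibble(
    cohort_id = "c1", n = n, age_min = 5, age_max = 85,
    female_fraction = female_fraction, field_strength = "3T",
    software_version = "6.0", offset_sd = 0)
  params <- tibble::tibble(
    measure_class = "subcortical_volume", base = 0, b1 = 0, b2 = 0, b3 = 0,
    sigma = 1, sex_d = sex_d, sex_log_vr = sex_log_vr,
    vr_age_slope = vr_age_slope, rho_m = rho_m, rho_f = rho_f,
    missing_rate = 0)
  sim_config(seed = seed, cohorts = cohorts, params = params,
             catalog = small_catalog(p), scanner_sd = 0, noise = noise)
}

# structured generator used in harmonization tests: cohort offsets, cubic
# age trend, scanner effects
structured_config <- function(seed, n_cohorts = 4, n = 200, p = 3, ...) {
  co <- default_cohorts(n_cohorts)
  co$n <- n
  dots <- list(...)
  params <- default_sim_params()[1, ]
  for (nm in names(dots)) params[[nm]] <- dots[[nm]]
  sim_config(seed = seed, cohorts = co, params = params,
             catalog = small_catalog(p))
}

# quick adjustment recipe for tests (small forest keeps runtimes down)
test_recipe <- function(...) {
  adjustment_recipe(n_trees = 100, min_node = 50, rf_seed = 11L, ...)
}

# independent brute-force variance-ratio enumeration oracle
enumerate_vr_p <- function(x, n_m, sided = "two") {
  n <- length(x)
  obs_m <- x[seq_len(n_m)]; obs_f <- x[-seq_len(n_m)]
  T_obs <- var(obs_m) / var(obs_f)
  sets <- combn(n, n_m)
  Tb <- apply(sets, 2, function(id) var(x[id]) / var(x[-id]))
  # same tie tolerance as the implementation (analytic ties, fp noise)
  if (sided == "greater") mean(Tb > T_obs * (1 + 1e-9)) else {
    mean(abs(log(Tb)) >= abs(log(T_obs)) * (1 - 1e-9) - 1e-9)
  }
}
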
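#' Simulation configuration for multi-cohort lifespan morphometry
#'
#' Bundles everything [simulate_cohorts()] needs: a cohort plan (sizes, age
#' windows, sex ratios, scanner labels), per-measure-class generative
#' parameters, and a seed.  Defaults emulate a pooled lifespan mega-analysis:
#' 20 cohorts totalling ~8,000 subjects with heterogeneous age coverage of
#' 1-90 years, 52% female, cohort- and scanner-specific offsets, male-larger
#' mean shifts (Cohen's d about 0.7 for volumes and area, 0.1 for thickness),
#' greater male variance (log variance ratios 0.22 / 0.25 / 0.06), a variance
#' gap that narrows with age for volumes and area, and sex-specific
#' inter-regional correlation.
#'
#' @param seed Integer seed; the generated table is bit-identical for a given
#'   config.
#' @param cohorts Tibble with columns `cohort_id`, `n`, `age_min`, `age_max`,
#'   `female_fraction`, `field_strength`, `software_version`, `offset_sd`
#'   (cohort offset SD as a multiple of the class residual SD).  See
#'   [default_cohorts()].
#' @param params Per-class generative parameters, see [default_sim_params()].
#' @param catalog Region catalog giving the measures to generate.
#' @param scanner_sd SD of additive field-strength and software-version
#'   shifts, as a multiple of the class residual SD.  Scanner labels are
#'   carried by cohorts, so these effects are nested in cohort as in real
#'   multi-site designs.
#' @param noise `"gaussian"` (default) or `"t"` (scaled Student t with
#'   `t_df` degrees of freedom, unit variance) for stress-testing
#'   permutation inference under heavy tails.
#' @param t_df Degrees of freedom for `noise = "t"`; must exceed 2.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       cohorts = default_cohorts(),
                       params = default_sim_params(),
                       catalog = dk_catalog(),
                       scanner_sd = 0.3,
                       noise = c("gaussian", "t"),
                       t_df = 8) {
  noise <- match.arg(noise)
  stopifnot(is.numeric(seed), length(seed) == 1)
  need <- c("cohort_id", "n", "age_min", "age_max", "female_fraction",
            "field_strength", "software_version", "offset_sd")
  if (!all(need %in% names(cohorts))) {
    abort(paste0("`cohorts` must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(cohorts$n < 2)) abort("each cohort needs n >= 2")
  if (any(cohorts$age_max <= cohorts$age_min)) abort("age_max must exceed age_min")
  if (any(cohorts$female_fraction < 0 | cohorts$female_fraction > 1)) {
    abort("female_fraction must be in [0, 1]")
  }
  if (any(params$sigma <= 0)) abort("residual SD `sigma` must be positive")
  if (noise == "t" && t_df <= 2) abort("t_df must exceed 2 for finite variance")
  # compound-symmetry correlation is PSD iff rho >= -1/(p-1); full matrices
  # are checked at generation time when dimensions are known
  structure(list(seed = as.integer(seed), cohorts = cohorts, params = params,
                 catalog = catalog, scanner_sd = scanner_sd, noise = noise,
                 t_df = t_df),
            class = "sim_config")
}

#' @rdname sim_config
#' @param n_cohorts Number of cohorts in the default plan (cycled sizes and
#'   age windows; 20 gives ~8,000 subjects).
#' @export
default_cohorts <- function(n_cohorts = 20) {
  sizes <- rep(c(100L, 150L, 250L, 400L, 600L, 1000L, 300L, 200L, 120L, 910L),
               length.out = n_cohorts)
  starts <- round(seq(1, 65, length.out = n_cohorts))
  widths <- rep(c(10, 15, 25, 60, 89), length.out = n_cohorts)
  tibble::tibble(
    cohort_id = sprintf("cohort%02d", seq_len(n_cohorts)),
    n = sizes,
    age_min = starts,
    age_max = pmin(starts + widths, 90),
    female_fraction = 0.52,
    field_strength = rep(c("1.5T", "3T"), length.out = n_cohorts),
    software_version = rep(c("4.1", "5.1", "5.3", "6.0"), length.out = n_cohorts),
    offset_sd = 0.5
  )
}

#' @rdname sim_config
#' @export
default_sim_params <- function() {
  tibble::tibble(
    measure_class = MEASURE_CLASSES,
    # baseline value and cubic lifespan trajectory on a = age / 100
    base = c(7000, 2500, 2.9),
    b1 = c(8000, 3000, -0.9),
    b2 = c(-12000, -5000, 0.4),
    b3 = c(4000, 1500, 0),
    sigma = c(500, 300, 0.15),
    sex_d = c(0.70, 0.71, 0.10),
    sex_log_vr = c(0.22, 0.25, 0.06),
    vr_age_slope = c(-0.10, -0.08, 0),
    rho_m = c(0.45, 0.50, 0.35),
    rho_f = c(0.50, 0.50, 0.30),
    missing_rate = 0
  )
}

#' Generate a multi-cohort subject table with known ground truth
#'
#' For subject \eqn{i} and measure \eqn{m} of class \eqn{c} the generated
#' value is
#' \deqn{y_{im} = base_c + f_c(age_i) + cohort_{km} + scanner_{im}
#'       + \Delta_m 1[male_i] + \sigma_c s_i \epsilon_{im}}
#' where \eqn{f_c} is the class cubic age trajectory, cohort and scanner
#' offsets are drawn once per cohort/label and measure, the male mean shift
#' \eqn{\Delta_m} is scaled so the population Cohen's d equals the configured
#' `sex_d`, the noise \eqn{\epsilon} is correlated across regions with the
#' sex-specific correlation matrix, and the per-subject scale is
#' \eqn{s_i = \exp((log VR + vr\_age\_slope \cdot z_{age,i}) / 2)} for males
#' and 1 for females, so the male/female variance ratio equals
#' `exp(sex_log_vr)` at the mean age and drifts with standardized age at rate
#' `vr_age_slope`.
#'
#' @param config A [sim_config()].
#' @return A subject-table tibble (same schema as [read_subject_table()])
#'   with attributes `catalog` and `ground_truth`.
#' @seealso [ground_truth()]
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohorts_impl(config))
}

simulate_cohorts_impl <- function(config) {
  ch <- config$cohorts
  n_total <- sum(ch$n)
  age <- numeric(0); sex <- character(0); cohort <- character(0)
  for (k in seq_len(nrow(ch))) {
    age <- c(age, runif(ch$n[k], ch$age_min[k], ch$age_max[k]))
    sex <- c(sex, ifelse(runif(ch$n[k]) < ch$female_fraction[k], "F", "M"))
    cohort <- c(cohort, rep(ch$cohort_id[k], ch$n[k]))
  }
  idx <- match(cohort, ch$cohort_id)
  subjects <- tibble::tibble(
    subject_id = sprintf("sub%06d", seq_len(n_total)),
    cohort = cohort,
    sex = factor(sex, levels = c("M", "F")),
    age = age,
    field_strength = ch$field_strength[idx],
    software_version = ch$software_version[idx]
  )
  z_age <- as.numeric(scale(age))
  male <- sex == "M"

  truth <- list()
  for (cl in unique(config$catalog$measure_class)) {
    pr <- config$params[config$params$measure_class == cl, ]
    if (nrow(pr) != 1) abort(paste0("missing simulation parameters for class ", cl))
    ids <- config$catalog$measure_id[config$catalog$measure_class == cl]
    p <- length(ids)
    Lm <- chol_cs(pr$rho_m, p, cl); Lf <- chol_cs(pr$rho_f, p, cl)
    Z <- noise_matrix(n_total, p, config$noise, config$t_df)
    E <- matrix(0, n_total, p)
    if (any(male)) E[male, ] <- Z[male, , drop = FALSE] %*% Lm
    if (any(!male)) E[!male, ] <- Z[!male, , drop = FALSE] %*% Lf
    # per-subject noise scale: male variance exceeds female by exp(log VR),
    # with the gap drifting along standardized age
    s <- ifelse(male, exp((pr$sex_log_vr + pr$vr_age_slope * z_age) / 2), 1)
    delta <- pr$sex_d * pr$sigma * sqrt((exp(pr$sex_log_vr) + 1) / 2)
    a <- age / 100
    traj <- pr$base + pr$b1 * a + pr$b2 * a^2 + pr$b3 * a^3
    co_off <- matrix(rnorm(nrow(ch) * p, 0, 1), nrow(ch), p) *
      (ch$offset_sd * pr$sigma)
    fs_lev <- unique(ch$field_strength); sv_lev <- unique(ch$software_version)
    fs_off <- matrix(rnorm(length(fs_lev) * p, 0, config$scanner_sd * pr$sigma),
                     length(fs_lev), p)
    sv_off <- matrix(rnorm(length(sv_lev) * p, 0, config$scanner_sd * pr$sigma),
                     length(sv_lev), p)
    Y <- traj + delta * male + pr$sigma * (s * E) +
      co_off[idx, , drop = FALSE] +
      fs_off[match(subjects$field_strength, fs_lev), , drop = FALSE] +
      sv_off[match(subjects$software_version, sv_lev), , drop = FALSE]
    if (pr$missing_rate > 0) {
      Y[matrix(runif(n_total * p) < pr$missing_rate, n_total, p)] <- NA_real_
    }
    colnames(Y) <- ids
    subjects <- dplyr::bind_cols(subjects, tibble::as_tibble(Y))
    truth[[cl]] <- tibble::tibble(
      measure_id = ids, measure_class = cl, sigma = pr$sigma,
      sex_d = pr$sex_d, sex_log_vr = pr$sex_log_vr,
      vr_age_slope = pr$vr_age_slope, rho_m = pr$rho_m, rho_f = pr$rho_f,
      delta = delta
    )
  }
  attr(subjects, "catalog") <- config$catalog
  attr(subjects, "ground_truth") <- list(
    config = config,
    measures = dplyr::bind_rows(truth)
  )
  subjects
}

# Cholesky factor of a compound-symmetry correlation matrix, with PSD check
chol_cs <- function(rho, p, class) {
  if (p == 1) return(matrix(1, 1, 1))
  if (rho >= 1 || rho < -1 / (p - 1)) {
    abort(paste0("compound-symmetry rho = ", rho, " is not positive ",
                 "semi-definite for ", p, " regions (class ", class, ")"))
  }
  R <- matrix(rho, p, p); diag(R) <- 1
  chol(R)
}

noise_matrix <- function(n, p, noise, t_df) {
  if (noise == "gaussian") {
    matrix(rnorm(n * p), n, p)
  } else {
    matrix(rt(n * p, df = t_df) / sqrt(t_df / (t_df - 2)), n, p)
  }
}

#' Ground-truth parameters of a simulated subject table
#'
#' Returns the exact per-measure parameters (Cohen's d, log variance ratio,
#' variance-gap age slope, correlation targets) a table was generated with,
#' enabling parameter-recovery tests.  Errors for tables that were not
#' produced by [simulate_cohorts()].
#'
#' @param data A subject table from [simulate_cohorts()].
#' @return A list with elements `config` (the [sim_config()]) and `measures`
#'   (tibble of per-measure true parameters).
#' @export
ground_truth <- function(data) {
  gt <- attr(data, "ground_truth", exact = TRUE)
  if (is.null(gt)) abort("table carries no simulation metadata; not produced by simulate_cohorts()")
  gt
}
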
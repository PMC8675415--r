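#' Cohen's d and pooled-variance t-test for one measure
#'
#' Effect size of the male-female mean difference on adjusted residuals:
#' `d = (mean_m - mean_f) / pooled SD` with (n-1)-weighted pooling, so a
#' negative d means the female mean is higher.  The t statistic uses the
#' same pooled SD (Student's two-sample test) for internal consistency with
#' d; Welch's test is available via `welch = TRUE`.
#'
#' @param values Numeric vector of per-subject (residualized) values.
#' @param sex Factor/character vector of `"M"`/`"F"` labels, same length.
#' @param welch Use Welch's unequal-variance t statistic instead.
#' @return One-row tibble: `n_m, n_f, mean_m, mean_f, d, t, df, p`.
#' @export
cohens_d <- function(values, sex, welch = FALSE) {
  g <- split_sexes(values, sex)
  n_m <- length(g$m); n_f <- length(g$f)
  if (n_m < 2 || n_f < 2) abort("need at least 2 non-missing values per sex")
  v_m <- var(g$m); v_f <- var(g$f)
  sp2 <- ((n_m - 1) * v_m + (n_f - 1) * v_f) / (n_m + n_f - 2)
  if (sp2 == 0) abort("pooled SD is zero; Cohen's d undefined")
  diff <- mean(g$m) - mean(g$f)
  d <- diff / sqrt(sp2)
  if (welch) {
    se <- sqrt(v_m / n_m + v_f / n_f)
    df <- se^4 / ((v_m / n_m)^2 / (n_m - 1) + (v_f / n_f)^2 / (n_f - 1))
  } else {
    se <- sqrt(sp2 * (1 / n_m + 1 / n_f))
    df <- n_m + n_f - 2
  }
  t <- diff / se
  tibble::tibble(n_m = n_m, n_f = n_f, mean_m = mean(g$m), mean_f = mean(g$f),
                 d = d, t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Male/female variance ratio
#'
#' Fisher's variance ratio `T = var_m / var_f` of the two sexes' residuals
#' (sample variances, n-1 denominator) and its log, which symmetrizes the
#' ratio around 0: positive log VR means greater male variance.
#'
#' @inheritParams cohens_d
#' @return One-row tibble: `n_m, n_f, var_m, var_f, T, log_vr`.
#' @export
variance_ratio <- function(values, sex) {
  g <- split_sexes(values, sex)
  if (length(g$m) < 2 || length(g$f) < 2) abort("need at least 2 non-missing values per sex")
  v_m <- var(g$m); v_f <- var(g$f)
  if (v_f == 0) abort("female variance is zero; variance ratio undefined")
  tibble::tibble(n_m = length(g$m), n_f = length(g$f), var_m = v_m, var_f = v_f,
                 T = v_m / v_f, log_vr = log(v_m) - log(v_f))
}

#' Permutation test of equal male/female variances
#'
#' Recomputes the variance ratio under `B` random permutations of the sex
#' labels among the residuals.  One-sided (`"greater"`): the p-value is the
#' proportion of permuted ratios strictly exceeding the observed one, as in
#' the classical formulation `p = sum(T_b > T) / B`.  Two-sided (default):
#' the proportion of permuted `|log T_b|` at or above the observed
#' `|log T|`.  With `exact = TRUE` (or whenever the number of distinct label
#' assignments is small) all `choose(n, n_m)` assignments are enumerated
#' instead of sampled.
#'
#' @inheritParams cohens_d
#' @param B Number of permutations (default 10,000).
#' @param seed Integer seed for the permutation stream.
#' @param sided `"two"` (on `|log T|`) or `"greater"` (male variance larger).
#' @param exact Enumerate all label assignments exhaustively (only feasible
#'   for small n); the identity assignment is included.
#' @param smooth Add-one smoothing `(count + 1) / (B + 1)` to avoid p = 0.
#' @return One-row tibble: variance-ratio columns plus `p_perm`, `B`,
#'   `sided`, `exact`.
#' @export
permutation_test_vr <- function(values, sex, B = 10000, seed = 1L,
                                sided = c("two", "greater"), exact = FALSE,
                                smooth = FALSE) {
  sided <- match.arg(sided)
  if (B <= 0 && !exact) abort("B must be positive")
  if (B < 100 && !exact) warn("B < 100 permutations gives a very coarse p-value")
  g <- split_sexes(values, sex)
  obs <- variance_ratio(values, sex)
  x <- c(g$m, g$f)
  n <- length(x); n_m <- length(g$m); n_f <- length(g$f)
  sx <- sum(x); sx2 <- sum(x^2)
  ratio_for <- function(id_m) {
    s1 <- sum(x[id_m]); s2 <- sum(x[id_m]^2)
    v_m <- (s2 - s1^2 / n_m) / (n_m - 1)
    v_f <- ((sx2 - s2) - (sx - s1)^2 / n_f) / (n_f - 1)
    v_m / v_f
  }
  if (exact) {
    if (choose(n, n_m) > 2e5) abort("exact enumeration infeasible for this n; use random permutations")
    Tb <- apply(combn(n, n_m), 2, ratio_for)
    B_used <- length(Tb)
  } else {
    Tb <- withr::with_seed(seed, vapply(seq_len(B), function(b) {
      ratio_for(sample.int(n, n_m))
    }, numeric(1)))
    B_used <- B
  }
  # relative tolerance so analytic ties (e.g. label-complement assignments)
  # are resolved consistently despite floating-point noise
  tol <- 1e-9
  count <- if (sided == "greater") {
    sum(Tb > obs$T * (1 + tol))
  } else {
    sum(abs(log(Tb)) >= abs(obs$log_vr) * (1 - tol) - tol)
  }
  p <- if (smooth) (count + 1) / (B_used + 1) else count / B_used
  dplyr::mutate(obs, p_perm = p, B = B_used, sided = sided, exact = exact)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values (monotone) with rejection flags at `alpha`.
#' Computed with `stats::p.adjust(method = "BH")`.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed, propagated).
#' @param alpha FDR level for the rejection flags.
#' @return A tibble with columns `p`, `q`, `reject`.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, reject = !is.na(q) & q <= alpha)
}

#' Correlate variance ratios with mean-difference effect sizes
#'
#' Pearson correlation between a vector of per-measure log variance ratios
#' and the matching Cohen's d values, asking whether regions with larger
#' mean sex differences are also the more variance-discrepant ones.
#'
#' @param log_vr,d Matched numeric vectors (same measures, same order),
#'   length at least 3.
#' @return One-row tibble: `r`, `df` (n - 2), `p` (two-sided).
#' @export
correlate_vr_with_d <- function(log_vr, d) {
  if (length(log_vr) != length(d)) abort("log_vr and d must have equal length")
  if (length(d) < 3) abort("need at least 3 measures")
  ct <- cor.test(log_vr, d, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Per-measure mean-difference tests over a table
#'
#' Runs [cohens_d()] for every measure on pairwise-complete rows and applies
#' FDR correction within each measure class (subcortical volume, cortical
#' area, cortical thickness are reported as separate families).
#'
#' @param data An adjusted table from [adjust()] (any subject-shaped tibble
#'   works; analyses use each measure's non-missing rows).
#' @param measures Measure columns; default all catalog measures present.
#' @param alpha FDR level.
#' @param welch Use Welch's t statistic.
#' @return A tibble of class `brainvar_meantest`, one row per measure:
#'   `measure_id, measure_class, n_m, n_f, mean_m, mean_f, d, t, p, q,
#'   significant`.
#' @export
test_means <- function(data, measures = NULL, alpha = 0.05, welch = FALSE) {
  catalog <- attr(data, "catalog", exact = TRUE) %||% dk_catalog()
  measures <- measures %||% catalog_measures(data, catalog)
  rows <- purrr::map(measures, function(m) {
    ok <- !is.na(data[[m]])
    dplyr::mutate(cohens_d(data[[m]][ok], data$sex[ok], welch = welch),
                  measure_id = m, .before = 1)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(measure_class = measure_class_of(.data$measure_id, catalog),
                  .after = "measure_id") |>
    dplyr::group_by(.data$measure_class) |>
    dplyr::mutate(q = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$q <= alpha)
  new_result(out, "brainvar_meantest", alpha = alpha, welch = welch)
}

#' Per-measure variance-ratio permutation tests over a table
#'
#' Runs [permutation_test_vr()] for every measure with a per-measure seed
#' derived deterministically from `seed`, then FDR-corrects within measure
#' class.
#'
#' @inheritParams test_means
#' @inheritParams permutation_test_vr
#' @return A tibble of class `brainvar_vartest`, one row per measure:
#'   `measure_id, measure_class, n_m, n_f, var_m, var_f, T, log_vr, p_perm,
#'   q, significant`.
#' @export
test_variances <- function(data, measures = NULL, B = 10000, seed = 1L,
                           sided = c("two", "greater"), alpha = 0.05,
                           smooth = FALSE) {
  sided <- match.arg(sided)
  catalog <- attr(data, "catalog", exact = TRUE) %||% dk_catalog()
  measures <- measures %||% catalog_measures(data, catalog)
  rows <- purrr::imap(rlang::set_names(measures), function(m, nm) {
    ok <- !is.na(data[[m]])
    permutation_test_vr(data[[m]][ok], data$sex[ok], B = B,
                        seed = seed + rf_seed_offset(m), sided = sided,
                        smooth = smooth) |>
      dplyr::mutate(measure_id = m, .before = 1)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(measure_class = measure_class_of(.data$measure_id, catalog),
                  .after = "measure_id") |>
    dplyr::group_by(.data$measure_class) |>
    dplyr::mutate(q = p.adjust(.data$p_perm, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$q <= alpha) |>
    dplyr::select(-"exact")
  new_result(out, "brainvar_vartest", alpha = alpha, B = B, seed = seed,
             sided = sided)
}

split_sexes <- function(values, sex) {
  sex <- as.character(sex)
  ok <- !is.na(values) & sex %in% c("M", "F")
  list(m = values[ok & sex == "M"], f = values[ok & sex == "F"])
}

new_result <- function(tbl, class, ...) {
  meta <- list(...)
  for (nm in names(meta)) attr(tbl, nm) <- meta[[nm]]
  class(tbl) <- c(class, "brainvar_result", class(tbl))
  tbl
}
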
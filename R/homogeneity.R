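#' Sex-specific standardization of measures
#'
#' Within each sex, centers and scales every measure to mean 0 and SD 1,
#' removing sex-specific means and standard deviations so that subsequent
#' inter-regional correlation comparisons are not driven by mean or variance
#' sex differences.
#'
#' @param data An adjusted table.
#' @param measures Measure columns; default all catalog measures present.
#' @return The tibble with measure columns standardized within sex.
#' @export
standardize_by_sex <- function(data, measures = NULL) {
  catalog <- attr(data, "catalog", exact = TRUE) %||% dk_catalog()
  measures <- measures %||% catalog_measures(data, catalog)
  for (m in measures) {
    for (s in c("M", "F")) {
      i <- which(data$sex == s & !is.na(data[[m]]))
      if (length(i) < 2 || sd(data[[m]][i]) == 0) {
        abort(paste0("zero or undefined within-sex SD for measure ", m))
      }
      data[[m]][i] <- (data[[m]][i] - mean(data[[m]][i])) / sd(data[[m]][i])
    }
  }
  data
}

sex_correlations <- function(X, male) {
  list(M = cor(X[male, , drop = FALSE], use = "pairwise.complete.obs"),
       F = cor(X[!male, , drop = FALSE], use = "pairwise.complete.obs"))
}

# atanh with clipping at |r| = 1 - 1e-12; the unit diagonal clips silently,
# off-diagonal clipping (a degenerate edge) warns when asked
fisher_z <- function(r, warn_clip = FALSE) {
  clip <- abs(r) >= 1 - 1e-12
  if (is.matrix(clip)) diag(clip) <- FALSE
  if (any(clip, na.rm = TRUE) && warn_clip) {
    warn("correlation(s) at |r| = 1 clipped before Fisher z-transform")
  }
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

#' Male-minus-female anatomical correlation difference
#'
#' Pearson inter-regional correlation matrices are computed for males
#' (`M_ij`) and females (`F_ij`) over pairwise-complete rows, along with
#' their difference `M - F` and the per-edge Fisher-z difference
#' `atanh(M_ij) - atanh(F_ij)`.
#'
#' @param data A sex-standardized table (see [standardize_by_sex()]).
#' @param measures Region measure columns (at least 2).
#' @return List of class `brainvar_corrdiff` with matrices `M`, `F`, `diff`,
#'   `z` and the `measures` used.
#' @export
correlation_difference <- function(data, measures = NULL) {
  catalog <- attr(data, "catalog", exact = TRUE) %||% dk_catalog()
  measures <- measures %||% catalog_measures(data, catalog)
  if (length(measures) < 2) abort("need at least 2 regions")
  male <- data$sex == "M"
  if (sum(male) < 3 || sum(!male) < 3) abort("need at least 3 subjects per sex")
  X <- as.matrix(data[, measures])
  cc <- sex_correlations(X, male)
  structure(list(M = cc$M, F = cc$F, diff = cc$M - cc$F,
                 z = fisher_z(cc$M, warn_clip = TRUE) - fisher_z(cc$F),
                 measures = measures),
            class = "brainvar_corrdiff")
}

#' Permutation test of sex differences in anatomical correlations
#'
#' For each of `B` permutations, sex labels are shuffled over whole subjects
#' (preserving each subject's cross-region profile), both correlation
#' matrices are recomputed and the per-edge Fisher-z difference is formed;
#' the two-sided p-value per edge is the proportion of permuted `|z|` at or
#' above the observed one.  Edges significant at `alpha` are counted by the
#' sign of the observed difference (male-stronger vs female-stronger) and
#' the two directional counts are compared with a 1-df equal-proportions
#' chi-square ([chisq_directional()]).
#'
#' @inheritParams correlation_difference
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @param alpha Per-edge significance level (uncorrected, as is conventional
#'   for these edge maps; apply [fdr_bh()] to `edges$p` for a corrected
#'   variant).
#' @param exact Enumerate all `choose(n, n_m)` sex-label assignments instead
#'   of sampling (small n only).
#' @return An object of class `brainvar_homogeneity`: list with matrices
#'   (`M`, `F`, `diff`, `z`), long-format `edges` tibble
#'   (`region_i, region_j, M, F, diff, z, p, sig, direction`), `counts`
#'   (`n_male_stronger`, `n_female_stronger`, `n_significant`, `n_edges`),
#'   `chisq` tibble, `B`, `alpha`, `seed`.
#' @export
permutation_edge_test <- function(data, measures = NULL, B = 10000,
                                  seed = 1L, alpha = 0.05, exact = FALSE) {
  if (B <= 0 && !exact) abort("B must be positive")
  cd <- correlation_difference(data, measures)
  measures <- cd$measures
  X <- as.matrix(data[, measures])
  male <- data$sex == "M"
  n_m <- sum(male); n <- nrow(X)
  ut <- upper.tri(cd$z)
  z_obs <- abs(cd$z[ut])
  count <- numeric(length(z_obs))
  zdiff_for <- function(pm) {
    cc <- sex_correlations(X, pm)
    abs(fisher_z(cc$M) - fisher_z(cc$F))[ut]
  }
  if (exact) {
    if (choose(n, n_m) > 2e5) abort("exact enumeration infeasible for this n")
    sets <- combn(n, n_m)
    for (b in seq_len(ncol(sets))) {
      pm <- logical(n); pm[sets[, b]] <- TRUE
      count <- count + (zdiff_for(pm) >= z_obs)
    }
    B <- ncol(sets)
  } else {
    withr::with_seed(seed, {
      for (b in seq_len(B)) {
        pm <- logical(n); pm[sample.int(n, n_m)] <- TRUE
        count <- count + (zdiff_for(pm) >= z_obs)
      }
    })
  }
  p <- count / B
  ij <- which(ut, arr.ind = TRUE)
  edges <- tibble::tibble(
    region_i = measures[ij[, 1]], region_j = measures[ij[, 2]],
    M = cd$M[ut], F = cd$F[ut], diff = cd$diff[ut], z = cd$z[ut], p = p,
    sig = p <= alpha,
    direction = dplyr::case_when(
      p <= alpha & cd$diff[ut] > 0 ~ "male_stronger",
      p <= alpha & cd$diff[ut] < 0 ~ "female_stronger",
      .default = "ns"))
  counts <- c(n_male_stronger = sum(edges$direction == "male_stronger"),
              n_female_stronger = sum(edges$direction == "female_stronger"))
  structure(list(M = cd$M, F = cd$F, diff = cd$diff, z = cd$z, edges = edges,
                 counts = tibble::tibble(
                   n_male_stronger = counts[[1]],
                   n_female_stronger = counts[[2]],
                   n_significant = sum(counts),
                   n_edges = n_region_pairs(length(measures))),
                 chisq = chisq_directional(counts[[1]], counts[[2]]),
                 B = B, alpha = alpha, seed = seed),
            class = "brainvar_homogeneity")
}

#' Chi-square test of directional significance counts
#'
#' One-degree-of-freedom goodness-of-fit of the two directional counts
#' (edges significantly stronger in males vs in females) against equal
#' expectation N/2 each: `chi2 = sum((O - E)^2 / E)`.
#'
#' @param n_male_stronger,n_female_stronger Non-negative integer counts.
#' @return One-row tibble `chi2, df, p, n`; with both counts zero the test
#'   is undefined and all values are `NA` (no-test marker).
#' @examples
#' chisq_directional(2, 16)   # chi2 = 10.889
#' chisq_directional(478, 6)  # chi2 = 460.300
#' @export
chisq_directional <- function(n_male_stronger, n_female_stronger) {
  n <- n_male_stronger + n_female_stronger
  if (n < 1) {
    return(tibble::tibble(chi2 = NA_real_, df = NA_integer_, p = NA_real_, n = 0L))
  }
  ct <- suppressWarnings(chisq.test(c(n_male_stronger, n_female_stronger),
                                    p = c(0.5, 0.5)))
  tibble::tibble(chi2 = unname(ct$statistic), df = 1L, p = ct$p.value,
                 n = as.integer(n))
}
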
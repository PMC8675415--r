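#' Adjustment recipe for two-step covariate harmonization
#'
#' Describes the covariates removed before any sex comparison: stage 1 is an
#' ordinary least-squares fit on cohort indicators plus a cubic polynomial in
#' age (age divided by 100 first, to condition the design); stage 2 is a
#' random-forest regression of the stage-1 residuals on scanner field
#' strength and segmentation-software version, catching label effects that
#' interact or act non-linearly.  Sex is deliberately never a covariate, so
#' sex-linked mean and variance structure survives adjustment.
#'
#' @param include_age Remove the (nonlinear) age trend in stage 1?
#' @param age_degree Polynomial degree for age (default cubic).
#' @param include_cohort Remove cohort offsets in stage 1?
#' @param rf_covariates Categorical columns for the stage-2 forest.
#' @param global_cov Optional extra linear stage-1 covariate (e.g. total
#'   brain volume analogue stored in column `global_cov`).
#' @param n_trees,min_node Random-forest size and minimum terminal-node size.
#'   The default large leaves (50) keep the forest from absorbing residual
#'   variance through scanner-label overfitting.
#' @param rf_seed Seed fixing the forest; recorded in the output metadata.
#'
#' @return A list of class `adjustment_recipe`.
#' @export
adjustment_recipe <- function(include_age = TRUE, age_degree = 3,
                              include_cohort = TRUE,
                              rf_covariates = c("field_strength", "software_version"),
                              global_cov = FALSE,
                              n_trees = 500, min_node = 50, rf_seed = 101L) {
  stopifnot(age_degree >= 1)
  structure(list(include_age = include_age, age_degree = age_degree,
                 include_cohort = include_cohort, rf_covariates = rf_covariates,
                 global_cov = global_cov, n_trees = n_trees,
                 min_node = min_node, rf_seed = as.integer(rf_seed)),
            class = "adjustment_recipe")
}

stage1_design <- function(data, recipe) {
  parts <- list(`(Intercept)` = rep(1, nrow(data)))
  if (recipe$include_cohort) {
    lev <- unique(data$cohort)
    if (length(lev) > 1) {
      for (l in lev[-1]) parts[[paste0("cohort", l)]] <- as.numeric(data$cohort == l)
    }
  }
  if (recipe$include_age) {
    a <- data$age / 100
    for (k in seq_len(recipe$age_degree)) parts[[paste0("age", k)]] <- a^k
  }
  if (isTRUE(recipe$global_cov)) {
    if (!"global_cov" %in% names(data)) abort("recipe requests `global_cov` but the table has no such column")
    parts$global_cov <- data$global_cov
  }
  do.call(cbind, parts)
}

#' Stage-1 adjustment: cohort offsets and nonlinear age by OLS
#'
#' Regresses one measure on cohort indicator contrasts and a polynomial in
#' age/100 (plus the optional global covariate) over its non-missing rows and
#' returns the table with that column replaced by the residuals, which are
#' exactly orthogonal to every design column.
#'
#' @param data A subject table.
#' @param measure A single measure column name.
#' @param recipe An [adjustment_recipe()].
#' @return The input tibble with `measure` residualized; the fitted
#'   coefficients are appended to `attr(, "stage1_fits")`.
#' @export
adjust_stage1 <- function(data, measure, recipe = adjustment_recipe()) {
  y <- data[[measure]]
  if (is.null(y)) abort(paste0("no column `", measure, "` in table"))
  ok <- !is.na(y)
  X <- stage1_design(data[ok, , drop = FALSE], recipe)
  if (sum(ok) <= ncol(X)) {
    abort(paste0("measure ", measure, ": ", sum(ok),
                 " non-missing rows cannot identify ", ncol(X), " parameters"))
  }
  fit <- lm.fit(X, y[ok])
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[fit$qr$pivot[(fit$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient stage-1 design for ", measure,
                 "; aliased column(s): ", paste(aliased, collapse = ", ")))
  }
  res <- rep(NA_real_, nrow(data))
  res[ok] <- fit$residuals
  data[[measure]] <- res
  fits <- attr(data, "stage1_fits") %||% list()
  fits[[measure]] <- coef(fit)
  attr(data, "stage1_fits") <- fits
  data
}

#' Stage-2 adjustment: random-forest removal of scanner-label effects
#'
#' Fits a random forest of the stage-1 residuals on the categorical scanner
#' covariates and subtracts its predictions.  Covariates with a single
#' observed level are dropped with a warning; with no usable covariate the
#' residuals pass through unchanged.  Out-of-bag percent variance explained
#' is recorded per measure in `attr(, "stage2_summary")` — when scanner
#' labels are nested in cohort (already removed in stage 1) it is near zero
#' and the stage is effectively a no-op, which is expected.
#'
#' @inheritParams adjust_stage1
#' @return The tibble with `measure` replaced by stage-2 residuals.
#' @export
adjust_stage2 <- function(data, measure, recipe = adjustment_recipe()) {
  covs <- intersect(recipe$rf_covariates, names(data))
  if (length(covs) < length(recipe$rf_covariates)) {
    abort(paste0("rf covariate(s) absent from table: ",
                 paste(setdiff(recipe$rf_covariates, covs), collapse = ", ")))
  }
  y <- data[[measure]]
  ok <- !is.na(y)
  keep <- character(0)
  for (cv in covs) {
    if (length(unique(data[[cv]][ok])) > 1) keep <- c(keep, cv)
    else warn(paste0("covariate `", cv, "` has a single level; dropped from stage 2"))
  }
  summ <- attr(data, "stage2_summary") %||%
    tibble::tibble(measure_id = character(), oob_var_explained = numeric(),
                   covariates = character())
  if (!length(keep) || var(y[ok]) == 0) {
    attr(data, "stage2_summary") <- dplyr::bind_rows(summ, tibble::tibble(
      measure_id = measure, oob_var_explained = NA_real_, covariates = ""))
    if (var(y[ok]) == 0) data[[measure]][ok] <- 0
    return(data)
  }
  X <- as.data.frame(lapply(data[ok, keep, drop = FALSE], factor))
  rf <- withr::with_seed(recipe$rf_seed + rf_seed_offset(measure), {
    randomForest::randomForest(x = X, y = y[ok], ntree = recipe$n_trees,
                               nodesize = recipe$min_node)
  })
  data[[measure]][ok] <- y[ok] - predict(rf, X)
  attr(data, "stage2_summary") <- dplyr::bind_rows(summ, tibble::tibble(
    measure_id = measure,
    oob_var_explained = tail(rf$rsq, 1) * 100,
    covariates = paste(keep, collapse = ",")))
  data
}

# stable per-measure seed offset (order-independent), kept well below 2^31
rf_seed_offset <- function(measure) {
  sum(utf8ToInt(measure) * seq_along(utf8ToInt(measure))) %% 100000L
}

#' Two-step covariate harmonization of a subject table
#'
#' Applies [adjust_stage1()] then [adjust_stage2()] to each requested
#' measure, returning a table of residuals aligned row-for-row with the
#' input.  All downstream sex comparisons (means, variance ratios, shift
#' functions, anatomical correlations) operate on this output.
#'
#' @param data A subject table ([read_subject_table()] or
#'   [simulate_cohorts()]).
#' @param measures Measure columns to adjust; default all catalog measures
#'   present in the table.
#' @param recipe An [adjustment_recipe()].
#' @return A tibble of class `brainvar_adjusted`: covariate columns
#'   unchanged, measure columns replaced by residuals (mean ~ 0).
#'   Attributes: `recipe`, `stage1_fits`, `stage2_summary`, plus `catalog`
#'   and `ground_truth` carried over when present.
#' @export
adjust <- function(data, measures = NULL, recipe = adjustment_recipe()) {
  catalog <- attr(data, "catalog", exact = TRUE) %||% dk_catalog()
  measures <- measures %||% catalog_measures(data, catalog)
  out <- data
  for (m in measures) {
    out <- adjust_stage1(out, m, recipe)
    out <- adjust_stage2(out, m, recipe)
  }
  attr(out, "recipe") <- recipe
  attr(out, "measures") <- measures
  class(out) <- c("brainvar_adjusted", class(data))
  out
}
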
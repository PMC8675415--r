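#' Absolute residuals of one measure
#'
#' The absolute value of a subject's adjusted residual is the dispersion
#' response used to model variance change: for mean-zero residuals,
#' `E|r| = sigma * sqrt(2/pi)` under normality, so regression of `|r|` on
#' age and sex captures how the spread varies across age and between sexes.
#'
#' @param data An adjusted table.
#' @param measure Measure column name.
#' @return Tibble `subject_id, cohort, sex, age, abs_resid` (rows with
#'   missing residuals dropped; pairing with age/sex preserved).
#' @export
absolute_residuals <- function(data, measure) {
  if (!measure %in% names(data)) abort(paste0("no column `", measure, "`"))
  out <- tibble::tibble(subject_id = data$subject_id, cohort = data$cohort,
                        sex = data$sex, age = data$age,
                        abs_resid = abs(data[[measure]]))
  out[!is.na(out$abs_resid), ]
}

#' Fit an age-by-sex dispersion interaction model
#'
#' OLS of the absolute residual on an age term, sex, and their interaction:
#' model order 1 uses age, order 2 uses age squared (the age term enters both
#' the main effect and the interaction exactly as given, not as a full
#' quadratic polynomial).  Sex is coded male = 1, female = 0, so a positive
#' sex coefficient means greater male dispersion and a negative interaction
#' means the male excess dispersion shrinks as the age term grows.  Age is
#' standardized (z-scored over the analysed subjects) by default before the
#' power is taken; `scale_age = "raw"` fits on raw years.
#'
#' @param abs_resid Numeric vector of absolute residuals.
#' @param age,sex Covariates aligned with `abs_resid`.
#' @param order 1 (linear age) or 2 (quadratic age).
#' @param scale_age `"z"` (default) or `"raw"`.
#' @return A tibble with one row per term (`intercept`, `age_term`, `sex`,
#'   `sex_age`): `estimate, se, t, p`, plus columns `order` and `scale_age`.
#' @export
fit_interaction <- function(abs_resid, age, sex, order = 1,
                            scale_age = c("z", "raw")) {
  scale_age <- match.arg(scale_age)
  if (!order %in% 1:2) abort("order must be 1 or 2")
  ok <- !is.na(abs_resid) & !is.na(age) & !is.na(sex)
  if (sum(ok) < 10) abort("need at least 10 subjects")
  y <- abs_resid[ok]; a <- age[ok]; s <- as.numeric(as.character(sex[ok]) == "M")
  if (length(unique(s)) < 2) abort("both sexes must be present")
  if (sd(a) == 0) abort("age is constant; interaction model unidentified")
  if (scale_age == "z") a <- (a - mean(a)) / sd(a)
  at <- a^order
  X <- cbind(intercept = 1, age_term = at, sex = s, sex_age = at * s)
  fit <- lm.fit(X, y)
  rdf <- length(y) - fit$rank
  sigma2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  est <- fit$coefficients
  tv <- est / se
  tibble::tibble(term = colnames(X), estimate = unname(est), se = unname(se),
                 t = unname(tv), p = unname(2 * pt(-abs(tv), rdf)),
                 order = order, scale_age = scale_age)
}

#' Age-by-sex dispersion tests over a table
#'
#' For each measure and requested model order, regresses the absolute
#' residual on age term x sex and FDR-corrects the interaction p-values
#' within measure class and order.
#'
#' @param data An adjusted table.  The default residual recipe for this
#'   analysis also removes the nonlinear age trend, so `|r|` measures
#'   dispersion and an age main effect on `|r|` reflects age-varying spread;
#'   adjust with `include_age = FALSE` upstream to reproduce the reading in
#'   which age is left in the measures themselves.
#' @param measures Measure columns; default all catalog measures present.
#' @param orders Model orders to fit (subset of `c(1, 2)`).
#' @param alpha FDR level for the interaction term.
#' @param scale_age Passed to [fit_interaction()].
#' @return A tibble of class `brainvar_ageint`, one row per measure x order:
#'   coefficient estimates/SEs/p-values in wide form plus `p_interaction`,
#'   `q_interaction`, `significant`.
#' @export
test_age_interaction <- function(data, measures = NULL, orders = c(1, 2),
                                 alpha = 0.05, scale_age = "z") {
  catalog <- attr(data, "catalog", exact = TRUE) %||% dk_catalog()
  measures <- measures %||% catalog_measures(data, catalog)
  rows <- purrr::map(measures, function(m) {
    ar <- absolute_residuals(data, m)
    purrr::map(orders, function(o) {
      ct <- fit_interaction(ar$abs_resid, ar$age, ar$sex, order = o,
                            scale_age = scale_age)
      wide <- tidyr::pivot_wider(
        dplyr::select(ct, "term", "estimate", "se", "p"),
        names_from = "term",
        values_from = c("estimate", "se", "p"), names_sep = "_")
      dplyr::mutate(wide, measure_id = m, order = o, .before = 1)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(measure_class = measure_class_of(.data$measure_id, catalog),
                  .after = "measure_id") |>
    dplyr::rename(p_interaction = "p_sex_age") |>
    dplyr::group_by(.data$measure_class, .data$order) |>
    dplyr::mutate(q_interaction = p.adjust(.data$p_interaction, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$q_interaction <= alpha)
  new_result(out, "brainvar_ageint", alpha = alpha, scale_age = scale_age,
             sex_coding = "male=1, female=0")
}
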
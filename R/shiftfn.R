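#' Center two groups to a common (zero) mean
#'
#' Mean alignment applied before quantile comparison, so the shift function
#' reflects differences in spread and shape rather than in location.
#'
#' @param male,female Numeric vectors (missing values dropped).
#' @return List with centered `male`, `female` and the original `means`.
#' @export
align_means <- function(male, female) {
  male <- male[!is.na(male)]; female <- female[!is.na(female)]
  if (!length(male) || !length(female)) abort("both groups must be non-empty")
  means <- c(male = mean(male), female = mean(female))
  list(male = male - means["male"], female = female - means["female"],
       means = means)
}

# Harrell-Davis weights: column q holds Beta((n+1)p, (n+1)(1-p)) mass over
# the n order-statistic cells; the estimate is w'sort(x).  Computing the
# matrix once lets bootstrap replicates reuse it (all resamples share n).
hd_weights <- function(n, probs) {
  W <- vapply(probs, function(p) {
    a <- (n + 1) * p; b <- (n + 1) * (1 - p)
    diff(pbeta(seq(0, 1, length.out = n + 1), a, b))
  }, numeric(n))
  matrix(W, nrow = n)
}

#' Estimate quantiles of one group
#'
#' Three estimators: `"harrell_davis"` (default; a smooth L-estimator,
#' Beta-weighted average of all order statistics), `"empirical"`
#' (`stats::quantile` type 8), and `"forest"` (a quantile regression forest
#' with age as the conditioning variable; leaf-pooled conditional quantiles
#' averaged over the observed age distribution).  Output is forced
#' non-decreasing by sorting.
#'
#' @param values Numeric vector (missing dropped).
#' @param probs Probabilities strictly inside (0, 1); default deciles.
#' @param estimator One of `"harrell_davis"`, `"empirical"`, `"forest"`.
#' @param age Numeric vector aligned with `values`; required for `"forest"`.
#' @param n_trees Forest size for `estimator = "forest"`.
#' @param seed Seed for the forest.
#' @return Numeric vector of quantiles, one per probability.
#' @export
estimate_quantiles <- function(values, probs = seq(0.1, 0.9, by = 0.1),
                               estimator = c("harrell_davis", "empirical", "forest"),
                               age = NULL, n_trees = 200, seed = 1L) {
  estimator <- match.arg(estimator)
  if (any(probs <= 0 | probs >= 1)) abort("probabilities must lie strictly in (0, 1)")
  keep <- !is.na(values)
  x <- values[keep]
  if (length(x) < 10 && estimator != "empirical") {
    abort("need at least 10 observations for smooth decile estimation")
  }
  q <- switch(estimator,
    harrell_davis = as.numeric(crossprod(hd_weights(length(x), probs), sort(x))),
    empirical = unname(quantile(x, probs, type = 8)),
    forest = {
      if (is.null(age)) abort("estimator = \"forest\" needs `age`")
      df <- data.frame(y = x, age = age[keep])
      # large leaves stabilize the pooled tail quantiles
      rf <- ranger::ranger(y ~ age, data = df, num.trees = n_trees,
                           quantreg = TRUE, seed = seed,
                           min.node.size = max(50, ceiling(0.1 * nrow(df))))
      pred <- predict(rf, df, type = "quantiles", quantiles = probs)$predictions
      colMeans(pred)
    })
  sort(q)
}

#' Shift function: decile distance between the sexes
#'
#' After aligning the two distributions' means, estimates the deciles
#' `Q_m(q)` and `Q_f(q)` of the male and female residuals and their
#' difference `D(q) = Q_m(q) - Q_f(q)`.  A stratified bootstrap (resampling
#' within sex) gives a standard error per decile and normal-approximation
#' 95% confidence intervals `D +- 1.96 SE`.  A flat D indicates a uniform
#' shift (no variability difference); a positive slope in q — negative D in
#' the lower tail and/or positive D in the upper tail, with CIs excluding
#' zero — indicates greater male spread; the reverse indicates greater
#' female spread.
#'
#' @param male,female Numeric vectors of adjusted residuals for one measure.
#' @param probs Probabilities at which to compare (default deciles 0.1-0.9).
#' @param n_boot Bootstrap replicates for the standard errors.
#' @param seed Integer seed for the bootstrap stream.
#' @param estimator Quantile estimator, see [estimate_quantiles()].
#' @param age_m,age_f Ages aligned with `male`/`female` (forest estimator
#'   only).
#' @param ci `"normal"` (D +- 1.96 SE, default) or `"percentile"` bootstrap
#'   intervals.
#' @return An object of class `brainvar_shift`: list with `table` (tibble
#'   `q, Q_m, Q_f, D, se, lo, hi, sig`), `classification` (one of
#'   `greater_male_variance`, `greater_female_variance`, `parallel`),
#'   `n_m`, `n_f`, `n_boot`, `seed`, `estimator`, `means`.
#' @export
shift_function <- function(male, female, probs = seq(0.1, 0.9, by = 0.1),
                           n_boot = 1000, seed = 1L,
                           estimator = c("harrell_davis", "empirical", "forest"),
                           age_m = NULL, age_f = NULL,
                           ci = c("normal", "percentile")) {
  estimator <- match.arg(estimator); ci <- match.arg(ci)
  al <- align_means(male, female)
  m <- al$male; f <- al$female
  min_n <- ceiling(1 / min(c(probs, 1 - probs)) - 1e-9)
  if (length(m) < min_n || length(f) < min_n) {
    abort(paste0("need at least ", min_n, " observations per sex for these quantiles"))
  }
  est <- function(x, age = NULL) {
    estimate_quantiles(x, probs, estimator, age = age, seed = seed)
  }
  Qm <- est(m, age_m); Qf <- est(f, age_f)
  D <- Qm - Qf
  boot <- withr::with_seed(seed, {
    Wm <- if (estimator == "harrell_davis") hd_weights(length(m), probs)
    Wf <- if (estimator == "harrell_davis") hd_weights(length(f), probs)
    vapply(seq_len(n_boot), function(b) {
      im <- sample.int(length(m), replace = TRUE)
      fi <- sample.int(length(f), replace = TRUE)
      qm <- if (estimator == "harrell_davis") {
        sort(as.numeric(crossprod(Wm, sort(m[im]))))
      } else est(m[im], age_m[im])
      qf <- if (estimator == "harrell_davis") {
        sort(as.numeric(crossprod(Wf, sort(f[fi]))))
      } else est(f[fi], age_f[fi])
      qm - qf
    }, numeric(length(probs)))
  })
  se <- apply(boot, 1, sd)
  if (ci == "normal") {
    lo <- D - 1.96 * se; hi <- D + 1.96 * se
  } else {
    lo <- apply(boot, 1, quantile, 0.025); hi <- apply(boot, 1, quantile, 0.975)
  }
  tbl <- tibble::tibble(q = probs, Q_m = Qm, Q_f = Qf, D = D, se = se,
                        lo = lo, hi = hi, sig = lo > 0 | hi < 0)
  structure(list(table = tbl, classification = classify_shift(tbl),
                 n_m = length(m), n_f = length(f), n_boot = n_boot,
                 seed = seed, estimator = estimator, ci = ci,
                 means = al$means),
            class = "brainvar_shift")
}

# sign pattern of significant decile differences -> slope direction
classify_shift <- function(tbl) {
  lower <- tbl$q < 0.5; upper <- tbl$q > 0.5
  male_evi <- sum(tbl$sig & ((lower & tbl$D < 0) | (upper & tbl$D > 0)))
  female_evi <- sum(tbl$sig & ((lower & tbl$D > 0) | (upper & tbl$D < 0)))
  if (male_evi > 0 && female_evi == 0) "greater_male_variance"
  else if (female_evi > 0 && male_evi == 0) "greater_female_variance"
  else "parallel"
}

#' Shift functions for a set of measures
#'
#' Applies [shift_function()] to each requested measure of an adjusted
#' table.  By default (mirroring the analysis sequence) callers pass the
#' FDR-significant measures from [test_variances()]; any measure is
#' accepted.
#'
#' @param data An adjusted table.
#' @param measures Measure columns to analyse.
#' @inheritParams shift_function
#' @return A tibble of class `brainvar_shiftset`: one row per measure and
#'   decile (`measure_id, q, Q_m, Q_f, D, se, lo, hi, sig, classification`).
#' @export
shift_functions <- function(data, measures, probs = seq(0.1, 0.9, by = 0.1),
                            n_boot = 1000, seed = 1L,
                            estimator = "harrell_davis") {
  rows <- purrr::map(measures, function(m) {
    ok <- !is.na(data[[m]])
    sf <- shift_function(data[[m]][ok & data$sex == "M"],
                         data[[m]][ok & data$sex == "F"],
                         probs = probs, n_boot = n_boot,
                         seed = seed + rf_seed_offset(m), estimator = estimator,
                         age_m = data$age[ok & data$sex == "M"],
                         age_f = data$age[ok & data$sex == "F"])
    dplyr::mutate(sf$table, measure_id = m, classification = sf$classification,
                  .before = 1)
  })
  new_result(dplyr::bind_rows(rows), "brainvar_shiftset", n_boot = n_boot,
             seed = seed, estimator = estimator)
}
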
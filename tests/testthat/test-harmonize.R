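make_deterministic_table <- function(n = 120, with_age_trend = TRUE) {
  # pure cohort offsets + noise-free cubic age trend, two cohorts
  age <- seq(2, 88, length.out = n)
  cohort <- rep(c("a", "b"), length.out = n)
  a <- age / 100
  y <- ifelse(cohort == "a", 10, -5) +
    if (with_age_trend) 3 * a - 7 * a^2 + 2 * a^3 else 0
  tb <- tibble::tibble(
    subject_id = paste0("s", seq_len(n)), cohort = cohort,
    sex = factor(rep(c("M", "F"), each = n / 2), c("M", "F")), age = age,
    field_strength = rep(c("1.5T", "3T"), length.out = n),
    software_version = "6.0", lh_thalamus_vol = y)
  attr(tb, "catalog") <- small_catalog(14)
  tb
}

test_that("stage 1 fits noise-free cohort plus cubic-age data exactly", {
  tb <- make_deterministic_table()
  adj <- adjust_stage1(tb, "lh_thalamus_vol", test_recipe())
  expect_lt(max(abs(adj$lh_thalamus_vol)), 1e-8)
})

test_that("omitting age from the recipe leaves the age trend in residuals", {
  tb <- make_deterministic_table()
  adj <- adjust_stage1(tb, "lh_thalamus_vol", test_recipe(include_age = FALSE))
  expect_gt(abs(cor(adj$lh_thalamus_vol, tb$age)), 0.5)
})

test_that("stage-1 residuals are orthogonal to every design column", {
  tb <- simulate_cohorts(structured_config(seed = 21, n = 300, p = 2))
  rec <- test_recipe()
  for (m in names(tb)[7:8]) {
    adj <- adjust_stage1(tb, m, rec)
    r <- adj[[m]]
    # direct projection oracle: reconstruct the design and check X'r = 0
    a <- tb$age / 100
    X <- cbind(1, outer(tb$cohort, unique(tb$cohort)[-1], "==") * 1,
               a, a^2, a^3)
    expect_lt(max(abs(crossprod(X, r))) / sd(r) / nrow(X), 1e-8)
    # per-cohort residual means vanish (OLS orthogonality)
    expect_lt(max(abs(tapply(r, tb$cohort, mean))), 1e-9 * sd(r))
  }
})

test_that("stage 2 is a near no-op without scanner effects", {
  cfg <- structured_config(seed = 22, n_cohorts = 4, n = 500, p = 1)
  cfg$scanner_sd <- 0
  tb <- simulate_cohorts(cfg)
  m <- names(tb)[7]
  s1 <- adjust_stage1(tb, m, test_recipe())
  s2 <- adjust_stage2(s1, m, test_recipe())
  expect_gt(cor(s1[[m]], s2[[m]]), 0.95)
})

test_that("stage 2 removes an additive software-version shift", {
  n <- 2000
  set.seed(31)
  sv <- sample(c("5.3", "6.0"), n, replace = TRUE)
  tb <- tibble::tibble(
    subject_id = paste0("s", seq_len(n)),
    cohort = sample(c("a", "b"), n, replace = TRUE),
    sex = factor(sample(c("M", "F"), n, TRUE), c("M", "F")),
    age = runif(n, 5, 85),
    field_strength = "3T", software_version = sv,
    lh_thalamus_vol = rnorm(n, sd = 1) + 10 * (sv == "6.0"))
  attr(tb, "catalog") <- small_catalog(14)
  # cohort labels are independent of version here, so stage 1 leaves the
  # shift in place and stage 2 must remove it
  s1 <- adjust_stage1(tb, "lh_thalamus_vol",
                      test_recipe(include_age = FALSE, include_cohort = FALSE))
  expect_gt(abs(diff(tapply(s1$lh_thalamus_vol, sv, mean))), 5)
  # field_strength is constant here; its expected drop warning is noise
  s2 <- suppressWarnings(adjust_stage2(s1, "lh_thalamus_vol", test_recipe()))
  means <- tapply(s2$lh_thalamus_vol, sv, mean)
  expect_true(all(abs(means) < 0.5))
})

test_that("constant residuals pass stage 2 as zero", {
  tb <- make_deterministic_table(with_age_trend = FALSE)
  tb$lh_thalamus_vol <- 4
  s1 <- adjust_stage1(tb, "lh_thalamus_vol", test_recipe(include_age = FALSE))
  s2 <- suppressWarnings(adjust_stage2(s1, "lh_thalamus_vol", test_recipe()))
  expect_true(all(abs(s2$lh_thalamus_vol) < 1e-8))
})

test_that("single-level scanner covariates are dropped with a warning, not an error", {
  tb <- make_deterministic_table()
  tb$software_version <- "6.0"
  tb$lh_thalamus_vol <- tb$lh_thalamus_vol + rnorm(nrow(tb))
  s1 <- adjust_stage1(tb, "lh_thalamus_vol", test_recipe())
  expect_warning(adjust_stage2(s1, "lh_thalamus_vol", test_recipe()),
                 "software_version")
})

test_that("rank-deficient designs fail naming the offending column", {
  tb <- make_deterministic_table()
  tb$global_cov <- tb$age / 100  # collinear with the linear age term
  expect_error(adjust_stage1(tb, "lh_thalamus_vol",
                             test_recipe(global_cov = TRUE)),
               "global_cov|age")
})

test_that("full adjustment removes covariate-explained variance and is deterministic", {
  tb <- simulate_cohorts(structured_config(seed = 23, n_cohorts = 4, n = 300, p = 2))
  rec <- test_recipe()
  adj1 <- adjust(tb, recipe = rec)
  adj2 <- adjust(tb, recipe = rec)
  ms <- names(tb)[7:8]
  expect_identical(adj1[ms], adj2[ms])
  r2 <- function(y, tb) summary(stats::lm(
    y ~ cohort + poly(age, 3) + field_strength + software_version,
    data = tb))$r.squared
  for (m in ms) {
    expect_lt(r2(adj1[[m]], tb), r2(tb[[m]], tb))
    expect_lt(r2(adj1[[m]], tb), 0.05)
  }
  # residuals no longer project onto the cubic age design
  expect_lt(abs(cor(adj1[[ms[1]]], tb$age)), 0.05)
})

test_that("adjusting an empty measure list returns the table untouched", {
  tb <- make_deterministic_table()
  adj <- adjust(tb, measures = character(0), recipe = test_recipe())
  expect_equal(adj$lh_thalamus_vol, tb$lh_thalamus_vol)
})

test_that("missing values propagate and row alignment is preserved", {
  tb <- simulate_cohorts(structured_config(seed = 24, n = 150, p = 1))
  m <- names(tb)[7]
  tb[[m]][c(3, 77)] <- NA
  adj <- adjust(tb, m, test_recipe())
  expect_true(all(is.na(adj[[m]][c(3, 77)])))
  expect_equal(sum(is.na(adj[[m]])), 2)
  expect_identical(adj$subject_id, tb$subject_id)
})
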
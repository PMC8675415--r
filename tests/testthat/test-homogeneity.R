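test_that("sex-specific standardization removes sex means and variances exactly", {
  tb <- simulate_cohorts(noise_config(seed = 401, n = 400, p = 3,
                                      sex_log_vr = 0.4, sex_d = 0.6))
  std <- standardize_by_sex(tb)
  for (m in names(tb)[7:9]) {
    for (s in c("M", "F")) {
      expect_lt(abs(mean(std[[m]][std$sex == s])), 1e-12)
      expect_equal(sd(std[[m]][std$sex == s]), 1, tolerance = 1e-12)
    }
    # configured d and log VR are gone after standardization
    expect_lt(abs(cohens_d(std[[m]], std$sex)$d), 1e-12)
    expect_lt(abs(variance_ratio(std[[m]], std$sex)$log_vr), 1e-12)
  }
  # idempotence
  std2 <- standardize_by_sex(std)
  expect_equal(std2[7:9], std[7:9], tolerance = 1e-12)

  tb$lh_accumbens_vol[tb$sex == "M"] <- 1
  expect_error(standardize_by_sex(tb), "lh_accumbens_vol")
})

test_that("identical sex distributions give a zero difference matrix", {
  set.seed(402)
  X <- matrix(rnorm(60), 20, 3)
  tb <- tibble::tibble(subject_id = paste0("s", 1:40), cohort = "c",
                       sex = factor(rep(c("M", "F"), each = 20), c("M", "F")),
                       age = runif(40), field_strength = "3T",
                       software_version = "6.0")
  ms <- small_catalog(3)$measure_id
  for (j in 1:3) tb[[ms[j]]] <- c(X[, j], X[, j])
  attr(tb, "catalog") <- small_catalog(3)
  cd <- correlation_difference(tb)
  expect_true(all(abs(cd$diff) < 1e-12))
  expect_true(all(abs(cd$z) < 1e-6))
  expect_equal(unname(diag(cd$diff)), rep(0, 3))
  expect_true(isSymmetric(cd$diff))

  # locality: perturbing one region only changes its row/column
  tb2 <- tb
  tb2[[ms[2]]][tb2$sex == "M"] <- sample(X[, 2])
  cd2 <- correlation_difference(tb2)
  expect_true(all(abs(cd2$diff[c(1, 3), c(1, 3)]) < 1e-12))
  expect_gt(max(abs(cd2$diff[2, -2])), 0)
})

test_that("a configured correlation difference is recovered from large samples", {
  cfg <- noise_config(seed = 403, n = 10000, p = 4, rho_m = 0.5, rho_f = 0.3)
  tb <- standardize_by_sex(simulate_cohorts(cfg))
  cd <- correlation_difference(tb)
  off <- cd$diff[upper.tri(cd$diff)]
  expect_true(all(abs(off - 0.2) < 0.05))
})

test_that("edge permutation p equals exhaustive enumeration for tiny samples", {
  set.seed(404)
  tb <- tibble::tibble(subject_id = paste0("s", 1:8), cohort = "c",
                       sex = factor(rep(c("M", "F"), each = 4), c("M", "F")),
                       age = runif(8), field_strength = "3T",
                       software_version = "6.0")
  ms <- small_catalog(3)$measure_id
  for (m in ms) tb[[m]] <- rnorm(8)
  attr(tb, "catalog") <- small_catalog(3)

  res <- permutation_edge_test(tb, B = 1, exact = TRUE)
  expect_equal(res$B, choose(8, 4))

  # independent brute force over all 70 assignments
  X <- as.matrix(tb[, ms])
  zd <- function(male) {
    zc <- function(r) atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
    (zc(cor(X[male, ])) - zc(cor(X[!male, ])))[upper.tri(diag(3))]
  }
  obs <- abs(zd(tb$sex == "M"))
  sets <- combn(8, 4)
  counts <- rowSums(apply(sets, 2, function(id) {
    male <- seq_len(8) %in% id
    abs(zd(male)) >= obs
  }))
  expect_equal(res$edges$p, counts / ncol(sets))
})

test_that("directional chi-square reproduces its closed form", {
  a <- chisq_directional(2, 16)
  expect_equal(a$chi2, 10.889, tolerance = 1e-3)
  expect_lt(a$p, 0.001)
  expect_equal(a$n, 18L)

  b <- chisq_directional(478, 6)
  expect_equal(b$chi2, 460.300, tolerance = 1e-2)
  expect_lt(b$p, 0.001)

  eq <- chisq_directional(7, 7)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)

  none <- chisq_directional(0, 0)
  expect_true(is.na(none$chi2))
  expect_equal(none$n, 0L)
})

test_that("sex swap negates the difference matrices and keeps the chi-square", {
  tb <- simulate_cohorts(noise_config(seed = 405, n = 300, p = 3,
                                      rho_m = 0.6, rho_f = 0.2))
  tb <- standardize_by_sex(tb)
  sw <- tb
  sw$sex <- factor(ifelse(tb$sex == "M", "F", "M"), c("M", "F"))
  a <- correlation_difference(tb); b <- correlation_difference(sw)
  expect_equal(b$diff, -a$diff, tolerance = 1e-12)
  expect_equal(b$z, -a$z, tolerance = 1e-12)
  ra <- permutation_edge_test(tb, B = 200, seed = 9)
  rb <- permutation_edge_test(sw, B = 200, seed = 9)
  expect_equal(rb$counts$n_male_stronger, ra$counts$n_female_stronger)
  expect_equal(rb$chisq$chi2, ra$chisq$chi2)
})

test_that("directional counts concentrate on the configured side and bookkeeping holds", {
  cfg <- noise_config(seed = 406, n = 4000, p = 4, rho_m = 0.55, rho_f = 0.25)
  tb <- standardize_by_sex(simulate_cohorts(cfg))
  res <- permutation_edge_test(tb, B = 500, seed = 10)
  expect_equal(res$counts$n_edges, n_region_pairs(4))
  expect_equal(res$counts$n_significant,
               res$counts$n_male_stronger + res$counts$n_female_stronger)
  expect_lte(res$counts$n_significant, res$counts$n_edges)
  expect_gt(res$counts$n_male_stronger, res$counts$n_female_stronger)
  expect_equal(sum(res$edges$sig), res$counts$n_significant)
})
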
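test_that("cohens_d matches its definition and the pooled t-test", {
  # identical groups: null identity
  x <- c(rnorm(20, sd = 2))
  row <- cohens_d(c(x, x), rep(c("M", "F"), each = 20))
  expect_equal(row$d, 0)
  expect_equal(row$p, 1)

  # means differ by 1 with pooled SD 1: d = 1 by construction
  f <- c(-1, 1) / sqrt(2)
  m <- f + 1
  expect_equal(cohens_d(c(m, f), rep(c("M", "F"), each = 2))$d, 1)

  # sign convention: negative d when the female mean is higher
  expect_lt(cohens_d(c(f, m), rep(c("M", "F"), each = 2))$d, 0)

  # independent oracle: stats::t.test with var.equal = TRUE
  set.seed(101)
  v <- rnorm(200); s <- rep(c("M", "F"), 100)
  row <- cohens_d(v, s)
  tt <- t.test(v[s == "M"], v[s == "F"], var.equal = TRUE)
  expect_equal(row$t, unname(tt$statistic))
  expect_equal(row$p, tt$p.value)

  # large-sample recovery of a known standardized mean difference
  set.seed(102)
  vals <- c(rnorm(10000, 0.5), rnorm(10000, 0))
  sex <- rep(c("M", "F"), each = 10000)
  expect_lt(abs(cohens_d(vals, sex)$d - 0.5), 0.05)

  expect_error(cohens_d(rep(1, 10), rep(c("M", "F"), 5)), "pooled SD")
})

test_that("variance_ratio follows the scaling law and closed forms", {
  f <- rnorm(50)
  vr <- variance_ratio(c(2 * f, f), rep(c("M", "F"), each = 50))
  expect_equal(vr$T, 4)
  expect_equal(vr$log_vr, log(4))

  vr0 <- variance_ratio(c(f, f), rep(c("M", "F"), each = 50))
  expect_equal(vr0$T, 1)
  expect_equal(vr0$log_vr, 0)

  set.seed(103)
  vals <- c(rnorm(100000, sd = 1.2), rnorm(100000, sd = 1))
  sex <- rep(c("M", "F"), each = 100000)
  expect_lt(abs(variance_ratio(vals, sex)$log_vr - 2 * log(1.2)), 0.02)

  expect_error(variance_ratio(c(f, rep(0, 50)), rep(c("M", "F"), each = 50)),
               "female variance")
})

test_that("variance ratio is scale-equivariant in the male deviations", {
  set.seed(104)
  vals <- rnorm(80); sex <- rep(c("M", "F"), 40)
  base <- variance_ratio(vals, sex)
  for (c_ in c(0.5, 3)) {
    scaled <- vals
    i <- sex == "M"
    scaled[i] <- mean(vals[i]) + c_ * (vals[i] - mean(vals[i]))
    vr <- variance_ratio(scaled, sex)
    expect_equal(vr$T, base$T * c_^2)
    expect_equal(vr$log_vr, base$log_vr + 2 * log(c_))
  }
})

test_that("permutation p equals exhaustive enumeration for small n", {
  set.seed(105)
  x <- c(2.3, -1.1, 0.4, 5.0, -0.2, 1.7)
  sex <- rep(c("M", "F"), each = 3)
  for (sided in c("two", "greater")) {
    p_exact <- permutation_test_vr(x, sex, seed = 1, sided = sided,
                                   exact = TRUE)
    expect_equal(p_exact$B, choose(6, 3))
    # brute-force oracle coded independently in the helper
    expect_equal(p_exact$p_perm, enumerate_vr_p(x, 3, sided))
    # random permutations converge to the same value
    p_rand <- permutation_test_vr(x, sex, B = 20000, seed = 2, sided = sided)
    expect_lt(abs(p_rand$p_perm - p_exact$p_perm), 0.02)
  }
})

test_that("label swap negates log VR and preserves the two-sided permutation p", {
  set.seed(106)
  x <- rnorm(16); sex <- rep(c("M", "F"), each = 8)
  swapped <- ifelse(sex == "M", "F", "M")
  a <- permutation_test_vr(x, sex, exact = TRUE)
  b <- permutation_test_vr(x, swapped, exact = TRUE)
  expect_equal(b$log_vr, -a$log_vr)
  expect_equal(b$p_perm, a$p_perm)
})

test_that("permutation arguments are validated and smoothing bounds p away from 0", {
  x <- c(rnorm(10, sd = 3), rnorm(10)); sex <- rep(c("M", "F"), each = 10)
  expect_error(permutation_test_vr(x, sex, B = 0), "positive")
  expect_warning(permutation_test_vr(x, sex, B = 50, seed = 1), "coarse")
  p_smooth <- permutation_test_vr(x, sex, B = 200, seed = 1, smooth = TRUE)
  expect_gt(p_smooth$p_perm, 0)
})

test_that("fdr_bh reproduces a hand-rolled Benjamini-Hochberg step-up", {
  # brute-force step-up: q_i = min over j >= i of m p_(j) / j
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(res$reject))
  expect_equal(res$q, bh_oracle(c(0.01, 0.02, 0.03, 0.04)))

  expect_equal(fdr_bh(rep(1, 5))$q, rep(1, 5))
  expect_false(any(fdr_bh(rep(1, 5))$reject))

  one <- fdr_bh(0.04)
  expect_equal(one$q, 0.04)
  expect_true(one$reject)

  set.seed(107)
  p <- runif(40)
  expect_equal(fdr_bh(p)$q, bh_oracle(p))
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("correlate_vr_with_d returns Pearson r with n - 2 df", {
  v <- seq(0.1, 0.4, length.out = 14)
  expect_equal(correlate_vr_with_d(v, v)$r, 1)
  expect_equal(correlate_vr_with_d(v, rnorm(14))$df, 12)

  # constructed orthogonality: centered x and y with zero cross-product
  x <- c(-1, 1, -1, 1); y <- c(-1, -1, 1, 1)
  expect_lt(abs(correlate_vr_with_d(x, y)$r), 1e-12)
  expect_error(correlate_vr_with_d(1:3, 1:4), "equal length")
})

test_that("table-level tests apply FDR within measure class and keep q >= p", {
  tb <- simulate_cohorts(noise_config(seed = 108, n = 600, p = 4,
                                      sex_log_vr = 0.5, sex_d = 0.4))
  vt <- test_variances(tb, B = 300, seed = 5)
  mt <- test_means(tb)
  expect_true(all(vt$q >= vt$p_perm))
  expect_true(all(mt$q >= mt$p))
  expect_equal(nrow(vt), 4)
  # within a single class BH equals a direct p.adjust
  expect_equal(vt$q, p.adjust(vt$p_perm, "BH"))
  # deterministic under the same seed
  vt2 <- test_variances(tb, B = 300, seed = 5)
  expect_identical(tidy(vt), tidy(vt2))
})
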
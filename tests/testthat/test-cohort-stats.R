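test_that("uncorrected chi-square regenerates the reference cohort statistics", {
  counts <- clinical_reference_counts()
  printed <- c(sex = 1.162, circadian_rhythm = 0.009, comorbidity = 2.749,
               inducement = 3.039, perinatal_injury = 6.986,
               family_history = 0.832, mri = 4.469, tle = 0.221,
               head_injury = 0.005)
  for (f in names(printed)) {
    expect_equal(round(chi_square(counts[[f]])$statistic, 3),
                 unname(printed[f]), tolerance = 1e-9)
  }
  expect_equal(chi_square(counts$circadian_rhythm)$df, 2)
})

test_that("chi-square invariances and degenerate tables behave", {
  t0 <- matrix(c(10, 20, 5, 10), 2, byrow = TRUE)  # proportional rows
  expect_equal(chi_square(t0)$statistic, 0)
  t1 <- matrix(c(12, 40, 12, 10), 2, byrow = TRUE)
  s <- chi_square(t1)$statistic
  expect_equal(chi_square(t1[2:1, ])$statistic, s)
  expect_equal(chi_square(t1[, 2:1])$statistic, s)
  expect_equal(chi_square(t(t1))$statistic, s)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "zero")
  expect_error(chi_square(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("normality gate routes to pooled t or Mann-Whitney Z", {
  withr::local_seed(31)
  # normal data, identical groups -> t path, statistic 0
  v <- rnorm(30)
  r <- two_group_quantitative(v, v)
  expect_identical(r$test, "t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_true(all(c("mean", "sd") %in% names(r$summary$SF)))
  # heavily skewed data -> Mann-Whitney path
  w <- exp(rnorm(30, 0, 2))
  r2 <- two_group_quantitative(w, w)
  expect_identical(r2$test, "mann-whitney")
  expect_equal(r2$statistic, 0)
  expect_true(all(c("median", "iqr") %in% names(r2$summary$SF)))
  # a large shift is detected on either path
  expect_lt(two_group_quantitative(rnorm(20), rnorm(20) + 10)$p, 0.001)
  expect_lt(two_group_quantitative(w, w * 50)$p, 0.001)
  expect_error(two_group_quantitative(1:2, 1:5), "at least 3")
})

test_that("the gated test keeps its nominal type-I error under the null", {
  withr::local_seed(33)
  reject <- 0
  n_rep <- 1000
  for (i in seq_len(n_rep)) {
    p <- two_group_quantitative(rnorm(20), rnorm(20))$p
    reject <- reject + (p < 0.05)
  }
  expect_gte(reject / n_rep, 0.03)
  expect_lte(reject / n_rep, 0.07)
})

test_that("Mann-Whitney Z agrees with the base-R test on tied data", {
  withr::local_seed(35)
  x <- sample(1:8, 40, replace = TRUE)
  y <- sample(2:9, 30, replace = TRUE)
  mw <- mann_whitney_z(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = FALSE, exact = FALSE))
  expect_equal(mw$U, unname(ref$statistic))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-12)
})

test_that("pooled t from summaries reproduces reference and textbook values", {
  # reference cohort follow-up time (group summaries)
  r <- pooled_t_from_summaries(32.58, 9.83, 52, 36.18, 8.91, 22)
  expect_equal(r$statistic, -1.481, tolerance = 0.01)
  expect_equal(r$df, 72)
  # textbook case: pooled sd 2, se = 2*sqrt(2/5)
  expect_equal(pooled_t_from_summaries(10, 2, 5, 12, 2, 5)$statistic,
               -1.5811, tolerance = 1e-4)
  expect_equal(pooled_t_from_summaries(5, 1, 10, 5, 2, 10)$statistic, 0)
  # degenerate: zero variance
  expect_equal(pooled_t_from_summaries(3, 0, 5, 3, 0, 5)$statistic, 0)
  expect_identical(pooled_t_from_summaries(4, 0, 5, 3, 0, 5)$statistic, Inf)
  expect_error(pooled_t_from_summaries(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("Benjamini-Hochberg adjustment is the standard step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.8, 0.04, 0.3)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj), order(p))  # monotone in the order statistics
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("cohort tables assemble one test per clinical/EEG feature", {
  clin <- generate_clinical(30, 20, seed = 51)
  tab <- clinical_comparison_table(clin)
  expect_equal(nrow(tab), 15)
  expect_setequal(unique(tab$type), c("quantitative", "categorical"))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  fm <- toy_feature_matrix(n_sf = 12, n_nsf = 10, n_feat = 4, effect = 1,
                           seed = 5)
  fm$feature_names <- colnames(fm$values) <- c("delta-F8", "theta-T3",
                                               "alpha-Cz", "beta-Pz")
  ft <- feature_comparison_table(fm)
  expect_equal(nrow(ft), 4)
  expect_true(all(ft$p_adjusted >= ft$p))
})
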
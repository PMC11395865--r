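test_that("icc2k matches the from-scratch ANOVA oracle", {
  # fixed 6 x 2 volume table
  tab <- matrix(c(2715, 588, 360, 9499, 33, 320,
                  2640, 612, 335, 9720, 41, 298), ncol = 2)
  expect_equal(icc2k(tab)$icc, icc2k_oracle(tab), tolerance = 1e-10)
  # 50 random tables with realistic target/rater structure
  set.seed(61)
  for (i in 1:50) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    m <- matrix(rep(rnorm(n, 100, 30), k) + rep(rnorm(k, 0, 5), each = n) +
                  rnorm(n * k, 0, 8), n, k)
    expect_equal(icc2k(m)$icc, icc2k_oracle(m), tolerance = 1e-10)
  }
})

test_that("icc2k separates absolute agreement from consistency", {
  base <- cbind(seq(10, 100, by = 10), seq(10, 100, by = 10))
  perfect <- icc2k(base)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$interpretation, "excellent")
  offset <- base; offset[, 2] <- offset[, 2] + 20
  expect_lt(icc2k(offset)$icc, 1)
  expect_equal(icc3k(offset), 1, tolerance = 1e-12)
})

test_that("icc2k is invariant to common rescaling of all cells", {
  set.seed(62)
  m <- matrix(rnorm(24, 5000, 1500), 8, 3)
  expect_equal(icc2k(m / 1000)$icc, icc2k(m)$icc, tolerance = 1e-12)
})

test_that("icc2k confidence interval brackets the estimate", {
  set.seed(63)
  m <- matrix(rep(rnorm(10, 100, 30), 2) + rnorm(20, 0, 5), 10, 2)
  r <- icc2k(m)
  expect_lte(r$ci[1], r$icc)
  expect_gte(r$ci[2], r$icc)
  expect_lte(r$ci[2], 1)
})

test_that("icc2k rejects incomplete or undersized tables", {
  expect_error(icc2k(matrix(c(1, NA, 3, 4), 2)), "complete")
  expect_error(icc2k(matrix(1:3, 3, 1)), "at least 2")
  flat <- icc2k(matrix(c(5, 5, 5, 5, 5, 5), 3, 2))
  expect_true(flat$degenerate)
})

test_that("pearson correlation matches the covariance definition", {
  expect_equal(pearson_correlation(1:10, 1:10)$r, 1)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1)
  x <- c(2795, 635, 354, 8164, 294)
  y <- c(2715, 588, 360, 9499, 320)
  r <- pearson_correlation(x, y)
  expect_equal(r$r, pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(r$r_squared, r$r^2)
  expect_lt(r$p, 0.05)
  # invariance under positive affine transforms
  expect_equal(pearson_correlation(3 * x + 100, y / 2 + 7)$r, r$r,
               tolerance = 1e-12)
  expect_error(pearson_correlation(1:2, 1:2), "lengths")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
})

test_that("tukey_hsd controls the family-wise comparisons", {
  set.seed(64)
  same <- lapply(1:3, function(i) rnorm(10, 50, 5))
  t_same <- tukey_hsd(same)
  expect_equal(nrow(t_same), 3)          # 3 choose 2
  # far-separated tight groups are strongly significant
  sep <- list(a = rnorm(10, 0, 1), b = rnorm(10, 10, 1))
  expect_lt(tukey_hsd(sep)$p_adj, 0.001)
  # identical-distribution groups: adjusted p near 1
  ident <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  expect_true(all(tukey_hsd(ident)$p_adj > 0.99))
  expect_error(tukey_hsd(list(a = 1, b = 1:3)), "n >= 2")
})

test_that("tukey adjusted p-values are never below the unadjusted ones", {
  set.seed(65)
  for (i in 1:10) {
    g <- lapply(1:sample(3:5, 1), function(j) rnorm(sample(4:9, 1), j, 2))
    tk <- tukey_hsd(g)
    expect_true(all(tk$p_adj >= tk$p_unadj - 1e-12))
  }
})

test_that("compare_volumes runs paired t-tests per subgroup", {
  p <- c(100, 200, 300, 400, 150, 250)
  r0 <- compare_volumes(p, p)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # a 10 sigma shift at n = 10 is decisive
  set.seed(66)
  w <- rnorm(10, 100, 5)
  r1 <- compare_volumes(w + 50, w)
  expect_lt(r1$p, 0.001)
  # subgroups produce one row each plus the pooled row
  sub <- rep(c("Gb", "BM"), each = 3)
  r2 <- compare_volumes(p, p + c(1, -1, 2, -2, 1, -1), subgroup = sub)
  expect_setequal(r2$subgroup, c("all", "Gb", "BM"))
  expect_error(compare_volumes(1, 2), "fewer than 2")
  # unpaired mode accepts the same interface
  r3 <- compare_volumes(p, p + 5, paired = FALSE)
  expect_true(is.finite(r3$p))
})

test_that("likert summaries convert to percent with both SD conventions", {
  all10 <- likert_agreement_summary(rep(10L, 6))
  expect_equal(all10$mean_pct, 100)
  expect_equal(all10$sd_pct, 0)
  two4 <- likert_agreement_summary(c(4L, 4L))
  expect_equal(two4$mean_pct, 40)
  expect_equal(two4$sd_pct, 0)
  # {3, 7}: population SD 20, sample SD 28.28
  pop <- likert_agreement_summary(c(3L, 7L), sd = "population")
  expect_equal(pop$sd_pct, 20)
  samp <- likert_agreement_summary(c(3L, 7L), sd = "sample")
  expect_equal(samp$sd_pct, sqrt(2) * 20, tolerance = 1e-12)
  # single-observation subgroups flag SD 0
  one <- likert_agreement_summary(c(7L, 6L, 8L), subgroup = c("a", "a", "b"))
  expect_true(one$single_obs[one$subgroup == "b"])
  expect_equal(one$sd_pct[one$subgroup == "b"], 0)
  expect_error(likert_agreement_summary(c(3.5, 4)), "integers")
  expect_error(likert_agreement_summary(c(11L)), "0..10")
})
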
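test_that("ICC(2,1) equals the longhand ANOVA value on a small table", {
  x <- matrix(c(9, 2, 5, 8,
                7, 4, 6, 9), ncol = 2)    # 4 joints, 2 methods
  res <- icc_two_way_random_absolute(paired_joint_table(x[, 1], x[, 2]))
  expect_equal(res$icc, aov_icc21(x), tolerance = 1e-10)
  # column exchange symmetry (two-way random treats raters as exchangeable)
  res_sw <- icc_two_way_random_absolute(paired_joint_table(x[, 2], x[, 1]))
  expect_equal(res_sw$icc, res$icc, tolerance = 1e-12)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
})

test_that("perfect agreement gives ICC 1 and shuffling destroys it", {
  a <- c(3, 8, 1, 14, 6, 9, 2, 11, 5, 7)
  perfect <- icc_two_way_random_absolute(paired_joint_table(a, a))
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$label, "almost perfect")
  set.seed(5)
  shuffled <- icc_two_way_random_absolute(paired_joint_table(a, sample(a)))
  expect_lt(abs(shuffled$icc), 0.35)
})

test_that("zero between-joint variance yields NaN with a warning", {
  expect_warning(res <- icc_two_way_random_absolute(
    paired_joint_table(rep(2, 5), rep(2, 5))), "undefined")
  expect_true(is.nan(res$icc))
})

test_that("exact signed-rank p equals full 2^n enumeration", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    a <- round(rnorm(n, 10, 3), 1)
    b <- round(a + rnorm(n, 0.5, 2), 1)   # ties in |diff| possible
    p_pkg <- wilcoxon_signed_rank(paired_joint_table(a, b), method = "exact")
    expect_equal(as.numeric(p_pkg), enum_wilcoxon(a - b), tolerance = 1e-12,
                 label = paste("rep", rep))
  }
})

test_that("signed-rank edge cases behave as documented", {
  # all-equal pairs: p = 1 with a warning
  expect_warning(p <- wilcoxon_signed_rank(paired_joint_table(1:6, 1:6)),
                 "zero")
  expect_equal(as.numeric(p), 1)
  # n = 6 all-positive differences: exact two-sided p = 2/64
  p6 <- wilcoxon_signed_rank(paired_joint_table(2:7, 1:6))
  expect_equal(as.numeric(p6), 2 / 64)
  # antisymmetric differences put W at the null median
  p_anti <- wilcoxon_signed_rank(paired_joint_table(c(5, 5, 9, 9),
                                                    c(4, 6, 8, 10)))
  expect_equal(attr(p_anti, "statistic"), sum(rank(c(1, 1, 1, 1))[c(1, 3)]))
  expect_equal(as.numeric(p_anti), 1)
  # agreement with the stats implementation when no ties or zeros occur
  set.seed(42)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(as.numeric(wilcoxon_signed_rank(paired_joint_table(a, b))),
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # asymptotic branch stays close to the stats implementation
  set.seed(43)
  a <- rnorm(40); b <- a + rnorm(40, 0.3)
  expect_equal(as.numeric(wilcoxon_signed_rank(paired_joint_table(a, b),
                                               method = "asymptotic")),
               stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("PPV and sensitivity are bounded percentages with guarded inputs", {
  expect_equal(ppv(10, 20), 50)
  expect_equal(ppv(20, 20), 100)
  expect_equal(ppv(0, 5), 0)
  expect_equal(sensitivity(10, 20), 50)
  expect_equal(sensitivity(0, 7), 0)
  expect_error(ppv(1, 0), "undefined")
  expect_error(sensitivity(1, 0), "undefined")
  set.seed(44)
  for (i in 1:50) {
    n <- sample(1:30, 1); m <- sample(0:n, 1)
    expect_true(ppv(m, n) >= 0 && ppv(m, n) <= 100)
    expect_true(sensitivity(m, n) >= 0 && sensitivity(m, n) <= 100)
  }
  expect_error(ppv(6, 5), "matched")
})

test_that("the reliability report assembles joint and lesion levels", {
  set.seed(45)
  counts <- paired_joint_table(rpois(8, 20), rpois(8, 18))
  surf <- paired_joint_table(runif(8, 10, 50), runif(8, 10, 50))
  lab <- array(0L, c(6, 6, 6)); lab[1:3, , ] <- 1L
  m <- match_interruptions(label_volume(lab, 0.082),
                           label_volume(lab, 0.082))
  rep <- reliability_report(list(count = counts, surface_mm2 = surf),
                            matches = list(k1 = m))
  expect_equal(nrow(rep$joint), 2L)
  expect_named(rep$joint,
               c("metric", "mean_A", "sd_A", "mean_B", "sd_B", "wilcoxon_p",
                 "icc", "icc_ci_low", "icc_ci_high", "icc_label"))
  expect_equal(rep$lesion$ppv_percent, 100)
  expect_equal(rep$lesion$sensitivity_percent, 100)
  expect_output(print(rep), "Joint level")
})
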
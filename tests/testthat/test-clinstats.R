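test_that("Bland-Altman statistics match hand arithmetic", {
  r <- bland_altman(c(10, 12, 14), c(11, 12, 16))
  expect_equal(r$mean_difference, 1)
  expect_equal(r$sd_difference, 1)
  expect_equal(r$loa_low, 1 - 1.96)
  expect_equal(r$loa_high, 1 + 1.96)

  same <- bland_altman(c(3, 5, 9, 2), c(3, 5, 9, 2))
  expect_equal(c(same$mean_difference, same$sd_difference,
                 same$loa_low, same$loa_high), c(0, 0, 0, 0))
  shifted <- bland_altman(c(3, 5, 9), c(3, 5, 9) + 2.5)
  expect_equal(shifted$mean_difference, 2.5)
  expect_equal(shifted$sd_difference, 0)
  # listwise deletion and the minimum-n contract
  expect_equal(bland_altman(c(1, 2, 3, NA), c(2, 3, 4, 9))$n, 3L)
  expect_error(bland_altman(c(1, NA, 3), c(2, 3, 4)), "at least 3")
})

test_that("Bland-Altman limits bracket about 95% of Gaussian differences", {
  set.seed(14)
  cov <- replicate(40, {
    d1 <- rnorm(250); d2 <- d1 + rnorm(250, sd = 0.7)
    r <- bland_altman(d1, d2)
    mean(r$differences >= r$loa_low & r$differences <= r$loa_high)
  })
  expect_gte(mean(cov), 0.93)
})

test_that("Spearman repeatability: monotone limits and exact enumeration", {
  x <- c(3, 9, 1, 7, 5, 11)
  expect_equal(spearman_repeatability(x, x^3)$rho, 1)
  expect_equal(spearman_repeatability(x, -x)$rho, -1)
  r <- spearman_repeatability(rep(2, 6), c(1, 2, 3, 4, 5, 6))
  expect_true(r$degenerate)
  expect_true(is.na(r$rho))
  expect_error(spearman_repeatability(1:3, 3:1), "at least 4")

  set.seed(3)
  for (rep in 1:4) {
    a <- rnorm(6); b <- rnorm(6)
    got <- spearman_repeatability(a, b)
    expect_identical(got$method, "exact-permutation")
    expect_equal(got$p, oracle_spearman_p(a, b))
  }
  # ties handled through average ranks in both routes
  a <- c(1, 1, 2, 3, 4, 5); b <- c(2, 1, 1, 5, 4, 4)
  expect_equal(spearman_repeatability(a, b)$p, oracle_spearman_p(a, b))
})

test_that("Wilcoxon signed-rank exact p equals full sign enumeration", {
  set.seed(8)
  for (rep in 1:100) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n), sample(c(0, 1, 2), 1))   # induces ties and zeros
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_signed_rank(d)
    expect_identical(got$method, "exact")
    expect_equal(got$p, oracle_signed_rank_p(d), label = paste(d, collapse = ","))
  }
  # agreement with the reference implementation when ties/zeros are absent
  set.seed(9)
  d <- rnorm(15)
  got <- wilcoxon_signed_rank(d)
  ref <- stats::wilcox.test(d, exact = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
})

test_that("the normality gate selects the test the differences call for", {
  set.seed(21)
  b <- rnorm(20)
  lg <- longitudinal_compare(b, b + rnorm(20, 0.2, 0.5))
  expect_identical(lg$test_used, "paired-t")
  expect_gte(lg$shapiro_p, 0.05)

  skew <- rexp(20)^2
  ls <- longitudinal_compare(b, b + skew)
  expect_identical(ls$test_used, "wilcoxon-signed-rank")
  expect_lt(ls$shapiro_p, 0.05)

  ident <- longitudinal_compare(b, b)
  expect_true(ident$degenerate)
  expect_equal(ident$effect, 0)
  expect_error(longitudinal_compare(1:4, 2:5), "at least 5")
})

test_that("correlation cells choose methods, families and flags correctly", {
  co <- generate_cohort(19, seed = 31L)
  cm <- correlation_matrix(co)
  # 13 outcomes -> 78 unique pairs, all available here
  expect_identical(nrow(cm), 78L)
  expect_identical(unique(cm$m), nrow(cm))
  expect_true(all(cm$method[cm$outcome1 %in% c("4SC", "TUG", "10MWR") |
                            cm$outcome2 %in% c("4SC", "TUG", "10MWR")] ==
                  "spearman"))
  expect_true(all(cm$method[!(cm$outcome1 %in% c("4SC", "TUG", "10MWR") |
                              cm$outcome2 %in% c("4SC", "TUG", "10MWR"))] ==
                  "pearson"))
  expect_true(all(abs(cm$r[cm$available]) <= 1))
  expect_identical(cm$significant_bonferroni,
                   cm$available & cm$p_raw < 0.05 / cm$m)
  # generated direction: fat fraction anticorrelates with walk distance
  cell <- cm[cm$outcome1 %in% c("2MWD", "MRI_FF") &
             cm$outcome2 %in% c("2MWD", "MRI_FF"), ]
  expect_lt(cell$r, 0)
})

test_that("Bonferroni flagging is monotone in the family size", {
  co <- generate_cohort(19, seed = 31L)
  cm_full <- correlation_matrix(co)
  few <- co[co$outcome %in% c("MRI_FF", "2MWD", "MMT", "FVC"), ]
  class(few) <- class(co)
  cm_few <- correlation_matrix(few)
  key <- function(d) paste(d$outcome1, d$outcome2)
  shared <- intersect(key(cm_full), key(cm_few))
  sig_full <- cm_full$significant_bonferroni[match(shared, key(cm_full))]
  sig_few <- cm_few$significant_bonferroni[match(shared, key(cm_few))]
  # larger family (more comparisons) can only lose significance
  expect_true(all(!sig_full | sig_few))
})

test_that("outlier sensitivity identifies a planted antagonistic point", {
  x <- c(1, 2, 3, 4, 5, 6, 10)
  y <- c(1, 2, 3, 4, 5, 6, -5)          # on a line except the last point
  r <- sensitivity_excluding_outlier(x, y)
  expect_identical(r$excluded_index, 7L)
  expect_equal(r$r_excluded, 1)
  expect_gt(r$r_excluded, r$r_full)
  expect_error(sensitivity_excluding_outlier(1:4, 1:4), "at least 5")
})

test_that("without an outlier the exclusion barely moves the correlation", {
  # generating model: r_true = 0.7 / sqrt(0.7^2 + 0.7^2) ~ 0.707; dropping
  # the largest standardized residual shifts |r| up slightly by construction,
  # so the checks are on the size of the move and on both estimates staying
  # inside the Fisher-z sampling band of the generating correlation
  set.seed(77)
  r_true <- 0.7 / sqrt(0.7^2 + 0.7^2)
  res <- replicate(200, {
    x <- rnorm(30); y <- 0.7 * x + rnorm(30, sd = 0.7)
    r <- sensitivity_excluding_outlier(x, y)
    c(delta = r$r_excluded - r$r_full, full = r$r_full, excl = r$r_excluded)
  })
  expect_lt(max(abs(res["delta", ])), 0.15)
  z_dev <- abs(atanh(res[c("full", "excl"), ]) - atanh(r_true))
  expect_lt(mean(z_dev > 4 / sqrt(30 - 3)), 0.01)
})

test_that("cohort summary table carries both longitudinal and repeatability columns", {
  co <- generate_cohort(19, seed = 12L)
  s <- summarize_cohort(co)
  expect_identical(nrow(s), 13L)
  repeatable <- c("2MWD", "10MWR", "4SC", "TUG", "PUL")
  expect_true(all(!is.na(s$repeat_rho[s$outcome %in% repeatable])))
  expect_true(all(is.na(s$repeat_rho[!s$outcome %in% repeatable])))
  expect_true(all(s$test_used %in% c("paired-t", "wilcoxon-signed-rank")))
  # repeatability of day-1 vs day-2 should be strong by construction
  expect_true(all(s$repeat_rho[s$outcome %in% repeatable] > 0.7))
})
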
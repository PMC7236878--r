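# All n! permutations of 1..n as an (n!) x n integer matrix. Used for the
# exact Spearman null; n is capped well below memory limits by the caller.
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  out <- matrix(1L, 1L, 1L)
  for (k in 2:max(2L, n)) {
    if (n == 1L) break
    pieces <- vector("list", k)
    for (pos in seq_len(k)) {
      left <- if (pos > 1L) out[, seq_len(pos - 1L), drop = FALSE] else NULL
      right <- if (pos < k) out[, pos:(k - 1L), drop = FALSE] else NULL
      pieces[[pos]] <- cbind(left, k, right)
    }
    out <- do.call(rbind, pieces)
  }
  out
}

#' Bland-Altman repeatability summary
#'
#' Differences are `day2 - day1` after listwise deletion of incomplete pairs;
#' the 95% limits of agreement are the mean difference plus/minus 1.96 times
#' its SD (n - 1 denominator).
#'
#' @param day1,day2 paired measurement vectors.
#' @param outcome optional outcome name carried through.
#' @return A `bland_altman` list: `outcome`, `n`, `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, plus the per-pair `means` and
#'   `differences` for plotting.
#' @export
bland_altman <- function(day1, day2, outcome = NULL) {
  if (length(day1) != length(day2)) stop("day1 and day2 must be paired")
  keep <- stats::complete.cases(day1, day2)
  d1 <- day1[keep]; d2 <- day2[keep]
  n <- length(d1)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  diffs <- d2 - d1
  m <- mean(diffs); s <- stats::sd(diffs)
  structure(list(outcome = outcome, n = n, mean_difference = m,
                 sd_difference = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 means = (d1 + d2) / 2, differences = diffs),
            class = "bland_altman")
}

#' Spearman rank correlation for repeatability
#'
#' Rho on average ranks. The two-sided p-value is exact -- computed by full
#' enumeration of all n! rank permutations -- for n <= 9, and by the
#' t-distribution approximation otherwise. Constant input, for which ranks
#' are undefined, returns a flagged degenerate result rather than a silent
#' NaN.
#'
#' @param day1,day2 paired measurement vectors (n >= 4 after listwise
#'   deletion).
#' @return list with `rho`, `p`, `n`, `method` (`"exact-permutation"` or
#'   `"t-approximation"`), `degenerate`.
#' @export
spearman_repeatability <- function(day1, day2) {
  if (length(day1) != length(day2)) stop("day1 and day2 must be paired")
  keep <- stats::complete.cases(day1, day2)
  x <- day1[keep]; y <- day2[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate",
                degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    rx0 <- as.vector(scale(rx)); ry0 <- as.vector(scale(ry))
    rho_null <- as.vector(matrix(ry0[perms], nrow(perms), n) %*% rx0) / (n - 1)
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method, degenerate = FALSE)
}

# Exact pmf of the signed-rank statistic for given positive magnitudes'
# ranks, via the generating function over all 2^n sign assignments. Ranks are
# average ranks, so they are multiples of 1/2; doubling makes them integers
# and the convolution a small dynamic program.
signed_rank_pmf <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L); f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1:(total + 1L - r)]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Exact Wilcoxon signed-rank test
#'
#' Signed-rank statistic W (sum of ranks of positive differences, zeros
#' dropped, average ranks for tied magnitudes). The two-sided p-value is the
#' exact probability, under random signs, of a statistic at least as far from
#' the null mean as observed -- identical to full 2^n sign enumeration, but
#' computed by convolution so ties are handled exactly. For n > `exact_max`
#' the normal approximation with tie correction is used.
#'
#' @param d vector of paired differences.
#' @param exact_max largest n for which the exact null is used (default 25).
#' @return list with `statistic` (W), `p`, `n` (nonzero differences),
#'   `method`, `degenerate` (all differences zero).
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 25L) {
  d <- d[!is.na(d)]
  dz <- d[d != 0]
  n <- length(dz)
  if (n == 0)
    return(list(statistic = NA_real_, p = NA_real_, n = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(dz))
  W <- sum(r[dz > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    pmf <- signed_rank_pmf(r2)
    w2 <- 2 * W; mu2 <- sum(r2) / 2
    support <- seq_along(pmf) - 1
    p <- sum(pmf[abs(support - mu2) >= abs(w2 - mu2) - 1e-9])
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = W, p = min(p, 1), n = n, method = method, degenerate = FALSE)
}

# Hodges-Lehmann estimate and (approximate under ties) 95% CI from the
# sorted Walsh averages, inverted through the signed-rank null quantiles.
hodges_lehmann <- function(d, conf = 0.95) {
  d <- d[!is.na(d)]
  n <- length(d)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  walsh <- sort((d[idx[, 1]] + d[idx[, 2]]) / 2)
  est <- stats::median(walsh)
  k <- stats::qsignrank((1 - conf) / 2, n)
  M <- length(walsh)
  lo <- if (k + 1 <= M) walsh[k + 1] else walsh[1]
  hi <- if (M - k >= 1) walsh[M - k] else walsh[M]
  c(estimate = est, lo = lo, hi = hi)
}

#' Normality-gated longitudinal comparison
#'
#' Compares paired baseline and follow-up values. A Shapiro-Wilk test on the
#' paired differences gates the choice: paired t-test when the differences
#' look normal at level `alpha`, exact Wilcoxon signed-rank otherwise. The
#' effect estimate is the mean difference with its t-interval for the t
#' branch, and the Hodges-Lehmann median difference with a Walsh-average
#' interval for the signed-rank branch.
#'
#' @param baseline,followup paired vectors (n >= 5 after listwise deletion).
#' @param alpha normality-gate and significance level (default 0.05).
#' @param outcome optional outcome name carried through.
#' @return A `longitudinal_result` list: `outcome`, `n`, `test_used`,
#'   `shapiro_p`, `statistic`, `p_value`, `effect`, `ci_low`, `ci_high`,
#'   `degenerate`.
#' @export
longitudinal_compare <- function(baseline, followup, alpha = 0.05,
                                 outcome = NULL) {
  if (length(baseline) != length(followup)) stop("inputs must be paired")
  keep <- stats::complete.cases(baseline, followup)
  b <- baseline[keep]; f <- followup[keep]
  n <- length(b)
  if (n < 5) stop("need at least 5 complete pairs, got ", n)
  d <- f - b
  res <- list(outcome = outcome, n = n)
  if (all(d == 0)) {
    return(structure(c(res, list(
      test_used = "wilcoxon-signed-rank", shapiro_p = NA_real_,
      statistic = NA_real_, p_value = NA_real_, effect = 0,
      ci_low = 0, ci_high = 0, degenerate = TRUE)),
      class = "longitudinal_result"))
  }
  shapiro_p <- if (stats::sd(d) == 0) 0 else stats::shapiro.test(d)$p.value
  if (shapiro_p >= alpha) {
    tt <- stats::t.test(f, b, paired = TRUE, conf.level = 0.95)
    out <- list(test_used = "paired-t", shapiro_p = shapiro_p,
                statistic = unname(tt$statistic), p_value = tt$p.value,
                effect = unname(tt$estimate),
                ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                degenerate = FALSE)
  } else {
    w <- wilcoxon_signed_rank(d)
    hl <- hodges_lehmann(d)
    out <- list(test_used = "wilcoxon-signed-rank", shapiro_p = shapiro_p,
                statistic = w$statistic, p_value = w$p,
                effect = unname(hl["estimate"]),
                ci_low = unname(hl["lo"]), ci_high = unname(hl["hi"]),
                degenerate = w$degenerate)
  }
  structure(c(res, out), class = "longitudinal_result")
}

cohort_wide_baseline <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  base <- cohort[cohort$visit == "baseline" & cohort$day == 1L, ]
  stats::reshape(base[, c("participant_id", "outcome", "value")],
                 idvar = "participant_id", timevar = "outcome",
                 direction = "wide")
}

#' Pairwise correlation matrix with a Bonferroni family
#'
#' Baseline day-1 values only, pairwise-complete. A pair is assessed by
#' Spearman correlation if either member is in `nonnormal`, by Pearson
#' otherwise. The Bonferroni family size m is the number of unique pairs
#' actually computed; a cell is flagged significant when its raw p-value is
#' below `alpha / m`. Pairs with fewer than 3 complete observations are
#' marked unavailable and do not count toward m.
#'
#' @param cohort a `cohort_table` (long format).
#' @param nonnormal outcome names assessed by Spearman (default the three
#'   short timed tests, whose distributions are right-skewed).
#' @param alpha family significance level.
#' @return data frame of cells: `outcome1`, `outcome2`, `method`, `n`, `r`,
#'   `p_raw`, `m`, `significant_bonferroni`, `available`; attribute `m`.
#' @export
correlation_matrix <- function(cohort, nonnormal = c("4SC", "TUG", "10MWR"),
                               alpha = 0.05) {
  wide <- cohort_wide_baseline(cohort)
  outs <- sub("^value\\.", "", names(wide)[-1])
  if (length(outs) < 2) stop("need at least 2 outcomes")
  vals <- wide[, -1, drop = FALSE]
  cells <- list()
  for (i in seq_along(outs)[-length(outs)]) for (j in (i + 1):length(outs)) {
    x <- vals[[i]]; y <- vals[[j]]
    keep <- stats::complete.cases(x, y)
    n <- sum(keep)
    method <- if (outs[i] %in% nonnormal || outs[j] %in% nonnormal)
      "spearman" else "pearson"
    if (n < 3) {
      cells[[length(cells) + 1]] <- data.frame(
        outcome1 = outs[i], outcome2 = outs[j], method = method, n = n,
        r = NA_real_, p_raw = NA_real_, available = FALSE)
      next
    }
    ct <- suppressWarnings(stats::cor.test(x[keep], y[keep], method = method,
                                           exact = FALSE))
    cells[[length(cells) + 1]] <- data.frame(
      outcome1 = outs[i], outcome2 = outs[j], method = method, n = n,
      r = unname(ct$estimate), p_raw = ct$p.value, available = TRUE)
  }
  df <- do.call(rbind, cells)
  m <- sum(df$available)
  df$m <- m
  df$significant_bonferroni <- df$available & !is.na(df$p_raw) &
    df$p_raw < alpha / m
  attr(df, "alpha") <- alpha
  attr(df, "m") <- m
  df
}

#' Outlier sensitivity analysis of a bivariate correlation
#'
#' Identifies the most extreme outlying point as the one with the largest
#' absolute standardized residual from the least-squares line of y on x, and
#' reports the Pearson correlation with and without it.
#'
#' @param x,y paired vectors (n >= 5 after listwise deletion).
#' @return list with `r_full`, `r_excluded`, `excluded_index` (index into
#'   the complete pairs), `n`.
#' @export
sensitivity_excluding_outlier <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs, got ", n)
  fit <- stats::lm(y ~ x)
  rs <- stats::rstandard(fit)
  idx <- which.max(abs(rs))
  list(r_full = stats::cor(x, y),
       r_excluded = stats::cor(x[-idx], y[-idx]),
       excluded_index = unname(idx), n = n)
}

#' Trial-style outcome summary table
#'
#' Per outcome: baseline day-1 median/IQR/range; follow-up day-1 summary and
#' the normality-gated longitudinal comparison against baseline; and, for
#' outcomes with day-2 repeats, the Spearman repeatability coefficient and
#' Bland-Altman limits of agreement.
#'
#' @param cohort a `cohort_table`.
#' @param alpha significance and normality-gate level.
#' @return data frame with one row per outcome.
#' @export
summarize_cohort <- function(cohort, alpha = 0.05) {
  outs <- unique(cohort$outcome)
  rows <- lapply(outs, function(o) {
    sub <- cohort[cohort$outcome == o, ]
    pick <- function(visit, day) {
      v <- sub[sub$visit == visit & sub$day == day, c("participant_id", "value")]
      stats::setNames(v$value, v$participant_id)
    }
    b1 <- pick("baseline", 1L); f1 <- pick("followup", 1L)
    f2 <- pick("followup", 2L)
    ids <- intersect(names(b1), names(f1))
    lc <- longitudinal_compare(b1[ids], f1[ids], alpha = alpha, outcome = o)
    qs <- function(v) c(median = stats::median(v),
                        q1 = unname(stats::quantile(v, 0.25)),
                        q3 = unname(stats::quantile(v, 0.75)),
                        min = min(v), max = max(v))
    bs <- qs(b1); fs <- qs(f1)
    row <- data.frame(
      outcome = o, n = lc$n,
      baseline_median = bs["median"], baseline_q1 = bs["q1"],
      baseline_q3 = bs["q3"], baseline_min = bs["min"], baseline_max = bs["max"],
      followup_median = fs["median"], followup_q1 = fs["q1"],
      followup_q3 = fs["q3"], followup_min = fs["min"], followup_max = fs["max"],
      test_used = lc$test_used, shapiro_p = lc$shapiro_p,
      p_value = lc$p_value, effect = lc$effect,
      ci_low = lc$ci_low, ci_high = lc$ci_high,
      repeat_rho = NA_real_, repeat_rho_p = NA_real_,
      repeat_mean_diff = NA_real_, repeat_loa_low = NA_real_,
      repeat_loa_high = NA_real_)
    if (length(f2) >= 4) {
      ids2 <- intersect(names(f1), names(f2))
      sp <- spearman_repeatability(f1[ids2], f2[ids2])
      ba <- bland_altman(f1[ids2], f2[ids2], outcome = o)
      row$repeat_rho <- sp$rho; row$repeat_rho_p <- sp$p
      row$repeat_mean_diff <- ba$mean_difference
      row$repeat_loa_low <- ba$loa_low; row$repeat_loa_high <- ba$loa_high
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
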
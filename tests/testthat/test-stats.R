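# Independent enumeration oracle for the Friedman permutation null:
# permutes values within each block and recomputes the classic statistic
# 12/(nk(k+1)) * sum(R_j^2) - 3n(k+1) (valid for untied data).
friedman_perm_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  classic <- function(m) {
    rsum <- colSums(t(apply(m, 1, rank)))
    12 / (n * k * (k + 1)) * sum(rsum^2) - 3 * n * (k + 1)
  }
  obs <- classic(tab)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  idx <- expand.grid(rep(list(seq_along(perms)), n))
  hits <- 0
  for (r in seq_len(nrow(idx))) {
    m <- tab
    for (i in seq_len(n)) m[i, ] <- tab[i, perms[[idx[r, i]]]]
    if (classic(m) >= obs - 1e-9) hits <- hits + 1
  }
  hits / nrow(idx)
}

test_that("Friedman statistic behaves at its analytic extremes", {
  # fully tied blocks: no evidence, p = 1
  tied <- matrix(rep(c(1, 1, 1), 4), 4, 3, byrow = TRUE)
  res <- friedman_test(tied)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 2)
  # perfectly consistent ordering attains the maximum n(k-1)
  consistent <- matrix(rep(c(1, 2, 3), 5), 5, 3, byrow = TRUE) +
    matrix(rnorm(15, sd = 0.01), 5, 3)
  consistent <- t(apply(consistent, 1, sort))
  expect_equal(friedman_test(consistent)$statistic, 10, tolerance = 1e-9)
})

test_that("Friedman chi-square route matches the reference implementation", {
  set.seed(30)
  for (rep in 1:5) {
    tab <- matrix(rnorm(8 * 4), 8, 4)
    mine <- friedman_test(tab)
    ref <- stats::friedman.test(tab)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("exact Friedman p-values reproduce full permutation enumeration", {
  set.seed(31)
  for (rep in 1:3) {
    tab <- matrix(rnorm(12), 4, 3)
    exact <- friedman_test(tab, method = "exact")$p_value
    expect_equal(exact, friedman_perm_oracle(tab), tolerance = 0.02)
  }
})

test_that("the Friedman statistic is invariant to within-block monotone transforms", {
  set.seed(32)
  tab <- matrix(rexp(15), 5, 3)
  s0 <- friedman_test(tab)$statistic
  expect_equal(friedman_test(log(tab))$statistic, s0)
  expect_equal(friedman_test(tab^3)$statistic, s0)
})

test_that("Wilcoxon exact p matches hand-enumerable cases", {
  # six uniformly positive pairs: W = 21, p = 2/2^6
  res <- wilcoxon_signed_rank(1:6 + 0.5, rep(0, 6))
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 0.03125)
  expect_equal(res$method, "exact")
  # perfectly symmetric differences: p = 1
  d <- c(1, -1, 2, -2, 3, -3)
  expect_equal(wilcoxon_signed_rank(d)$p_value, 1)
  # the exact null distribution is a proper distribution
  dist <- ssvepr:::signed_rank_null(rank(abs(rnorm(10))))
  expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
  # degenerate inputs
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "no nonzero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0)), "at least 5")
})

test_that("Wilcoxon agrees with the reference implementation and its own approximation", {
  set.seed(33)
  x <- rnorm(12) + 0.8
  mine <- wilcoxon_signed_rank(x)
  ref <- stats::wilcox.test(x, exact = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # at the exact/approximate boundary the two routes agree closely
  y <- rnorm(15) + 0.6
  p_exact <- wilcoxon_signed_rank(y, exact = TRUE)$p_value
  p_approx <- wilcoxon_signed_rank(y, exact = FALSE)$p_value
  expect_lt(abs(p_exact - p_approx), 0.02)
  # pratt zero handling runs and keeps zeros in the ranking
  z <- c(0, 0, 1, 2, 3, 4, 5, -1)
  pratt <- wilcoxon_signed_rank(z, zero_method = "pratt")
  expect_equal(pratt$n, 6)
  expect_true(pratt$p_value >= 0 && pratt$p_value <= 1)
})

test_that("Bonferroni correction divides the level by the comparison count", {
  set.seed(34)
  tab <- matrix(rnorm(10 * 5), 10, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
  ph <- bonferroni_posthoc(tab, alpha = 0.05)
  expect_equal(nrow(ph), 10)                    # k(k-1)/2
  expect_equal(unique(ph$alpha_corrected), 0.005)
  tab2 <- tab[, 1:2]
  expect_equal(unique(bonferroni_posthoc(tab2, alpha = 0.05)$alpha_corrected),
               0.05)
  expect_error(bonferroni_posthoc(tab[, 1, drop = FALSE]), "at least 2")
})

test_that("Friedman type-I error is calibrated under the null", {
  set.seed(35)
  rejections <- vapply(seq_len(2000), function(i) {
    friedman_test(matrix(rnorm(60), 20, 3))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)   # 0.05 +/- 0.02
  expect_lte(mean(rejections), 0.07)
})

test_that("Friedman detects conditions separated by one within-block sd", {
  set.seed(36)
  hits <- vapply(seq_len(400), function(i) {
    tab <- matrix(rnorm(60), 20, 3)
    tab <- sweep(tab, 2, c(0, 1, 2), "+")   # adjacent effects of 1 sd
    friedman_test(tab)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("the omnibus-gated procedure controls family-wise error", {
  set.seed(37)
  fwer <- vapply(seq_len(2000), function(i) {
    tab <- matrix(rnorm(80), 20, 4)
    om <- friedman_test(tab)
    if (om$p_value >= 0.05) return(FALSE)
    any(bonferroni_posthoc(tab, alpha = 0.05)$significant)
  }, logical(1))
  expect_lte(mean(fwer), 0.06)
})

test_that("condition_stats pivots ERSP tables and gates the post-hoc stage", {
  set.seed(38)
  tab <- expand.grid(subject = paste0("S", 1:5), frequency = c(14, 17),
                     condition = c("a", "b", "c"))
  tab$ersp <- rnorm(nrow(tab)) + 3 * (tab$condition == "c")
  res <- condition_stats(tab)
  expect_lt(res$p_value, 0.05)
  expect_false(is.null(res$pairwise))
  expect_true(all(res$pairwise$alpha_corrected == 0.05 / 3))
  # null data: no post-hoc stage
  tab$ersp <- rnorm(nrow(tab))
  res0 <- condition_stats(tab)
  if (res0$p_value >= 0.05) expect_null(res0$pairwise)
  # missing cells rejected
  expect_error(condition_stats(tab[-1, ]), "missing")
})
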
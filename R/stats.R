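#' Friedman rank test for repeated measures
#'
#' Nonparametric omnibus test for differences among `k` conditions
#' measured in `n` matched blocks. Values are ranked within each block
#' (mid-ranks for ties) and the tie-corrected chi-square statistic
#' \deqn{Q = (k-1) \sum_j (R_j - n(k+1)/2)^2 /
#'       (\sum_{ij} r_{ij}^2 - nk(k+1)^2/4)}
#' is referred to a chi-square distribution with `k - 1` degrees of
#' freedom, or to the exact within-block permutation distribution
#' (`method = "exact"`, enumerating all `(k!)^n` arrangements; only
#' feasible for small tables). A table in which every block is constant
#' yields `Q = 0`, `p = 1`.
#'
#' @param table numeric matrix, blocks x conditions, no missing values.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return An object of class `ssvep_stat` with `statistic`, `df`,
#'   `p_value`, `n_blocks`, `n_conditions`.
#' @export
friedman_test <- function(table, method = c("chisq", "exact")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (anyNA(table)) stop("table has missing cells")
  n <- nrow(table)
  k <- ncol(table)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 conditions")
  r <- t(apply(table, 1, rank))
  stat <- friedman_statistic(r, n, k)
  p <- if (method == "chisq") {
    if (is.na(stat)) 1 else stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  } else {
    friedman_exact_p(r, n, k, stat)
  }
  structure(list(test = "Friedman rank test",
                 statistic = if (is.na(stat)) 0 else stat,
                 df = k - 1, p_value = p, n_blocks = n, n_conditions = k,
                 method = method, pairwise = NULL),
            class = "ssvep_stat")
}

# Tie-corrected statistic from a within-block rank matrix; NA when all
# blocks are fully tied (degenerate denominator).
friedman_statistic <- function(r, n, k) {
  colsums <- colSums(r)
  num <- (k - 1) * sum((colsums - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (den <= .Machine$double.eps * n * k) return(NA_real_)
  num / den
}

friedman_exact_p <- function(r, n, k, stat_obs) {
  if (is.na(stat_obs)) return(1)
  n_arrangements <- factorial(k)^n
  if (n_arrangements > 5e5)
    stop("exact enumeration infeasible: (k!)^n = ", n_arrangements)
  perms <- permutations_of(k)
  idx <- rep(1L, n)
  count <- 0L
  total <- 0L
  repeat {
    colsums <- numeric(k)
    for (i in seq_len(n)) colsums <- colsums + r[i, perms[[idx[i]]]]
    num <- (k - 1) * sum((colsums - n * (k + 1) / 2)^2)
    den <- sum(r^2) - n * k * (k + 1)^2 / 4
    if (num / den >= stat_obs - 1e-9) count <- count + 1L
    total <- total + 1L
    pos <- 1L
    while (pos <= n && idx[pos] == length(perms)) {
      idx[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > n) break
    idx[pos] <- idx[pos] + 1L
  }
  count / total
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(k - 1))
    for (pos in 0:(k - 1))
      out[[length(out) + 1]] <- append(p, k, after = pos)
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on the signed ranks of paired differences. Zero
#' differences are dropped (`zero_method = "drop"`, the textbook rule) or
#' retained for ranking and then discarded (`"pratt"`). Tied difference
#' magnitudes receive mid-ranks. The statistic `W` is the sum of ranks of
#' positive differences. The p-value is exact - computed from the full
#' null distribution over all 2^n sign assignments via the generating
#' function of the (possibly tied) ranks - for `n <= exact_limit`, and a
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param x first paired sample, or a vector of differences if `y` is
#'   `NULL`.
#' @param y second paired sample.
#' @param zero_method `"drop"` or `"pratt"`.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact p-value;
#'   `NULL` decides by `exact_limit`.
#' @param exact_limit largest `n` for which the exact distribution is
#'   used by default.
#' @return List with `statistic` (W), `p_value`, `n` (nonzero pairs) and
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, zero_method = c("drop", "pratt"),
                                 exact = NULL, exact_limit = 15) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("`x` and `y` must have equal length")
    x - y
  }
  nonzero <- d != 0
  if (!any(nonzero)) stop("no nonzero pairs")
  if (sum(nonzero) < 5)
    stop("need at least 5 nonzero pairs (have ", sum(nonzero), ")")
  ranks <- if (zero_method == "drop") {
    d <- d[nonzero]
    rank(abs(d))
  } else {
    rank(abs(d))[nonzero]
  }
  if (zero_method == "pratt") d <- d[nonzero]
  n <- length(d)
  w <- sum(ranks[d > 0])
  use_exact <- exact %||% (n <= exact_limit)
  if (use_exact) {
    dist <- signed_rank_null(ranks)
    w2 <- round(2 * w)
    lo <- sum(dist$prob[dist$w2 <= w2 + 1e-9])
    hi <- sum(dist$prob[dist$w2 >= w2 - 1e-9])
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- sum(ranks) / 2
    sigma <- sqrt(sum(ranks^2) / 4)
    z <- (w - mu - 0.5 * sign(w - mu)) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

# Exact null distribution of 2W (doubled to keep mid-ranks integral)
# over all sign assignments, by polynomial convolution.
signed_rank_null <- function(ranks) {
  r2 <- round(2 * ranks)
  probs <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), probs)
    probs <- c(probs, rep(0, r)) + shifted
  }
  probs <- probs / 2^length(r2)
  list(w2 = seq_along(probs) - 1, prob = probs)
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' Runs a Wilcoxon signed-rank test for every pair of conditions and
#' flags significance at the Bonferroni-corrected level `alpha / m`,
#' where `m = k(k-1)/2` is the number of comparisons.
#'
#' @param table numeric matrix, blocks x conditions (named columns).
#' @param alpha family-wise significance level.
#' @param ... passed to [wilcoxon_signed_rank()].
#' @return Data frame with one row per condition pair: `condition_a`,
#'   `condition_b`, `statistic`, `p_value`, `alpha_corrected`,
#'   `significant`.
#' @export
bonferroni_posthoc <- function(table, alpha = 0.05, ...) {
  table <- as.matrix(table)
  k <- ncol(table)
  if (k < 2) stop("need at least 2 conditions")
  labels <- colnames(table) %||% paste0("C", seq_len(k))
  m <- k * (k - 1) / 2
  level <- alpha / m
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    wt <- wilcoxon_signed_rank(table[, i1], table[, i2], ...)
    data.frame(condition_a = labels[i1], condition_b = labels[i2],
               statistic = wt$statistic, p_value = wt$p_value,
               alpha_corrected = level, significant = wt$p_value < level)
  })
  do.call(rbind, rows)
}

#' Omnibus-plus-post-hoc inference on an ERSP table
#'
#' Builds the blocks x conditions matrix from an ERSP table - one block
#' per (subject, frequency) pair, one column per condition - and runs the
#' Friedman omnibus test. When the omnibus test is significant at
#' `alpha`, Bonferroni-corrected pairwise Wilcoxon signed-rank tests
#' identify which conditions differ.
#'
#' @param ersp_table a [compute_ersp_table()] data frame (or any data
#'   frame with columns `subject`, `frequency`, `condition`, `ersp`).
#' @param alpha significance level for the omnibus test and the
#'   family-wise level of the post-hoc tests.
#' @param method omnibus p-value method, see [friedman_test()].
#' @return An `ssvep_stat` with the omnibus results and, when the
#'   omnibus test is significant, a `pairwise` data frame.
#' @export
condition_stats <- function(ersp_table, alpha = 0.05, method = "chisq") {
  blocks <- ersp_blocks(ersp_table)
  res <- friedman_test(blocks, method = method)
  res$alpha <- alpha
  if (res$p_value >= alpha) {
    res$posthoc_note <- sprintf("omnibus not significant at alpha = %g", alpha)
  } else if (nrow(blocks) < 5) {
    res$posthoc_note <- sprintf(
      "omnibus significant but only %d block(s); post-hoc signed-rank tests need >= 5",
      nrow(blocks))
  } else {
    res$pairwise <- bonferroni_posthoc(blocks, alpha = alpha)
  }
  res
}

# Pivot an ERSP table to a blocks x conditions matrix
# (block = subject x frequency).
ersp_blocks <- function(ersp_table) {
  block <- interaction(ersp_table$subject, ersp_table$frequency, drop = TRUE)
  conds <- unique(ersp_table$condition)
  mat <- vapply(conds, function(cond) {
    sel <- ersp_table$condition == cond
    v <- ersp_table$ersp[sel][match(levels(block), block[sel])]
    v
  }, numeric(nlevels(block)))
  if (anyNA(mat)) stop("ERSP table has missing (subject, frequency, condition) cells")
  colnames(mat) <- conds
  rownames(mat) <- levels(block)
  mat
}

#' @export
print.ssvep_stat <- function(x, ...) {
  cat(sprintf("%s: chi-square = %.4g, df = %d, p = %.4g (%s; n = %d blocks, k = %d)\n",
              x$test, x$statistic, x$df, x$p_value, x$method,
              x$n_blocks, x$n_conditions))
  if (!is.null(x$pairwise)) {
    cat("post-hoc Wilcoxon signed-rank (Bonferroni-corrected):\n")
    print(x$pairwise, row.names = FALSE)
  } else if (!is.null(x$posthoc_note)) {
    cat(x$posthoc_note, "; no post-hoc tests run\n", sep = "")
  }
  invisible(x)
}

# JSON-serializable record of a test result.
stat_provenance <- function(x) {
  out <- list(test = x$test, statistic = x$statistic, df = x$df,
              p_value = x$p_value, n_blocks = x$n_blocks,
              n_conditions = x$n_conditions, method = x$method)
  if (!is.null(x$pairwise)) out$pairwise <- x$pairwise
  out
}
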
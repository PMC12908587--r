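# Bespoke exact statistics shared by every module.
#
# The cohort sizes in this problem (n = 16, 8 vs 8) make asymptotic rank
# tests unreliable, so the Wilcoxon family is implemented with exact null
# distributions (dynamic-programming counts) for small samples and a
# tie-corrected normal approximation with continuity correction otherwise.

# Exact null distribution of the rank-sum of a sample of size n1 drawn
# without replacement from ranks 1..N: counts[w + 1] = number of subsets of
# size n1 summing to w. Counts fit in doubles for the sizes used here.
ranksum_null_counts <- function(n1, N) {
  max_w <- sum((N - n1 + 1L):N)
  counts <- matrix(0, nrow = n1 + 1L, ncol = max_w + 1L)
  counts[1L, 1L] <- 1
  for (r in seq_len(N)) {
    # iterate subset size downwards so each rank is used at most once
    for (k in min(r, n1):1L) {
      w <- seq(r, max_w)
      counts[k + 1L, w + 1L] <- counts[k + 1L, w + 1L] + counts[k, w - r + 1L]
    }
  }
  counts[n1 + 1L, ]
}

#' Wilcoxon rank-sum test (exact for small samples)
#'
#' Two-sided test that two independent samples come from the same
#' distribution, using the rank-sum statistic of the first sample. For
#' `length(a)`, `length(b)` both at most `exact_limit` and untied data the
#' p-value is exact (full null distribution of the rank sum); otherwise
#' midranks are used with a tie-corrected normal approximation and
#' continuity correction.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_limit Largest per-group size for which the exact
#'   distribution is used (default 25).
#' @return A list with `statistic` (rank sum of `a`), `p.value`, `exact`
#'   (logical), and `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value # exact 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 25L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(pooled) > 0L
  mu <- n1 * (N + 1) / 2
  if (!ties && n1 <= exact_limit && n2 <= exact_limit) {
    counts <- ranksum_null_counts(n1, N)
    total <- sum(counts)
    w_vals <- seq_along(counts) - 1L
    p_lo <- sum(counts[w_vals <= W]) / total
    p_hi <- sum(counts[w_vals >= W]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = W, p.value = p, exact = TRUE,
                method = "exact Wilcoxon rank-sum"))
  }
  if (W == mu) {
    return(list(statistic = W, p.value = 1, exact = FALSE,
                method = "normal-approximation Wilcoxon rank-sum"))
  }
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_corr)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = W, p.value = p, exact = FALSE,
       method = "normal-approximation Wilcoxon rank-sum (midranks)")
}

# Exact null distribution of the positive-rank sum W+ for n untied
# differences: coefficients of prod_{r=1..n} (1 + x^r).
signedrank_null_counts <- function(n) {
  counts <- numeric(n * (n + 1) / 2 + 1L)
  counts[1L] <- 1
  for (r in seq_len(n)) {
    upper <- length(counts)
    idx <- seq(upper, r + 1L)
    counts[idx] <- counts[idx] + counts[idx - r]
  }
  counts
}

#' Wilcoxon signed-rank test on paired differences (exact for small n)
#'
#' Two-sided one-sample test of symmetry about zero. Zero differences are
#' dropped (Wilcoxon's original treatment); at least 5 nonzero differences
#' are required. Exact for at most `exact_limit` untied absolute
#' differences, otherwise tie-corrected normal approximation.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_limit Largest n for the exact distribution (default 25).
#' @return A list with `statistic` (positive-rank sum), `p.value`,
#'   `n_used`, `n_zero`, `exact`, `method`.
#' @export
wilcoxon_signed_rank <- function(d, exact_limit = 25L) {
  d <- as.numeric(d)
  if (anyNA(d)) stop("missing values not allowed")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L) stop("need at least 5 nonzero differences (got ", n, ")")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  mu <- n * (n + 1) / 4
  if (!ties && n <= exact_limit) {
    counts <- signedrank_null_counts(n)
    total <- 2^n
    w_vals <- seq_along(counts) - 1L
    p_lo <- sum(counts[w_vals <= W]) / total
    p_hi <- sum(counts[w_vals >= W]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = W, p.value = p, n_used = n, n_zero = n_zero,
                exact = TRUE, method = "exact Wilcoxon signed-rank"))
  }
  if (W == mu) {
    return(list(statistic = W, p.value = 1, n_used = n, n_zero = n_zero,
                exact = FALSE,
                method = "normal-approximation Wilcoxon signed-rank"))
  }
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = W, p.value = p, n_used = n, n_zero = n_zero,
       exact = FALSE,
       method = "normal-approximation Wilcoxon signed-rank (midranks)")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric point probabilities not
#' exceeding that of the observed table (the standard two-sided
#' convention), at fixed margins.
#'
#' @param tab 2x2 matrix of non-negative integer counts with both margins
#'   positive.
#' @return A list with `p.value` and the observed table.
#' @examples
#' fisher_exact_2x2(matrix(c(1, 7, 7, 1), 2))$p.value # 130/12870
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("both margins must be positive")
  }
  m <- sum(tab[, 1L]); n <- sum(tab[, 2L]); k <- sum(tab[1L, ])
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p.value = min(1, p), table = tab, method = "Fisher exact (two-sided)")
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite, each with
#'   nonzero variance.
#' @param names Optional character pair naming the variables.
#' @return A list of class `gf_assoc` with `r`, `t`, `df`, `p.value`, `n`.
#' @export
pearson_assoc <- function(x, y, names = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y)))) {
    stop("values must be finite and non-missing")
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input")
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(pair = names, n = n, r = r, t = t_stat, df = df,
                 p.value = max(p, .Machine$double.xmin)),
            class = "gf_assoc")
}

#' @method print gf_assoc
#' @export
print.gf_assoc <- function(x, ...) {
  cat(sprintf("Pearson association %s ~ %s: r = %.3f (n = %d, p = %.3g)\n",
              x$pair[1L], x$pair[2L], x$r, x$n, x$p.value))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(pvals) {
  p <- as.numeric(pvals)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

#' Alpha-diversity vs metabolic-adaptation association panel
#'
#' The four correlations relating community diversity to energy-expenditure
#' adaptation: baseline Shannon index vs RMR and TDEE adaptation, and the
#' pre-to-post change in Shannon index vs RMR and TDEE adaptation.
#' Complete-case analysis; the number of dropped subjects is recorded.
#'
#' @param alpha_pre Baseline Shannon index per subject.
#' @param alpha_delta Post-minus-pre Shannon change per subject.
#' @param adaptation_rmr,adaptation_tdee Metabolic adaptation (kcal/day),
#'   aligned with the diversity vectors.
#' @return A list of class `gf_assoc_panel`: four `gf_assoc` objects
#'   (`pre_rmr`, `pre_tdee`, `delta_rmr`, `delta_tdee`), the complete-case
#'   `n`, `n_dropped`, and a long-format `data` table for export.
#' @export
diversity_adaptation_analysis <- function(alpha_pre, alpha_delta,
                                          adaptation_rmr, adaptation_tdee) {
  len <- length(alpha_pre)
  if (length(alpha_delta) != len || length(adaptation_rmr) != len ||
      length(adaptation_tdee) != len) {
    stop("all inputs must be aligned per subject (equal length)")
  }
  keep <- stats::complete.cases(alpha_pre, alpha_delta,
                                adaptation_rmr, adaptation_tdee)
  n_dropped <- sum(!keep)
  if (sum(keep) < 5L) stop("fewer than 5 complete cases")
  ap <- alpha_pre[keep]; ad <- alpha_delta[keep]
  mr <- adaptation_rmr[keep]; mt <- adaptation_tdee[keep]
  res <- list(
    pre_rmr = pearson_assoc(ap, mr, c("shannon_pre", "adaptation_rmr")),
    pre_tdee = pearson_assoc(ap, mt, c("shannon_pre", "adaptation_tdee")),
    delta_rmr = pearson_assoc(ad, mr, c("shannon_delta", "adaptation_rmr")),
    delta_tdee = pearson_assoc(ad, mt, c("shannon_delta", "adaptation_tdee")),
    n = sum(keep), n_dropped = n_dropped,
    data = data.frame(shannon_pre = ap, shannon_delta = ad,
                      adaptation_rmr = mr, adaptation_tdee = mt))
  class(res) <- "gf_assoc_panel"
  res
}

#' @method print gf_assoc_panel
#' @export
print.gf_assoc_panel <- function(x, ...) {
  cat(sprintf("Diversity-adaptation associations (n = %d, %d dropped):\n",
              x$n, x$n_dropped))
  for (nm in c("pre_rmr", "pre_tdee", "delta_rmr", "delta_tdee")) {
    print(x[[nm]])
  }
  invisible(x)
}
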
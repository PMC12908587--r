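# Exact tests against brute-force enumeration oracles.

test_that("exact rank-sum matches the enumeration oracle on all small sizes", {
  set.seed(11)
  for (n1 in 2:7) {
    for (n2 in 2:7) {
      a <- rnorm(n1); b <- rnorm(n2) + runif(1, -1, 1)
      res <- wilcoxon_rank_sum(a, b)
      expect_true(res$exact)
      expect_equal(res$p.value, oracle_ranksum_p(a, b),
                   tolerance = 1e-12,
                   label = sprintf("ranksum n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("rank-sum frozen examples and tie handling", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  # identical multisets: midrank path, W at its null mean
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_false(res$exact)
  expect_equal(res$p.value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact signed-rank matches the 2^n enumeration oracle", {
  set.seed(12)
  for (n in 5:12) {
    d <- rnorm(n) + 0.4
    res <- wilcoxon_signed_rank(d)
    expect_true(res$exact)
    expect_equal(res$p.value, oracle_signedrank_p(d), tolerance = 1e-12,
                 label = sprintf("signed-rank n=%d", n))
  }
})

test_that("signed-rank frozen examples, zero and tie policy", {
  # all 8 differences positive, untied: p = 2 / 2^8
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 7, 8) / 10)$p.value,
               0.0078125)
  # symmetric +/- pairs: tied |d|, W at its null mean -> p = 1
  expect_equal(wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))$p.value, 1)
  # zeros are dropped and counted
  res <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5) / 10)
  expect_equal(res$n_zero, 2)
  expect_equal(res$n_used, 5)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0, 1, 2)), "5 nonzero")
})

test_that("Fisher exact matches enumeration for tables up to N = 20", {
  expect_equal(fisher_exact_2x2(matrix(c(4, 4, 4, 4), 2))$p.value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(1, 7, 7, 1), 2))$p.value,
               130 / 12870, tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:60) {
    N <- sample(4:20, 1)
    repeat {
      cells <- as.vector(stats::rmultinom(1, N, rep(0.25, 4)))
      tab <- matrix(cells, 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    p <- fisher_exact_2x2(tab)$p.value
    expect_equal(p, oracle_fisher_p(tab), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("pearson_assoc matches cor.test and handles edge cases", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_assoc(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_assoc(x, 2 * x + 1)$p.value, 0)
  expect_equal(pearson_assoc(x, -x)$r, -1)
  set.seed(14)
  for (rep in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    ref <- stats::cor.test(a, b)
    res <- pearson_assoc(a, b)
    expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_assoc(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_assoc(1:2, 1:2), "at least 3")
})

test_that("bh_fdr reproduces step-up arithmetic and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(15)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(!is.unsorted(q[order(p)]))           # monotone in sorted p
    # re-adjusting q never decreases it and preserves monotonicity
    q2 <- bh_fdr(q)
    expect_true(all(q2 >= q - 1e-15))
    expect_true(!is.unsorted(q2[order(p)]))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("diversity_adaptation_analysis aligns subjects and drops NAs", {
  set.seed(16)
  h0 <- rnorm(12); dh <- rnorm(12); ar <- rnorm(12); at <- rnorm(12)
  res <- diversity_adaptation_analysis(h0, dh, ar, at)
  expect_equal(res$n, 12)
  expect_equal(res$delta_tdee$r, cor(dh, at))
  # shuffling all inputs identically leaves every r unchanged
  o <- sample(12)
  res2 <- diversity_adaptation_analysis(h0[o], dh[o], ar[o], at[o])
  expect_equal(res2$pre_rmr$r, res$pre_rmr$r)
  # NA drops are complete-case and counted
  ar[3] <- NA
  res3 <- diversity_adaptation_analysis(h0, dh, ar, at)
  expect_equal(res3$n, 11)
  expect_equal(res3$n_dropped, 1)
  expect_error(diversity_adaptation_analysis(h0[1:4], dh[1:4], ar[1:4],
                                             at[1:4]), "complete cases")
})
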
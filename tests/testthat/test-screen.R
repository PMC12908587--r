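# Species filter and the cross-validated AUROC screen.

test_that("auroc equals the trapezoidal ROC oracle and the U identity", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(8:20, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    scores <- round(rnorm(n), sample(c(1, 8), 1)) # sometimes tied
    expect_equal(auroc(scores, labels),
                 oracle_auc_trapezoid(scores, labels), tolerance = 1e-12)
  }
  expect_error(auroc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("filter_species applies abundance and prevalence rules in order", {
  tab <- rbind(c(0.001, 0.01, 0.4, 0.0001),
               c(0.001, 0.00, 0.4, 0.0001),
               c(0.001, 0.01, 0.4, 0.0001),
               c(0.001, 0.00, 0.4, 0.0001),
               c(0.001, 0.01, 0.4, 0.0001))
  colnames(tab) <- c("spA", "spB", "spC", "spD")
  # spA passes both; spB fails prevalence (60% < 80%); spC passes;
  # spD fails mean abundance. Order: descending mean RA.
  expect_equal(filter_species(tab), c("spC", "spA"))
  # equal mean abundance -> ties broken by species id
  tab2 <- cbind(spZ = rep(0.5, 5), spY = rep(0.5, 5))
  expect_equal(filter_species(tab2), c("spY", "spZ"))
  expect_error(filter_species(tab[, 4, drop = FALSE]), "relaxing")
})

test_that("stratified folds keep both classes and are seed-deterministic", {
  labels <- rep(c(TRUE, FALSE), each = 8)
  f1 <- gutfit:::stratified_kfold(labels, 3, seed = 99)
  f2 <- gutfit:::stratified_kfold(labels, 3, seed = 99)
  expect_identical(f1, f2)
  for (k in 1:3) {
    expect_true(any(labels[f1 == k]) && any(!labels[f1 == k]))
  }
})

make_screen_fixture <- function(seed, n = 16, n_species = 12,
                                strong = "sp01") {
  set.seed(seed)
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  tab <- matrix(rexp(n * n_species), n)
  colnames(tab) <- sprintf("sp%02d", seq_len(n_species))
  tab[, strong] <- ifelse(labels, 10, 1) + runif(n, 0, 0.5)
  tab <- tab / rowSums(tab)
  rownames(tab) <- sprintf("S%02d_pre", seq_len(n))
  list(tab = tab, labels = labels)
}

test_that("a perfectly separating species scores AUROC 1 in every repeat", {
  fx <- make_screen_fixture(62)
  res <- univariate_auroc_screen(fx$tab, fx$labels, seed = 5,
                                 compute_ci = TRUE, n_boot = 500)
  row <- res[res$species == "sp01", ]
  expect_equal(row$auroc_mean, 1)
  expect_equal(row$auroc_sd, 0)
  expect_equal(c(row$ci_lo, row$ci_hi), c(1, 1))
  expect_equal(row$p, 2 / 12870, tolerance = 1e-12)
  expect_true(row$highly_predictive)
  expect_true(row$robust)
})

test_that("fold splits are shared across species within a repeat", {
  fx <- make_screen_fixture(63)
  res <- univariate_auroc_screen(fx$tab, fx$labels, repeats = 4, seed = 6,
                                 compute_ci = FALSE)
  folds <- attr(res, "folds")
  expect_length(folds, 4)
  # re-running with the same seed reproduces the folds and results exactly
  res2 <- univariate_auroc_screen(fx$tab, fx$labels, repeats = 4, seed = 6,
                                  compute_ci = FALSE)
  expect_identical(attr(res2, "folds"), folds)
  expect_equal(res2$auroc_mean, res$auroc_mean)
})

test_that("screen AUROC is invariant to monotone abundance transforms", {
  fx <- make_screen_fixture(64)
  res <- univariate_auroc_screen(fx$tab, fx$labels, repeats = 3, seed = 7,
                                 compute_ci = FALSE)
  tab_t <- fx$tab
  tab_t[, "sp03"] <- log1p(1000 * tab_t[, "sp03"])
  res_t <- univariate_auroc_screen(tab_t, fx$labels, repeats = 3, seed = 7,
                                   compute_ci = FALSE)
  # ranks within a fold are preserved exactly; pooling across folds mixes
  # calibrations, so invariance holds only up to a small pooling effect
  expect_equal(res_t$auroc_mean[res_t$species == "sp03"],
               res$auroc_mean[res$species == "sp03"], tolerance = 0.05)
})

test_that("ScreenResult invariants hold on a null screen", {
  set.seed(65)
  labels <- rep(c(TRUE, FALSE), each = 8)
  tab <- matrix(rexp(16 * 20), 16)
  colnames(tab) <- sprintf("sp%02d", 1:20)
  tab <- tab / rowSums(tab)
  res <- univariate_auroc_screen(tab, labels, repeats = 5, seed = 8,
                                 n_boot = 300)
  expect_true(all(res$auroc_mean >= 0 & res$auroc_mean <= 1))
  expect_true(all(res$ci_lo <= res$auroc_mean + 1e-12))
  expect_true(all(res$ci_hi >= res$auroc_mean - 1e-12))
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("auc_pvalue_mannwhitney ties the U statistic to the rank-sum test", {
  scores <- c(2 + 1:8 / 10, 1:8 / 10)
  labels <- rep(c(TRUE, FALSE), each = 8)
  res <- auc_pvalue_mannwhitney(scores, labels)
  expect_equal(res$auc, 1)
  expect_equal(res$p.value, 2 / 12870, tolerance = 1e-12)
  same <- auc_pvalue_mannwhitney(rep(c(1, 2), 8), rep(c(TRUE, TRUE, FALSE, FALSE), 4))
  expect_equal(same$p.value, 1)
  expect_error(auc_pvalue_mannwhitney(1:4, rep(TRUE, 4)), "both classes")
})

test_that("bootstrap_auroc_ci covers the null and is stable in n_boot", {
  set.seed(66)
  labels <- rep(c(TRUE, FALSE), each = 8)
  covered <- vapply(1:60, function(s) {
    sc <- rnorm(16)
    ci <- bootstrap_auroc_ci(sc, labels, n_boot = 400, seed = s)
    ci[1] <= 0.5 && ci[2] >= 0.5
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  sc <- rnorm(16) + labels
  ci_a <- bootstrap_auroc_ci(sc, labels, n_boot = 2000, seed = 1)
  ci_b <- bootstrap_auroc_ci(sc, labels, n_boot = 4000, seed = 2)
  expect_lt(max(abs(ci_a - ci_b)), 0.05)
})

test_that("multivariate_regularized selects a planted species, not noise", {
  fx <- make_screen_fixture(67, n_species = 30)
  res <- multivariate_regularized(fx$tab, fx$labels, seed = 9)
  expect_true("sp01" %in% res$selected$species)
  expect_gt(res$selected$coefficient[res$selected$species == "sp01"], 0)
  # permuted labels: selection collapses to (near) nothing
  sizes <- vapply(1:30, function(s) {
    set.seed(700 + s)
    nrow(suppressMessages(
      multivariate_regularized(fx$tab, sample(fx$labels), seed = s)$selected))
  }, numeric(1))
  expect_lte(stats::median(sizes), 2)
})

test_that("compare_group_aurocs contrasts flagged species against the rest", {
  fx <- make_screen_fixture(68, n_species = 16)
  res <- univariate_auroc_screen(fx$tab, fx$labels, repeats = 3, seed = 10,
                                 compute_ci = FALSE)
  cmp <- compare_group_aurocs(res, c("sp01"))
  expect_equal(cmp$n_flagged, 1)
  expect_gt(cmp$mean_flagged, cmp$mean_other)
  # identical groups -> p = 1
  res2 <- res
  res2$auroc_mean <- rep(c(0.6, 0.7), 8)
  cmp2 <- compare_group_aurocs(res2, rep(c(TRUE, TRUE, FALSE, FALSE), 4))
  expect_equal(cmp2$p.value, 1)
  expect_error(compare_group_aurocs(res, rep(TRUE, 16)), "non-empty")
})
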
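# Species filtering and the cross-validated univariate AUROC screen.

#' Area under the ROC curve from scores and binary labels
#'
#' Computed through the rank (Mann-Whitney U) identity
#' `AUROC = U / (n1 * n0)`, with ties contributing 1/2. Orientation is the
#' fitted score itself, so values below 0.5 are possible.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or two-level) labels; `TRUE` is the positive
#'   class.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment: within each class, shuffled indices are
# dealt to folds round-robin, so every fold keeps both classes for
# 2 <= k <= min(class sizes).
stratified_kfold <- function(labels, k, seed = NULL) {
  labels <- as.logical(labels)
  if (k < 2L) stop("k must be >= 2")
  if (min(sum(labels), sum(!labels)) < k) {
    stop("each class must have at least k members for stratified k-fold")
  }
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Univariate logistic regression with a tiny ridge penalty on the slope:
# with 2/3 of n = 16 subjects a single species often separates the classes
# perfectly and the unpenalized MLE diverges; the penalty (default 1e-6)
# keeps the Newton iteration finite without materially moving the
# decision scores. Feature is standardized with training-fold statistics.
logistic_ridge_fit <- function(x, y, lambda = 1e-6, max_iter = 25L) {
  mu <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  z <- (x - mu) / s
  X <- cbind(1, z)
  beta <- c(0, 0)
  pen <- diag(c(0, lambda))
  for (iter in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- crossprod(X, y - p) - pen %*% beta
    H <- crossprod(X, X * w) + pen + diag(1e-12, 2L)
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  list(beta = beta, mu = mu, s = s)
}

logistic_ridge_predict <- function(fit, x) {
  stats::plogis(pmin(pmax(fit$beta[1L] + fit$beta[2L] * (x - fit$mu) / fit$s,
                          -30), 30))
}

#' Filter species by mean abundance and prevalence in pre-training samples
#'
#' Keeps species whose mean relative abundance across pre samples exceeds
#' `min_mean_ra` (default 0.05%) and that are detected (abundance above
#' `detection`) in at least `min_prevalence` of pre samples (default 80%).
#' The result is deterministically ordered by descending mean relative
#' abundance with ties broken by species id.
#'
#' @param table_pre Pre-training samples x species relative-abundance
#'   matrix.
#' @param min_mean_ra Mean relative-abundance threshold (proportion).
#' @param min_prevalence Required detection fraction of pre samples.
#' @param detection Abundance strictly above which a species counts as
#'   detected.
#' @return Character vector of retained species ids.
#' @export
filter_species <- function(table_pre, min_mean_ra = 5e-4,
                           min_prevalence = 0.8, detection = 0) {
  table_pre <- as.matrix(table_pre)
  if (nrow(table_pre) < 1L) stop("need at least one pre-training sample")
  mean_ra <- colMeans(table_pre)
  prevalence <- colMeans(table_pre > detection)
  keep <- mean_ra > min_mean_ra & prevalence >= min_prevalence
  if (!any(keep)) {
    stop("no species pass the filter; consider relaxing the thresholds")
  }
  ids <- colnames(table_pre)[keep]
  ids[order(-mean_ra[keep], ids)]
}

#' Mann-Whitney p-value for a ROC curve
#'
#' Exploits `U / (n1 * n0) = AUROC`: a two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test on the prediction scores of the two classes, exact for
#' small samples.
#'
#' @param scores Prediction scores (e.g. pooled out-of-fold scores).
#' @param labels Logical labels, `TRUE` = positive class.
#' @return List with `auc`, `p.value`, `statistic`.
#' @export
auc_pvalue_mannwhitney <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  w <- wilcoxon_rank_sum(scores[labels], scores[!labels])
  list(auc = auroc(scores, labels), p.value = w$p.value,
       statistic = w$statistic, exact = w$exact)
}

# Vectorized bootstrap AUROCs given per-class resample index matrices.
bootstrap_auc_values <- function(scores_pos, scores_neg, rp, rn) {
  B <- nrow(rp)
  P <- matrix(scores_pos[rp], nrow = B)
  N <- matrix(scores_neg[rn], nrow = B)
  acc <- numeric(B)
  for (i in seq_len(ncol(P))) {
    for (j in seq_len(ncol(N))) {
      acc <- acc + (P[, i] > N[, j]) + 0.5 * (P[, i] == N[, j])
    }
  }
  acc / (ncol(P) * ncol(N))
}

#' Stratified bootstrap percentile confidence interval for AUROC
#'
#' Subjects are resampled with replacement within each class, so every
#' resample retains both classes.
#'
#' @param scores Prediction scores per subject.
#' @param labels Logical labels; each class needs >= 3 members.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_auroc_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                               seed = NULL) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 < 3L || n0 < 3L) stop("each class needs at least 3 members")
  with_seed(seed, {
    rp <- matrix(sample.int(n1, n_boot * n1, replace = TRUE), nrow = n_boot)
    rn <- matrix(sample.int(n0, n_boot * n0, replace = TRUE), nrow = n_boot)
    aucs <- bootstrap_auc_values(scores[labels], scores[!labels], rp, rn)
    unname(stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' Repeated stratified k-fold univariate AUROC screen
#'
#' For every species, a univariate logistic regression of the response
#' label on the species' pre-training relative abundance is evaluated by
#' repeated stratified k-fold cross-validation (defaults: 10 repeats,
#' k = 3). Within a repeat the fold split is shared across species, making
#' the per-species AUROCs directly comparable; out-of-fold scores are
#' pooled within a repeat into one ROC AUC, and the reported AUROC is the
#' mean (and sd) over repeats. Per-fold AUROC averaging is also emitted
#' (`auroc_mean_folds`). The per-subject scores averaged over repeats feed
#' an exact Mann-Whitney p-value, Benjamini-Hochberg q-values across
#' species, and a stratified bootstrap percentile CI.
#'
#' @param table_pre Pre-training samples x species relative-abundance
#'   matrix (rows = subjects).
#' @param labels Logical responder labels aligned with rows.
#' @param repeats,k Cross-validation design (default 10 x 3).
#' @param seed Run seed; fold and bootstrap seeds derive from it.
#' @param auroc_threshold "Highly predictive" cut-off on the mean AUROC
#'   (default 0.8).
#' @param fdr_threshold FDR cut-off entering the `robust` flag (default 0.1).
#' @param n_boot,ci_level Bootstrap CI parameters.
#' @param compute_ci Set `FALSE` to skip the bootstrap (faster).
#' @return Data frame of class `gf_screen`, one row per species:
#'   `species`, `auroc_mean`, `auroc_sd`, `auroc_mean_folds`, `ci_lo`,
#'   `ci_hi`, `p`, `q`, `highly_predictive`, `robust`. The fold
#'   assignments are kept in the `"folds"` attribute, the per-subject mean
#'   scores in `"subject_scores"`.
#' @export
univariate_auroc_screen <- function(table_pre, labels, repeats = 10L, k = 3L,
                                    seed = 1L, auroc_threshold = 0.8,
                                    fdr_threshold = 0.1, n_boot = 2000L,
                                    ci_level = 0.95, compute_ci = TRUE) {
  table_pre <- as.matrix(table_pre)
  labels <- as.logical(labels)
  n <- nrow(table_pre)
  if (length(labels) != n) stop("labels must match the table rows")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  if (n < 2L * k) stop("need n >= 2k samples")
  folds <- lapply(seq_len(repeats), function(r) {
    stratified_kfold(labels, k, seed = derive_seed(seed, r))
  })
  n_species <- ncol(table_pre)
  auc_rep <- matrix(NA_real_, nrow = n_species, ncol = repeats)
  auc_fold <- matrix(NA_real_, nrow = n_species, ncol = repeats)
  subject_scores <- matrix(0, nrow = n, ncol = n_species,
                           dimnames = list(rownames(table_pre),
                                           colnames(table_pre)))
  for (s in seq_len(n_species)) {
    x <- table_pre[, s]
    for (r in seq_len(repeats)) {
      fold <- folds[[r]]
      oof <- numeric(n)
      fold_aucs <- numeric(k)
      for (f in seq_len(k)) {
        test <- fold == f
        fit <- logistic_ridge_fit(x[!test], labels[!test])
        oof[test] <- logistic_ridge_predict(fit, x[test])
        fold_aucs[f] <- auroc(oof[test], labels[test])
      }
      auc_rep[s, r] <- auroc(oof, labels)
      auc_fold[s, r] <- mean(fold_aucs)
      subject_scores[, s] <- subject_scores[, s] + oof / repeats
    }
  }
  auroc_mean <- rowMeans(auc_rep)
  auroc_sd <- apply(auc_rep, 1L, stats::sd)
  p <- vapply(seq_len(n_species), function(s) {
    auc_pvalue_mannwhitney(subject_scores[, s], labels)$p.value
  }, numeric(1))
  q <- bh_fdr(p)
  ci_lo <- ci_hi <- rep(NA_real_, n_species)
  if (compute_ci) {
    n1 <- sum(labels); n0 <- sum(!labels)
    boot <- with_seed(derive_seed(seed, 99991L), {
      list(rp = matrix(sample.int(n1, n_boot * n1, replace = TRUE),
                       nrow = n_boot),
           rn = matrix(sample.int(n0, n_boot * n0, replace = TRUE),
                       nrow = n_boot))
    })
    probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
    for (s in seq_len(n_species)) {
      aucs <- bootstrap_auc_values(subject_scores[labels, s],
                                   subject_scores[!labels, s],
                                   boot$rp, boot$rn)
      qs <- stats::quantile(aucs, probs, names = FALSE)
      ci_lo[s] <- qs[1L]; ci_hi[s] <- qs[2L]
    }
  }
  out <- data.frame(species = colnames(table_pre),
                    auroc_mean = auroc_mean, auroc_sd = auroc_sd,
                    auroc_mean_folds = rowMeans(auc_fold),
                    ci_lo = ci_lo, ci_hi = ci_hi, p = p, q = q,
                    highly_predictive = auroc_mean > auroc_threshold,
                    robust = !is.na(ci_lo) & q < fdr_threshold & ci_lo > 0.5,
                    stringsAsFactors = FALSE)
  attr(out, "folds") <- folds
  attr(out, "subject_scores") <- subject_scores
  attr(out, "params") <- list(repeats = repeats, k = k, seed = seed,
                              auroc_threshold = auroc_threshold,
                              fdr_threshold = fdr_threshold)
  class(out) <- c("gf_screen", "data.frame")
  out
}

#' L1-regularized multivariate response prediction
#'
#' Lasso-penalized logistic regression over the filtered species, with the
#' penalty chosen by stratified k-fold cross-validation maximizing AUROC
#' (largest penalty within the maximum, so the sparsest such model wins
#' ties). Features are z-scored before penalization. An empty selection is
#' a legitimate outcome (reported, not an error).
#'
#' @param X Pre-training samples x species matrix (filtered species).
#' @param labels Logical responder labels.
#' @param seed Run seed for the CV folds.
#' @param nfolds Number of stratified CV folds (default 3).
#' @return List with `selected` (data frame of nonzero-coefficient species
#'   and signs), `lambda`, `cv_auc`.
#' @export
multivariate_regularized <- function(X, labels, seed = 1L, nfolds = 3L) {
  X <- as.matrix(X)
  labels <- as.logical(labels)
  if (nrow(X) < 6L) stop("need at least 6 samples")
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  Z <- scale(X[, keep, drop = FALSE])
  y <- as.integer(labels)
  # glmnet warns about class counts < 8 on every fit at this cohort size;
  # that is the expected regime here, so the warnings are silenced
  full <- suppressWarnings(
    glmnet::glmnet(Z, y, family = "binomial", alpha = 1,
                   standardize = FALSE))
  lambdas <- full$lambda
  fold <- stratified_kfold(labels, nfolds, seed = derive_seed(seed, 7L))
  cv_auc <- matrix(NA_real_, nrow = nfolds, ncol = length(lambdas))
  for (f in seq_len(nfolds)) {
    test <- fold == f
    fit <- suppressWarnings(
      glmnet::glmnet(Z[!test, , drop = FALSE], y[!test],
                     family = "binomial", alpha = 1,
                     standardize = FALSE, lambda = lambdas))
    pred <- suppressWarnings(
      stats::predict(fit, Z[test, , drop = FALSE], s = lambdas,
                     type = "link"))
    cv_auc[f, ] <- apply(pred, 2L, function(sc) {
      if (length(unique(y[test])) < 2L) NA_real_ else auroc(sc, labels[test])
    })
  }
  mean_auc <- colMeans(cv_auc, na.rm = TRUE)
  # one-standard-error rule: the largest penalty (lambdas descend, so the
  # first index) whose CV AUROC is within one SE of the maximum; under an
  # exchangeable null this collapses to the empty model
  i_max <- which.max(mean_auc)
  se_max <- stats::sd(cv_auc[, i_max]) / sqrt(nfolds)
  if (!is.finite(se_max)) se_max <- 0
  best <- which(mean_auc >= mean_auc[i_max] - se_max)[1L]
  beta <- as.matrix(stats::coef(full, s = lambdas[best]))[-1L, 1L]
  nz <- which(beta != 0)
  selected <- data.frame(species = colnames(Z)[nz],
                         coefficient = unname(beta[nz]),
                         stringsAsFactors = FALSE)
  if (nrow(selected) == 0L) {
    message("no species selected at the CV-optimal penalty")
  }
  list(selected = selected, lambda = lambdas[best],
       cv_auc = mean_auc[best])
}

#' Compare mean AUROCs between a flagged species group and the rest
#'
#' Two-sided exact Wilcoxon rank-sum test on per-species mean AUROC, e.g.
#' comparing a taxon of interest against all other screened species.
#'
#' @param screen Result of [univariate_auroc_screen()].
#' @param group_flag Logical vector per screened species, or a character
#'   vector of flagged species ids.
#' @return List with `p.value`, `mean_flagged`, `sd_flagged`,
#'   `mean_other`, `sd_other`, group sizes.
#' @export
compare_group_aurocs <- function(screen, group_flag) {
  if (is.character(group_flag)) {
    group_flag <- screen$species %in% group_flag
  }
  if (length(group_flag) != nrow(screen)) {
    stop("group_flag must cover every screened species")
  }
  a <- screen$auroc_mean[group_flag]
  b <- screen$auroc_mean[!group_flag]
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  w <- wilcoxon_rank_sum(a, b)
  list(p.value = w$p.value, statistic = w$statistic,
       mean_flagged = mean(a), sd_flagged = stats::sd(a),
       mean_other = mean(b), sd_other = stats::sd(b),
       n_flagged = length(a), n_other = length(b))
}
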
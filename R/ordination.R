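# Principal coordinates analysis and distance-based permutation tests.

check_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(D < 0)) stop("distances must be non-negative")
  D
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering `B = -1/2 * J %*% D^2 %*% J` followed by an
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their eigenvalues. Axes with non-positive eigenvalues are
#' dropped (no Cailliez/Lingoes correction); the mass of negative
#' eigenvalues is reported so the user can judge how non-Euclidean the
#' input is.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param eig_tol Relative tolerance below which eigenvalues are treated
#'   as zero.
#' @return List of class `gf_pcoa`: `points` (samples x retained axes),
#'   `eig` (retained eigenvalues, non-increasing), `prop_explained`,
#'   `negative_mass` (sum of |negative eigenvalues| / sum of |all|).
#' @export
pcoa <- function(D, eig_tol = 1e-9) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  scale_ref <- max(abs(e$values), eig_tol)
  pos <- e$values > eig_tol * scale_ref
  neg_mass <- sum(abs(e$values[e$values < 0])) / max(sum(abs(e$values)), eig_tol)
  if (!any(pos)) stop("no positive eigenvalues; degenerate distance matrix")
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  structure(list(points = pts, eig = e$values[pos],
                 prop_explained = e$values[pos] / sum(e$values[pos]),
                 negative_mass = neg_mass, all_eig = e$values),
            class = "gf_pcoa")
}

permanova_pseudo_f <- function(d2, labels) {
  n <- nrow(d2)
  groups <- split(seq_len(n), labels)
  g <- length(groups)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(groups, function(idx) {
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
  ss_between <- ss_tot - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Anderson-style one-way pseudo-F computed from squared inter-sample
#' distances (`SS_total = sum of d^2 / n` over pairs; within-group sums
#' analogously per group), with a permutation p-value obtained by
#' permuting whole-sample labels. The add-one estimator
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)` is used. Pre/post samples
#' of one subject are permuted independently unless `strata` is given, in
#' which case labels are permuted at the stratum level (all samples of a
#' stratum move together).
#'
#' @param D Distance matrix.
#' @param labels Group labels (>= 2 groups, each with >= 2 members).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional RNG seed for the permutations.
#' @param strata Optional stratum id per sample (e.g. subject) for
#'   restricted permutations.
#' @return List with `f`, `p.value`, `n_perm`, `ss_between`, `ss_within`.
#' @export
permanova <- function(D, labels, n_perm = 9999, seed = NULL, strata = NULL) {
  D <- check_distance_matrix(D)
  labels <- as.factor(labels)
  if (length(labels) != nrow(D)) stop("labels must match the distance matrix")
  sizes <- table(labels)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need >= 2 groups with >= 2 members each")
  }
  d2 <- D^2
  f_obs <- permanova_pseudo_f(d2, labels)
  n <- nrow(D)
  perm_labels <- if (is.null(strata)) {
    function() sample(labels)
  } else {
    strata <- as.factor(strata)
    stratum_label <- tapply(as.character(labels), strata, function(x) {
      if (length(unique(x)) != 1L) {
        stop("labels must be constant within strata")
      }
      x[1L]
    })
    stratum_of <- match(strata, names(stratum_label))
    function() {
      shuffled <- sample(stratum_label)
      factor(shuffled[stratum_of], levels = levels(labels))
    }
  }
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      permanova_pseudo_f(d2, perm_labels()) >= f_obs
    }, logical(1)))
  })
  groups <- split(seq_len(n), labels)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(groups, function(idx) sum(d2[idx, idx]) / (2 * length(idx)),
                          numeric(1)))
  list(f = f_obs, p.value = (1 + count) / (1 + n_perm), n_perm = n_perm,
       ss_between = ss_tot - ss_within, ss_within = ss_within)
}

oneway_f <- function(x, labels) {
  groups <- split(x, labels)
  n <- length(x); g <- length(groups)
  grand <- mean(x)
  ss_between <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ss_within == 0) {
    return(if (ss_between == 0) 0 else Inf)
  }
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the distance matrix by [pcoa()] (all retained positive axes),
#' computes each sample's Euclidean distance to its own group centroid
#' (the group mean coordinate), and tests equality of mean dispersion with
#' a one-way F statistic whose null distribution is obtained by permuting
#' group labels over the fixed centroid distances (the standard
#' permutation scheme for this test).
#'
#' @inheritParams permanova
#' @return List with `f`, `p.value`, `distances` (per-sample distance to
#'   own-group centroid), `labels`, `n_perm`.
#' @export
dispersion_test <- function(D, labels, n_perm = 9999, seed = NULL) {
  D <- check_distance_matrix(D)
  labels <- as.factor(labels)
  if (length(labels) != nrow(D)) stop("labels must match the distance matrix")
  sizes <- table(labels)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need >= 2 groups with >= 2 members each")
  }
  Y <- pcoa(D)$points
  dists <- numeric(nrow(Y))
  for (g in levels(labels)) {
    idx <- which(labels == g)
    centroid <- colMeans(Y[idx, , drop = FALSE])
    dists[idx] <- sqrt(rowSums(sweep(Y[idx, , drop = FALSE], 2L, centroid)^2))
  }
  f_obs <- oneway_f(dists, labels)
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      oneway_f(dists, sample(labels)) >= f_obs
    }, logical(1)))
  })
  names(dists) <- rownames(D)
  list(f = f_obs, p.value = (1 + count) / (1 + n_perm),
       distances = dists, labels = labels, n_perm = n_perm)
}

#' Compare groups' distances to their own centroid
#'
#' Exact two-sided Wilcoxon rank-sum test between the two groups'
#' per-sample centroid distances (from [dispersion_test()]).
#'
#' @param distances Per-sample centroid distances, or the result list of
#'   [dispersion_test()] (in which case `labels` is taken from it).
#' @param labels Two-level group labels aligned with `distances`.
#' @return The [wilcoxon_rank_sum()] result, plus per-group means.
#' @export
centroid_distance_comparison <- function(distances, labels = NULL) {
  if (is.list(distances) && !is.null(distances$distances)) {
    labels <- distances$labels
    distances <- distances$distances
  }
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two groups required")
  a <- distances[labels == levels(labels)[1L]]
  b <- distances[labels == levels(labels)[2L]]
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  res <- wilcoxon_rank_sum(a, b)
  res$group_means <- stats::setNames(c(mean(a), mean(b)), levels(labels))
  res
}
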
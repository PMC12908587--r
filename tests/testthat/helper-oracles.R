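# Independent brute-force oracles for the exact tests and the
# phylogenetic metrics. These deliberately use naive enumeration /
# explicit path unions, never the package's own code paths.

# Exact two-sided rank-sum p by enumerating all C(N, n1) rank subsets.
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  W <- sum(rank(c(a, b))[seq_len(n1)])
  sums <- combn(N, n1, sum)
  p_lo <- mean(sums <= W)
  p_hi <- mean(sums >= W)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns.
oracle_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- drop(signs %*% r)
  min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
}

# Two-sided Fisher p by explicit hypergeometric point-mass enumeration
# with choose() products (no dhyper).
oracle_fisher_p <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - n):min(k, m)
  pmass <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- pmass[support == tab[1, 1]]
  min(1, sum(pmass[pmass <= p_obs * (1 + 1e-7)]))
}

# Node -> parent map and leaf descendants for naive tree traversals.
tree_parents <- function(tree) {
  parents <- integer(max(tree$edge))
  parents[tree$edge[, 2]] <- tree$edge[, 1]
  parents
}

# Faith PD by explicit root-to-leaf path union.
oracle_faith_pd <- function(present, tree) {
  parents <- tree_parents(tree)
  root <- length(tree$tip.label) + 1L
  edges_used <- logical(nrow(tree$edge))
  edge_of_child <- match(seq_len(max(tree$edge)), tree$edge[, 2])
  for (sp in present) {
    node <- match(sp, tree$tip.label)
    while (node != root) {
      edges_used[edge_of_child[node]] <- TRUE
      node <- parents[node]
    }
  }
  sum(tree$edge.length[edges_used])
}

# Weighted UniFrac by per-branch summation with recursively enumerated
# descendant leaf sets.
oracle_weighted_unifrac <- function(x, y, tree, normalized = TRUE) {
  n_tip <- length(tree$tip.label)
  descendants <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, descendants))
  }
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    leaves <- descendants(tree$edge[e, 2])
    A <- sum(x[intersect(names(x), leaves)])
    B <- sum(y[intersect(names(y), leaves)])
    num <- num + tree$edge.length[e] * abs(A - B)
    den <- den + tree$edge.length[e] * (A + B)
  }
  if (normalized) num / den else num
}

# Trapezoidal ROC-curve integration (independent of the rank identity).
oracle_auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!labels] >= t), 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

random_composition <- function(n_species, zeros = 0L) {
  p <- stats::rexp(n_species)
  if (zeros > 0L) p[sample.int(n_species, zeros)] <- 0
  p / sum(p)
}
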
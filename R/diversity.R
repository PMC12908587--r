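# Alpha and beta taxonomic diversity over species relative abundances and
# a rooted phylogeny (ape "phylo" trees).

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over positive entries, in natural-log units
#' (nats) by default; the base is configurable.
#'
#' @param p Composition (non-negative, summing to 1 within 1e-6).
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index.
#' @export
shannon <- function(p, base = exp(1)) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("composition entries must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) {
    stop("composition must sum to 1 (got ", format(sum(p)), ")")
  }
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

# Per-edge descendant weights for each sample: matrix E x S where entry
# (e, s) is the total abundance of sample s carried by the subtree below
# edge e. Tips absent from `table` columns get zero weight.
edge_sample_weights <- function(table, tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  tips <- tree$tip.label
  missing <- setdiff(colnames(table), tips)
  if (length(missing) > 0L) {
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  }
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  S <- nrow(table)
  node_w <- matrix(0, nrow = n_node, ncol = S)
  idx <- match(colnames(table), tips)
  node_w[idx, ] <- t(table)
  E <- nrow(tree$edge)
  A <- matrix(0, nrow = E, ncol = S)
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  for (e in seq_len(E)) {
    w <- node_w[child[e], ]
    A[e, ] <- w
    node_w[parent[e], ] <- node_w[parent[e], ] + w
  }
  list(weights = A, lengths = tree$edge.length)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the subtree connecting the present species to
#' the root: every edge whose descendant set contains at least one present
#' leaf contributes its length (the stem path to the root is included; the
#' root itself carries no edge).
#'
#' @param present Character vector of present species (leaf labels).
#' @param tree Rooted `phylo` tree with branch lengths.
#' @return Phylogenetic diversity in branch-length units.
#' @export
faith_pd <- function(present, tree) {
  present <- unique(as.character(present))
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0L) {
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(present) == 0L) return(0)
  ind <- matrix(1, nrow = 1L, ncol = length(present),
                dimnames = list("s", present))
  ew <- edge_sample_weights(ind, tree)
  sum(ew$lengths[ew$weights[, 1L] > 0])
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|x - y|) / sum(x + y)`, bounded in \[0, 1\] for non-negative
#' inputs.
#'
#' @param x,y Abundance vectors over the same species universe.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must share the species universe")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  denom <- sum(x + y)
  if (denom == 0) stop("both communities are empty")
  sum(abs(x - y)) / denom
}

#' Weighted UniFrac dissimilarity
#'
#' For each branch b with length l_b, let A_b and B_b be the fractions of
#' each community descending from b. The normalized weighted UniFrac is
#' `sum(l_b * |A_b - B_b|) / sum(l_b * (A_b + B_b))`; the raw variant
#' returns the numerator only.
#'
#' @param x,y Named compositions (names are leaf labels, subsets of the
#'   tree's tips).
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param normalized Divide by the abundance-weighted total branch length
#'   (default `TRUE`).
#' @return Dissimilarity (in \[0, 1\] when normalized).
#' @export
weighted_unifrac <- function(x, y, tree, normalized = TRUE) {
  if (is.null(names(x)) || is.null(names(y))) {
    stop("compositions must be named by species")
  }
  tab <- matrix(0, nrow = 2L, ncol = length(union(names(x), names(y))))
  colnames(tab) <- union(names(x), names(y))
  tab[1L, names(x)] <- x
  tab[2L, names(y)] <- y
  ew <- edge_sample_weights(tab, tree)
  num <- sum(ew$lengths * abs(ew$weights[, 1L] - ew$weights[, 2L]))
  if (!normalized) return(num)
  den <- sum(ew$lengths * (ew$weights[, 1L] + ew$weights[, 2L]))
  if (den == 0) stop("both communities are empty on the tree")
  num / den
}

#' Pairwise beta-diversity distance matrix
#'
#' @param table Samples x species relative-abundance matrix with row and
#'   column names.
#' @param metric `"bray_curtis"` or `"weighted_unifrac"`.
#' @param tree Required for weighted UniFrac.
#' @param normalized Passed to [weighted_unifrac()].
#' @return Symmetric matrix with zero diagonal and a `"metric"` attribute.
#' @export
beta_diversity <- function(table, metric = c("bray_curtis", "weighted_unifrac"),
                           tree = NULL, normalized = TRUE) {
  metric <- match.arg(metric)
  table <- as.matrix(table)
  n <- nrow(table)
  D <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  if (metric == "bray_curtis") {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- bray_curtis(table[i, ], table[j, ])
      }
    }
  } else {
    if (is.null(tree)) stop("weighted UniFrac requires a tree")
    ew <- edge_sample_weights(table, tree)
    A <- ew$weights; l <- ew$lengths
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        num <- sum(l * abs(A[, i] - A[, j]))
        d <- if (normalized) num / sum(l * (A[, i] + A[, j])) else num
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  attr(D, "metric") <- metric
  D
}

#' Alpha diversity per sample
#'
#' Shannon index and (when a tree is supplied) Faith's PD over the species
#' with positive abundance in each sample.
#'
#' @param table Samples x species relative-abundance matrix.
#' @param tree Optional rooted `phylo` tree covering the species.
#' @return Data frame with `sample_id`, `shannon`, and `faith_pd`.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  table <- as.matrix(table)
  out <- data.frame(sample_id = rownames(table),
                    shannon = apply(table, 1L, shannon),
                    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    out$faith_pd <- apply(table, 1L, function(p) {
      faith_pd(colnames(table)[p > 0], tree)
    })
  }
  rownames(out) <- NULL
  out
}
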
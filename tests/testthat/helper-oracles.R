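# Independent oracles: everything here is deliberately brute-force and
# shares no code path with the package internals it checks.

# Ancestor list (including the node itself) by walking parent pointers.
ancestor_path <- function(tree, node) {
  n_root <- length(tree$tip.label) + 1L
  path <- node
  while (node != n_root) {
    node <- tree$edge[tree$edge[, 2L] == node, 1L]
    path <- c(path, node)
  }
  path
}

# Root-to-node depth by summing edge lengths along the ancestor path.
brute_depth <- function(tree, node) {
  path <- ancestor_path(tree, node)
  if (length(path) == 1L) return(0)
  sum(vapply(path[-length(path)], function(ch)
    tree$edge.length[tree$edge[, 2L] == ch], numeric(1)))
}

# Shared-path depth of two nodes = depth of their most recent common
# ancestor, found by intersecting root paths.
brute_shared_depth <- function(tree, a, b) {
  pa <- ancestor_path(tree, a)
  pb <- ancestor_path(tree, b)
  common <- intersect(pa, pb)
  max(vapply(common, function(k) brute_depth(tree, k), numeric(1)))
}

# O(n^2) phylogenetic covariance from pairwise MRCA depths.
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- if (i == j) brute_depth(tree, i)
               else brute_shared_depth(tree, i, j)
  }
  C
}

# Dense multivariate-normal log-density (no Cholesky shortcuts shared with
# the package: plain solve() and determinant()).
dmvn_log <- function(x, mu, S) {
  n <- length(x)
  r <- x - mu
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(S)$modulus) +
            sum(r * solve(S, r)))
}

# Joint tips+internal-nodes BM covariance (unit rate) from brute-force
# shared depths, for the conditional-mean ASR oracle.
brute_joint_cov <- function(tree) {
  ids <- seq_len(length(tree$tip.label) + tree$Nnode)
  J <- matrix(0, length(ids), length(ids))
  for (i in ids) for (j in ids) {
    J[i, j] <- if (i == j) brute_depth(tree, i)
               else brute_shared_depth(tree, i, j)
  }
  J
}

# Random test trees: branch lengths positive, topology random.
rand_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}
rand_ultra <- function(n) ape::rcoal(n)

named_trait <- function(tree, vals) stats::setNames(vals, tree$tip.label)
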
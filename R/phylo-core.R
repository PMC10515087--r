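#' Parse a Newick string into a phylogeny
#'
#' Reads a rooted tree with branch lengths from a Newick string and validates
#' it for comparative analysis: balanced parentheses, unique tip labels, and a
#' branch length on every non-root edge. Polytomies are preserved.
#'
#' @param text A single Newick string (terminating `;` optional but
#'   recommended).
#' @return An object of class `phylo` (see \pkg{ape}).
#' @seealso [write_newick()], [prune_to_taxa()]
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("unbalanced Newick: ", depth, " unclosed '(' at end of string")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse failed: ", substr(text, 1, 60))
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny as a Newick string
#'
#' Branch lengths are always emitted, at 10 significant digits, so trees
#' round-trip through [parse_newick()] to 1e-9 or better — well below the
#' precision any divergence-time analysis carries.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @keywords internal
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (length(tree$tip.label) < 1L) stop("tree has no tips")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; every non-root edge needs one")
  if (anyNA(tree$edge.length))
    stop("missing branch length on edge(s) ",
         paste(which(is.na(tree$edge.length)), collapse = ", "))
  if (any(tree$edge.length < 0))
    stop("negative branch length on edge(s) ",
         paste(which(tree$edge.length < 0), collapse = ", "))
  invisible(tree)
}

#' Root-to-node depths
#'
#' Path-length sum from the root to every node, in the tree's time units.
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over all nodes (tips first, ape node numbering).
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Tree height
#'
#' Maximum root-to-tip depth (My for a time-calibrated tree).
#'
#' @param tree A `phylo` object.
#' @return A single number.
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_along(tree$tip.label)])
}

#' Test ultrametricity within a relative tolerance
#'
#' A tree is treated as ultrametric when the spread of root-to-tip depths is
#' at most `tol` times the tree height. Time-calibrated trees stored at
#' finite precision pass this gate; genuinely non-ultrametric trees do not.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on the tip-depth spread (default `1e-6`).
#' @return Logical scalar.
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(d)
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips outside `keep`, suppressing the unbranched internal nodes
#' this creates (their branch lengths are summed), so every retained tip keeps
#' its original root-to-tip depth and all pairwise MRCA depths among retained
#' tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain.
#' @return The pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  hit <- keep %in% tree$tip.label
  if (!any(hit))
    stop("no requested taxa found in the tree; unmatched: ",
         paste(utils::head(keep[!hit], 10), collapse = ", "),
         if (sum(!hit) > 10) ", ...")
  if (all(tree$tip.label %in% keep)) return(tree)
  ape::keep.tip(tree, keep[hit])
}

#' Phylogenetic variance-covariance matrix
#'
#' The Brownian-motion covariance structure implied by a tree: `C[i, j]` is
#' the depth of the most recent common ancestor of tips `i` and `j`, and the
#' diagonal holds tip depths. Multiplying by a rate σ² gives the trait
#' covariance under BM.
#'
#' @param tree A `phylo` object with at least two tips.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  if (length(tree$tip.label) < 2L) stop("need at least two tips")
  validate_phylogeny(tree)
  ape::vcv.phylo(tree)
}

#' Transform a phylogenetic covariance under an evolutionary model
#'
#' Produces the unit-rate covariance structure of the four standard
#' continuous-trait models; σ² multiplies the result downstream.
#'
#' * `BM` — identity transform.
#' * `LA` — Pagel's lambda: off-diagonal entries scaled by `lambda`,
#'   diagonal unchanged; `lambda = 1` is BM, `lambda = 0` removes all
#'   phylogenetic covariance.
#' * `OU` — single-optimum Ornstein-Uhlenbeck, fixed-root (non-stationary)
#'   convention: `C'[i,j] = exp(-2*alpha*(T - C[i,j])) *
#'   (1 - exp(-2*alpha*C[i,j])) / (2*alpha)` with `T` the tree height.
#'   Requires an ultrametric input.
#' * `WN` — white noise: `T * I`, the star structure with tip variance equal
#'   to tree height, so σ² keeps the same per-My scaling as the other models.
#'
#' @param C Covariance matrix from [phylo_vcv()].
#' @param model One of `"BM"`, `"OU"`, `"LA"`, `"WN"`.
#' @param alpha OU attraction strength (1/My), required and `> 0` for `"OU"`.
#' @param lambda Pagel's lambda in `[0, 1]`, required for `"LA"`.
#' @param height Tree height `T`; defaults to `max(diag(C))`.
#' @param ultra_tol Relative ultrametricity tolerance for the OU gate.
#' @return The transformed covariance matrix (symmetric PSD).
#' @export
transform_covariance <- function(C, model = c("BM", "OU", "LA", "WN"),
                                 alpha = NULL, lambda = NULL,
                                 height = NULL, ultra_tol = 1e-6) {
  model <- match.arg(model)
  if (is.null(height)) height <- max(diag(C))
  switch(model,
    BM = C,
    LA = {
      if (is.null(lambda) || is.na(lambda) || lambda < 0 || lambda > 1)
        stop("LA requires lambda in [0, 1]")
      d <- diag(C)
      Cl <- lambda * C
      diag(Cl) <- d
      Cl
    },
    OU = {
      if (is.null(alpha) || is.na(alpha) || alpha <= 0)
        stop("OU requires alpha > 0")
      d <- diag(C)
      if ((max(d) - min(d)) > ultra_tol * max(d))
        stop("OU transform requires an ultrametric tree (relative tip-depth ",
             "spread ", signif((max(d) - min(d)) / max(d), 3), ")")
      ou_cov_entry(C, alpha, height)
    },
    WN = {
      W <- diag(height, nrow(C))
      dimnames(W) <- dimnames(C)
      W
    }
  )
}

# Fixed-root OU unit-rate covariance, applied elementwise to shared-path
# depths s: exp(-2a(T - s)) (1 - exp(-2a s)) / (2a). Works for matrices and
# for node-to-tip shared depths alike.
#' @keywords internal
ou_cov_entry <- function(s, alpha, height) {
  exp(-2 * alpha * (height - s)) * (1 - exp(-2 * alpha * s)) / (2 * alpha)
}
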
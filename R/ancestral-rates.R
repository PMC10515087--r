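# Ancestral reconstruction on the best-model-transformed covariance, absolute
# per-tip rates (trait change per My between a tip and its reconstructed
# ancestor), and the paired t-test on ln rates.

#' Reconstruct ancestral states under a fitted model
#'
#' Conditional-expectation (GLS) ancestral states: the tip covariance is
#' transformed per the fitted model, internal-node-to-tip covariances use the
#' same transform rule evaluated at the shared-path depth (the depth of the
#' MRCA of node and tip), and each internal node estimate is the BM
#' conditional mean `a_k = mu + c_k' C'^{-1} (x - mu)`. The root estimate is
#' the GLS mean. Under white noise every ancestor is the grand GLS mean.
#'
#' @param tree A `phylo` object.
#' @param x Named trait vector on the tree's tips.
#' @param fit A `model_fit` from [fit_trait_model()] on exactly this
#'   (tree, x).
#' @return Named numeric vector of ancestral states for internal nodes
#'   (names are ape node numbers, root first), with attribute `model`.
#' @export
reconstruct_ancestors <- function(tree, x, fit) {
  n <- length(tree$tip.label)
  if (!inherits(fit, "model_fit")) stop("fit must be a model_fit")
  if (fit$n_tips != n)
    stop("model fitted on ", fit$n_tips, " tips but tree has ", n)
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("trait values missing for some tips")
  nodes <- (n + 1L):(n + tree$Nnode)

  C <- phylo_vcv(tree)
  Tht <- max(diag(C))
  if (fit$model == "WN") {
    mu <- mean(x)  # GLS mean under T*I is the arithmetic mean
    anc <- stats::setNames(rep(mu, tree$Nnode), nodes)
    attr(anc, "model") <- "WN"
    return(anc)
  }
  Ct <- transform_covariance(C, fit$model, alpha = fit$alpha,
                             lambda = fit$lambda, height = Tht)
  fac <- chol_factor(Ct)
  g <- gls_profile(fac, as.numeric(x))
  # shared-path depths between each internal node and each tip
  M <- ape::mrca(tree, full = TRUE)
  d <- node_depths(tree)
  S <- matrix(d[M[nodes, seq_len(n), drop = FALSE]],
              nrow = length(nodes), ncol = n)
  Sx <- switch(fit$model,
    BM = S,
    LA = fit$lambda * S,
    OU = ou_cov_entry(S, fit$alpha, Tht))
  anc <- as.numeric(g$mu + Sx %*% chol_solve(fac, x - g$mu))
  anc[1L] <- g$mu  # root (first internal node in ape numbering)
  anc <- stats::setNames(anc, nodes)
  attr(anc, "model") <- fit$model
  anc
}

#' Absolute evolutionary rate at each tip
#'
#' For each species, the absolute difference between its trait value and the
#' reconstructed state of its immediate ancestor, divided by the divergence
#' time separating them: `|x_tip - a_parent| / t`, in trait units per My.
#'
#' By default `t` is the terminal branch length; `divergence = "age"` instead
#' uses the tip's root-to-tip age. Under a white-noise fit the ancestor of
#' every tip is the grand mean and `t` is the tip depth (star structure).
#' Tips on zero-length terminal branches are excluded and counted (attribute
#' `n_excluded_zero`), not dropped silently.
#'
#' @param tree A `phylo` object.
#' @param x Named trait vector.
#' @param anc Ancestral states from [reconstruct_ancestors()].
#' @param divergence `"terminal"` (default) or `"age"`.
#' @return A data frame of class `tip_rates` with columns `species`, `trait`
#'   (attribute-driven, default `"trait"`), `tip_value`, `ancestor_estimate`,
#'   `branch_time`, `abs_rate`, `model_used`.
#' @param trait_name Label for the `trait` column.
#' @export
tip_absolute_rates <- function(tree, x, anc, divergence = c("terminal", "age"),
                               trait_name = "trait") {
  divergence <- match.arg(divergence)
  n <- length(tree$tip.label)
  x <- x[tree$tip.label]
  model <- attr(anc, "model"); if (is.null(model)) model <- "BM"
  parent <- integer(n)
  tip_edge <- match(seq_len(n), tree$edge[, 2L])
  parent <- tree$edge[tip_edge, 1L]
  blen <- tree$edge.length[tip_edge]
  depths <- node_depths(tree)[seq_len(n)]
  if (model == "WN" || divergence == "age") {
    btime <- depths
  } else {
    btime <- blen
  }
  a_est <- as.numeric(anc[as.character(parent)])
  if (model == "WN") a_est <- rep(as.numeric(anc[1L]), n)
  keep <- btime > 0
  out <- data.frame(
    species = tree$tip.label[keep], trait = trait_name,
    tip_value = as.numeric(x)[keep], ancestor_estimate = a_est[keep],
    branch_time = btime[keep],
    abs_rate = abs(as.numeric(x)[keep] - a_est[keep]) / btime[keep],
    model_used = model, stringsAsFactors = FALSE)
  class(out) <- c("tip_rates", "data.frame")
  attr(out, "n_excluded_zero") <- sum(!keep)
  out
}

#' Paired t-test on log absolute rates
#'
#' Species-level paired comparison of two traits' absolute rates: for every
#' species with both rates strictly positive,
#' `d_s = ln(rate_A) - ln(rate_B)`; the test is a two-sided one-sample t-test
#' of `d` against zero with `m - 1` degrees of freedom. Zero rates are
#' excluded (ln undefined) and counted.
#'
#' Degenerate cases: all `d = 0` gives `t = 0, p = 1`; a constant nonzero
#' `d` (zero standard deviation) is reported with `p = 0` and
#' `degenerate = TRUE`.
#'
#' @param ratesA,ratesB `tip_rates` data frames (or any data frames with
#'   `species` and `abs_rate` columns).
#' @return Object of class `paired_rate_test` with fields `trait_A`,
#'   `trait_B`, `m`, `mean_ln_rate_A`, `mean_ln_rate_B`, `t_statistic`,
#'   `df`, `p_value`, `n_excluded_zero`, `degenerate`.
#' @export
paired_rate_test <- function(ratesA, ratesB) {
  tA <- if ("trait" %in% names(ratesA)) ratesA$trait[1L] else "A"
  tB <- if ("trait" %in% names(ratesB)) ratesB$trait[1L] else "B"
  m0 <- merge(ratesA[, c("species", "abs_rate")],
              ratesB[, c("species", "abs_rate")],
              by = "species", suffixes = c("_A", "_B"))
  pos <- m0$abs_rate_A > 0 & m0$abs_rate_B > 0
  n_zero <- sum(!pos)
  m0 <- m0[pos, , drop = FALSE]
  m <- nrow(m0)
  if (m < 3L)
    stop("fewer than 3 species with positive rates in both traits (", m, ")")
  lA <- log(m0$abs_rate_A); lB <- log(m0$abs_rate_B)
  d <- lA - lB
  sd_d <- stats::sd(d)
  degenerate <- FALSE
  # constant differences up to floating point: the t statistic is undefined
  if (sd_d <= 1e-12 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-12) { tstat <- 0; p <- 1 }
    else { tstat <- sign(mean(d)) * Inf; p <- 0; degenerate <- TRUE }
  } else {
    tstat <- mean(d) / (sd_d / sqrt(m))
    p <- 2 * stats::pt(abs(tstat), df = m - 1, lower.tail = FALSE)
  }
  structure(list(trait_A = tA, trait_B = tB, m = m,
                 mean_ln_rate_A = mean(lA), mean_ln_rate_B = mean(lB),
                 t_statistic = tstat, df = m - 1L, p_value = p,
                 n_excluded_zero = n_zero, degenerate = degenerate),
            class = "paired_rate_test")
}

#' @export
print.paired_rate_test <- function(x, ...) {
  cat(sprintf("Paired t-test on ln rates: %s vs %s (m = %d, %d zero-rate excluded)\n",
              x$trait_A, x$trait_B, x$m, x$n_excluded_zero))
  cat(sprintf("  mean ln rate: %.4f vs %.4f\n",
              x$mean_ln_rate_A, x$mean_ln_rate_B))
  cat(sprintf("  t = %.4f (df = %d), p = %.4g%s\n", x$t_statistic, x$df,
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
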
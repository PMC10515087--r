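# Phylogenetic generalized least squares: single-predictor regression whose
# residual covariance follows the tree, with Pagel's lambda either fixed
# (default 1, BM residuals) or profiled by ML.

#' Phylogenetic generalized least squares regression
#'
#' Fits `y ~ x` with residual covariance `V = C(lambda)` (off-diagonals of the
#' phylogenetic covariance scaled by lambda). Coefficients are the GLS
#' solution `(X'V^-1 X)^-1 X'V^-1 y`; the slope test uses
#' `t = slope / SE(slope)` with `n - 2` df and residual variance
#' `RSS_V / (n - 2)`. `R^2 = 1 - RSS_V / TSS_V`, where `TSS_V` is the GLS
#' residual sum of squares of the intercept-only model under the same `V`,
#' so the statistic stays coherent when `V != I`.
#'
#' @param tree A `phylo` object.
#' @param y,x Named numeric vectors (response, predictor) on a common species
#'   set present in the tree; pruning is handled internally.
#' @param lambda_mode `"fixed"` (use `lambda`) or `"ml"` (profile lambda on
#'   `[0, 1]` by maximizing the ML log-likelihood of the regression model).
#' @param lambda Fixed lambda value, default 1 (BM residuals).
#' @param response,predictor Labels carried into the result.
#' @return Object of class `pgls_fit`: `slope`, `intercept`, `R2`,
#'   `p_value` (slope, two-sided), `t_statistic`, `lambda_used`,
#'   `lambda_mode`, `n`, `response`, `predictor`.
#' @export
pgls_fit <- function(tree, y, x, lambda_mode = c("fixed", "ml"), lambda = 1,
                     response = "y", predictor = "x") {
  lambda_mode <- match.arg(lambda_mode)
  sp <- sort(intersect(intersect(names(y)[!is.na(y)], names(x)[!is.na(x)]),
                       tree$tip.label))
  if (length(sp) < 3L) stop("need at least 3 species; have ", length(sp))
  tr <- prune_to_taxa(tree, sp)
  yv <- y[tr$tip.label]; xv <- x[tr$tip.label]
  if (stats::var(xv) == 0) stop("zero-variance predictor")
  C <- phylo_vcv(tr)
  n <- length(sp)

  solve_gls <- function(lam) {
    V <- transform_covariance(C, "LA", lambda = lam)
    fac <- chol_factor(V)
    X <- cbind(1, as.numeric(xv))
    Vx <- apply(X, 2L, function(col) chol_solve(fac, col))
    XtVX <- crossprod(X, Vx)
    XtVy <- crossprod(Vx, as.numeric(yv))
    beta <- solve(XtVX, XtVy)
    resid <- as.numeric(yv) - X %*% beta
    rss <- sum(resid * chol_solve(fac, resid))
    # ML log-likelihood with profiled residual rate (for lambda search)
    s2 <- rss / n
    lnL <- -0.5 * (n * log(2 * pi * s2) + fac$logdet + n)
    list(beta = beta, rss = rss, XtVX = XtVX, fac = fac, lnL = lnL)
  }

  lam <- lambda
  if (lambda_mode == "ml") {
    f <- function(l) solve_gls(l)$lnL
    opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- rbind(c(opt$maximum, opt$objective), c(0, f(0)), c(1, f(1)))
    lam <- cand[which.max(cand[, 2]), 1L]
  } else {
    if (is.na(lam) || lam < 0 || lam > 1) stop("lambda must be in [0, 1]")
  }
  g <- solve_gls(lam)
  # intercept-only baseline under the same V for R^2
  one <- rep(1, n)
  Vi1 <- chol_solve(g$fac, one)
  mu <- sum(Vi1 * yv) / sum(Vi1)
  r0 <- as.numeric(yv) - mu
  tss <- sum(r0 * chol_solve(g$fac, r0))
  s2 <- g$rss / (n - 2)
  se <- sqrt(s2 * solve(g$XtVX)[2L, 2L])
  tstat <- g$beta[2L] / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(list(response = response, predictor = predictor,
                 slope = unname(g$beta[2L]), intercept = unname(g$beta[1L]),
                 R2 = 1 - g$rss / tss, t_statistic = unname(tstat),
                 p_value = unname(p), lambda_used = lam,
                 lambda_mode = lambda_mode, n = n),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS: %s ~ %s (n = %d, lambda = %.3f [%s])\n", x$response,
              x$predictor, x$n, x$lambda_used, x$lambda_mode))
  cat(sprintf("  slope = %.4g  intercept = %.4g  R2 = %.3f  p = %.4g\n",
              x$slope, x$intercept, x$R2, x$p_value))
  invisible(x)
}

#' Tolerance-vs-niche PGLS panels across hardening strata
#'
#' The six regression panels of the tolerance/niche analysis:
#' `T_min ~ MTCM` and `T_max ~ MTWM`, each fitted for all species, the
#' hardened stratum, and the non-hardened stratum, on the stratum's pruned
#' tree. Strata with fewer than 3 usable species are skipped with a message.
#'
#' @param table Species-level analysis table from
#'   [assemble_analysis_table()].
#' @param tree A `phylo` object.
#' @inheritParams pgls_fit
#' @return Data frame: `panel`, `stratum`, `n`, `slope`, `intercept`, `R2`,
#'   `p_value`, `lambda`.
#' @export
figure4_panels <- function(table, tree, lambda_mode = "fixed", lambda = 1) {
  pairs <- list(c("T_min", "MTCM"), c("T_max", "MTWM"))
  strata <- c("all", "hardened", "non_hardened")
  rows <- list()
  for (pr in pairs) for (st in strata) {
    sub <- if (st == "all") table else table[table$hardening == st, ]
    yv <- stats::setNames(sub[[pr[1L]]], sub$species)
    xv <- stats::setNames(sub[[pr[2L]]], sub$species)
    usable <- sum(!is.na(yv) & !is.na(xv) & names(yv) %in% tree$tip.label)
    lab <- paste0(pr[1L], "~", pr[2L])
    if (usable < 3L) {
      message("panel ", lab, " / ", st, " skipped (n = ", usable, ")")
      next
    }
    f <- pgls_fit(tree, yv, xv, lambda_mode = lambda_mode, lambda = lambda,
                  response = pr[1L], predictor = pr[2L])
    rows[[length(rows) + 1L]] <- data.frame(
      panel = lab, stratum = st, n = f$n, slope = f$slope,
      intercept = f$intercept, R2 = f$R2, p_value = f$p_value,
      lambda = f$lambda_used, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
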
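# GLS machinery shared by the model fits, the rate LRT, the ancestral
# reconstruction and PGLS. All likelihoods are full ML (divisor n), matching
# the rate-estimation convention used throughout the package; REML is offered
# where it matters via the `reml` flag.

# Cholesky factor with a single jitter retry: megatree polytomies can create
# numerically singular blocks. Returns list(R, logdet).
#' @keywords internal
chol_factor <- function(C) {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    jit <- 1e-10 * max(diag(C))
    R <- tryCatch(chol(C + diag(jit, nrow(C))), error = function(e) NULL)
    if (is.null(R))
      stop("covariance is singular even after jitter; condition estimate ",
           signif(kappa(C), 3))
  }
  list(R = R, logdet = 2 * sum(log(diag(R))))
}

# C^{-1} v through the Cholesky factor.
#' @keywords internal
chol_solve <- function(fac, v) {
  backsolve(fac$R, backsolve(fac$R, v, transpose = TRUE))
}

# Profile GLS under covariance structure C (unit rate): GLS mean, residual
# quadratic form Q, ML rate Q/n, and the maximized log-likelihood.
#' @keywords internal
gls_profile <- function(fac, x, reml = FALSE) {
  n <- length(x)
  one <- rep(1, n)
  Ci1 <- chol_solve(fac, one)
  Cix <- chol_solve(fac, x)
  mu <- sum(Ci1 * x) / sum(Ci1)
  r <- x - mu
  Q <- sum(r * chol_solve(fac, r))
  if (reml) {
    sigma2 <- Q / (n - 1)
    lnL <- -0.5 * ((n - 1) * log(2 * pi * sigma2) + fac$logdet +
                     log(sum(Ci1)) + (n - 1))
  } else {
    sigma2 <- Q / n
    lnL <- if (sigma2 > 0)
      -0.5 * (n * log(2 * pi * sigma2) + fac$logdet + n)
    else NA_real_
  }
  list(mu = mu, Q = Q, sigma2 = sigma2, lnL = lnL, n = n)
}

#' Brownian-motion log-likelihood and rate by maximum likelihood
#'
#' Closed-form ML estimates for a single continuous trait under Brownian
#' motion with covariance structure `C`: the GLS root state
#' \eqn{\hat\mu = (1'C^{-1}1)^{-1} 1'C^{-1}x}, the rate
#' \eqn{\hat\sigma^2 = (x-\hat\mu)'C^{-1}(x-\hat\mu)/n} (ML divisor `n`), and
#' \eqn{\ln L = -\frac12[n\ln(2\pi\hat\sigma^2) + \ln|C| + n]}.
#'
#' @param C Phylogenetic covariance from [phylo_vcv()] (possibly transformed).
#' @param x Named numeric trait vector; names must match `rownames(C)` (any
#'   order).
#' @param reml Use REML (divisor `n - 1` and the REML likelihood) instead of
#'   ML. Default `FALSE`.
#' @return A list with `lnL`, `sigma2`, `root`, `n`, and `degenerate` (`TRUE`
#'   for a constant trait, where `sigma2 = 0` and `lnL` is `NA`).
#' @export
bm_loglik <- function(C, x, reml = FALSE) {
  x <- align_trait(C, x)
  if (length(x) < 2L) stop("need at least two species")
  fac <- chol_factor(C)
  g <- gls_profile(fac, x, reml = reml)
  list(lnL = g$lnL, sigma2 = g$sigma2, root = g$mu, n = g$n,
       degenerate = g$sigma2 <= 0)
}

# Reorder a named trait vector to the covariance's species order.
#' @keywords internal
align_trait <- function(C, x) {
  sp <- rownames(C)
  if (!is.null(names(x)) && !is.null(sp)) {
    miss <- setdiff(sp, names(x))
    if (length(miss))
      stop("trait values missing for: ", paste(utils::head(miss, 5),
                                               collapse = ", "))
    x <- x[sp]
  } else if (length(x) != nrow(C)) {
    stop("trait length does not match covariance dimension")
  }
  if (anyNA(x)) stop("trait vector contains NA")
  as.numeric(stats::setNames(x, sp))
}

#' Fit a continuous-trait evolutionary model by maximum likelihood
#'
#' Fits one of Brownian motion (`BM`), single-optimum Ornstein-Uhlenbeck
#' (`OU`), Pagel's lambda (`LA`) or white noise (`WN`) to a trait on a
#' phylogeny. BM and WN have closed-form ML solutions; for OU and LA the
#' single shape parameter is profiled by a bounded one-dimensional search
#' (log-spaced grid plus local refinement for α; direct bounded optimization
#' plus endpoint checks for λ), with σ² and the root state profiled
#' analytically at every candidate.
#'
#' α is searched on `[1e-8/T, 50/T]` (T = tree height) so the OU family spans
#' effectively-BM to effectively-white-noise; λ on `[0, 1]`.
#'
#' @param tree A `phylo` object.
#' @param x Named trait vector (names = tip labels).
#' @param model One of `"BM"`, `"OU"`, `"LA"`, `"WN"`.
#' @param reml Use REML instead of ML (default `FALSE`).
#' @param tol Convergence tolerance on the shape parameter.
#' @return An object of class `model_fit`: model, `sigma2` (trait²/My),
#'   `root_state`, `alpha` (OU), `lambda` (LA), `lnL`, `k`, `AIC`
#'   (`2k - 2 lnL`, k = 2 for BM/WN, 3 for OU/LA), `n_tips`, `valid`.
#'   A constant trait yields `sigma2 = 0`, `valid = FALSE` and `NA`
#'   likelihood so batch pipelines can skip and log rather than fail.
#' @export
fit_trait_model <- function(tree, x, model = c("BM", "OU", "LA", "WN"),
                            reml = FALSE, tol = 1e-8) {
  model <- match.arg(model)
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("trait values missing for some tips")
  n <- length(x)
  if (model %in% c("OU", "LA") && n < 4L)
    stop(model, " fit needs at least 4 tips (3 free parameters)")
  C <- phylo_vcv(tree)
  Tht <- max(diag(C))
  k <- if (model %in% c("BM", "WN")) 2L else 3L

  if (stats::var(x) == 0) {
    return(new_model_fit(model, sigma2 = 0, root_state = x[[1L]],
                         alpha = NA_real_, lambda = NA_real_,
                         lnL = NA_real_, k = k, n_tips = n, valid = FALSE))
  }

  profile_at <- function(Cm) {
    gls_profile(chol_factor(Cm), as.numeric(x), reml = reml)
  }

  if (model == "BM") {
    g <- profile_at(C)
    return(new_model_fit("BM", g$sigma2, g$mu, NA_real_, NA_real_,
                         g$lnL, k, n, TRUE))
  }
  if (model == "WN") {
    g <- profile_at(transform_covariance(C, "WN", height = Tht))
    return(new_model_fit("WN", g$sigma2, g$mu, NA_real_, NA_real_,
                         g$lnL, k, n, TRUE))
  }
  if (model == "LA") {
    f <- function(l) profile_at(transform_covariance(C, "LA", lambda = l))$lnL
    opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = tol)
    cand <- rbind(c(opt$maximum, opt$objective), c(0, f(0)), c(1, f(1)))
    best <- cand[which.max(cand[, 2]), ]
    g <- profile_at(transform_covariance(C, "LA", lambda = best[1]))
    return(new_model_fit("LA", g$sigma2, g$mu, NA_real_, best[1],
                         g$lnL, k, n, TRUE))
  }
  # OU: log grid then refinement between the best point's neighbours
  lo <- 1e-8 / Tht; hi <- 50 / Tht
  grid <- exp(seq(log(lo), log(hi), length.out = 30L))
  fou <- function(a)
    profile_at(transform_covariance(C, "OU", alpha = a, height = Tht))$lnL
  vals <- vapply(grid, fou, numeric(1))
  i <- which.max(vals)
  bl <- grid[max(1L, i - 1L)]; bh <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(fou, c(bl, bh), maximum = TRUE,
                         tol = max(tol, 1e-12 * Tht))
  a_hat <- if (opt$objective >= vals[i]) opt$maximum else grid[i]
  g <- profile_at(transform_covariance(C, "OU", alpha = a_hat, height = Tht))
  new_model_fit("OU", g$sigma2, g$mu, a_hat, NA_real_, g$lnL, k, n, TRUE)
}

#' @keywords internal
new_model_fit <- function(model, sigma2, root_state, alpha, lambda,
                          lnL, k, n_tips, valid) {
  structure(list(model = model, sigma2 = unname(sigma2),
                 root_state = unname(root_state), alpha = alpha,
                 lambda = lambda, lnL = unname(lnL),
                 AIC = if (is.na(lnL)) NA_real_ else 2 * k - 2 * lnL,
                 k = k, n_tips = n_tips, valid = valid),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Model fit: %s on %d tips%s\n", x$model, x$n_tips,
              if (!x$valid) " [degenerate]" else ""))
  cat(sprintf("  sigma2 = %.6g  root = %.6g  lnL = %.4f  AIC = %.4f\n",
              x$sigma2, x$root_state, x$lnL, x$AIC))
  if (x$model == "OU") cat(sprintf("  alpha  = %.6g\n", x$alpha))
  if (x$model == "LA") cat(sprintf("  lambda = %.6g\n", x$lambda))
  invisible(x)
}

#' @export
as.data.frame.model_fit <- function(x, ...) {
  data.frame(model = x$model, sigma2 = x$sigma2, root_state = x$root_state,
             alpha = x$alpha, lambda = x$lambda, lnL = x$lnL, AIC = x$AIC,
             k = x$k, n_tips = x$n_tips, valid = x$valid)
}

#' Fit all four models to one trait
#'
#' Convenience wrapper running [fit_trait_model()] for BM, OU, LA and WN
#' (OU/LA skipped with a message below 4 tips).
#'
#' @inheritParams fit_trait_model
#' @return A named list of `model_fit` objects.
#' @export
fit_all_models <- function(tree, x, reml = FALSE) {
  models <- c("BM", "WN", if (length(tree$tip.label) >= 4L) c("LA", "OU"))
  stats::setNames(lapply(models, function(m)
    fit_trait_model(tree, x, m, reml = reml)), models)
}

#' Select the best model by AIC
#'
#' Returns the fit with the lowest AIC. Exact ties are broken by fewer free
#' parameters, then by the fixed model order BM < WN < LA < OU.
#'
#' @param fits A (possibly named) list of `model_fit` objects on identical
#'   data.
#' @return The winning `model_fit`.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied")
  fits <- Filter(function(f) f$valid && !is.na(f$AIC), fits)
  if (length(fits) == 0L) stop("no valid fits to select from")
  ord <- c(BM = 1L, WN = 2L, LA = 3L, OU = 4L)
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  kk <- vapply(fits, `[[`, integer(1), "k")
  mo <- ord[vapply(fits, `[[`, character(1), "model")]
  fits[[order(aic, kk, mo)[1L]]]
}
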
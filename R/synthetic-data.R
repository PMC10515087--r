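# Seeded generators: Yule trees, correlated traits on trees (exact
# covariance factorization plus an independent branchwise simulator used as a
# cross-check oracle), and a full scenario emulating the structure of the
# real analysis — fast-evolving cold tolerance, slower coupled cold niche,
# near-equal heat tolerance and warm niche, hardening strata with different
# regimes, occurrence clouds on smooth climate surfaces.

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Pure-birth tree conditioned on the number of tips, optionally rescaled to
#' a stated height so branch lengths carry My units compatible with °C²/My
#' rates.
#'
#' @param n Number of tips (≥ 2).
#' @param birth_rate Speciation rate (1/My).
#' @param seed Optional RNG seed for reproducibility.
#' @param height Rescale the tree to this total height (My); `NULL` keeps the
#'   simulated height.
#' @return A `phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n, birth_rate = 0.1, seed = NULL,
                               height = NULL) {
  if (n < 2L || birth_rate <= 0) stop("need n >= 2 and birth_rate > 0")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = birth_rate, death = 0)
  if (!is.null(height)) {
    tr$edge.length <- tr$edge.length * (height / tree_height(tr))
  }
  tr
}

#' Simulate two correlated traits under Brownian motion on a tree
#'
#' Exact draw from the 2n-dimensional normal with covariance
#' `[[s2A*C, rho*sqrt(s2A*s2B)*C], [., s2B*C]]` via Cholesky factorization of
#' the tree covariance and of the 2x2 trait covariance (matrix-normal
#' construction).
#'
#' @param tree A `phylo` object.
#' @param sigma2A,sigma2B Rates (trait²/My), `> 0`.
#' @param rho Between-trait correlation in `[-1, 1]`.
#' @param rootA,rootB Root states.
#' @param seed Optional RNG seed.
#' @return List with named vectors `A` and `B`.
#' @export
simulate_bivariate_traits <- function(tree, sigma2A, sigma2B, rho = 0,
                                      rootA = 0, rootB = 0, seed = NULL) {
  if (sigma2A <= 0 || sigma2B <= 0) stop("rates must be positive")
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_vcv(tree)
  n <- nrow(C)
  Rc <- chol_factor(C)$R
  # closed-form upper Cholesky of the 2x2 trait covariance (exact at |rho|=1)
  sA <- sqrt(sigma2A); sB <- sqrt(sigma2B)
  Rt <- rbind(c(sA, rho * sB), c(0, sB * sqrt(max(0, 1 - rho^2))))
  Z <- matrix(stats::rnorm(2L * n), n, 2L)
  X <- crossprod(Rc, Z) %*% Rt  # cov(vec X) = Sig (x) C
  list(A = stats::setNames(rootA + X[, 1L], rownames(C)),
       B = stats::setNames(rootB + X[, 2L], rownames(C)))
}

#' Simulate a trait under a fixed-root Ornstein-Uhlenbeck process
#'
#' Multivariate-normal draw with the fixed-root OU covariance used by the
#' likelihoods (see [transform_covariance()]), root fixed at the optimum.
#'
#' @param tree Ultrametric `phylo`.
#' @param sigma2 Diffusion rate (`> 0`).
#' @param alpha Attraction strength (`> 0`, 1/My).
#' @param optimum Optimum (and root) value.
#' @param seed Optional RNG seed.
#' @return Named trait vector.
#' @export
simulate_ou_traits <- function(tree, sigma2, alpha, optimum = 0,
                               seed = NULL) {
  if (sigma2 <= 0 || alpha <= 0) stop("sigma2 and alpha must be positive")
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_vcv(tree)
  Ct <- sigma2 * transform_covariance(C, "OU", alpha = alpha)
  R <- chol_factor(Ct)$R
  z <- stats::rnorm(nrow(C))
  stats::setNames(optimum + as.numeric(crossprod(R, z)), rownames(C))
}

#' Branchwise Brownian-motion simulator (cross-check oracle)
#'
#' Independent of the covariance-factorization path: walks the tree from the
#' root adding a `N(0, sigma2 * branch_length)` increment on every branch.
#' Used to cross-validate the exact-covariance simulator and the likelihoods.
#'
#' @param tree A `phylo` object.
#' @param sigma2 Rate (`> 0`).
#' @param root Root state.
#' @param seed Optional RNG seed.
#' @return Named tip-trait vector.
#' @export
simulate_bm_branchwise <- function(tree, sigma2, root = 0, seed = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  state <- numeric(n + tree$Nnode)
  state[n + 1L] <- root
  ord <- rev(ape::postorder(tree))  # parent-before-child edge order
  inc <- stats::rnorm(nrow(tree$edge), 0,
                      sqrt(sigma2 * tree$edge.length))
  for (e in ord)
    state[tree$edge[e, 2L]] <- state[tree$edge[e, 1L]] + inc[e]
  stats::setNames(state[seq_len(n)], tree$tip.label)
}

#' Scenario configuration
#'
#' The stated world of the synthetic analysis scenario: defaults emulate the
#' structure of the real dataset — cold tolerance (`T_min`) evolving fast in
#' hardened species and slowly in non-hardened ones, the cold niche (`MTCM`)
#' coupled to it (tightly when hardened, weakly otherwise) with slower BM
#' noise, and heat tolerance / warm niche (`T_max`/`MTWM`) evolving at
#' near-equal modest rates. Occurrences are Gaussian clouds positioned so the
#' climate surfaces return each species' niche.
#'
#' @param n_species Number of species (tips).
#' @param birth_rate Yule speciation rate (1/My).
#' @param height Tree height (My).
#' @param prop_hardening Proportions of hardened / non-hardened / unknown.
#' @param prop_group Proportions of angiosperm / gymnosperm / fern.
#' @param root Root states (°C) for T_min, T_max, MTCM, MTWM.
#' @param sigma2_T_min Per-stratum BM rates of T_min (°C²/My).
#' @param sigma2_T_max Per-stratum BM rates of T_max.
#' @param coupling_MTCM Per-stratum slope of MTCM on T_min.
#' @param noise_MTCM Per-stratum BM rate of the MTCM residual.
#' @param coupling_MTWM Slope of MTWM on T_max (all strata).
#' @param noise_MTWM BM rate of the MTWM residual.
#' @param rho Correlation between the T_min and T_max latent BMs.
#' @param n_occ_per_species Occurrences per species.
#' @param occ_sd SD (degrees) of each species' occurrence cloud.
#' @param grid Extent and linear-gradient coefficients of the Bio5/Bio6
#'   surfaces (`bio = intercept + lat_slope*lat + lon_slope*lon`).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(
    n_species = 300L, birth_rate = 0.1, height = 60,
    prop_hardening = c(hardened = 0.5, non_hardened = 0.2, unknown = 0.3),
    prop_group = c(angiosperm = 0.7, gymnosperm = 0.1, fern = 0.2),
    root = c(T_min = -12, T_max = 46, MTCM = -5, MTWM = 28),
    sigma2_T_min = c(hardened = 1.0, non_hardened = 0.05, unknown = 0.3),
    sigma2_T_max = c(hardened = 0.05, non_hardened = 0.05, unknown = 0.05),
    coupling_MTCM = c(hardened = 0.25, non_hardened = 0.5, unknown = 0.3),
    noise_MTCM = c(hardened = 0.04, non_hardened = 0.08, unknown = 0.06),
    coupling_MTWM = 0.2, noise_MTWM = 0.048, rho = 0,
    n_occ_per_species = 25L, occ_sd = 2,
    grid = list(xll = 0, yll = 0, cellsize = 0.5, ncols = 40, nrows = 120,
                bio6 = c(intercept = 22, lat_slope = -0.6, lon_slope = 0),
                bio5 = c(intercept = 33, lat_slope = -0.2,
                         lon_slope = 0.4))) {
  cfg <- list(n_species = as.integer(n_species), birth_rate = birth_rate,
              height = height, prop_hardening = prop_hardening,
              prop_group = prop_group, root = root,
              sigma2_T_min = sigma2_T_min, sigma2_T_max = sigma2_T_max,
              coupling_MTCM = coupling_MTCM, noise_MTCM = noise_MTCM,
              coupling_MTWM = coupling_MTWM, noise_MTWM = noise_MTWM,
              rho = rho, n_occ_per_species = as.integer(n_occ_per_species),
              occ_sd = occ_sd, grid = grid)
  stopifnot(all(sigma2_T_min > 0), all(sigma2_T_max > 0),
            all(noise_MTCM > 0), noise_MTWM > 0, abs(rho) <= 1)
  if (abs(sum(prop_hardening) - 1) > 1e-8)
    stop("hardening proportions must sum to 1")
  if (abs(sum(prop_group) - 1) > 1e-8)
    stop("group proportions must sum to 1")
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate a full synthetic analysis scenario
#'
#' Produces every input the pipeline consumes: an ultrametric tree, a
#' species-level trait table with hardening and group strata, per-occurrence
#' climate records sampled from smooth gradient surfaces, the Bio5/Bio6
#' grids, and the true niche values. A pure function of (config, seed).
#'
#' Within each hardening stratum, `T_min` is Brownian with the stratum's
#' rate (one shared latent BM scaled per stratum, so within-stratum analyses
#' see exact BM at the stated rate); `MTCM = root + a_s*(T_min - root) +
#' BM noise`, giving the stratum-dependent coupling and a slower niche rate.
#' `T_max`/`MTWM` are built the same way with near-equal rates.
#'
#' @param config A [scenario_config()].
#' @param seed RNG seed (one seed drives the whole scenario).
#' @return List: `tree`, `traits` (trait table), `occurrences`, `grid`
#'   (list of `bio5`, `bio6` [climate_grid]s), `niche_true`, `config`,
#'   `seed`.
#' @export
make_study_scenario <- function(config = scenario_config(), seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  n <- config$n_species
  tree <- simulate_yule_tree(n, config$birth_rate, height = config$height)
  sp <- tree$tip.label
  strata <- sample(names(config$prop_hardening), n, replace = TRUE,
                   prob = config$prop_hardening)
  groups <- sample(names(config$prop_group), n, replace = TRUE,
                   prob = config$prop_group)

  C <- phylo_vcv(tree)
  Rc <- chol_factor(C)$R
  unit_bm <- function() as.numeric(crossprod(Rc, stats::rnorm(n)))
  u_min <- unit_bm()
  u_max0 <- unit_bm()
  u_max <- config$rho * u_min + sqrt(1 - config$rho^2) * u_max0
  e_ctm <- unit_bm()
  e_wtm <- unit_bm()

  s_min <- sqrt(config$sigma2_T_min[strata])
  s_max <- sqrt(config$sigma2_T_max[strata])
  T_min <- config$root[["T_min"]] + s_min * u_min
  T_max <- config$root[["T_max"]] + s_max * u_max
  MTCM <- config$root[["MTCM"]] +
    config$coupling_MTCM[strata] * (T_min - config$root[["T_min"]]) +
    sqrt(config$noise_MTCM[strata]) * e_ctm
  MTWM <- config$root[["MTWM"]] +
    config$coupling_MTWM * (T_max - config$root[["T_max"]]) +
    sqrt(config$noise_MTWM) * e_wtm

  g <- config$grid
  bio6_fun <- function(lo, la)
    g$bio6[["intercept"]] + g$bio6[["lat_slope"]] * la +
      g$bio6[["lon_slope"]] * lo
  bio5_fun <- function(lo, la)
    g$bio5[["intercept"]] + g$bio5[["lat_slope"]] * la +
      g$bio5[["lon_slope"]] * lo
  grid_bio6 <- make_climate_grid(g$xll, g$yll, g$cellsize, g$ncols, g$nrows,
                                 bio6_fun)
  grid_bio5 <- make_climate_grid(g$xll, g$yll, g$cellsize, g$ncols, g$nrows,
                                 bio5_fun)
  xmax <- g$xll + g$ncols * g$cellsize
  ymax <- g$yll + g$nrows * g$cellsize
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  # place each species so the surfaces return its niche values
  lat_c <- clamp((MTCM - g$bio6[["intercept"]]) / g$bio6[["lat_slope"]],
                 g$yll + g$cellsize, ymax - g$cellsize)
  lon_c <- clamp((MTWM - g$bio5[["intercept"]] -
                    g$bio5[["lat_slope"]] * lat_c) / g$bio5[["lon_slope"]],
                 g$xll + g$cellsize, xmax - g$cellsize)
  m <- config$n_occ_per_species
  occ <- data.frame(
    species = rep(sp, each = m),
    longitude = clamp(stats::rnorm(n * m, rep(lon_c, each = m),
                                   config$occ_sd),
                      g$xll + g$cellsize / 2, xmax - g$cellsize / 2),
    latitude = clamp(stats::rnorm(n * m, rep(lat_c, each = m),
                                  config$occ_sd),
                     g$yll + g$cellsize / 2, ymax - g$cellsize / 2),
    stringsAsFactors = FALSE)
  occ$bio5 <- extract_grid_values(grid_bio5, occ$longitude, occ$latitude)
  occ$bio6 <- extract_grid_values(grid_bio6, occ$longitude, occ$latitude)

  traits <- data.frame(species = sp, T_min = unname(T_min),
                       T_max = unname(T_max), hardening = strata,
                       group = groups, stringsAsFactors = FALSE)
  niche_true <- data.frame(species = sp, MTCM = unname(MTCM),
                           MTWM = unname(MTWM), stringsAsFactors = FALSE)
  list(tree = tree, traits = traits, occurrences = occ,
       grid = list(bio5 = grid_bio5, bio6 = grid_bio6),
       niche_true = niche_true, config = config, seed = seed)
}

#' Write a scenario to pipeline input files
#'
#' Emits `tree.nwk`, `traits.tsv`, `occurrences.tsv`, `bio5.asc`,
#' `bio6.asc`, and a `manifest.txt` recording the seed and key parameters.
#' Output is byte-identical for the same (config, seed).
#'
#' @param scenario Result of [make_study_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(scenario$tree, file.path(dir, "tree.nwk"))
  write_table_tsv(scenario$traits, file.path(dir, "traits.tsv"))
  write_table_tsv(scenario$occurrences, file.path(dir, "occurrences.tsv"))
  write_esri_grid(scenario$grid$bio5, file.path(dir, "bio5.asc"))
  write_esri_grid(scenario$grid$bio6, file.path(dir, "bio6.asc"))
  cfg <- scenario$config
  keyvals <- c(
    paste0("seed=", scenario$seed),
    paste0("n_species=", cfg$n_species),
    paste0("birth_rate=", cfg$birth_rate),
    paste0("height=", cfg$height),
    paste0("sigma2_T_min=", paste(cfg$sigma2_T_min, collapse = ",")),
    paste0("sigma2_T_max=", paste(cfg$sigma2_T_max, collapse = ",")))
  writeLines(keyvals, file.path(dir, "manifest.txt"))
  invisible(dir)
}
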
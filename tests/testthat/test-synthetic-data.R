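test_that("Yule simulation is conditioned, ultrametric, reproducible", {
  expect_equal(length(simulate_yule_tree(2, 0.5, seed = 1)$tip.label), 2L)
  t1 <- simulate_yule_tree(40, 0.2, seed = 7)
  t2 <- simulate_yule_tree(40, 0.2, seed = 7)
  expect_identical(write_newick(t1), write_newick(t2))
  for (s in 1:20) {
    tr <- simulate_yule_tree(sample(10:200, 1), 0.1, seed = s)
    expect_true(is_ultrametric_tol(tr, tol = 1e-8))
  }
  # expected (unscaled) height grows with n at fixed birth rate
  h_small <- mean(vapply(1:20, function(s)
    tree_height(simulate_yule_tree(20, 0.1, seed = s)), numeric(1)))
  h_big <- mean(vapply(1:20, function(s)
    tree_height(simulate_yule_tree(400, 0.1, seed = 100 + s)), numeric(1)))
  expect_gt(h_big, h_small)
  # rescaling pins the height
  expect_equal(tree_height(simulate_yule_tree(50, 0.1, seed = 3,
                                              height = 60)), 60)
  expect_error(simulate_yule_tree(1, 0.1), "n >= 2")
})

test_that("bivariate simulation hits the requested covariance", {
  tr <- rand_ultra(30)
  xy <- simulate_bivariate_traits(tr, 2, 2, rho = 1, rootA = 0, rootB = 5,
                                  seed = 2)
  expect_equal(unname(xy$A - mean(xy$A)), unname(xy$B - mean(xy$B)),
               tolerance = 1e-6)

  # rho = 0: contrasts cross-correlation near zero
  big <- rand_ultra(300)
  xy0 <- simulate_bivariate_traits(big, 1, 1, rho = 0, seed = 3)
  r <- stats::cor(ape::pic(xy0$A, big), ape::pic(xy0$B, big))
  expect_lt(abs(r), 0.15)

  # replicate sample covariance converges to the target (Frobenius)
  tr8 <- rand_ultra(8)
  C8 <- phylo_vcv(tr8)
  set.seed(4)
  draws <- t(replicate(2000,
    as.numeric(simulate_bivariate_traits(tr8, 2, 1, rho = 0.5)$A)))
  S <- stats::cov(draws) * (1999 / 2000)
  target <- 2 * C8[colnames(C8), colnames(C8)]
  expect_lt(norm(S - target, "F") / norm(target, "F"), 0.1)

  expect_error(simulate_bivariate_traits(tr, -1, 1), "positive")
  expect_error(simulate_bivariate_traits(tr, 1, 1, rho = 1.2), "rho")
})

test_that("branchwise BM oracle agrees with the factorized simulator", {
  tr8 <- rand_ultra(8)
  C8 <- phylo_vcv(tr8)
  set.seed(9)
  draws <- t(replicate(2000, as.numeric(
    simulate_bm_branchwise(tr8, 1.5)[rownames(C8)])))
  S <- stats::cov(draws) * (1999 / 2000)
  expect_lt(norm(S - 1.5 * C8, "F") / norm(1.5 * C8, "F"), 0.1)
})

test_that("OU simulation matches its stationary and BM limits", {
  tr <- rand_ultra(10)
  tr$edge.length <- tr$edge.length / tree_height(tr)
  expect_identical(simulate_ou_traits(tr, 1, 2, seed = 5),
                   simulate_ou_traits(tr, 1, 2, seed = 5))

  # large alpha: tip variance ~ sigma2 / (2 alpha)
  set.seed(6)
  a <- 25  # alpha * T = 25
  tips <- replicate(800, as.numeric(simulate_ou_traits(tr, 2, a)))
  expect_equal(stats::var(as.numeric(tips)), 2 / (2 * a),
               tolerance = 0.15)

  # tiny alpha behaves like BM in likelihood terms
  set.seed(7)
  gaps <- replicate(20, {
    x <- simulate_ou_traits(tr, 1, 1e-6)
    abs(fit_trait_model(tr, x, "BM")$lnL -
          bm_loglik(phylo_vcv(tr), x)$lnL)
  })
  expect_lt(max(gaps), 1e-6)
})

test_that("scenarios are deterministic down to the written bytes", {
  cfg <- scenario_config(n_species = 60)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(make_study_scenario(cfg, seed = 11), d1)
  write_scenario(make_study_scenario(cfg, seed = 11), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  d3 <- withr::local_tempdir()
  write_scenario(make_study_scenario(cfg, seed = 12), d3)
  expect_false(identical(readLines(file.path(d1, "traits.tsv")),
                         readLines(file.path(d3, "traits.tsv"))))
})

test_that("scenario structure matches its stated world", {
  sc <- make_study_scenario(scenario_config(n_species = 120), seed = 2)
  expect_equal(nrow(sc$traits), 120L)
  expect_true(all(sc$occurrences$bio5 >= sc$occurrences$bio6))
  expect_false(anyNA(sc$occurrences$bio5))
  expect_setequal(unique(sc$traits$hardening),
                  c("hardened", "non_hardened", "unknown"))
  # summarized niche tracks the generating niche values
  ni <- summarize_niche(sc$occurrences)
  m <- merge(ni, sc$niche_true, by = "species")
  expect_gt(stats::cor(m$mean_MTCM, m$MTCM), 0.95)
  expect_gt(stats::cor(m$mean_MTWM, m$MTWM), 0.9)
  expect_error(scenario_config(prop_hardening = c(hardened = 0.9,
                                                  non_hardened = 0.2,
                                                  unknown = 0.2)),
               "sum to 1")
})
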
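test_that("two-tip reconstruction is the inverse-branch-length mean", {
  tr <- parse_newick("(A:1,B:3);")
  x <- c(A = 0, B = 4)
  fit <- fit_trait_model(tr, x, "BM")
  anc <- reconstruct_ancestors(tr, x, fit)
  expect_equal(unname(anc[1]), 1)  # (0/1 + 4/3) / (1/1 + 1/3)
  rates <- tip_absolute_rates(tr, x, anc)
  expect_equal(rates$abs_rate[rates$species == "A"], 1)
  expect_equal(rates$abs_rate[rates$species == "B"], 1)
})

test_that("constant traits reconstruct constant ancestors, zero rates", {
  tr <- rand_ultra(8)
  x <- named_trait(tr, rep(4.2, 8))
  for (m in c("BM", "WN")) {
    fit <- fit_trait_model(tr, x, m)
    anc <- reconstruct_ancestors(tr, x, fit)
    expect_equal(as.numeric(anc), rep(4.2, tr$Nnode))
    expect_true(all(tip_absolute_rates(tr, x, anc)$abs_rate == 0))
  }
})

test_that("ancestral estimates equal dense conditional-MVN means", {
  for (s in 1:8) {
    set.seed(s)
    tr <- if (s %% 2) rand_tree(7) else rand_ultra(7)
    x <- simulate_bm_branchwise(tr, 1.3, seed = s)
    fit <- fit_trait_model(tr, x, "BM")
    anc <- reconstruct_ancestors(tr, x, fit)
    J <- brute_joint_cov(tr)
    n <- 7L
    idx_t <- seq_len(n)
    for (k in seq_len(tr$Nnode - 1L) + 1L) {  # non-root internal nodes
      node <- n + k
      cond <- fit$root_state +
        J[node, idx_t] %*% solve(J[idx_t, idx_t],
                                 as.numeric(x) - fit$root_state)
      expect_equal(unname(anc[as.character(node)]), as.numeric(cond),
                   tolerance = 1e-8)
    }
    expect_equal(unname(anc[1]), fit$root_state)
  }
})

test_that("reconstruction invariances hold", {
  tr <- rand_ultra(12)
  x <- simulate_bm_branchwise(tr, 1, seed = 31)
  fit <- fit_trait_model(tr, x, "BM")
  anc <- reconstruct_ancestors(tr, x, fit)

  # shifting the trait shifts the states, leaves rates unchanged
  fit2 <- fit_trait_model(tr, x + 50, "BM")
  anc2 <- reconstruct_ancestors(tr, x + 50, fit2)
  expect_equal(unname(anc2), unname(anc) + 50, tolerance = 1e-8)
  expect_equal(tip_absolute_rates(tr, x + 50, anc2)$abs_rate,
               tip_absolute_rates(tr, x, anc)$abs_rate, tolerance = 1e-8)

  # lambda = 1 reconstruction equals BM exactly
  fla <- fit
  fla$model <- "LA"; fla$lambda <- 1
  expect_equal(reconstruct_ancestors(tr, x, fla), anc,
               ignore_attr = TRUE, tolerance = 1e-12)

  # mismatched fit is rejected
  expect_error(reconstruct_ancestors(rand_ultra(5),
                                     named_trait(rand_ultra(5), rnorm(5)),
                                     fit), "fitted on")
})

test_that("WN reconstruction collapses to the grand mean on tip depths", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(2, 6)
  x <- named_trait(star, c(1, 2, 3, 4, 5, 9))
  fit <- fit_trait_model(star, x, "WN")
  anc <- reconstruct_ancestors(star, x, fit)
  expect_equal(as.numeric(anc), 4)
  rates <- tip_absolute_rates(star, x, anc)
  expect_equal(rates$abs_rate, abs(as.numeric(x) - 4) / 2)
  expect_equal(rates$branch_time, rep(2, 6))
})

test_that("zero-length terminal branches are excluded and counted", {
  tr <- parse_newick("((A:0,B:1):1,C:2);")
  x <- c(A = 1, B = 2, C = 3)
  fit <- fit_trait_model(tr, x, "BM")
  rates <- tip_absolute_rates(tr, x, reconstruct_ancestors(tr, x, fit))
  expect_equal(attr(rates, "n_excluded_zero"), 1L)
  expect_false("A" %in% rates$species)
})

test_that("tip rates shrink with terminal branch length under BM", {
  set.seed(17)
  rhos <- replicate(30, {
    tr <- rand_ultra(256)
    x <- simulate_bm_branchwise(tr, 1)
    fit <- fit_trait_model(tr, x, "BM")
    r <- tip_absolute_rates(tr, x, reconstruct_ancestors(tr, x, fit))
    stats::cor(r$branch_time, r$abs_rate, method = "spearman")
  })
  expect_lt(stats::median(rhos), 0)
  expect_gt(mean(rhos < 0), 0.9)
})

test_that("paired ln-rate t-test handles regular and degenerate input", {
  tr <- rand_ultra(50)
  x <- simulate_bm_branchwise(tr, 1, seed = 8)
  fit <- fit_trait_model(tr, x, "BM")
  r <- tip_absolute_rates(tr, x, reconstruct_ancestors(tr, x, fit))

  same <- paired_rate_test(r, r)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  re <- r; re$abs_rate <- exp(1) * re$abs_rate
  shifted <- paired_rate_test(re, r)
  expect_true(shifted$degenerate)
  expect_equal(shifted$p_value, 0)
  expect_equal(shifted$mean_ln_rate_A - shifted$mean_ln_rate_B, 1)

  expect_error(paired_rate_test(r[1:2, ], r[1:2, ]), "fewer than 3")
})

test_that("paired test detects a fourfold rate ratio", {
  set.seed(23)
  tr <- rand_ultra(200)
  hits <- replicate(200, {
    xy <- simulate_bivariate_traits(tr, sigma2A = 4, sigma2B = 1, rho = 0)
    fA <- fit_trait_model(tr, xy$A, "BM")
    fB <- fit_trait_model(tr, xy$B, "BM")
    rA <- tip_absolute_rates(tr, xy$A, reconstruct_ancestors(tr, xy$A, fA))
    rB <- tip_absolute_rates(tr, xy$B, reconstruct_ancestors(tr, xy$B, fB))
    p <- paired_rate_test(rA, rB)
    p$p_value < 0.05 && p$mean_ln_rate_A > p$mean_ln_rate_B
  })
  expect_gte(mean(hits), 0.9)
})
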
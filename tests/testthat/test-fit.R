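test_that("the prior-free phase descends and yields non-negative loadings", {
  sim <- tiny_sim(seed = 6)
  Ys <- row_standardize(sim$Y)
  fit <- fit_base(Ys, pf_control(k = 3, seed = 6, base_max_iter = 200))
  expect_s3_class(fit, "pathfactor")
  expect_true(all(fit$Z >= 0))
  expect_identical(dim(fit$Z), c(120L, 3L))
  expect_identical(dim(fit$B), c(3L, 30L))
  expect_null(fit$U)
  expect_true(all(diff(fit$trace$objective) <= 1e-9 * fit$trace$objective[-1]))
  expect_identical(fit$trace$phase, rep("base", nrow(fit$trace)))
})

test_that("fitting requires standardized input and a latent dimension", {
  sim <- tiny_sim(seed = 6)
  expect_error(fit_base(sim$Y, pf_control(k = 3)), class = "pf_invalid_input")
  Ys <- row_standardize(sim$Y)
  expect_error(fit_base(Ys, pf_control()), class = "pf_invalid_input")
  expect_error(pathfactor(sim$Y), class = "pf_invalid_input")
  expect_error(pathfactor(sim$Y, k = 1000), class = "pf_invalid_input")
  expect_error(pathfactor(as.data.frame(sim$Y), k = 3), class = "pf_invalid_input")
})

test_that("a low-noise low-rank matrix is reconstructed accurately", {
  set.seed(61)
  Z <- matrix(abs(rnorm(150 * 4)), 150, 4)
  B <- matrix(rnorm(4 * 50), 4, 50)
  Y <- Z %*% B + matrix(rnorm(150 * 50, 0, 0.05), 150, 50)
  dimnames(Y) <- list(sprintf("g%03d", 1:150), sprintf("s%02d", 1:50))
  # explicit small ridge penalties: the spectral defaults deliberately shrink
  # components near the noise floor, which is not what this test measures
  fit <- pathfactor(Y, k = 4,
                    control = pf_control(seed = 61, lambda1 = 5e-4, lambda2 = 1e-3))
  Ys <- row_standardize(Y)
  rel_resid <- sqrt(sum((Ys - fitted(fit))^2) / sum(Ys^2))
  expect_lt(rel_resid, 0.05)
})

test_that("per-LV pathway regression recovers a planted sparse support", {
  set.seed(62)
  C <- block_prior(300, 8, 30)
  u_true <- numeric(8); u_true[c(2, 5)] <- c(1.2, 0.8)
  z <- as.vector(C %*% u_true) + abs(rnorm(300, 0, 0.05))
  up <- fit_pathway_u(z, C, pf_control(k = 2, seed = 62), lv_index = 1)
  expect_identical(up$support, c(2L, 5L))
  expect_equal(unname(up$u[c(2, 5)]), c(1.2, 0.8), tolerance = 0.05)
  expect_true(all(up$u[-c(2, 5)] == 0))
  expect_gt(up$lambda3, 0)
})

test_that("the penalty path has the configured length and spans three decades", {
  set.seed(63)
  C <- block_prior(200, 6, 30)
  z <- as.vector(C %*% c(1, 0, 0, 0.7, 0, 0)) + abs(rnorm(200, 0, 0.1))
  up <- fit_pathway_u(z, C, pf_control(k = 2, seed = 63), 1)
  expect_length(up$lambda_path, 20L)
  ratios <- up$lambda_path[-1] / up$lambda_path[-20]
  expect_equal(ratios, rep(ratios[1], 19), tolerance = 1e-10)
  expect_equal(up$lambda_path[20] / up$lambda_path[1], 1e-3, tolerance = 1e-10)
  expect_true(all(diff(up$lambda_path) < 0))
})

test_that("a permuted loading vector yields an empty support almost always", {
  set.seed(64)
  C <- block_prior(300, 8, 30)
  z0 <- as.vector(C %*% c(0, 1.2, 0, 0, 0.8, 0, 0, 0)) + abs(rnorm(300, 0, 0.05))
  empty <- 0L
  for (r in 1:100) {
    z <- sample(z0)   # destroys the gene-set alignment, keeps the marginal
    up <- fit_pathway_u(z, C, pf_control(k = 2, seed = r), lv_index = r)
    empty <- empty + (length(up$support) == 0L)
  }
  expect_gte(empty, 90L)
})

test_that("noise-free planted supports match exhaustive subset enumeration", {
  for (s in 1:10) {
    set.seed(s)
    C <- block_prior(20, 4, 5)
    planted <- sort(sample(4, 2))
    u_true <- numeric(4); u_true[planted] <- runif(2, 0.5, 1.5)
    z <- as.vector(C %*% u_true)
    up <- fit_pathway_u(z, C, pf_control(k = 2, seed = s), 1)
    oracle <- best_subset_nnls(z, C)
    expect_identical(oracle$support, planted)   # the oracle finds the truth
    expect_identical(sort(up$support), planted) # and so does the fit
  }
})

test_that("degenerate pathway-regression inputs return an empty path", {
  C <- block_prior(40, 2, 10)
  ctl <- pf_control(k = 2, seed = 1)
  expect_identical(fit_pathway_u(rep(1, 40), C, ctl, 1)$support, integer(0))
  C0 <- C * 0
  z <- abs(rnorm(40))
  expect_identical(fit_pathway_u(z, C0, ctl, 1)$support, integer(0))
  expect_error(fit_pathway_u(z[1:10], C, ctl, 1), class = "pf_invalid_input")
})

test_that("the full phase records its pathway-refresh schedule in the trace", {
  sim <- tiny_sim(seed = 7)
  fit <- pathfactor(sim$Y, sim$C, control = pf_control(k = 3, seed = 7))
  tr <- fit$trace[fit$trace$phase == "full", ]
  expect_identical(tr$iteration[1], 0L)        # entry refit row
  expect_true(tr$u_updated[1])
  refreshes <- tr$iteration[tr$u_updated]
  expect_lte(length(refreshes), 5L)            # refresh cap, entry included
  later <- refreshes[-1]
  expect_true(all(later %% 2L == 0L))          # every-other-iteration schedule
})

test_that("full-phase fits link pathway-driven LVs to their planted sets", {
  # seed chosen so the planted LVs have disjoint set supports: LVs that share
  # a supporting set are only identifiable up to mixing, which is a generator
  # property, not what this test measures
  sim <- make_synthetic(synth_spec(n_genes = 300, n_samples = 60, n_sets = 8,
                                   k = 6, prior_lvs = 4, genes_per_set = 20,
                                   noise_sd = 0.1, n_labels = 2, seed = 12))
  fit <- pathfactor(sim$Y, sim$C, control = pf_control(k = 6, seed = 12))
  expect_gte(count_pathway_lvs(fit), 3L)
  # matched loading correlations identify the planted LVs
  m <- match_latents(fit$Z, sim$Z_true)
  expect_gte(sum(m$cor[m$true <= 4] > 0.9), 3L)
})

test_that("misaligned or missized priors are data errors", {
  sim <- tiny_sim(seed = 9)
  Ys <- row_standardize(sim$Y)
  Cbad <- sim$C
  rownames(Cbad)[1] <- "not_a_gene"
  expect_error(fit_full(Ys, Cbad, pf_control(k = 3, seed = 9)),
               class = "pf_data_error")
  expect_error(fit_full(Ys, sim$C[-1, ], pf_control(k = 3, seed = 9)),
               class = "pf_data_error")
})

test_that("identical seeds give bitwise-identical fits and leave the RNG alone", {
  sim <- tiny_sim(seed = 10)
  set.seed(999); before <- .Random.seed
  f1 <- pathfactor(sim$Y, sim$C, control = pf_control(k = 3, seed = 10,
                                                      base_max_iter = 80,
                                                      full_max_iter = 40))
  expect_identical(.Random.seed, before)   # fitting must not disturb the stream
  f2 <- pathfactor(sim$Y, sim$C, control = pf_control(k = 3, seed = 10,
                                                      base_max_iter = 80,
                                                      full_max_iter = 40))
  expect_identical(f1$Z, f2$Z)
  expect_identical(f1$B, f2$B)
  expect_identical(f1$U, f2$U)
})

test_that("fitting on a masked prior keeps dimensions and runs end to end", {
  sim <- tiny_sim(seed = 13)
  plan <- make_holdout(sim$C, fraction = 0.10, seed = 13)
  fit <- pathfactor(sim$Y, plan$masked_C,
                    control = pf_control(k = 3, seed = 13,
                                         base_max_iter = 80, full_max_iter = 40))
  expect_identical(dim(fit$Z), dim(sim$Z_true))
  expect_identical(nrow(fit$U), ncol(sim$C))
})
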
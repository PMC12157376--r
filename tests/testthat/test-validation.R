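test_that("holdout plans mask the stratified fraction per set, minimum one", {
  C <- block_prior(200, 5, 30)
  C <- cbind(C, lonely = c(1, rep(0, 199)))          # single-member set
  C[1:12, 5] <- 1                                     # widen set05 to 42 members
  plan <- make_holdout(C, fraction = 0.10, seed = 3)
  expect_s3_class(plan, "pf_holdout")
  sizes <- vapply(colnames(C)[1:5], function(s) length(plan$held_out[[s]]), 0L)
  members <- colSums(C)[1:5]
  expect_identical(unname(sizes), pmax(1L, as.integer(round(0.10 * members))))
  expect_identical(plan$skipped, "lonely")
  expect_false("lonely" %in% names(plan$held_out))
  # masked entries are zeroed exactly at the held-out indices
  for (s in names(plan$held_out)) {
    idx <- plan$held_out[[s]]
    expect_true(all(C[idx, s] == 1))
    expect_true(all(plan$masked_C[idx, s] == 0))
    expect_identical(sum(C[, s]) - length(idx), sum(plan$masked_C[, s]))
  }
  # deterministic given the seed
  plan2 <- make_holdout(C, fraction = 0.10, seed = 3)
  expect_identical(plan$held_out, plan2$held_out)
  expect_error(make_holdout(C, fraction = 0), class = "pf_invalid_input")
})

test_that("rank-sum AUC equals exhaustive pair counting", {
  set.seed(71)
  for (r in 1:20) {
    h <- rnorm(sample(2:8, 1)); b <- rnorm(sample(3:20, 1))
    if (r %% 3 == 0) h[1] <- b[1]    # inject a tie
    expect_equal(ranksum_auc(h, b)$auc, auc_exhaustive(h, b), tolerance = 1e-12)
  }
  expect_identical(ranksum_auc(c(5, 6), c(1, 2, 3))$auc, 1)
  expect_identical(ranksum_auc(c(1, 2), c(5, 6, 7))$auc, 0)
  expect_error(ranksum_auc(numeric(0), 1:3), class = "pf_invalid_input")
  expect_error(ranksum_auc(c(1, NA), 1:3), class = "pf_invalid_input")
})

test_that("rank-sum p-values match the reference implementation", {
  set.seed(72)
  # exact branch: small, tie-free
  for (r in 1:10) {
    h <- rnorm(6); b <- rnorm(10)
    ref <- wilcox.test(h, b, alternative = "greater", exact = TRUE)$p.value
    expect_equal(ranksum_auc(h, b)$p_value, ref, tolerance = 1e-12)
  }
  # normal-approximation branch: large samples with ties
  h <- round(rnorm(40, 1), 1); b <- round(rnorm(60), 1)
  ref <- wilcox.test(h, b, alternative = "greater", exact = FALSE,
                     correct = TRUE)$p.value
  expect_equal(ranksum_auc(h, b)$p_value, ref, tolerance = 1e-9)
})

test_that("rank-sum p-values are uniform under the null", {
  set.seed(73)
  p <- replicate(400, ranksum_auc(rnorm(8), rnorm(12))$p_value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 1e-4)
  expect_gt(mean(p < 0.05) , 0.01); expect_lt(mean(p < 0.05), 0.10)
})

test_that("BH adjustment matches the step-up formula and preserves order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  set.seed(74)
  p <- runif(1000)
  adj <- bh_fdr(p)
  expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-14)
  o <- order(p)
  expect_true(all(diff(adj[o]) >= 0))
  expect_true(all(adj <= 1))
  # permutation invariance: adjusting a shuffled vector shuffles the result
  perm <- sample(1000)
  expect_equal(bh_fdr(p[perm]), adj[perm], tolerance = 1e-14)
  expect_error(bh_fdr(c(0.5, 0)), class = "pf_invalid_input")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "pf_invalid_input")
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})

test_that("cross-validation scores planted structure and excludes set members from background", {
  sim <- make_synthetic(synth_spec(n_genes = 300, n_samples = 60, n_sets = 8,
                                   k = 6, prior_lvs = 4, genes_per_set = 20,
                                   noise_sd = 0.1, n_labels = 2, seed = 14))
  plan <- make_holdout(sim$C, fraction = 0.10, seed = 14)
  fit <- pathfactor(sim$Y, plan$masked_C, control = pf_control(k = 6, seed = 14))
  rep <- crossval_report(fit, sim$C, plan)
  expect_s3_class(rep, "pf_crossval")
  expect_gt(nrow(rep), 0)
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  expect_equal(rep$fdr, bh_stepup_oracle(rep$pval), tolerance = 1e-12)
  # background excludes every original member of the set, masked or not
  for (i in seq_len(nrow(rep)))
    expect_identical(rep$n_background[i],
                     nrow(sim$Y) - as.integer(sum(sim$C[, rep$set[i]])))
  # planted pairs dominate: strong mean AUC at low noise
  expect_gt(mean(rep$auc), 0.85)
  # tested pairs are exactly the positive-coefficient pairs with held-out genes
  for (i in seq_len(nrow(rep)))
    expect_gt(fit$U[rep$set[i], rep$lv[i]], 0)
})

test_that("a prior-free model yields an empty cross-validation report", {
  sim <- tiny_sim(seed = 15)
  plan <- make_holdout(sim$C, seed = 15)
  fit <- pathfactor(sim$Y, k = 3, seed = 15)
  expect_identical(nrow(crossval_report(fit, sim$C, plan)), 0L)
})

test_that("LV counting applies the FDR gate before the per-LV maximum", {
  rep <- data.frame(
    lv = c(1L, 1L, 2L, 3L),
    set = c("a", "b", "c", "d"),
    auc = c(0.95, 0.75, 0.85, 0.99),
    pval = c(0.001, 0.002, 0.003, 0.2),
    fdr = c(0.004, 0.008, 0.012, 0.2),   # lv 3 fails the gate despite AUC 0.99
    n_heldout = 3L, n_background = 100L)
  class(rep) <- c("pf_crossval", "data.frame")
  out <- lv_auc_summary(rep, thresholds = c(0.7, 0.8, 0.9), fdr_cutoff = 0.05)
  expect_identical(out$n_lvs, c(2L, 2L, 1L))
  best <- attr(out, "best_pairs")
  expect_identical(best$set[best$lv == 1], "a")   # max AUC wins within the LV
  empty <- lv_auc_summary(rep[0, ], thresholds = c(0.7, 0.9))
  expect_identical(empty$n_lvs, c(0L, 0L))
})

test_that("tissue alignment reproduces per-label Welch t statistics", {
  set.seed(75)
  B <- matrix(rnorm(4 * 40), 4, 40, dimnames = list(NULL, sprintf("s%02d", 1:40)))
  labels <- setNames(rep(c("x", "y"), each = 20), colnames(B))
  B[2, labels == "x"] <- B[2, labels == "x"] + 3
  out <- tissue_alignment(B, labels)
  expect_s3_class(out, "pf_alignment")
  expect_identical(out$best_lv[out$label == "x"], 2L)
  for (lab in c("x", "y")) {
    idx <- labels == lab
    ref <- max(vapply(1:4, function(l)
      t.test(B[l, idx], B[l, !idx])$statistic, 0))
    expect_equal(out$max_t[out$label == lab], ref, tolerance = 1e-10)
  }
  # label ordering follows the score columns when names are present
  shuffled <- labels[sample(40)]
  expect_equal(tissue_alignment(B, shuffled)$max_t, out$max_t, tolerance = 1e-12)
})

test_that("alignment skips labels without enough samples and flags gaps", {
  B <- matrix(rnorm(2 * 10), 2, 10, dimnames = list(NULL, paste0("s", 1:10)))
  labels <- setNames(c("solo", rep(c("a", "b"), c(5, 4))), colnames(B))
  expect_warning(out <- tissue_alignment(B, labels), "skipped")
  expect_false("solo" %in% out$label)
  expect_error(tissue_alignment(B, labels[1:9]), class = "pf_data_error")
  expect_error(tissue_alignment(B, unname(labels[1:9])), class = "pf_invalid_input")
})

test_that("reports serialize to tab-separated files with fixed headers", {
  d <- withr::local_tempdir()
  rep <- data.frame(lv = 1L, set = "a", auc = 0.9, pval = 0.01, fdr = 0.02,
                    n_heldout = 2L, n_background = 50L)
  class(rep) <- c("pf_crossval", "data.frame")
  f <- file.path(d, "r.tsv")
  write_report(rep, f)
  back <- read.delim(f)
  expect_identical(names(back),
                   c("lv", "set", "auc", "pval", "fdr", "n_heldout", "n_background"))
  expect_equal(back$auc, 0.9)
})
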
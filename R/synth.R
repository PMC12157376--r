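# Seeded synthetic-data generator following the model's own generative
# structure (Z ~ CU with non-negative sparse U, Y ~ ZB + Gaussian noise), so
# fitting, pathway recovery, calibration and alignment are all testable
# without external data. It deliberately does NOT emulate sequencing
# physics (counts, library size, batch) — see the methods vignette.

#' Specification of a synthetic dataset
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param n_sets number of prior gene sets.
#' @param k number of latent variables.
#' @param prior_lvs how many LVs are prior-driven (supported on `U`).
#' @param genes_per_set members per gene set (disjoint blocks unless
#'   `overlap > 0`).
#' @param u_density fraction of sets linked to each prior-driven LV (at
#'   least one).
#' @param noise_sd standard deviation of the additive Gaussian noise on `Y`.
#' @param z_jitter_sd half-normal jitter added to prior-driven loadings.
#' @param n_labels number of sample label blocks; label `l` boosts LV `l`'s
#'   scores by `label_effect` within its block.
#' @param label_effect additive score shift defining the label blocks.
#' @param overlap fraction of extra members each set borrows from other
#'   blocks (0 keeps sets disjoint).
#' @param seed seed; all outputs are deterministic given the spec.
#' @return a `pf_synth_spec` list.
#' @export
synth_spec <- function(n_genes = 2000L, n_samples = 300L, n_sets = 40L,
                       k = 15L, prior_lvs = 10L, genes_per_set = 30L,
                       u_density = 0.05, noise_sd = 0.1, z_jitter_sd = 0.05,
                       n_labels = 5L, label_effect = 3, overlap = 0,
                       seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
               n_sets = as.integer(n_sets), k = as.integer(k),
               prior_lvs = as.integer(prior_lvs),
               genes_per_set = as.integer(genes_per_set),
               u_density = u_density, noise_sd = noise_sd,
               z_jitter_sd = z_jitter_sd, n_labels = as.integer(n_labels),
               label_effect = label_effect, overlap = overlap,
               seed = as.integer(seed))
  if (spec$prior_lvs > spec$k) pf_stop_input("prior_lvs must not exceed k")
  if (spec$genes_per_set < 2L) pf_stop_input("genes_per_set must be >= 2")
  if (spec$noise_sd < 0) pf_stop_input("noise_sd must be >= 0")
  if (spec$overlap == 0 && spec$n_sets * spec$genes_per_set > spec$n_genes)
    pf_stop_input(sprintf(
      "infeasible spec: %d sets x %d genes/set exceed %d genes without overlap",
      spec$n_sets, spec$genes_per_set, spec$n_genes))
  if (spec$n_labels > spec$k) pf_stop_input("n_labels must not exceed k")
  structure(spec, class = "pf_synth_spec")
}

#' Generate a synthetic expression dataset with planted structure
#'
#' Draws, deterministically for a given spec: a block-membership prior `C`;
#' sparse non-negative `U_true` supported on the first `prior_lvs` LV
#' columns; loadings `Z_true = C U_true + |half-normal|` for prior-driven
#' LVs and dense `|half-normal|` columns for free LVs; scores `B_true` with
#' Gaussian entries plus label-block shifts; and
#' `Y = Z_true B_true + N(0, noise_sd)`.
#'
#' @param spec a [synth_spec()].
#' @return list with `Y` (dimnamed matrix), `C` (binary prior), `Z_true`,
#'   `B_true`, `U_true`, `labels` (named by sample), and `spec`.
#' @examples
#' sim <- make_synthetic(synth_spec(n_genes = 100, n_samples = 30, n_sets = 4,
#'                                  k = 3, prior_lvs = 2, genes_per_set = 20,
#'                                  n_labels = 2, seed = 1))
#' dim(sim$Y); colSums(sim$C)
#' @export
make_synthetic <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "pf_synth_spec"))
  with_seed(spec$seed, {
    gn <- sprintf("g%04d", seq_len(spec$n_genes))
    sn <- sprintf("s%04d", seq_len(spec$n_samples))
    setn <- sprintf("set%02d", seq_len(spec$n_sets))
    C <- matrix(0, spec$n_genes, spec$n_sets, dimnames = list(gn, setn))
    for (j in seq_len(spec$n_sets)) {
      block <- ((j - 1L) * spec$genes_per_set + 1L):(j * spec$genes_per_set)
      block <- block[block <= spec$n_genes]
      C[block, j] <- 1
      if (spec$overlap > 0) {
        extra <- max(1L, round(spec$overlap * spec$genes_per_set))
        C[sample(setdiff(seq_len(spec$n_genes), block), extra), j] <- 1
      }
    }
    U <- matrix(0, spec$n_sets, spec$k, dimnames = list(setn, NULL))
    if (spec$prior_lvs > 0) for (l in seq_len(spec$prior_lvs)) {
      m <- max(1L, round(spec$u_density * spec$n_sets))
      U[sample(spec$n_sets, m), l] <- stats::runif(m, 0.5, 1.5)
    }
    Z <- C %*% U
    if (spec$prior_lvs > 0) {
      jit <- abs(matrix(stats::rnorm(spec$n_genes * spec$prior_lvs, 0, spec$z_jitter_sd),
                        spec$n_genes, spec$prior_lvs))
      Z[, seq_len(spec$prior_lvs)] <- Z[, seq_len(spec$prior_lvs)] + jit
    }
    n_free <- spec$k - spec$prior_lvs
    if (n_free > 0) {
      Z[, (spec$prior_lvs + 1L):spec$k] <-
        abs(matrix(stats::rnorm(spec$n_genes * n_free), spec$n_genes, n_free))
    }
    rownames(Z) <- gn
    B <- matrix(stats::rnorm(spec$k * spec$n_samples), spec$k, spec$n_samples,
                dimnames = list(NULL, sn))
    labels <- NULL
    if (spec$n_labels > 0) {
      blocks <- sort(rep_len(seq_len(spec$n_labels), spec$n_samples))
      labels <- stats::setNames(sprintf("tissue%02d", blocks), sn)
      for (l in seq_len(spec$n_labels)) B[l, blocks == l] <- B[l, blocks == l] + spec$label_effect
    }
    Y <- Z %*% B
    if (spec$noise_sd > 0)
      Y <- Y + matrix(stats::rnorm(length(Y), 0, spec$noise_sd), nrow(Y), ncol(Y))
    dimnames(Y) <- list(gn, sn)
    list(Y = Y, C = C, Z_true = Z, B_true = B, U_true = U,
         labels = labels, spec = spec)
  })
}

#' Match estimated to true latent variables
#'
#' Factorizations are identifiable only up to column permutation and scale,
#' so estimated LVs are matched to truth by maximum-weight bipartite
#' matching on the absolute Pearson correlation of loading columns.
#' Zero-variance columns get zero correlation (recorded in the
#' `zero_variance` attribute).
#'
#' @param Z_est,Z_true loading matrices with equal gene dimension.
#' @return data frame with columns `est`, `true`, `cor`, ordered by `true`.
#' @export
match_latents <- function(Z_est, Z_true) {
  stopifnot_matrix(Z_est); stopifnot_matrix(Z_true)
  if (nrow(Z_est) != nrow(Z_true))
    pf_stop_input("loading matrices disagree on gene dimension")
  ke <- ncol(Z_est); kt <- ncol(Z_true)
  sd_e <- apply(Z_est, 2, stats::sd); sd_t <- apply(Z_true, 2, stats::sd)
  zv <- list(est = which(sd_e == 0), true = which(sd_t == 0))
  A <- matrix(0, ke, kt)
  ok_e <- sd_e > 0; ok_t <- sd_t > 0
  if (any(ok_e) && any(ok_t))
    A[ok_e, ok_t] <- abs(stats::cor(Z_est[, ok_e, drop = FALSE],
                                    Z_true[, ok_t, drop = FALSE]))
  # maximum-weight bipartite matching on the correlation matrix
  g <- igraph::make_bipartite_graph(c(rep(FALSE, ke), rep(TRUE, kt)), edges = integer(0))
  pairs <- expand.grid(e = seq_len(ke), t = seq_len(kt))
  g <- igraph::add_edges(g, rbind(pairs$e, ke + pairs$t))
  igraph::E(g)$weight <- A[cbind(pairs$e, pairs$t)] + 1e-9  # keep weights positive
  m <- igraph::max_bipartite_match(g)$matching
  est <- seq_len(ke)
  true <- m[est] - ke
  keep <- !is.na(true)
  out <- data.frame(est = est[keep], true = as.integer(true[keep]),
                    cor = A[cbind(est[keep], as.integer(true[keep]))])
  out <- out[order(out$true), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "zero_variance") <- zv
  out
}
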
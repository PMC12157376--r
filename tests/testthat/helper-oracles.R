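# Shared fixtures and independent oracle implementations used across the
# test files. Oracles are deliberately written from the defining formulas
# (or as exhaustive enumeration), not by calling the package code paths
# they are meant to check.

# small synthetic dataset with sane defaults for unit tests
tiny_sim <- function(n_genes = 120, n_samples = 30, n_sets = 4, k = 3,
                     prior_lvs = 2, genes_per_set = 20, noise_sd = 0.1,
                     n_labels = 2, seed = 1, ...) {
  make_synthetic(synth_spec(n_genes = n_genes, n_samples = n_samples,
                            n_sets = n_sets, k = k, prior_lvs = prior_lvs,
                            genes_per_set = genes_per_set, noise_sd = noise_sd,
                            n_labels = n_labels, seed = seed, ...))
}

# disjoint block membership matrix
block_prior <- function(n_genes, n_sets, size) {
  C <- matrix(0, n_genes, n_sets,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("set%02d", seq_len(n_sets))))
  for (j in seq_len(n_sets)) C[((j - 1) * size + 1):(j * size), j] <- 1
  C
}

# first-order-method oracle for the ridge score update:
# argmin_B ||Y - ZB||_F^2 + l2 ||B||_F^2
ridge_oracle_B <- function(Y, Z, l2) {
  k <- ncol(Z); m <- ncol(Y)
  fn <- function(b) { B <- matrix(b, k, m); sum((Y - Z %*% B)^2) + l2 * sum(B^2) }
  gr <- function(b) { B <- matrix(b, k, m)
                      as.vector(-2 * crossprod(Z, Y - Z %*% B) + 2 * l2 * B) }
  o <- stats::optim(numeric(k * m), fn, gr, method = "L-BFGS-B",
                    control = list(maxit = 5000, factr = 10))
  matrix(o$par, k, m)
}

# first-order-method oracle for the smooth loading subproblem:
# argmin_Z ||Y - ZB||_F^2 + l1 ||Z - T||_F^2
ridge_oracle_Z <- function(Y, B, l1, Tm = NULL) {
  n <- nrow(Y); k <- nrow(B)
  if (is.null(Tm)) Tm <- matrix(0, n, k)
  fn <- function(z) { Z <- matrix(z, n, k)
                      sum((Y - Z %*% B)^2) + l1 * sum((Z - Tm)^2) }
  gr <- function(z) { Z <- matrix(z, n, k)
                      as.vector(-2 * (Y - Z %*% B) %*% t(B) + 2 * l1 * (Z - Tm)) }
  o <- stats::optim(numeric(n * k), fn, gr, method = "L-BFGS-B",
                    control = list(maxit = 5000, factr = 10))
  matrix(o$par, n, k)
}

# Benjamini-Hochberg step-up adjustment from the defining formula
# adj_i = min_{j: p_j >= p_i} p_j * m / rank(p_j), clipped at 1
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# rank-sum AUC by exhaustive pair counting (ties count one half)
auc_exhaustive <- function(h, b) {
  wins <- 0
  for (x in h) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(h) * length(b))
}

# maximum-weight bipartite matching by brute force over permutations
brute_force_match <- function(A) {
  ke <- nrow(A); kt <- ncol(A)
  stopifnot(ke == kt)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- NULL; best_w <- -Inf
  for (p in perms(seq_len(kt))) {
    w <- sum(A[cbind(seq_len(ke), p)])
    if (w > best_w) { best_w <- w; best <- p }
  }
  list(perm = best, weight = best_w)
}

# exhaustive best-subset non-negative regression with intercept: returns the
# support minimizing the residual sum of squares (smaller support wins ties)
best_subset_nnls <- function(z, C, tol = 1e-12) {
  p <- ncol(C)
  best <- integer(0); best_rss <- sum((z - mean(z))^2)
  for (mask in seq_len(2^p - 1)) {
    sub <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    X <- C[, sub, drop = FALSE]
    # 2-block coordinate descent: non-negative LS plus free intercept
    mu <- 0; u <- numeric(length(sub))
    for (i in 1:200) {
      u_new <- pracma::lsqnonneg(X, z - mu)$x
      mu_new <- mean(z - X %*% u_new)
      conv <- abs(mu_new - mu) + sum(abs(u_new - u)) < 1e-12
      u <- u_new; mu <- mu_new
      if (conv) break
    }
    rss <- sum((z - X %*% u - mu)^2)
    if (rss < best_rss - tol ||
        (abs(rss - best_rss) < tol && length(sub) < length(best))) {
      best <- sub; best_rss <- rss
    }
  }
  list(support = sort(best), rss = best_rss)
}

# standardized copy of a matrix by plain vectorized R (n-1 sd convention)
standardize_oracle <- function(Y) {
  mu <- rowMeans(Y)
  sd <- apply(Y, 1, stats::sd)
  out <- (Y - mu) / ifelse(sd == 0, 1, sd)
  out[sd == 0, ] <- 0
  out
}
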
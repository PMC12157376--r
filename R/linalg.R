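# Penalized objective, spectral initialization, and the closed-form block
# updates. The objective is quadratic in each of B and Z, so both block
# minimizers are available in closed form (ridge normal equations); the
# non-negativity of Z is imposed by projecting the unconstrained ridge
# solution onto the non-negative orthant.

# elastic penalty applied per LV column of U: alpha*||u||_1 + (1-alpha)/2*||u||_2^2
u_penalty <- function(u, alpha) alpha * sum(abs(u)) + (1 - alpha) / 2 * sum(u^2)

#' Value of the penalized factorization objective
#'
#' Computes
#' \eqn{\|Y - ZB\|_F^2 + \lambda_1\|Z - CU\|_F^2 + \lambda_2\|B\|_F^2 +
#' \sum_l \lambda_{3,l}(\alpha\|U_{\cdot l}\|_1 + \frac{1-\alpha}{2}\|U_{\cdot l}\|_2^2)}.
#' With `U` (or `C`) absent the prior term reduces to the ridge
#' \eqn{\lambda_1\|Z\|_F^2} of the prior-free base phase.
#'
#' @param Y genes x samples matrix or `pf_fbm` handle.
#' @param Z genes x k non-negative loadings.
#' @param B k x samples scores.
#' @param lambda1,lambda2 non-negative ridge penalties on the prior term and B.
#' @param C optional genes x gene-sets binary prior.
#' @param U optional gene-sets x k non-negative coefficients.
#' @param lambda3 optional length-k vector of per-LV sparsity penalties.
#' @param alpha L1 mixing weight of the elastic penalty on U columns.
#' @return non-negative scalar.
#' @export
objective_value <- function(Y, Z, B, lambda1, lambda2,
                            C = NULL, U = NULL, lambda3 = NULL, alpha = 0.9) {
  if (bk_nrow(Y) != nrow(Z) || bk_ncol(Y) != ncol(B) || ncol(Z) != nrow(B))
    pf_stop_input("dimension mismatch among Y, Z, B")
  k <- ncol(Z)
  Tm <- 0
  if (!is.null(U)) {
    if (is.null(C)) pf_stop_input("U supplied without C")
    if (nrow(U) != ncol(C) || ncol(U) != k || nrow(C) != nrow(Z))
      pf_stop_input("dimension mismatch among C, U, Z")
    Tm <- C %*% U
  }
  val <- bk_resid_ss(Y, Z, B) +
    lambda1 * sum((Z - Tm)^2) +
    lambda2 * sum(B^2)
  if (!is.null(lambda3) && !is.null(U)) {
    if (length(lambda3) != k) pf_stop_input("lambda3 must have one entry per LV")
    val <- val + sum(vapply(seq_len(k),
                            function(l) lambda3[l] * u_penalty(U[, l], alpha), 0))
  }
  val
}

#' Spectral initialization of the factorization
#'
#' Computes the truncated rank-`k` SVD of standardized `Y` (via the
#' column-blocked crossproduct `Y'Y`, so file-backed inputs never load
#' fully), derives the ridge penalties from the retained spectrum
#' (`lambda2 = s_k`, the k-th singular value, and `lambda1 = lambda2 / 2`,
#' placing the implied singular-value shrinkage `sqrt(lambda1 lambda2)` at
#' the noise-level boundary of the retained spectrum), and builds a
#' non-negative starting `Z` by
#' column-wise split-sign projection of the left singular vectors: each
#' vector is oriented toward its larger positive mass, negatives are clamped
#' to zero, and columns are rescaled to unit norm. `B` is the ridge
#' projection of `Y` onto that `Z`.
#'
#' @param Y standardized genes x samples matrix or `pf_fbm` handle.
#' @param k number of latent variables, at most `min(dim(Y))`.
#' @return list with `Z`, `B`, `lambda1`, `lambda2` and the retained
#'   `singular_values`.
#' @export
svd_init <- function(Y, k) {
  if (!bk_standardized(Y))
    pf_stop_input("svd_init expects a row-standardized matrix (see row_standardize)")
  n <- bk_nrow(Y); m <- bk_ncol(Y)
  if (k > min(n, m) || k < 1L)
    pf_stop_input(sprintf("k = %d must be in [1, min(genes, samples) = %d]", k, min(n, m)))
  S <- bk_crossprod_self(Y)
  eig <- eigen(S, symmetric = TRUE)
  s <- sqrt(pmax(eig$values[seq_len(k)], 0))
  # rank test on the Gram matrix with the usual max(dim) * eps scaling
  if (eig$values[k] <= max(n, m) * .Machine$double.eps * max(eig$values[1], 0))
    pf_stop_numeric("rank of Y below k; cannot derive spectral penalties")
  lambda2 <- s[k]
  lambda1 <- lambda2 / 2
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  Us <- bk_mult_right(Y, sweep(V, 2, s, "/"))   # left singular vectors
  Z0 <- apply(Us, 2, function(u) {
    if (sum(pmax(-u, 0)) > sum(pmax(u, 0))) u <- -u
    u <- pmax(u, 0)
    nrm <- sqrt(sum(u^2))
    if (nrm > 0) u / nrm else u
  })
  rownames(Z0) <- bk_rownames(Y)
  B0 <- update_B(Y, Z0, lambda2)
  list(Z = Z0, B = B0, lambda1 = lambda1, lambda2 = lambda2,
       singular_values = s)
}

#' Closed-form ridge update of the sample scores B
#'
#' Exact minimizer of the objective in `B` with `Z` fixed:
#' `B = (Z'Z + lambda2 I)^-1 Z'Y`.
#'
#' @param Y genes x samples matrix or `pf_fbm` handle.
#' @param Z genes x k loadings.
#' @param lambda2 ridge penalty; with `lambda2 = 0`, `Z` must have full
#'   column rank (a rank-deficient unpenalized system is an error, not a
#'   pseudo-inverse fallback).
#' @return k x samples matrix.
#' @export
update_B <- function(Y, Z, lambda2) {
  if (bk_nrow(Y) != nrow(Z)) pf_stop_input("Y and Z disagree on gene count")
  k <- ncol(Z)
  M <- crossprod(Z) + diag(lambda2, k)
  if (lambda2 == 0 && qr(Z)$rank < k)
    pf_stop_numeric("Z is rank-deficient and lambda2 = 0: system is singular")
  B <- solve(M, bk_crossprod_left(Z, Y))
  colnames(B) <- bk_colnames(Y)
  B
}

#' Projected ridge update of the gene loadings Z
#'
#' Solves the smooth subproblem in `Z` with `B` fixed,
#' `Z* = (YB' + lambda1 T)(BB' + lambda1 I)^-1` where `T = CU` in the full
#' phase and `T = 0` (argument absent) in the base phase, then projects
#' negative entries to zero.
#'
#' Because the Gram matrix `BB' + lambda1 I` is not diagonal, the projected
#' point is not the exact constrained minimizer of the Z block. With
#' `exact = TRUE` the update instead solves the non-negatively constrained
#' quadratic program to optimality (the subproblem separates over gene rows
#' into strictly convex QPs sharing one k x k Gram matrix, solved jointly by
#' block principal pivoting). The alternating fit uses the projected update
#' by default and falls back to the exact update on any iteration whose
#' objective would otherwise increase, which keeps the objective
#' non-increasing between pathway-coefficient refreshes.
#'
#' @param Y genes x samples matrix or `pf_fbm` handle.
#' @param B k x samples scores.
#' @param lambda1 ridge penalty toward the prior target; with `lambda1 = 0`,
#'   `B` must have full row rank.
#' @param prior_target optional genes x k matrix `CU`.
#' @param project set `FALSE` to return the unconstrained ridge solution.
#' @param exact set `TRUE` to return the exact constrained block minimizer
#'   instead of the projected ridge solution.
#' @return genes x k matrix, non-negative when `project = TRUE`.
#' @export
update_Z <- function(Y, B, lambda1, prior_target = NULL, project = TRUE,
                     exact = FALSE) {
  if (bk_ncol(Y) != ncol(B)) pf_stop_input("Y and B disagree on sample count")
  k <- nrow(B)
  if (!is.null(prior_target) &&
      (nrow(prior_target) != bk_nrow(Y) || ncol(prior_target) != k))
    pf_stop_input("prior_target must be genes x k")
  if (lambda1 == 0 && qr(t(B))$rank < k)
    pf_stop_numeric("B is rank-deficient and lambda1 = 0: system is singular")
  G <- tcrossprod(B) + diag(lambda1, k)
  N <- bk_mult_right(Y, t(B))
  if (!is.null(prior_target)) N <- N + lambda1 * prior_target
  Z <- N %*% solve(G)
  if (project) {
    Z <- if (exact) nnqp_solve(G, N, passive = Z > 0) else pmax(Z, 0)
  }
  rownames(Z) <- bk_rownames(Y)
  Z
}

# Exact solution of min_{z >= 0} z'Gz - 2 n'z for every row n of N (shared
# positive-definite k x k Gram matrix G), by block principal pivoting with
# Murty's backup rule. Rows sharing a passive-set pattern are solved in one
# batched linear solve, so the cost is a few small solves regardless of the
# gene count. The passive set is warm-started from the sign pattern of the
# unconstrained ridge solution.
nnqp_solve <- function(G, N, passive = NULL, max_iter = 100L, tol = 1e-12) {
  n_rows <- nrow(N); k <- ncol(N)
  P <- if (is.null(passive)) matrix(TRUE, n_rows, k) else passive
  Z <- matrix(0, n_rows, k)
  # per-row anti-cycling state (Kim & Park 2011 convention)
  slack <- rep(3L, n_rows)
  last_ninf <- rep(k + 1L, n_rows)
  key_pow <- 2^(seq_len(k) - 1)
  settled <- rep(FALSE, n_rows)       # rows whose KKT conditions already hold
  for (iter in seq_len(max_iter)) {
    # batched solve on the passive sets of the rows still in play
    open <- which(!settled)
    keys <- as.vector(P[open, , drop = FALSE] %*% key_pow)
    for (grp in split(open, keys)) {
      free <- which(P[grp[1], ])
      if (length(free) == 0L) { Z[grp, ] <- 0; next }
      Z[grp, ] <- 0
      Z[grp, free] <- t(solve(G[free, free, drop = FALSE],
                              t(N[grp, free, drop = FALSE])))
    }
    Zo <- Z[open, , drop = FALSE]
    Po <- P[open, , drop = FALSE]
    Wo <- N[open, , drop = FALSE] - Zo %*% G   # dual for active variables
    V <- (Po & (Zo < -tol)) | (!Po & (Wo > tol))
    ninf <- rowSums(V)
    bad <- ninf > 0L
    if (!any(bad)) break
    settled[open[!bad]] <- TRUE
    br <- open[bad]                   # global indices of infeasible rows
    improved <- ninf[bad] < last_ninf[br]
    last_ninf[br[improved]] <- ninf[bad][improved]
    slack[br[improved]] <- 3L
    has_slack <- !improved & slack[br] > 0L
    slack[br[has_slack]] <- slack[br[has_slack]] - 1L
    full <- improved | has_slack      # full exchange: flip every infeasibility
    if (any(full)) {
      fr <- br[full]
      P[fr, ] <- xor(P[fr, , drop = FALSE], V[bad, , drop = FALSE][full, , drop = FALSE])
    }
    for (i in which(!full)) {         # Murty's rule: flip the largest index only
      r <- br[i]
      j <- max(which(V[bad, , drop = FALSE][i, ]))
      P[r, j] <- !P[r, j]
    }
  }
  pmax(Z, 0)
}
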
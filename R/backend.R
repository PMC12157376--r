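# Column-blocked kernels over the expression matrix. Both backends (dense
# matrix in memory, pf_fbm on disk) go through the same block loop, so a fit
# on a file-backed matrix performs the identical arithmetic as an in-memory
# fit — out-of-core support changes storage, not results.

block_ranges <- function(n, block_size) {
  if (n == 0L) return(list())
  starts <- seq.int(0L, n - 1L, by = block_size)
  lapply(starts, function(s) c(s, min(s + block_size, n)))
}

bk_is_backend <- function(Y) is.matrix(Y) || inherits(Y, "pf_fbm")

bk_nrow <- function(Y) if (inherits(Y, "pf_fbm")) Y$n_rows else nrow(Y)
bk_ncol <- function(Y) if (inherits(Y, "pf_fbm")) Y$n_cols else ncol(Y)
bk_rownames <- function(Y) if (inherits(Y, "pf_fbm")) Y$row_names else rownames(Y)
bk_colnames <- function(Y) if (inherits(Y, "pf_fbm")) Y$col_names else colnames(Y)

bk_block_size <- function(Y, default = 1000L) {
  if (inherits(Y, "pf_fbm")) Y$block_size else default
}

# dense genes x width slice for a half-open 0-based column range
bk_block <- function(Y, b) {
  if (inherits(Y, "pf_fbm")) fbm_read_block(Y, cols = b)
  else Y[, (b[1] + 1L):b[2], drop = FALSE]
}

bk_standardized <- function(Y) {
  if (inherits(Y, "pf_fbm")) isTRUE(Y$standardized)
  else isTRUE(attr(Y, "standardized"))
}

# Y'Y (samples x samples), streamed over column-block pairs
bk_crossprod_self <- function(Y) {
  bs <- bk_block_size(Y)
  m <- bk_ncol(Y)
  S <- matrix(0, m, m)
  blocks <- block_ranges(m, bs)
  for (i in seq_along(blocks)) {
    bi <- blocks[[i]]
    Xi <- bk_block(Y, bi)
    ri <- (bi[1] + 1L):bi[2]
    S[ri, ri] <- crossprod(Xi)
    if (i < length(blocks)) for (j in (i + 1L):length(blocks)) {
      bj <- blocks[[j]]
      Xj <- bk_block(Y, bj)
      rj <- (bj[1] + 1L):bj[2]
      Cij <- crossprod(Xi, Xj)
      S[ri, rj] <- Cij
      S[rj, ri] <- t(Cij)
    }
  }
  S
}

# A'Y for dense A (genes x k) -> k x samples
bk_crossprod_left <- function(A, Y) {
  out <- matrix(0, ncol(A), bk_ncol(Y))
  for (b in block_ranges(bk_ncol(Y), bk_block_size(Y))) {
    out[, (b[1] + 1L):b[2]] <- crossprod(A, bk_block(Y, b))
  }
  out
}

# Y %*% M for dense M (samples x k) -> genes x k
bk_mult_right <- function(Y, M) {
  out <- matrix(0, bk_nrow(Y), ncol(M))
  for (b in block_ranges(bk_ncol(Y), bk_block_size(Y))) {
    out <- out + bk_block(Y, b) %*% M[(b[1] + 1L):b[2], , drop = FALSE]
  }
  out
}

# ||Y - Z B||_F^2 without materializing Y
bk_resid_ss <- function(Y, Z, B) {
  ss <- 0
  for (b in block_ranges(bk_ncol(Y), bk_block_size(Y))) {
    R <- bk_block(Y, b) - Z %*% B[, (b[1] + 1L):b[2], drop = FALSE]
    ss <- ss + sum(R * R)
  }
  ss
}

# two-pass row means and sample (n-1) standard deviations
bk_row_moments <- function(Y) {
  n <- bk_nrow(Y); m <- bk_ncol(Y)
  sums <- numeric(n)
  blocks <- block_ranges(m, bk_block_size(Y))
  for (b in blocks) sums <- sums + rowSums(bk_block(Y, b))
  mu <- sums / m
  ss <- numeric(n)
  for (b in blocks) ss <- ss + rowSums((bk_block(Y, b) - mu)^2)
  list(mean = mu, sd = sqrt(ss / (m - 1)))
}
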
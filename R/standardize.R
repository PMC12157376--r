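#' Standardize gene rows to mean zero, unit variance
#'
#' Each gene row is centered and scaled to unit sample standard deviation
#' (the n-1 convention), the preprocessing under which the Frobenius
#' penalties of the factorization are scale-free. Constant rows cannot be
#' scaled; they are set to all-zero (preserving index alignment with the
#' gene-set prior) and recorded in the `zeroed_rows` attribute, with a
#' warning.
#'
#' @param Y numeric genes x samples matrix, or a `pf_fbm` handle; at least
#'   two samples.
#' @param path for a file-backed input, base path for the standardized copy
#'   (default: alongside the input with a `_std` suffix).
#' @return the standardized matrix (same backend as the input) with the
#'   `standardized` attribute/metadata set and zeroed row names recorded.
#' @examples
#' Y <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
#' S <- row_standardize(Y)
#' range(rowMeans(S))
#' @export
row_standardize <- function(Y, path = NULL) {
  if (!bk_is_backend(Y)) stopifnot_matrix(Y)
  if (bk_ncol(Y) < 2L)
    pf_stop_input("row standardization needs at least 2 samples")
  mom <- bk_row_moments(Y)
  const <- mom$sd < .Machine$double.eps^0.5
  sd_use <- ifelse(const, 1, mom$sd)
  zeroed <- bk_rownames(Y)[const] %||% which(const)
  if (any(const))
    warning(sprintf("%d constant gene row(s) set to zero during standardization",
                    sum(const)), call. = FALSE)
  std_block <- function(b) {
    X <- (bk_block(Y, b) - mom$mean) / sd_use
    if (any(const)) X[const, ] <- 0
    X
  }
  blocks <- block_ranges(bk_ncol(Y), bk_block_size(Y))
  if (inherits(Y, "pf_fbm")) {
    base <- path %||% paste0(fbm_base_path(Y$bin), "_std")
    bin <- paste0(base, ".bin")
    con <- file(bin, "wb")
    for (b in blocks) writeBin(as.vector(std_block(b)), con, size = 8L, endian = "little")
    flush(con); close(con)
    meta <- list(format_version = FBM_FORMAT_VERSION,
                 n_rows = bk_nrow(Y), n_cols = bk_ncol(Y),
                 dtype = "float64", byte_order = "little", order = "column-major",
                 row_names = NULL, col_names = NULL, standardized = TRUE)
    if (!is.null(Y$row_names)) {
      meta$row_names <- paste0(basename(base), "_rows.txt")
      writeLines(Y$row_names, paste0(base, "_rows.txt"))
    }
    if (!is.null(Y$col_names)) {
      meta$col_names <- paste0(basename(base), "_cols.txt")
      writeLines(Y$col_names, paste0(base, "_cols.txt"))
    }
    jsonlite::write_json(meta, paste0(base, ".json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    out <- fbm_open(base, block_size = Y$block_size)
    attr(out, "zeroed_rows") <- zeroed
    out
  } else {
    out <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
    for (b in blocks) out[, (b[1] + 1L):b[2]] <- std_block(b)
    attr(out, "standardized") <- TRUE
    attr(out, "zeroed_rows") <- zeroed
    out
  }
}
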
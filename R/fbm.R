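# File-backed matrix: raw little-endian column-major float64 payload plus a
# JSON sidecar, deliberately simple enough to be read from any environment
# (numpy: fromfile + reshape(order="F")). Layout for base path "x":
#   x.bin        payload, 8 * n_rows * n_cols bytes
#   x.json       metadata sidecar
#   x_rows.txt   one row name per line (optional)
#   x_cols.txt   one column name per line (optional)

FBM_FORMAT_VERSION <- 1L

fbm_base_path <- function(path) sub("\\.(bin|json)$", "", path)

#' Write a matrix to the file-backed format
#'
#' Stores `x` as a raw column-major float64 payload with a JSON metadata
#' sidecar and optional row/column name files, and returns the opened handle.
#'
#' @param x numeric matrix.
#' @param path base path (a `.bin`/`.json` suffix is stripped); the payload
#'   goes to `<path>.bin`, metadata to `<path>.json`.
#' @param block_size column block size used for streamed access.
#' @return a `pf_fbm` handle (see [fbm_open()]).
#' @seealso [fbm_open()], [fbm_read_block()]
#' @export
fbm_write <- function(x, path, block_size = 1000L) {
  stopifnot_matrix(x)
  base <- fbm_base_path(path)
  bin <- paste0(base, ".bin")
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  # stream by column block so payloads larger than one allocation still write
  for (b in block_ranges(ncol(x), block_size)) {
    writeBin(as.vector(x[, (b[1] + 1L):b[2], drop = FALSE]), con,
             size = 8L, endian = "little")
  }
  flush(con)
  meta <- list(
    format_version = FBM_FORMAT_VERSION,
    n_rows = nrow(x), n_cols = ncol(x),
    dtype = "float64", byte_order = "little", order = "column-major",
    row_names = NULL, col_names = NULL,
    standardized = isTRUE(attr(x, "standardized"))
  )
  if (!is.null(rownames(x))) {
    meta$row_names <- paste0(basename(base), "_rows.txt")
    writeLines(rownames(x), paste0(base, "_rows.txt"))
  }
  if (!is.null(colnames(x))) {
    meta$col_names <- paste0(basename(base), "_cols.txt")
    writeLines(colnames(x), paste0(base, "_cols.txt"))
  }
  jsonlite::write_json(meta, paste0(base, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  fbm_open(base, block_size = block_size)
}

#' Open a file-backed matrix
#'
#' Validates the payload length against the sidecar metadata and returns a
#' lightweight handle; no data is loaded until blocks are read.
#'
#' @param path base path or path to the `.json`/`.bin` file.
#' @param block_size column block size for streamed access.
#' @return an object of class `pf_fbm` with `dim()`, `dimnames()` and
#'   `as.matrix()` methods.
#' @export
fbm_open <- function(path, block_size = 1000L) {
  base <- fbm_base_path(path)
  json <- paste0(base, ".json")
  bin <- paste0(base, ".bin")
  if (!file.exists(json)) pf_stop_data(sprintf("metadata sidecar not found: %s", json))
  if (!file.exists(bin)) pf_stop_data(sprintf("payload not found: %s", bin))
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != FBM_FORMAT_VERSION)
    pf_stop_data(sprintf("unsupported file-backed matrix format version in %s", json))
  n <- as.integer(meta$n_rows); m <- as.integer(meta$n_cols)
  expected <- 8 * as.numeric(n) * as.numeric(m)
  actual <- file.info(bin)$size
  if (!isTRUE(actual == expected))
    pf_stop_data(sprintf(
      "payload integrity error: %s has %.0f bytes, metadata implies %.0f (%d x %d float64)",
      bin, actual, expected, n, m))
  read_names <- function(f) {
    if (is.null(f) || is.na(f)) return(NULL)
    p <- file.path(dirname(base), f)
    if (!file.exists(p)) pf_stop_data(sprintf("name file not found: %s", p))
    readLines(p)
  }
  rn <- read_names(meta$row_names); cn <- read_names(meta$col_names)
  if (!is.null(rn) && length(rn) != n)
    pf_stop_data("row name file length does not match n_rows")
  if (!is.null(cn) && length(cn) != m)
    pf_stop_data("column name file length does not match n_cols")
  structure(list(bin = bin, json = json, n_rows = n, n_cols = m,
                 row_names = rn, col_names = cn,
                 standardized = isTRUE(meta$standardized),
                 block_size = as.integer(block_size)),
            class = "pf_fbm")
}

#' Read a dense block from a file-backed matrix
#'
#' Ranges are half-open, 0-based `[start, end)` pairs; `NULL` means the full
#' extent.
#'
#' @param fbm a `pf_fbm` handle from [fbm_open()].
#' @param rows,cols integer pairs `c(start, end)`, or `NULL`.
#' @return dense numeric matrix with the corresponding dimnames.
#' @export
fbm_read_block <- function(fbm, rows = NULL, cols = NULL) {
  stopifnot(inherits(fbm, "pf_fbm"))
  rows <- rows %||% c(0L, fbm$n_rows)
  cols <- cols %||% c(0L, fbm$n_cols)
  check_range <- function(r, max, what) {
    if (length(r) != 2L || r[1] < 0 || r[2] > max || r[1] >= r[2])
      pf_stop_input(sprintf(
        "%s range [%s, %s) out of bounds for extent %d", what, r[1], r[2], max))
  }
  check_range(rows, fbm$n_rows, "row"); check_range(cols, fbm$n_cols, "column")
  nr <- rows[2] - rows[1]; nc <- cols[2] - cols[1]
  out <- matrix(0, nr, nc)
  con <- file(fbm$bin, "rb")
  on.exit(close(con), add = TRUE)
  for (j in seq_len(nc)) {
    col0 <- cols[1] + j - 1L           # 0-based column index
    seek(con, 8 * (as.numeric(col0) * fbm$n_rows + rows[1]))
    out[, j] <- readBin(con, "double", n = nr, size = 8L, endian = "little")
  }
  if (!is.null(fbm$row_names)) rownames(out) <- fbm$row_names[(rows[1] + 1L):rows[2]]
  if (!is.null(fbm$col_names)) colnames(out) <- fbm$col_names[(cols[1] + 1L):cols[2]]
  out
}

#' @export
dim.pf_fbm <- function(x) c(x$n_rows, x$n_cols)

#' @export
dimnames.pf_fbm <- function(x) {
  if (is.null(x$row_names) && is.null(x$col_names)) NULL
  else list(x$row_names, x$col_names)
}

#' @export
as.matrix.pf_fbm <- function(x, ...) {
  m <- fbm_read_block(x)
  attr(m, "standardized") <- x$standardized
  m
}

#' @export
print.pf_fbm <- function(x, ...) {
  cat(sprintf("File-backed matrix: %d x %d float64 (%s)\n",
              x$n_rows, x$n_cols, x$bin))
  invisible(x)
}
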
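# Readers and writers: GMT gene sets, dense TSV expression, MatrixMarket
# coordinate format with companion name files, and the file-backed format.
# Names, not indices, are the exchange currency across files.

#' Read a GMT gene-set file into a binary membership matrix
#'
#' Each line: set name, description, then member genes, tab-separated.
#' Duplicate genes within a set are collapsed; set order is preserved; gene
#' rows appear in first-occurrence order.
#'
#' @param path GMT file path.
#' @return binary genes x sets matrix with dimnames; set descriptions in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) pf_stop_data(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) pf_stop_data(sprintf("GMT file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L)
    pf_stop_data(sprintf(
      "malformed GMT line %d in %s: expected name, description and >= 1 gene",
      bad[1], path))
  set_names <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(set_names))
    pf_stop_data(sprintf("duplicate gene-set names in %s: %s", path,
                         paste(unique(set_names[duplicated(set_names)]), collapse = ", ")))
  descriptions <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  genes <- unique(unlist(members))
  C <- matrix(0, length(genes), length(set_names),
              dimnames = list(genes, set_names))
  for (j in seq_along(members)) C[members[[j]], j] <- 1
  attr(C, "descriptions") <- stats::setNames(descriptions, set_names)
  C
}

#' Write a binary membership matrix as a GMT file
#'
#' @param C binary genes x sets matrix with dimnames.
#' @param path output path.
#' @param descriptions optional per-set description strings (defaults to the
#'   matrix's `descriptions` attribute, then `"na"`).
#' @export
write_gmt <- function(C, path, descriptions = NULL) {
  stopifnot_matrix(C)
  if (is.null(rownames(C)) || is.null(colnames(C)))
    pf_stop_input("membership matrix needs dimnames to write GMT")
  descriptions <- descriptions %||% attr(C, "descriptions") %||%
    rep("na", ncol(C))
  lines <- vapply(seq_len(ncol(C)), function(j) {
    paste(c(colnames(C)[j], descriptions[j], rownames(C)[C[, j] == 1]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

mtx_name_files <- function(path) {
  base <- sub("\\.mtx$", "", path)
  list(rows = paste0(base, "_rows.txt"), cols = paste0(base, "_cols.txt"))
}

#' Read an expression matrix (genes x samples)
#'
#' Supported formats: dense TSV (header row = sample names, first column =
#' gene names), MatrixMarket coordinate `.mtx` with companion
#' `_rows.txt`/`_cols.txt` name files (densified, with a size guard), and
#' the package's file-backed format (returned as a lazy `pf_fbm` handle).
#'
#' @param path input file.
#' @param format `"auto"` (by extension) or one of `"tsv"`, `"mtx"`,
#'   `"fbm"`.
#' @param max_cells refuse to densify a MatrixMarket file with more than
#'   this many entries.
#' @return numeric matrix with dimnames, or a `pf_fbm` handle.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx", "fbm"),
                            max_cells = 1e8) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = , txt = "tsv", mtx = "mtx",
                     json = , bin = "fbm",
                     pf_stop_input(sprintf(
                       "cannot infer format from extension of '%s'; pass format=", path)))
  }
  if (format == "fbm") return(fbm_open(path))
  if (!file.exists(path)) pf_stop_data(sprintf("expression file not found: %s", path))
  if (format == "tsv") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    gn <- as.character(df[[1]])
    Y <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(Y) <- "double"
  } else {
    M <- Matrix::readMM(path)
    if (as.numeric(nrow(M)) * ncol(M) > max_cells)
      pf_stop_data(sprintf(
        "MatrixMarket file %s would densify to %d x %d (> max_cells = %g); convert it to the file-backed format instead",
        path, nrow(M), ncol(M), max_cells))
    nf <- mtx_name_files(path)
    if (!file.exists(nf$rows) || !file.exists(nf$cols))
      pf_stop_data(sprintf("companion name files missing for %s (%s, %s)",
                           path, nf$rows, nf$cols))
    gn <- readLines(nf$rows)
    Y <- as.matrix(M)
    colnames(Y) <- readLines(nf$cols)
  }
  if (anyDuplicated(gn)) {
    pf_stop_data(sprintf("duplicate gene names in %s: %s", path,
                         paste(unique(gn[duplicated(gn)]), collapse = ", ")))
  }
  rownames(Y) <- gn
  if (anyNA(Y)) {
    bad <- which(is.na(Y), arr.ind = TRUE)[1, ]
    pf_stop_data(sprintf("missing value in %s at gene '%s', sample '%s'",
                         path, rownames(Y)[bad[1]], colnames(Y)[bad[2]]))
  }
  Y
}

#' Write an expression matrix
#'
#' @param Y numeric genes x samples matrix with dimnames.
#' @param path output path (for `mtx`, companion `_rows.txt`/`_cols.txt`
#'   name files are written next to it).
#' @param format one of `"tsv"`, `"mtx"`, `"fbm"`.
#' @export
write_expression <- function(Y, path, format = c("tsv", "mtx", "fbm")) {
  stopifnot_matrix(Y)
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(Y), Y, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(Y, sparse = TRUE), path)
    nf <- mtx_name_files(path)
    writeLines(rownames(Y), nf$rows)
    writeLines(colnames(Y), nf$cols)
  } else {
    fbm_write(Y, path)
  }
  invisible(path)
}

#' Read a sample label file
#'
#' Tab-separated, two columns (sample, label), with or without a header.
#'
#' @param path file path.
#' @return character vector of labels named by sample.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) pf_stop_data(sprintf("label file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) pf_stop_data(sprintf("label file %s needs two columns", path))
  if (identical(tolower(as.character(df[1, 1])), "sample")) df <- df[-1, , drop = FALSE]
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}
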
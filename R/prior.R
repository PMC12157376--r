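#' Align a gene-set prior matrix to an expression matrix
#'
#' Matches the binary membership matrix to the expression matrix's gene
#' order by exact name (after whitespace trimming): prior genes absent from
#' the expression matrix are dropped, expression genes absent from the prior
#' become all-zero rows (unannotated), and gene sets retaining fewer than
#' `min_overlap` member genes are removed. No identifier mapping between
#' naming schemes is attempted.
#'
#' @param C binary genes x gene-sets matrix with row and column names.
#' @param gene_names character vector of expression-matrix gene names, in
#'   order.
#' @param min_overlap minimum member genes present for a set to be retained.
#' @return binary matrix with `rownames = gene_names`; dropped set names in
#'   the `dropped_sets` attribute.
#' @export
align_prior <- function(C, gene_names, min_overlap = 2L) {
  stopifnot_matrix(C)
  if (is.null(rownames(C)) || is.null(colnames(C)))
    pf_stop_input("prior matrix needs gene row names and set column names")
  if (!all(C %in% c(0, 1)))
    pf_stop_input("prior matrix entries must be 0/1")
  rn <- trimws(rownames(C)); gn <- trimws(gene_names)
  common <- intersect(gn, rn)
  if (length(common) == 0L) {
    pf_stop_data(sprintf(
      "no genes shared between expression matrix and prior; examples of unmatched prior genes: %s",
      paste(utils::head(rn, 5), collapse = ", ")))
  }
  out <- matrix(0, length(gn), ncol(C), dimnames = list(gene_names, colnames(C)))
  out[match(common, gn), ] <- C[match(common, rn), , drop = FALSE]
  keep <- colSums(out) >= min_overlap
  dropped <- colnames(out)[!keep]
  out <- out[, keep, drop = FALSE]
  attr(out, "dropped_sets") <- dropped
  out
}
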
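MODEL_FORMAT_VERSION <- 1L

#' Save a fitted model to a directory
#'
#' `Z`, `B` and `U` are stored as file-backed payloads; penalties, fit
#' configuration, dimensions and payload MD5 checksums go into a JSON
#' manifest; the iteration trace is written as TSV. Loading reproduces the
#' matrices bit for bit.
#'
#' @param model fitted `pathfactor` object.
#' @param dir output directory (created if needed).
#' @export
model_save <- function(model, dir) {
  stopifnot(inherits(model, "pathfactor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fbm_write(model$Z, file.path(dir, "Z"))
  fbm_write(model$B, file.path(dir, "B"))
  has_u <- !is.null(model$U)
  if (has_u) fbm_write(model$U, file.path(dir, "U"))
  payloads <- c("Z", "B", if (has_u) "U")
  checksums <- as.list(tools::md5sum(file.path(dir, paste0(payloads, ".bin"))))
  names(checksums) <- payloads
  ctrl <- model$control
  manifest <- list(
    format_version = MODEL_FORMAT_VERSION,
    package_version = as.character(utils::packageVersion("pathfactor")),
    k = model$k, phase = model$phase,
    lambda1 = model$lambda1, lambda2 = model$lambda2,
    lambda3 = model$lambda3, alpha = model$alpha,
    n_iterations = model$n_iterations, converged = model$converged,
    dims = list(genes = nrow(model$Z), samples = ncol(model$B),
                sets = if (has_u) nrow(model$U) else 0L),
    control = ctrl[!vapply(ctrl, is.null, TRUE)],
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(model$trace, file.path(dir, "trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a fitted model from a directory
#'
#' Verifies the manifest version, payload checksums and dimensions before
#' reconstructing the `pathfactor` object.
#'
#' @param dir directory written by [model_save()].
#' @return a `pathfactor` object.
#' @export
model_load <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) pf_stop_data(sprintf("manifest not found in %s", dir))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$format_version), MODEL_FORMAT_VERSION))
    pf_stop_data(sprintf("unsupported model format version in %s", mf))
  for (nm in names(manifest$checksums)) {
    bin <- file.path(dir, paste0(nm, ".bin"))
    actual <- unname(tools::md5sum(bin))
    if (!identical(actual, manifest$checksums[[nm]]))
      pf_stop_data(sprintf("checksum mismatch for %s payload in %s", nm, dir))
  }
  Z <- as.matrix(fbm_open(file.path(dir, "Z")))
  B <- as.matrix(fbm_open(file.path(dir, "B")))
  U <- if ("U" %in% names(manifest$checksums))
    as.matrix(fbm_open(file.path(dir, "U"))) else NULL
  attr(Z, "standardized") <- NULL; attr(B, "standardized") <- NULL
  if (!is.null(U)) attr(U, "standardized") <- NULL
  d <- manifest$dims
  if (nrow(Z) != d$genes || ncol(B) != d$samples ||
      (!is.null(U) && nrow(U) != d$sets))
    pf_stop_data(sprintf("manifest dimensions disagree with payloads in %s", dir))
  trace_path <- file.path(dir, "trace.tsv")
  trace <- if (file.exists(trace_path))
    utils::read.delim(trace_path, sep = "\t", stringsAsFactors = FALSE) else NULL
  ctrl_args <- manifest$control
  ctrl <- do.call(pf_control, ctrl_args[names(ctrl_args) %in% names(formals(pf_control))])
  new_pathfactor(
    Z = Z, B = B, U = U, C = NULL,
    lambda1 = manifest$lambda1, lambda2 = manifest$lambda2,
    lambda3 = as.numeric(manifest$lambda3), alpha = manifest$alpha,
    k = as.integer(manifest$k),
    singular_values = NULL,
    n_iterations = as.integer(manifest$n_iterations),
    converged = isTRUE(manifest$converged),
    trace = trace, control = ctrl, phase = manifest$phase,
    u_paths = NULL, gene_names = rownames(Z), sample_names = colnames(B))
}
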
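# S3 methods for fitted pathfactor models.

#' @export
print.pathfactor <- function(x, ...) {
  cat("Pathway-informed latent variable factorization\n")
  cat(sprintf("  genes: %d   samples: %d   latent variables: %d\n",
              nrow(x$Z), ncol(x$B), x$k))
  cat(sprintf("  phase: %s   iterations: %d   converged: %s\n",
              x$phase, x$n_iterations, x$converged))
  cat(sprintf("  lambda1 = %.4g   lambda2 = %.4g\n", x$lambda1, x$lambda2))
  if (!is.null(x$U))
    cat(sprintf("  pathway-linked LVs: %d of %d (over %d retained gene sets)\n",
                count_pathway_lvs(x), x$k, nrow(x$U)))
  invisible(x)
}

#' @export
summary.pathfactor <- function(object, ...) {
  obj_final <- utils::tail(object$trace$objective, 1)
  lv <- data.frame(
    lv = seq_len(object$k),
    loading_norm = sqrt(colSums(object$Z^2)),
    score_var = apply(object$B, 1, stats::var),
    n_sets = if (is.null(object$U)) 0L else colSums(object$U > 0),
    lambda3 = object$lambda3
  )
  out <- list(k = object$k, phase = object$phase,
              converged = object$converged,
              n_iterations = object$n_iterations,
              final_objective = obj_final,
              lambda1 = object$lambda1, lambda2 = object$lambda2,
              pathway_linked = count_pathway_lvs(object),
              lv_table = lv)
  class(out) <- "summary.pathfactor"
  out
}

#' @export
print.summary.pathfactor <- function(x, ...) {
  cat(sprintf("pathfactor fit (%s phase): k = %d, %d iterations, converged = %s\n",
              x$phase, x$k, x$n_iterations, x$converged))
  cat(sprintf("final objective: %.6g\n", x$final_objective))
  cat(sprintf("pathway-linked LVs: %d\n", x$pathway_linked))
  print(x$lv_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract coefficients from a pathfactor model
#'
#' @param object fitted model.
#' @param which `"U"` (default) for gene-set x LV pathway coefficients,
#'   `"Z"` for gene loadings, `"B"` for sample scores.
#' @param ... unused.
#' @export
coef.pathfactor <- function(object, which = c("U", "Z", "B"), ...) {
  switch(match.arg(which), U = object$U, Z = object$Z, B = object$B)
}

#' @export
fitted.pathfactor <- function(object, ...) object$Z %*% object$B

#' Residuals of the reconstruction Y - ZB
#'
#' @param object fitted model.
#' @param Y the (standardized) expression matrix the model was fitted to.
#' @param ... unused.
#' @export
residuals.pathfactor <- function(object, Y, ...) {
  if (missing(Y)) pf_stop_input("supply the fitted expression matrix Y")
  if (inherits(Y, "pf_fbm")) Y <- as.matrix(Y)
  Y - fitted(object)
}

#' Project new samples onto fitted loadings
#'
#' Scores for new samples are the ridge projection
#' `B_new = (Z'Z + lambda2 I)^-1 Z' Y_new`, after matching genes by name and
#' (by default) row-standardizing the new data.
#'
#' @param object fitted model.
#' @param newdata genes x samples matrix with gene row names.
#' @param standardize row-standardize `newdata` first.
#' @param ... unused.
#' @return k x samples score matrix.
#' @export
predict.pathfactor <- function(object, newdata, standardize = TRUE, ...) {
  if (missing(newdata)) return(object$B)
  stopifnot_matrix(newdata)
  gn <- object$gene_names
  if (!is.null(gn)) {
    missing_genes <- setdiff(gn, rownames(newdata))
    if (length(missing_genes) > 0)
      pf_stop_data(sprintf("newdata lacks %d model genes (e.g. %s)",
                           length(missing_genes),
                           paste(utils::head(missing_genes, 5), collapse = ", ")))
    newdata <- newdata[gn, , drop = FALSE]
  }
  if (standardize) newdata <- suppressWarnings(row_standardize(newdata))
  update_B(newdata, object$Z, object$lambda2)
}

#' Simulate expression data from a fitted model
#'
#' Draws `Y* = ZB + E` with i.i.d. Gaussian noise at the residual scale of
#' the fit.
#'
#' @param object fitted model.
#' @param nsim number of simulated matrices.
#' @param seed optional seed.
#' @param Y the fitted expression matrix, used to estimate the residual
#'   standard deviation; if missing, unit noise is used.
#' @param ... unused.
#' @return list of `nsim` matrices.
#' @export
simulate.pathfactor <- function(object, nsim = 1, seed = NULL, Y, ...) {
  mu <- fitted(object)
  sigma <- if (missing(Y)) 1 else stats::sd(as.vector(residuals(object, Y)))
  runner <- function() mu + matrix(stats::rnorm(length(mu), 0, sigma),
                                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  if (!is.null(seed)) with_seed(seed, replicate(nsim, runner(), simplify = FALSE))
  else replicate(nsim, runner(), simplify = FALSE)
}

#' Plot the objective trace of a fit
#'
#' Objective value per iteration, split by phase; full-phase iterations at
#' which the pathway coefficients were refreshed are marked.
#'
#' @param x fitted model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pathfactor <- function(x, ...) {
  tr <- x$trace
  tr <- tr[is.finite(tr$objective), , drop = FALSE]
  idx <- seq_len(nrow(tr))
  graphics::plot(idx, tr$objective, type = "l", log = "y",
                 xlab = "iteration (both phases)", ylab = "objective",
                 main = "pathfactor objective trace", ...)
  full <- tr$phase == "full"
  if (any(full)) graphics::lines(idx[full], tr$objective[full], col = "steelblue")
  upd <- which(tr$u_updated)
  if (length(upd)) graphics::abline(v = idx[upd], lty = 3, col = "grey50")
  invisible(x)
}
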
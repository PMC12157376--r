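# Outer cross-validation: mask a fraction of each gene set's annotations
# before fitting, then test whether the masked member genes rank high in the
# corresponding LV's loadings (rank-sum AUC, BH FDR). Also the
# tissue-alignment t-statistic summary over sample labels.

#' Build a held-out annotation plan
#'
#' Masks a stratified random fraction of each gene set's member genes:
#' `round(fraction * members)` per set (at least 1 for sets with two or
#' more members). Single-member sets are skipped and recorded. The returned
#' `masked_C` is the prior to fit on; the original prior is kept for
#' scoring.
#'
#' @param C binary genes x gene-sets matrix with dimnames.
#' @param fraction fraction of members to mask (default 0.10).
#' @param seed seed making the plan deterministic.
#' @return a `pf_holdout` list: `held_out` (set name -> masked gene
#'   indices), `masked_C`, `fraction`, `seed`, `skipped`.
#' @export
make_holdout <- function(C, fraction = 0.10, seed = 1L) {
  stopifnot_matrix(C)
  if (ncol(C) < 1L) pf_stop_input("prior has no gene sets")
  if (fraction <= 0 || fraction >= 1) pf_stop_input("fraction must be in (0, 1)")
  sets <- colnames(C) %||% as.character(seq_len(ncol(C)))
  held <- list(); skipped <- character(0)
  masked <- C
  with_seed(seed, {
    for (j in seq_len(ncol(C))) {
      members <- which(C[, j] == 1)
      if (length(members) < 2L) { skipped <- c(skipped, sets[j]); next }
      n_mask <- max(1L, round(fraction * length(members)))
      sel <- sample(members, n_mask)
      held[[sets[j]]] <- sort(sel)
      masked[sel, j] <- 0
    }
  })
  structure(list(held_out = held, masked_C = masked,
                 fraction = fraction, seed = seed, skipped = skipped),
            class = "pf_holdout")
}

#' Rank-sum AUC of held-out versus background loadings
#'
#' The Mann-Whitney U statistic normalized to `[0, 1]`: the probability that
#' a random held-out gene outranks a random background gene on the LV's
#' loadings (ties count one half). The one-sided p-value (held-out greater)
#' uses the exact rank-sum distribution when `n1 * n2 <= 400` and there are
#' no ties, otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param heldout,background non-empty numeric vectors of loading values.
#' @return list with `auc` and `p_value`.
#' @export
ranksum_auc <- function(heldout, background) {
  n1 <- length(heldout); n2 <- length(background)
  if (n1 == 0L || n2 == 0L) pf_stop_input("both loading vectors must be non-empty")
  comb <- c(heldout, background)
  if (anyNA(comb)) pf_stop_input("loading vectors contain missing values")
  r <- rank(comb)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- U1 / (n1 * n2)
  has_ties <- anyDuplicated(comb) > 0
  if (!has_ties && n1 * n2 <= 400) {
    p <- 1 - stats::pwilcox(U1 - 1, n1, n2)
  } else {
    N <- n1 + n2
    tt <- table(comb)
    tie_term <- sum(tt^3 - tt)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    p <- if (sigma2 <= 0) 1 else
      stats::pnorm((U1 - n1 * n2 / 2 - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  list(auc = auc, p_value = min(max(p, .Machine$double.xmin), 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (monotone, clipped at 1), with input
#' validation: p-values must lie in (0, 1].
#'
#' @param p numeric vector of p-values.
#' @return vector of adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    pf_stop_input("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Score held-out annotation recovery
#'
#' For every (LV, gene set) pair with positive pathway coefficient in the
#' fitted `U`, tests whether the set's masked member genes have higher
#' loadings on that LV than background genes (genes never annotated to the
#' set — a set's own unmasked members are excluded from its background).
#' Pairs without held-out genes are omitted. BH FDR is attached across all
#' tested pairs.
#'
#' @param model `pathfactor` fit obtained on `plan$masked_C`.
#' @param C_original the unmasked prior.
#' @param plan the [make_holdout()] plan used for fitting.
#' @param all_pairs test every (LV, set) pair regardless of `U` support
#'   (exploratory).
#' @return a `pf_crossval` data frame with columns `lv`, `set`, `auc`,
#'   `pval`, `fdr`, `n_heldout`, `n_background`.
#' @export
crossval_report <- function(model, C_original, plan, all_pairs = FALSE) {
  stopifnot(inherits(model, "pathfactor"), inherits(plan, "pf_holdout"))
  empty <- data.frame(lv = integer(0), set = character(0), auc = numeric(0),
                      pval = numeric(0), fdr = numeric(0),
                      n_heldout = integer(0), n_background = integer(0))
  class(empty) <- c("pf_crossval", "data.frame")
  if (is.null(model$U) || nrow(model$U) == 0L) return(empty)
  sets <- rownames(model$U) %||% colnames(C_original)
  rows <- list()
  for (lv in seq_len(model$k)) {
    for (si in seq_along(sets)) {
      s <- sets[si]
      if (!all_pairs && model$U[si, lv] <= 0) next
      held <- plan$held_out[[s]]
      if (is.null(held) || length(held) == 0L) next
      members <- which(C_original[, s] == 1)
      background <- setdiff(seq_len(nrow(model$Z)), members)
      if (length(background) == 0L) next
      res <- ranksum_auc(model$Z[held, lv], model$Z[background, lv])
      rows[[length(rows) + 1L]] <- data.frame(
        lv = lv, set = s, auc = res$auc, pval = res$p_value, fdr = NA_real_,
        n_heldout = length(held), n_background = length(background))
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$pval)
  class(out) <- c("pf_crossval", "data.frame")
  out
}

#' Count LVs passing AUC thresholds at an FDR gate
#'
#' For each LV, keeps its tested pairs with FDR below `fdr_cutoff` and takes
#' the maximal AUC among them (ties on AUC broken by lower FDR, then set
#' name); each threshold then counts LVs whose best AUC reaches it.
#'
#' @param report a [crossval_report()] result.
#' @param thresholds AUC thresholds.
#' @param fdr_cutoff FDR gate applied before taking the per-LV maximum.
#' @return data frame with columns `threshold`, `n_lvs`, plus the per-LV
#'   best pairs in the `best_pairs` attribute.
#' @export
lv_auc_summary <- function(report, thresholds = c(0.7, 0.8, 0.9),
                           fdr_cutoff = 0.05) {
  if (nrow(report) == 0L) {
    return(data.frame(threshold = thresholds, n_lvs = 0L))
  }
  keep <- report[report$fdr < fdr_cutoff, , drop = FALSE]
  best <- NULL
  if (nrow(keep) > 0L) {
    ord <- order(keep$lv, -keep$auc, keep$fdr, keep$set)
    keep <- keep[ord, , drop = FALSE]
    best <- keep[!duplicated(keep$lv), , drop = FALSE]
  }
  counts <- vapply(thresholds,
                   function(t) if (is.null(best)) 0L else sum(best$auc >= t),
                   integer(1))
  out <- data.frame(threshold = thresholds, n_lvs = counts)
  attr(out, "best_pairs") <- best
  out
}

welch_t_rows <- function(B, in_idx) {
  x <- B[, in_idx, drop = FALSE]
  y <- B[, -in_idx, drop = FALSE]
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  (mx - my) / sqrt(vx / ncol(x) + vy / ncol(y))
}

#' Tissue / condition alignment of latent variables
#'
#' For every sample label, computes the Welch (unequal-variance) two-sample
#' t-statistic of each LV's scores between in-label samples and all others,
#' and reports the per-label maximum over LVs with the achieving LV. Labels
#' with fewer than two samples (on either side) are skipped with a warning.
#'
#' @param B k x samples score matrix with column names, or a `pathfactor`
#'   fit.
#' @param labels character vector of sample labels, named by sample where
#'   `B` has column names.
#' @return a `pf_alignment` data frame with columns `label`, `best_lv`,
#'   `max_t`.
#' @export
tissue_alignment <- function(B, labels) {
  if (inherits(B, "pathfactor")) B <- B$B
  stopifnot_matrix(B)
  if (!is.null(colnames(B)) && !is.null(names(labels))) {
    unmatched <- setdiff(colnames(B), names(labels))
    if (length(unmatched) > 0)
      pf_stop_data(sprintf("samples without labels: %s",
                           paste(utils::head(unmatched, 10), collapse = ", ")))
    labels <- labels[colnames(B)]
  }
  if (length(labels) != ncol(B))
    pf_stop_input("labels must cover every sample")
  rows <- list()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < 2L || ncol(B) - length(idx) < 2L) {
      warning(sprintf("label '%s' skipped: needs >= 2 samples on both sides", lab),
              call. = FALSE)
      next
    }
    t <- welch_t_rows(B, idx)
    rows[[length(rows) + 1L]] <- data.frame(
      label = lab, best_lv = which.max(t), max_t = max(t))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), best_lv = integer(0), max_t = numeric(0))
  class(out) <- c("pf_alignment", "data.frame")
  out
}

#' Write validation reports as tab-separated files
#'
#' Fixed headers: `lv, set, auc, pval, fdr, n_heldout, n_background` for
#' cross-validation reports; `label, best_lv, max_t` for alignment reports.
#'
#' @param report a `pf_crossval` or `pf_alignment` data frame.
#' @param path output file path.
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
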
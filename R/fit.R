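#' Fitting configuration
#'
#' Collects every tunable of the two-phase fit. Defaults follow the method's
#' stated conventions: a 20-point penalty path, 5-fold internal
#' cross-validation with the one-standard-error rule, `U` refreshed every
#' other full-phase iteration with at most 5 refreshes, and a 10% holdout
#' fraction for the outer validation.
#'
#' @param k number of latent variables.
#' @param tol relative Frobenius change of `B` below which a phase stops.
#' @param base_max_iter,full_max_iter iteration caps for the two phases.
#' @param u_update_period refresh `U` every this many full-phase iterations.
#' @param max_u_updates total cap on `U` refreshes (the entry fit counts).
#' @param n_lambda number of candidate penalties on the per-LV path.
#' @param cv_folds internal cross-validation folds for the per-LV path.
#' @param alpha L1 mixing weight of the elastic penalty on `U` columns.
#' @param lambda_min_ratio span of the geometric penalty path (default: 3
#'   decades below the empty-model penalty).
#' @param one_se use the one-standard-error selection rule (`FALSE` selects
#'   the CV-minimizing penalty).
#' @param holdout_fraction fraction of each gene set's members masked by
#'   [make_holdout()].
#' @param min_overlap minimum member genes for a prior set to be retained.
#' @param block_size column block size for streamed kernels.
#' @param seed base seed; per-LV fold assignments derive from `seed + lv`.
#' @param lambda1,lambda2 optional overrides of the spectrally derived ridge
#'   penalties.
#' @return a list of class `pf_control`.
#' @export
pf_control <- function(k = NULL, tol = 1e-6,
                       base_max_iter = 500L, full_max_iter = 200L,
                       u_update_period = 2L, max_u_updates = 5L,
                       n_lambda = 20L, cv_folds = 5L, alpha = 0.9,
                       lambda_min_ratio = 1e-3, one_se = TRUE,
                       holdout_fraction = 0.10, min_overlap = 2L,
                       block_size = 1000L, seed = 1L,
                       lambda1 = NULL, lambda2 = NULL) {
  ctrl <- list(k = if (is.null(k)) NULL else as.integer(k), tol = tol, base_max_iter = as.integer(base_max_iter),
               full_max_iter = as.integer(full_max_iter),
               u_update_period = as.integer(u_update_period),
               max_u_updates = as.integer(max_u_updates),
               n_lambda = as.integer(n_lambda), cv_folds = as.integer(cv_folds),
               alpha = alpha, lambda_min_ratio = lambda_min_ratio,
               one_se = isTRUE(one_se), holdout_fraction = holdout_fraction,
               min_overlap = as.integer(min_overlap),
               block_size = as.integer(block_size), seed = as.integer(seed),
               lambda1 = lambda1, lambda2 = lambda2)
  if (ctrl$holdout_fraction <= 0 || ctrl$holdout_fraction >= 1)
    pf_stop_input("holdout_fraction must be in (0, 1)")
  if (ctrl$n_lambda < 2L) pf_stop_input("n_lambda must be at least 2")
  if (ctrl$u_update_period < 1L) pf_stop_input("u_update_period must be >= 1")
  structure(ctrl, class = "pf_control")
}

rel_change <- function(new, old) {
  denom <- sqrt(sum(old^2))
  if (denom == 0) return(Inf)
  sqrt(sum((new - old)^2)) / denom
}

trace_row <- function(iteration, phase, objective, delta_b, u_updated) {
  data.frame(iteration = iteration, phase = phase, objective = objective,
             delta_b = delta_b, u_updated = u_updated)
}

new_pathfactor <- function(...) structure(list(...), class = "pathfactor")

#' Prior-free base phase
#'
#' Alternates the closed-form `B` and projected `Z` updates from the
#' spectral initialization until the relative Frobenius change of `B` drops
#' below `tol` or `base_max_iter` is reached. With `U = 0` the prior term is
#' the ridge `lambda1 ||Z||_F^2`, so no prior matrix is involved.
#'
#' @param Y standardized genes x samples matrix or `pf_fbm` handle.
#' @param control a [pf_control()] list with `k` set.
#' @param init optional precomputed [svd_init()] result.
#' @return a `pathfactor` object with `U = NULL` and an iteration `trace`.
#' @export
fit_base <- function(Y, control = pf_control(), init = NULL) {
  if (!bk_standardized(Y))
    pf_stop_input("Y must be row-standardized before fitting")
  k <- control$k
  if (is.null(k)) pf_stop_input("control$k must be set")
  init <- init %||% svd_init(Y, k)
  lambda1 <- control$lambda1 %||% init$lambda1
  lambda2 <- control$lambda2 %||% init$lambda2
  Z <- init$Z; B <- init$B
  obj_prev <- objective_value(Y, Z, B, lambda1, lambda2)
  trace <- list(); converged <- FALSE; it <- 0L
  while (it < control$base_max_iter) {
    it <- it + 1L
    Z_new <- update_Z(Y, B, lambda1)
    B_new <- update_B(Y, Z_new, lambda2)
    obj <- objective_value(Y, Z_new, B_new, lambda1, lambda2)
    if (obj > obj_prev) {
      # descent safeguard: redo the iteration with the exact Z minimizer,
      # which cannot increase the objective from the previous iterate
      Z_new <- update_Z(Y, B, lambda1, exact = TRUE)
      B_new <- update_B(Y, Z_new, lambda2)
      obj <- objective_value(Y, Z_new, B_new, lambda1, lambda2)
    }
    delta <- rel_change(B_new, B)
    Z <- Z_new; B <- B_new; obj_prev <- obj
    trace[[it]] <- trace_row(it, "base", obj, delta, FALSE)
    if (delta < control$tol) { converged <- TRUE; break }
  }
  new_pathfactor(
    Z = Z, B = B, U = NULL, C = NULL,
    lambda1 = lambda1, lambda2 = lambda2, lambda3 = rep(0, k),
    alpha = control$alpha, k = k,
    singular_values = init$singular_values,
    n_iterations = it, converged = converged,
    trace = do.call(rbind, trace) %||%
      trace_row(integer(0), character(0), numeric(0), numeric(0), logical(0)),
    control = control, phase = "base", u_paths = NULL)
}

# Unpenalized refit on the selected support: non-negative least squares on
# the set columns with a free intercept, solved by 2-block coordinate
# descent (each block is an exact convex minimizer, so this converges).
nnls_with_intercept <- function(X, z, max_iter = 200L, tol = 1e-12) {
  mu <- 0; u <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    u_new <- pracma::lsqnonneg(X, z - mu)$x
    mu_new <- mean(z - X %*% u_new)
    done <- abs(mu_new - mu) + sum(abs(u_new - u)) < tol
    u <- u_new; mu <- mu_new
    if (done) break
  }
  list(u = u, intercept = mu)
}

empty_upath <- function(lv_index, p, set_names = NULL, n_lambda = 0L) {
  u <- stats::setNames(numeric(p), set_names)
  structure(list(lv_index = lv_index, lambda_path = numeric(n_lambda),
                 cv_error = numeric(n_lambda), cv_se = numeric(n_lambda),
                 selected_lambda = 0, support = integer(0), u = u,
                 lambda3 = 0),
            class = "pf_upath")
}

#' Per-LV cross-validated sparse non-negative pathway regression
#'
#' Regresses one LV's gene loadings on the prior membership columns with an
#' L1-dominated elastic penalty under non-negativity, with an unpenalized
#' intercept absorbing the baseline of the non-negative loadings (solved by
#' glmnet). The penalty path holds `n_lambda` geometrically
#' spaced values spanning `lambda_min_ratio` below the smallest penalty
#' giving an empty model; the penalty is chosen by `cv_folds`-fold
#' cross-validation with the one-standard-error rule, and the selected
#' support is refit by unpenalized non-negative least squares to remove
#' attenuation bias. An empty support (the LV carries no prior signal) is a
#' valid, common outcome.
#'
#' @param z numeric gene-loading vector (one column of `Z`).
#' @param C binary genes x gene-sets matrix aligned to `z`.
#' @param control a [pf_control()] list.
#' @param lv_index LV index; fold assignment is seeded by `seed + lv_index`.
#' @return a `pf_upath` list: `lambda_path`, `cv_error`, `cv_se`,
#'   `selected_lambda`, `support` (column indices), full-length non-negative
#'   coefficient vector `u` (exact zeros off the support), and the
#'   objective-scale penalty `lambda3`.
#' @export
fit_pathway_u <- function(z, C, control = pf_control(), lv_index = 1L) {
  p <- ncol(C)
  if (length(z) != nrow(C)) pf_stop_input("loading vector and prior disagree on gene count")
  if (p == 0L || all(colSums(abs(C)) == 0) || stats::sd(z) == 0)
    return(empty_upath(lv_index, p, colnames(C)))
  n <- length(z)
  X <- C
  padded <- FALSE
  if (p == 1L) { X <- cbind(X, 0); padded <- TRUE }  # glmnet needs >= 2 columns
  # an unpenalized intercept absorbs the baseline of the (non-negative)
  # loading vector; without it every set picks up a spurious positive weight
  lmax <- tryCatch(
    glmnet::glmnet(X, z, alpha = control$alpha, lower.limits = 0,
                   intercept = TRUE, nlambda = 5)$lambda[1],
    error = function(e) NA_real_)
  if (!is.finite(lmax) || lmax <= 0)
    return(empty_upath(lv_index, p, colnames(C)))
  path <- lmax * 10^seq(0, log10(control$lambda_min_ratio),
                        length.out = control$n_lambda)
  foldid <- with_seed(control$seed + lv_index,
                      sample(rep_len(seq_len(control$cv_folds), n)))
  cv <- glmnet::cv.glmnet(X, z, alpha = control$alpha, lambda = path,
                          lower.limits = 0, intercept = TRUE,
                          foldid = foldid, standardize = TRUE)
  sel <- if (control$one_se) cv$lambda.1se else cv$lambda.min
  if (is.na(sel)) sel <- cv$lambda.min
  if (is.na(sel)) return(empty_upath(lv_index, p, colnames(C)))
  beta <- as.vector(stats::coef(cv$glmnet.fit, s = sel))[-1]
  if (padded) beta <- beta[1]
  # coefficients sitting numerically on the constraint boundary are zero
  support <- which(beta > 1e-8)
  u <- stats::setNames(numeric(p), colnames(C))
  if (length(support) > 0) {
    refit <- nnls_with_intercept(matrix(as.numeric(C[, support]), n), z)
    u[support] <- refit$u
  }
  lambda3 <- if (any(u > 0)) 2 * n * sel else 0
  # cv results aligned back to the requested path (cv.glmnet keeps the order)
  cvm <- cv$cvm[match(signif(path, 10), signif(cv$lambda, 10))]
  cvs <- cv$cvsd[match(signif(path, 10), signif(cv$lambda, 10))]
  structure(list(lv_index = lv_index, lambda_path = path,
                 cv_error = cvm, cv_se = cvs, selected_lambda = sel,
                 support = support, u = u, lambda3 = lambda3),
            class = "pf_upath")
}

refresh_U <- function(Z, C, control) {
  k <- ncol(Z)
  paths <- lapply(seq_len(k), function(l) fit_pathway_u(Z[, l], C, control, l))
  U <- vapply(paths, function(pz) pz$u, numeric(ncol(C)))
  U <- matrix(U, nrow = ncol(C), ncol = k,
              dimnames = list(colnames(C), colnames(Z)))
  list(U = U, lambda3 = vapply(paths, function(pz) pz$lambda3, 0),
       paths = paths)
}

#' Prior-integrating full phase
#'
#' Starting from a converged base-phase model, expresses each LV's loadings
#' as a sparse non-negative combination of prior sets ([fit_pathway_u()])
#' and alternates the closed-form updates with `Z` shrunk toward `C U`.
#' Because the pathway coefficients change slowly, `U` is refit once at
#' entry and then only on every `u_update_period`-th iteration, with at most
#' `max_u_updates` refits in total; afterwards `U` is frozen while `Z`, `B`
#' iterate to convergence.
#'
#' @param Y standardized genes x samples matrix or `pf_fbm` handle.
#' @param C binary prior aligned to `Y`'s genes (see [align_prior()]).
#' @param control a [pf_control()] list with `k` set.
#' @param base optional base-phase model from [fit_base()].
#' @return a `pathfactor` object carrying `U`, per-LV `lambda3`, the per-LV
#'   path diagnostics in `u_paths`, and the concatenated iteration `trace`.
#' @export
fit_full <- function(Y, C, control = pf_control(), base = NULL) {
  if (!bk_standardized(Y))
    pf_stop_input("Y must be row-standardized before fitting")
  gn <- bk_rownames(Y)
  if (!is.null(gn) && !identical(rownames(C), gn)) {
    bad <- utils::head(c(setdiff(rownames(C), gn), setdiff(gn, rownames(C))), 10)
    pf_stop_data(sprintf(
      "prior gene names not aligned to expression matrix; offending genes include: %s (use align_prior)",
      paste(bad, collapse = ", ")))
  }
  if (nrow(C) != bk_nrow(Y))
    pf_stop_data("prior and expression matrix disagree on gene count")
  base <- base %||% fit_base(Y, control)
  k <- base$k
  lambda1 <- base$lambda1; lambda2 <- base$lambda2
  Z <- base$Z; B <- base$B
  up <- refresh_U(Z, C, control)
  U <- up$U; lambda3 <- up$lambda3; paths <- up$paths
  u_updates <- 1L
  Tm <- C %*% U
  obj_prev <- objective_value(Y, Z, B, lambda1, lambda2, C, U, lambda3, control$alpha)
  trace <- list(trace_row(0L, "full", obj_prev, NA_real_, TRUE))
  converged <- FALSE; it <- 0L
  while (it < control$full_max_iter) {
    it <- it + 1L
    u_updated <- FALSE
    if (it %% control$u_update_period == 0L && u_updates < control$max_u_updates) {
      up <- refresh_U(Z, C, control)
      U <- up$U; lambda3 <- up$lambda3; paths <- up$paths
      Tm <- C %*% U
      u_updates <- u_updates + 1L
      u_updated <- TRUE
      # the cross-validated penalties lambda3 changed, so the previous
      # objective value is not comparable; re-anchor the descent safeguard
      obj_prev <- objective_value(Y, Z, B, lambda1, lambda2, C, U, lambda3,
                                  control$alpha)
    }
    Z_new <- update_Z(Y, B, lambda1, prior_target = Tm)
    B_new <- update_B(Y, Z_new, lambda2)
    obj <- objective_value(Y, Z_new, B_new, lambda1, lambda2, C, U, lambda3,
                           control$alpha)
    if (obj > obj_prev) {
      # descent safeguard: redo the iteration with the exact Z minimizer
      Z_new <- update_Z(Y, B, lambda1, prior_target = Tm, exact = TRUE)
      B_new <- update_B(Y, Z_new, lambda2)
      obj <- objective_value(Y, Z_new, B_new, lambda1, lambda2, C, U, lambda3,
                             control$alpha)
    }
    delta <- rel_change(B_new, B)
    Z <- Z_new; B <- B_new; obj_prev <- obj
    trace[[it + 1L]] <- trace_row(it, "full", obj, delta, u_updated)
    if (delta < control$tol && !u_updated) { converged <- TRUE; break }
  }
  new_pathfactor(
    Z = Z, B = B, U = U, C = C,
    lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
    alpha = control$alpha, k = k,
    singular_values = base$singular_values,
    n_iterations = it, converged = converged,
    trace = rbind(base$trace, do.call(rbind, trace)),
    control = control, phase = "full", u_paths = paths)
}

#' Count latent variables linked to at least one prior set
#'
#' Number of LVs whose `U` column has a positive entry. No target fraction
#' is enforced: depending on the data, all, some, or none of the LVs may be
#' pathway-linked.
#'
#' @param model a fitted `pathfactor` object.
#' @return integer count.
#' @export
count_pathway_lvs <- function(model) {
  stopifnot(inherits(model, "pathfactor"))
  if (is.null(model$U) || nrow(model$U) == 0L) return(0L)
  sum(colSums(model$U > 0) > 0)
}

#' Fit a pathway-informed latent variable factorization
#'
#' The front end to the two-phase fit. The expression matrix is
#' row-standardized if it is not already; the prior is aligned to the
#' expression genes by name; the prior-free base phase runs to convergence
#' from a truncated-SVD start with spectrally derived ridge penalties; and,
#' when a prior is supplied, the full phase aligns LVs to gene sets via
#' per-LV cross-validated sparse non-negative regression.
#'
#' @param Y numeric genes x samples matrix with dimnames, or a `pf_fbm`
#'   handle from [fbm_open()] for out-of-core fitting.
#' @param prior optional binary genes x gene-sets matrix (e.g. from
#'   [read_gmt()]); `NULL` fits the prior-free model only.
#' @param k number of latent variables.
#' @param control a [pf_control()] list; `k` here overrides `control$k`.
#' @param ... passed to [pf_control()] when `control` is not supplied.
#' @return an object of class `pathfactor`: non-negative loadings `Z`
#'   (genes x k), scores `B` (k x samples), pathway coefficients `U`
#'   (sets x k, or `NULL`), penalties `lambda1`, `lambda2`, per-LV
#'   `lambda3`, the iteration `trace`, and per-LV path diagnostics
#'   `u_paths`. Methods: `print`, `summary`, `coef`, `fitted`, `residuals`,
#'   `predict`, `plot`, `simulate`.
#' @examples
#' sim <- make_synthetic(synth_spec(n_genes = 150, n_samples = 40, n_sets = 6,
#'                                  k = 4, prior_lvs = 2, genes_per_set = 15,
#'                                  n_labels = 2, seed = 7))
#' fit <- pathfactor(sim$Y, sim$C, k = 4, seed = 7)
#' fit
#' count_pathway_lvs(fit)
#' @export
pathfactor <- function(Y, prior = NULL, k = NULL, control = NULL, ...) {
  cl <- match.call()
  control <- control %||% pf_control(...)
  if (!is.null(k)) control$k <- as.integer(k)
  if (is.null(control$k)) pf_stop_input("number of latent variables 'k' must be given")
  if (!bk_is_backend(Y)) pf_stop_input("Y must be a numeric matrix or a pf_fbm handle")
  if (control$k > min(bk_nrow(Y), bk_ncol(Y)))
    pf_stop_input(sprintf("k = %d exceeds min(genes, samples) = %d",
                          control$k, min(bk_nrow(Y), bk_ncol(Y))))
  Ys <- if (bk_standardized(Y)) Y else row_standardize(Y)
  fit <- if (is.null(prior)) {
    fit_base(Ys, control)
  } else {
    Ca <- align_prior(prior, bk_rownames(Ys) %||% as.character(seq_len(bk_nrow(Ys))),
                      min_overlap = control$min_overlap)
    fit_full(Ys, Ca, control)
  }
  fit$call <- cl
  fit$gene_names <- bk_rownames(Ys)
  fit$sample_names <- bk_colnames(Ys)
  fit$zeroed_rows <- attr(Ys, "zeroed_rows")
  fit
}
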
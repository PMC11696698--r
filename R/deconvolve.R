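#' Aggregate non-negative prototype weights into type proportions
#'
#' Sums the (non-negative) weights of all prototypes of each cell type at
#' each spot and divides by the spot's total weight, so each spot's
#' proportions lie on the probability simplex. Spots whose total weight is
#' zero carry no signal for any type; they get a uniform row `1/K` and a
#' warning naming them.
#'
#' @param M Non-negative weight matrix, spots x cells (e.g. from
#'   [nnls_weights()]).
#' @param cell_type Character vector of type labels, one per column of `M`.
#' @return A wide tibble: `spot` identifier column followed by one numeric
#'   column per cell type, in lexicographic type order. Spots that fell
#'   back to the uniform row are listed in the attribute `fallback_spots`.
#' @examples
#' M <- matrix(c(1, 3), 1, dimnames = list("s1", NULL))
#' aggregate_nnls(M, c("A", "B"))
#' @export
aggregate_nnls <- function(M, cell_type) {
  if (any(M < -1e-12)) {
    abort("`M` has negative entries; aggregate_nnls() expects NNLS weights.")
  }
  aggregate_weights(pmax(M, 0), cell_type, soft_threshold = FALSE)
}

#' Aggregate unconstrained weights with soft thresholding
#'
#' For ordinary least squares weights, which may be negative, each cell
#' type's weights are first summed per spot and the *per-type sums* are
#' clamped at zero (soft thresholding, `(z)+ = max(z, 0)`) before
#' normalizing across types. Clamping the sums rather than individual
#' entries lets negative and positive prototype weights of the same type
#' cancel first. Spots whose clamped sums are all zero fall back to a
#' uniform row with a warning.
#'
#' @param M Weight matrix, spots x cells (e.g. from [ols_weights()]);
#'   entries may be negative.
#' @inheritParams aggregate_nnls
#' @return A wide tibble as in [aggregate_nnls()].
#' @export
aggregate_sls <- function(M, cell_type) {
  aggregate_weights(M, cell_type, soft_threshold = TRUE)
}

aggregate_weights <- function(M, cell_type, soft_threshold) {
  cell_type <- as.character(cell_type)
  if (length(cell_type) != ncol(M)) {
    abort(sprintf(
      "%d labels for %d weight columns.", length(cell_type), ncol(M)
    ))
  }
  types <- sort(unique(cell_type))
  ind <- outer(cell_type, types, "==") * 1     # cells x K membership
  S <- M %*% ind                                # per-type weight sums
  if (soft_threshold) S <- pmax(S, 0)
  denom <- rowSums(S)
  bad <- denom <= 0
  if (any(bad)) {
    ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
    warn(sprintf(
      "%d spot(s) had no positive weight; assigned uniform proportions: %s",
      sum(bad), paste(utils::head(ids[bad], 5), collapse = ", ")
    ))
    S[bad, ] <- 1
    denom[bad] <- length(types)
  }
  P <- S / denom
  colnames(P) <- types
  out <- dplyr::bind_cols(
    tibble(spot = rownames(M) %||% sprintf("spot%04d", seq_len(nrow(M)))),
    as_tibble(P)
  )
  attr(out, "fallback_spots") <- unname(which(bad))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Soft-thresholded least squares (SLS) deconvolution
#'
#' The fast, tuning-free estimator: closed-form OLS prototype weights
#' ([ols_weights()]) followed by soft-thresholded per-type aggregation
#' ([aggregate_sls()]). Reference and spatial data must share the same
#' gene space (see [align_genes()] / [preprocess()]).
#'
#' @param ref A [reference_profile].
#' @param spatial A [spatial_expression] gene-aligned with `ref`.
#' @return A `deconv_fit` object; its `proportions` element is a wide
#'   tibble of per-spot type proportions. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' sim <- simulate_mixture(n_genes = 40, n_spots = 20, noise = "none",
#'                         seed = 1)
#' fit <- deconv_sls(sim$reference, sim$spatial)
#' glance(fit)
#' @export
deconv_sls <- function(ref, spatial) {
  check_deconv_inputs(ref, spatial)
  t0 <- proc.time()[["elapsed"]]
  M <- ols_weights(spatial$counts, ref$counts)
  P <- aggregate_sls(M, ref$cell_type)
  elapsed <- proc.time()[["elapsed"]] - t0
  new_deconv_fit(P, ref, spatial, method = "SLS", lambda = NULL,
                 cv = NULL, elapsed = elapsed)
}

#' Non-negative least squares (NNLS) deconvolution
#'
#' The reference estimator: ridge-penalized NNLS prototype weights by
#' projected gradient descent ([nnls_weights()]), aggregated into type
#' proportions ([aggregate_nnls()]). When `lambda` is a vector, the
#' penalty is first selected by gene-split cross-validation
#' ([cv_lambda()]) and the model is refitted on all genes with the
#' selected value.
#'
#' @inheritParams deconv_sls
#' @param lambda Ridge penalty: a single value (default 0.1) or a grid of
#'   candidates triggering cross-validation.
#' @param lr Gradient step size (default 0.1).
#' @param epochs Gradient iterations (default 1000).
#' @param n_fold Cross-validation folds when `lambda` is a grid
#'   (default 5).
#' @param warm_start Initialize at the clamped OLS solution
#'   (default `TRUE`).
#' @param seed Integer seed for the cross-validation gene shuffle.
#' @return A `deconv_fit`; when cross-validation ran, its `cv` element is
#'   the [cv_lambda()] report.
#' @export
deconv_nnls <- function(ref, spatial, lambda = 0.1, lr = 0.1,
                        epochs = 1000, n_fold = 5, warm_start = TRUE,
                        seed = NULL) {
  check_deconv_inputs(ref, spatial)
  t0 <- proc.time()[["elapsed"]]
  cv <- NULL
  if (length(lambda) > 1) {
    cv <- cv_lambda(spatial$counts, ref$counts, lambda_grid = lambda,
                    n_fold = n_fold, lr = lr, epochs = epochs,
                    warm_start = warm_start, seed = seed)
    lambda <- cv$selected_lambda
  }
  M <- nnls_weights(spatial$counts, ref$counts, lambda = lambda, lr = lr,
                    epochs = epochs, warm_start = warm_start)
  P <- aggregate_nnls(M, ref$cell_type)
  elapsed <- proc.time()[["elapsed"]] - t0
  new_deconv_fit(P, ref, spatial, method = "NNLS", lambda = lambda,
                 cv = cv, elapsed = elapsed)
}

new_deconv_fit <- function(P, ref, spatial, method, lambda, cv, elapsed) {
  structure(
    list(
      proportions = P,
      cell_types = setdiff(names(P), "spot"),
      coords = spatial$coords,
      method = method,
      lambda = lambda,
      cv = cv,
      n_genes = ncol(ref$counts),
      elapsed = elapsed
    ),
    class = "deconv_fit"
  )
}

check_deconv_inputs <- function(ref, spatial) {
  stopifnot(inherits(ref, "reference_profile"),
            inherits(spatial, "spatial_expression"))
  if (!identical(gene_ids(ref), gene_ids(spatial))) {
    abort("Inputs are not gene-aligned; run align_genes() or preprocess().")
  }
  invisible(TRUE)
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf(
    "<deconv_fit> %s: %d spots x %d cell types (%d genes)\n",
    x$method, nrow(x$proportions), length(x$cell_types), x$n_genes
  ))
  if (!is.null(x$lambda)) cat(sprintf("  lambda: %g%s\n", x$lambda,
    if (!is.null(x$cv)) " (cross-validated)" else ""))
  cat(sprintf("  solver time: %.3f s\n", x$elapsed))
  print(x$proportions, n = 5)
  invisible(x)
}

#' Tidy per-spot proportions of a deconvolution fit
#'
#' @param x A `deconv_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `spot`, `x`, `y`, `cell_type`,
#'   `proportion`.
#' @method tidy deconv_fit
#' @export
tidy.deconv_fit <- function(x, ...) {
  dplyr::bind_cols(x$proportions, x$coords) |>
    tidyr::pivot_longer(dplyr::all_of(x$cell_types),
                        names_to = "cell_type",
                        values_to = "proportion")
}

#' One-row summary of a deconvolution fit
#'
#' @param x A `deconv_fit`.
#' @param ... Unused.
#' @return A tibble with `method`, `n_spots`, `n_types`, `n_genes`,
#'   `lambda`, `elapsed`.
#' @method glance deconv_fit
#' @export
glance.deconv_fit <- function(x, ...) {
  tibble(
    method = x$method,
    n_spots = nrow(x$proportions),
    n_types = length(x$cell_types),
    n_genes = x$n_genes,
    lambda = x$lambda %||% NA_real_,
    elapsed = x$elapsed
  )
}
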
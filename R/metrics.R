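#' Root-mean-square error between proportion tables
#'
#' Pooled over all spot-by-type entries: the square root of the mean
#' squared elementwise difference. Both arguments must have the same
#' shape and column order; wide tibbles from [aggregate_nnls()] /
#' [aggregate_sls()] (identifier and coordinate columns are dropped),
#' matrices, or `deconv_fit` objects are accepted.
#'
#' @param P Estimated proportions.
#' @param P_true Reference proportions of identical shape and column
#'   order.
#' @return A single non-negative number.
#' @export
prop_rmse <- function(P, P_true) {
  a <- as_prop_matrix(P)
  b <- as_prop_matrix(P_true)
  check_same_shape(a, b)
  sqrt(mean((a - b)^2))
}

#' Mean Jensen-Shannon divergence between proportion tables
#'
#' For each spot, the Jensen-Shannon divergence (log base 2, so values
#' lie in [0, 1]) between the two probability vectors:
#' `0.5 KL(p || m) + 0.5 KL(q || m)` with `m = (p + q) / 2` and the
#' convention `0 log 0 = 0`. The per-spot divergences are averaged.
#' Every row of both inputs must lie on the probability simplex within
#' `1e-6`.
#'
#' @inheritParams prop_rmse
#' @return A single number in [0, 1].
#' @export
prop_jsd <- function(P, P_true) {
  a <- as_prop_matrix(P)
  b <- as_prop_matrix(P_true)
  check_same_shape(a, b)
  check_simplex(a, "P")
  check_simplex(b, "P_true")
  mean(vapply(seq_len(nrow(a)), function(i) {
    jsd_pair(a[i, ], b[i, ])
  }, numeric(1)))
}

jsd_pair <- function(p, q) {
  m <- (p + q) / 2
  0.5 * kl_bits(p, m) + 0.5 * kl_bits(q, m)
}

kl_bits <- function(p, m) {
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / m[nz]))
}

check_simplex <- function(a, name, tol = 1e-6) {
  if (any(a < -tol)) {
    abort(sprintf("`%s` has negative proportions.", name))
  }
  off <- abs(rowSums(a) - 1)
  if (any(off > tol)) {
    abort(sprintf(
      "%d row(s) of `%s` do not sum to 1 (max deviation %.2g).",
      sum(off > tol), name, max(off)
    ))
  }
  invisible(TRUE)
}

#' Marker-gene Pearson correlation of estimated proportions
#'
#' When ground-truth proportions are unknown, a type's estimated
#' proportions should still track the spatial expression of its marker
#' genes. For each cell type, spot counts are library-size normalized,
#' the type's marker genes are averaged per spot, and the Pearson
#' correlation with the type's estimated proportion column is computed
#' across spots. Types whose proportion or marker-expression column is
#' constant have no defined correlation; they are reported as `NA` with a
#' warning and excluded from the mean.
#'
#' @param P Estimated proportions (wide tibble, matrix, or `deconv_fit`).
#' @param spatial A [spatial_expression] holding the spot counts.
#' @param markers Named list: one character vector of marker gene
#'   identifiers per cell type; names must match `P`'s type columns, and
#'   every listed gene must be present in `spatial`.
#' @return A tibble with columns `cell_type`, `pcc`, and attribute
#'   `pcc_mean` (also returned by `mean(out$pcc, na.rm = TRUE)`).
#' @export
marker_pcc <- function(P, spatial, markers) {
  a <- as_prop_matrix(P)
  stopifnot(inherits(spatial, "spatial_expression"), is.list(markers))
  if (nrow(spatial$counts) != nrow(a)) {
    abort("`P` and `spatial` disagree on the number of spots.")
  }
  if (nrow(a) < 2) abort("Need at least 2 spots to correlate.")
  types <- colnames(a)
  if (!all(types %in% names(markers))) {
    abort(sprintf(
      "`markers` lacks entries for: %s",
      paste(setdiff(types, names(markers)), collapse = ", ")
    ))
  }
  missing <- setdiff(unlist(markers[types]), gene_ids(spatial))
  if (length(missing) > 0) {
    abort(sprintf(
      "Marker gene(s) absent from spatial data: %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  norm <- spatial$counts / pmax(rowSums(spatial$counts), .Machine$double.eps)
  pcc <- vapply(types, function(ty) {
    expr <- rowMeans(norm[, markers[[ty]], drop = FALSE])
    if (stats::sd(expr) == 0 || stats::sd(a[, ty]) == 0) {
      return(NA_real_)
    }
    cor(a[, ty], expr)
  }, numeric(1))
  if (anyNA(pcc)) {
    warn(sprintf(
      "No defined correlation (constant column) for: %s",
      paste(types[is.na(pcc)], collapse = ", ")
    ))
  }
  out <- tibble(cell_type = types, pcc = unname(pcc))
  attr(out, "pcc_mean") <- mean(pcc, na.rm = TRUE)
  out
}

#' Evaluate a deconvolution result
#'
#' Convenience wrapper computing whichever metrics the available inputs
#' allow: RMSE and Jensen-Shannon divergence against ground truth when
#' `truth` is given, and the mean marker-gene Pearson correlation when
#' `spatial` and `markers` are given.
#'
#' @param P Estimated proportions (wide tibble, matrix, or `deconv_fit`).
#' @param truth Optional ground-truth proportions of matching shape.
#' @param spatial Optional [spatial_expression] for marker correlation.
#' @param markers Optional named list of per-type marker genes.
#' @return A one-row tibble with columns among `rmse`, `jsd`, `pcc_mean`.
#' @export
evaluate_deconv <- function(P, truth = NULL, spatial = NULL,
                            markers = NULL) {
  out <- tibble(.rows = 1)
  if (!is.null(truth)) {
    out$rmse <- prop_rmse(P, truth)
    out$jsd <- prop_jsd(P, truth)
  }
  if (!is.null(spatial) && !is.null(markers)) {
    out$pcc_mean <- attr(marker_pcc(P, spatial, markers), "pcc_mean")
  }
  if (ncol(out) == 0) {
    abort("Supply `truth` and/or `spatial` + `markers` to evaluate.")
  }
  out
}

# Coerce proportion containers to a plain numeric matrix (spots x types).
as_prop_matrix <- function(P) {
  if (inherits(P, "deconv_fit")) P <- P$proportions
  if (is.data.frame(P)) {
    keep <- setdiff(names(P), c("spot", "x", "y"))
    m <- as.matrix(P[, keep, drop = FALSE])
    rownames(m) <- if ("spot" %in% names(P)) as.character(P$spot) else NULL
    P <- m
  }
  if (!is.matrix(P) || !is.numeric(P)) {
    abort("Proportions must be a numeric matrix, wide tibble, or deconv_fit.")
  }
  P
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    abort(sprintf(
      "Shape mismatch: %d x %d vs %d x %d.",
      nrow(a), ncol(a), nrow(b), ncol(b)
    ))
  }
  if (!is.null(colnames(a)) && !is.null(colnames(b)) &&
      !identical(colnames(a), colnames(b))) {
    abort("Column (cell type) order differs between the two tables.")
  }
  invisible(TRUE)
}
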
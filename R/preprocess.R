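#' Normalize each reference cell by its total counts
#'
#' Divides every cell's counts by that cell's total over all genes, so
#' each row becomes a gene-expression probability profile summing to 1.
#' Cells with zero total counts carry no information and are dropped with
#' a warning before dividing.
#'
#' @param ref A [reference_profile].
#' @return A [reference_profile] whose rows each sum to 1.
#' @export
normalize_cells <- function(ref) {
  stopifnot(inherits(ref, "reference_profile"))
  totals <- rowSums(ref$counts)
  zero <- totals == 0
  if (all(zero)) abort("Every cell has zero total counts; cannot normalize.")
  if (any(zero)) {
    warn(sprintf(
      "Dropping %d cell(s) with zero total counts: %s",
      sum(zero),
      paste(utils::head(rownames(ref$counts)[zero], 5), collapse = ", ")
    ))
    ref$counts <- ref$counts[!zero, , drop = FALSE]
    ref$cell_type <- ref$cell_type[!zero]
    totals <- totals[!zero]
  }
  ref$counts <- ref$counts / totals
  ref
}

#' Remove rarely observed cell types from the reference
#'
#' Cell types represented by fewer than `min_cells` cells are removed
#' together with their cells. Types with very few prototypes give
#' unstable one-vs-rest comparisons and noisy signatures.
#'
#' @param ref A [reference_profile].
#' @param min_cells Minimum number of cells a type needs to be kept
#'   (default 2).
#' @return A [reference_profile]; cell order among survivors is preserved.
#' @export
filter_rare_celltypes <- function(ref, min_cells = 2) {
  stopifnot(inherits(ref, "reference_profile"),
            is.numeric(min_cells), min_cells >= 1)
  tab <- table(ref$cell_type)
  keep_types <- names(tab)[tab >= min_cells]
  if (length(keep_types) == 0) {
    abort(sprintf(
      "No cell type has at least %d cells; nothing would remain.", min_cells
    ))
  }
  keep <- ref$cell_type %in% keep_types
  ref$counts <- ref$counts[keep, , drop = FALSE]
  ref$cell_type <- ref$cell_type[keep]
  ref
}

#' Select marker genes by one-vs-rest differential expression
#'
#' For every cell type, genes are ranked by a one-vs-rest Wilcoxon
#' rank-sum statistic (cells of the type against all other cells),
#' computed on `log1p` of the expression values, with genes upregulated
#' in the type ranked first. The top `gene_top` genes from each
#' comparison are pooled; their union (sorted by gene identifier) is the
#' marker set. Ranking ties are broken lexicographically by gene
#' identifier so the selection is deterministic.
#'
#' @param ref A [reference_profile] with at least two cell types,
#'   normally already normalized by [normalize_cells()].
#' @param gene_top Number of top-ranked genes kept per comparison
#'   (default 200).
#' @param method Differential-expression ranking rule: `"wilcoxon"`
#'   (default, tie-corrected standardized rank-sum) or `"ttest"` (Welch
#'   t statistic on `log1p` values).
#' @return Character vector of marker gene identifiers, sorted; length is
#'   at most `K * gene_top`.
#' @export
select_marker_genes <- function(ref, gene_top = 200,
                                method = c("wilcoxon", "ttest")) {
  stopifnot(inherits(ref, "reference_profile"),
            is.numeric(gene_top), gene_top >= 1)
  method <- match.arg(method)
  types <- sort(unique(ref$cell_type))
  if (length(types) < 2) {
    abort("One-vs-rest marker selection needs at least 2 cell types.")
  }
  genes <- gene_ids(ref)
  expr <- log1p(ref$counts)
  score_fun <- switch(method,
    wilcoxon = rank_sum_scores,
    ttest = welch_t_scores
  )
  top <- lapply(types, function(ty) {
    z <- score_fun(expr, ref$cell_type == ty)
    ord <- order(-z, genes)
    genes[ord[seq_len(min(gene_top, length(genes)))]]
  })
  sort(unique(unlist(top)))
}

# Tie-corrected standardized Wilcoxon rank-sum statistic per gene (column),
# for group membership `in_group` vs the rest. Positive = upregulated in
# the group. Constant genes score 0.
rank_sum_scores <- function(expr, in_group) {
  n <- nrow(expr)
  n1 <- sum(in_group)
  n2 <- n - n1
  r <- apply(expr, 2, rank)
  w <- colSums(r[in_group, , drop = FALSE])
  mu <- n1 * (n + 1) / 2
  tie_term <- apply(expr, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(sigma2 > 0, (w - mu) / sqrt(sigma2), 0)
  unname(z)
}

# Welch t statistic per gene; constant-variance degenerate genes score 0.
welch_t_scores <- function(expr, in_group) {
  a <- expr[in_group, , drop = FALSE]
  b <- expr[!in_group, , drop = FALSE]
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
  se2 <- v1 / nrow(a) + v2 / nrow(b)
  unname(ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0))
}

#' Preprocess gene-aligned reference and spatial data
#'
#' Applies the three preprocessing steps in order: (1) per-cell count
#' normalization of the reference ([normalize_cells()], optional), (2)
#' removal of rare cell types ([filter_rare_celltypes()]), and (3)
#' one-vs-rest marker-gene selection ([select_marker_genes()]). Both
#' outputs are restricted to the marker gene set in identical
#' (lexicographic) order. Spatial counts are left unnormalized: the
#' normalization step standardizes the reference profiles only.
#'
#' @param ref A [reference_profile], gene-aligned with `spatial` (see
#'   [align_genes()]).
#' @param spatial A [spatial_expression] sharing `ref`'s gene space.
#' @param cellcount_norm Normalize reference cells by total counts
#'   (default `TRUE`).
#' @param cellcount_min Minimum cells per retained type (default 2).
#' @param gene_top Top genes kept per one-vs-rest comparison (default 200).
#' @param de_method Marker ranking rule passed to [select_marker_genes()].
#' @return A list with elements `reference`, `spatial` (both restricted to
#'   the marker genes) and `markers` (the selected gene identifiers).
#' @export
preprocess <- function(ref, spatial, cellcount_norm = TRUE,
                       cellcount_min = 2, gene_top = 200,
                       de_method = c("wilcoxon", "ttest")) {
  stopifnot(inherits(ref, "reference_profile"),
            inherits(spatial, "spatial_expression"))
  de_method <- match.arg(de_method)
  if (!identical(gene_ids(ref), gene_ids(spatial))) {
    abort("Inputs are not gene-aligned; run align_genes() first.")
  }
  if (isTRUE(cellcount_norm)) ref <- normalize_cells(ref)
  ref <- filter_rare_celltypes(ref, min_cells = cellcount_min)
  markers <- select_marker_genes(ref, gene_top = gene_top, method = de_method)
  ref$counts <- ref$counts[, markers, drop = FALSE]
  spatial$counts <- spatial$counts[, markers, drop = FALSE]
  list(reference = ref, spatial = spatial, markers = markers)
}
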
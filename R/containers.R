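#' Reference expression profile
#'
#' Bundles a single-cell reference count matrix (cells x genes) with one
#' cell-type label per cell. Each row is a *prototype*: one observed
#' expression profile of its cell type, and a cell type is typically
#' represented by many prototypes. Counts may be raw reads or normalized
#' expression; they must be non-negative and gene identifiers must be
#' unique.
#'
#' @param counts Numeric matrix or data frame, cells in rows, genes in
#'   columns. Column names are the gene identifiers (required, unique);
#'   row names are cell identifiers (generated if absent).
#' @param cell_type Character vector of cell-type labels, one per row of
#'   `counts`.
#' @return An object of class `reference_profile`: a list with elements
#'   `counts` (matrix) and `cell_type` (character).
#' @examples
#' m <- matrix(c(5, 0, 1, 4), nrow = 2, dimnames = list(NULL, c("g1", "g2")))
#' ref <- reference_profile(m, c("A", "B"))
#' ref
#' @export
reference_profile <- function(counts, cell_type) {
  counts <- as_count_matrix(counts, what = "reference counts")
  cell_type <- as.character(cell_type)
  if (length(cell_type) != nrow(counts)) {
    abort(sprintf(
      "`cell_type` has %d labels but `counts` has %d cells.",
      length(cell_type), nrow(counts)
    ))
  }
  if (anyNA(cell_type)) abort("`cell_type` must not contain missing values.")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%04d", seq_len(nrow(counts)))
  }
  structure(
    list(counts = counts, cell_type = cell_type),
    class = "reference_profile"
  )
}

#' Spatial expression profile
#'
#' Bundles a spatial transcriptomics count matrix (spots x genes) with
#' per-spot planar coordinates. Each spot mixes the expression of the
#' cells it captures; deconvolution estimates that mixture.
#'
#' @param counts Numeric matrix or data frame, spots in rows, genes in
#'   columns; non-negative, gene names unique.
#' @param coords Data frame with numeric columns `x` and `y`, one row per
#'   spot.
#' @return An object of class `spatial_expression`: a list with elements
#'   `counts` (matrix) and `coords` (tibble with `x`, `y`).
#' @examples
#' m <- matrix(1:4, nrow = 2, dimnames = list(NULL, c("g1", "g2")))
#' sp <- spatial_expression(m, data.frame(x = c(0, 1), y = c(0, 1)))
#' sp
#' @export
spatial_expression <- function(counts, coords) {
  counts <- as_count_matrix(counts, what = "spatial counts")
  coords <- as_tibble(coords)
  if (!all(c("x", "y") %in% names(coords))) {
    abort("`coords` must contain columns `x` and `y`.")
  }
  coords <- coords[, c("x", "y")]
  if (nrow(coords) != nrow(counts)) {
    abort(sprintf(
      "`coords` has %d rows but `counts` has %d spots.",
      nrow(coords), nrow(counts)
    ))
  }
  if (!all(vapply(coords, is.numeric, logical(1)))) {
    abort("Coordinate columns `x` and `y` must be numeric.")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("spot%04d", seq_len(nrow(counts)))
  }
  structure(
    list(counts = counts, coords = coords),
    class = "spatial_expression"
  )
}

# Shared validation: numeric, non-negative, unique gene names.
as_count_matrix <- function(counts, what = "counts") {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort(sprintf("%s must be a numeric matrix or data frame.", what))
  }
  if (anyNA(counts)) abort(sprintf("%s contains missing values.", what))
  if (any(counts < 0)) {
    abort(sprintf("%s contains negative entries; counts must be >= 0.", what))
  }
  if (is.null(colnames(counts))) {
    abort(sprintf("%s must carry gene identifiers as column names.", what))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    abort(sprintf(
      "Duplicate gene identifiers are not allowed: %s",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  counts
}

#' @export
print.reference_profile <- function(x, ...) {
  k <- length(unique(x$cell_type))
  cat(sprintf(
    "<reference_profile> %d cells x %d genes, %d cell type%s\n",
    nrow(x$counts), ncol(x$counts), k, if (k == 1) "" else "s"
  ))
  tab <- sort(table(x$cell_type), decreasing = TRUE)
  cat("  ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.spatial_expression <- function(x, ...) {
  cat(sprintf(
    "<spatial_expression> %d spots x %d genes\n",
    nrow(x$counts), ncol(x$counts)
  ))
  invisible(x)
}

#' @export
dim.reference_profile <- function(x) dim(x$counts)

#' @export
dim.spatial_expression <- function(x) dim(x$counts)

#' Gene identifiers of a profile
#'
#' @param x A `reference_profile` or `spatial_expression`.
#' @return Character vector of gene identifiers in column order.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, c("reference_profile", "spatial_expression")))
  colnames(x$counts)
}

#' @method as_tibble reference_profile
#' @export
as_tibble.reference_profile <- function(x, ...) {
  out <- as_tibble(x$counts)
  dplyr::bind_cols(
    tibble(cell = rownames(x$counts), cell_type = x$cell_type),
    out
  )
}

#' @method as_tibble spatial_expression
#' @export
as_tibble.spatial_expression <- function(x, ...) {
  out <- as_tibble(x$counts)
  dplyr::bind_cols(tibble(spot = rownames(x$counts)), x$coords, out)
}
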
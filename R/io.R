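#' Read a single-cell reference from delimited files
#'
#' Reads a counts table (cells x genes, header row = gene identifiers,
#' first column = cell identifier) together with a metadata table keyed by
#' the same cell identifier, and attaches the cell-type label column named
#' by `cell_type_key`. Comma- or tab-delimited files are detected from the
#' file extension (`.tsv`/`.txt` are read as tab-delimited).
#'
#' @param counts_path Path to the counts table.
#' @param meta_path Path to the metadata table. If `NULL`, the cell-type
#'   column is looked up in the counts table itself.
#' @param cell_type_key Name of the metadata column holding cell-type
#'   labels (default `"cell_type"`).
#' @return A [reference_profile].
#' @seealso [write_reference()] for the inverse operation.
#' @export
read_reference <- function(counts_path, meta_path = NULL,
                           cell_type_key = "cell_type") {
  tab <- read_table_file(counts_path)
  if (is.null(meta_path)) {
    meta <- tab
  } else {
    meta <- read_table_file(meta_path)
  }
  if (!cell_type_key %in% names(meta)) {
    abort(sprintf(
      "Cell-type key '%s' not found in metadata columns: %s",
      cell_type_key, paste(utils::head(names(meta), 8), collapse = ", ")
    ))
  }
  counts <- delim_to_matrix(tab, drop = cell_type_key)
  labels <- align_meta(meta, rownames(counts))[[cell_type_key]]
  reference_profile(counts, labels)
}

#' Read a spatial expression profile from delimited files
#'
#' Reads a counts table (spots x genes, first column = spot identifier)
#' and a metadata table carrying numeric `x` and `y` coordinate columns.
#' Spot order follows the counts file.
#'
#' @param counts_path Path to the counts table.
#' @param meta_path Path to the metadata table with `x`/`y` columns. If
#'   `NULL`, coordinates are looked up in the counts table.
#' @return A [spatial_expression].
#' @export
read_spatial <- function(counts_path, meta_path = NULL) {
  tab <- read_table_file(counts_path)
  meta <- if (is.null(meta_path)) tab else read_table_file(meta_path)
  if (!all(c("x", "y") %in% names(meta))) {
    abort(sprintf(
      "Spatial metadata must contain coordinate columns `x` and `y`; found: %s",
      paste(utils::head(names(meta), 8), collapse = ", ")
    ))
  }
  counts <- delim_to_matrix(tab, drop = c("x", "y"))
  coords <- align_meta(meta, rownames(counts))[, c("x", "y")]
  spatial_expression(counts, coords)
}

#' Write a reference profile to delimited files
#'
#' @param ref A [reference_profile].
#' @param counts_path Output path for the counts table.
#' @param meta_path Output path for the metadata table (first column `id`,
#'   then `cell_type`).
#' @param cell_type_key Column name to use for the labels.
#' @return Invisibly, `ref`.
#' @export
write_reference <- function(ref, counts_path, meta_path,
                            cell_type_key = "cell_type") {
  stopifnot(inherits(ref, "reference_profile"))
  write_matrix_file(ref$counts, counts_path)
  meta <- tibble(id = rownames(ref$counts))
  meta[[cell_type_key]] <- ref$cell_type
  write_table_file(meta, meta_path)
  invisible(ref)
}

#' Write a spatial profile to delimited files
#'
#' @param spatial A [spatial_expression].
#' @param counts_path Output path for the counts table.
#' @param meta_path Output path for the metadata table (`id`, `x`, `y`).
#' @return Invisibly, `spatial`.
#' @export
write_spatial <- function(spatial, counts_path, meta_path) {
  stopifnot(inherits(spatial, "spatial_expression"))
  write_matrix_file(spatial$counts, counts_path)
  meta <- dplyr::bind_cols(tibble(id = rownames(spatial$counts)),
                           spatial$coords)
  write_table_file(meta, meta_path)
  invisible(spatial)
}

#' Restrict reference and spatial data to their shared genes
#'
#' Deconvolution regresses spot expression on reference profiles, so both
#' matrices must live in the same gene space. This restricts both inputs
#' to the intersection of their gene identifiers (exact, case-sensitive
#' string match) and puts the columns in lexicographic gene order, so the
#' result is deterministic regardless of input column order.
#'
#' @param ref A [reference_profile].
#' @param spatial A [spatial_expression].
#' @return A list with elements `reference` and `spatial`, both restricted
#'   to the common genes in identical order.
#' @examples
#' ref <- reference_profile(
#'   matrix(1, 2, 3, dimnames = list(NULL, c("g1", "g2", "g3"))), c("A", "B")
#' )
#' sp <- spatial_expression(
#'   matrix(1, 1, 3, dimnames = list(NULL, c("g2", "g3", "g4"))),
#'   data.frame(x = 0, y = 0)
#' )
#' shared <- align_genes(ref, sp)
#' gene_ids(shared$reference)
#' @export
align_genes <- function(ref, spatial) {
  stopifnot(inherits(ref, "reference_profile"),
            inherits(spatial, "spatial_expression"))
  common <- sort(intersect(gene_ids(ref), gene_ids(spatial)))
  if (length(common) == 0) {
    abort("Reference and spatial data share no gene identifiers.")
  }
  ref$counts <- ref$counts[, common, drop = FALSE]
  spatial$counts <- spatial$counts[, common, drop = FALSE]
  list(reference = ref, spatial = spatial)
}

# --- helpers -----------------------------------------------------------

read_table_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

# First column of a delimited counts table is the row identifier; any
# metadata columns named in `drop` are removed before matrix conversion.
delim_to_matrix <- function(tab, drop = character()) {
  ids <- as.character(tab[[1]])
  body <- tab[, -1, drop = FALSE]
  body <- body[, setdiff(names(body), drop), drop = FALSE]
  m <- as.matrix(body)
  if (!is.numeric(m)) abort("Count columns must all be numeric.")
  rownames(m) <- ids
  m
}

write_matrix_file <- function(m, path) {
  write_table_file(dplyr::bind_cols(tibble(id = rownames(m)), as_tibble(m)),
                   path)
}

write_table_file <- function(df, path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(df, path, delim = delim)
}

# Reorder a metadata table to match the counts row identifiers; falls back
# to positional match when the metadata carries no identifier overlap.
align_meta <- function(meta, ids) {
  key <- names(meta)[1]
  meta_ids <- as.character(meta[[key]])
  if (all(ids %in% meta_ids)) {
    meta[match(ids, meta_ids), , drop = FALSE]
  } else if (nrow(meta) == length(ids)) {
    meta
  } else {
    abort("Metadata rows do not match the counts table rows.")
  }
}
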
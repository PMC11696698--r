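#' Simulate a labelled single-cell reference
#'
#' Draws one gene-expression signature per cell type from a symmetric
#' Dirichlet over genes (smaller `signature_alpha` concentrates mass on
#' fewer genes, making types more distinct) and then draws
#' `cells_per_type` cells per type around that signature: with
#' `noise = "poisson"` each cell's counts are independent Poisson draws
#' with mean `cell_depth * signature`; with `noise = "none"` every cell
#' equals that expectation exactly, so all cells of a type are identical.
#'
#' @param n_types Number of cell types K (default 3).
#' @param cells_per_type Cells (prototypes) simulated per type
#'   (default 50).
#' @param n_genes Number of genes (default 300).
#' @param signature_alpha Dirichlet concentration per gene for the type
#'   signatures (default 0.1).
#' @param cell_depth Expected total counts per cell (default 2000).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param seed Integer seed; fixes every draw (default `NULL`: current
#'   RNG state).
#' @param signatures Optional K x n_genes signature matrix (rows sum to
#'   1) to reuse instead of drawing new ones.
#' @return A list with `reference` (a [reference_profile]) and
#'   `signatures` (K x n_genes matrix, row names = type names).
#' @export
simulate_reference <- function(n_types = 3, cells_per_type = 50,
                               n_genes = 300, signature_alpha = 0.1,
                               cell_depth = 2000,
                               noise = c("poisson", "none"),
                               seed = NULL, signatures = NULL) {
  noise <- match.arg(noise)
  stopifnot(n_types >= 1, cells_per_type >= 1, n_genes >= 1,
            signature_alpha > 0, cell_depth >= 1)
  run <- function() {
    if (is.null(signatures)) {
      signatures <- draw_signatures(n_types, n_genes, signature_alpha)
    }
    genes <- colnames(signatures)
    types <- rownames(signatures)
    labels <- rep(types, each = cells_per_type)
    mean_counts <- cell_depth * signatures[labels, , drop = FALSE]
    counts <- if (noise == "poisson") {
      matrix(rpois(length(mean_counts), mean_counts),
             nrow = nrow(mean_counts))
    } else {
      unname(mean_counts)
    }
    dimnames(counts) <- list(
      sprintf("cell%04d", seq_along(labels)), genes
    )
    list(reference = reference_profile(counts, labels),
         signatures = signatures)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

draw_signatures <- function(n_types, n_genes, alpha) {
  sig <- t(vapply(seq_len(n_types), function(k) {
    g <- rgamma(n_genes, shape = alpha)
    # guard against all-zero draws at tiny alpha
    if (sum(g) == 0) g[sample.int(n_genes, 1)] <- 1
    g / sum(g)
  }, numeric(n_genes)))
  dimnames(sig) <- list(
    sprintf("type%02d", seq_len(n_types)),
    sprintf("gene%04d", seq_len(n_genes))
  )
  sig
}

#' Simulate spatial spots as mixtures of type signatures
#'
#' Each spot's true cell-type proportions are drawn from a symmetric
#' Dirichlet on the K-simplex; its expected expression is the
#' proportion-weighted mixture of the type signatures scaled to
#' `spot_depth`. Counts are Poisson draws around that expectation
#' (`noise = "poisson"`) or the exact expectation (`noise = "none"`).
#' Spots are laid out on a square grid.
#'
#' @param signatures K x n_genes signature matrix with rows summing to 1
#'   (from [simulate_reference()]).
#' @param n_spots Number of spots (default 100).
#' @param spot_depth Expected total counts per spot (default 1e4).
#' @param prop_alpha Dirichlet concentration for the true proportions
#'   (default 1: uniform over the simplex).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param seed Integer seed (default `NULL`).
#' @return A list with `spatial` (a [spatial_expression]) and `truth`
#'   (wide tibble: `spot` plus one column per type, rows on the simplex).
#' @export
simulate_spots <- function(signatures, n_spots = 100, spot_depth = 1e4,
                           prop_alpha = 1, noise = c("poisson", "none"),
                           seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(is.matrix(signatures), n_spots >= 1, spot_depth >= 1,
            prop_alpha > 0)
  run <- function() {
    k <- nrow(signatures)
    P <- t(vapply(seq_len(n_spots), function(i) {
      g <- rgamma(k, shape = prop_alpha)
      if (sum(g) == 0) g[sample.int(k, 1)] <- 1
      g / sum(g)
    }, numeric(k)))
    colnames(P) <- rownames(signatures)
    mean_counts <- spot_depth * (P %*% signatures)
    counts <- if (noise == "poisson") {
      matrix(rpois(length(mean_counts), mean_counts),
             nrow = n_spots)
    } else {
      unname(mean_counts)
    }
    ids <- sprintf("spot%04d", seq_len(n_spots))
    dimnames(counts) <- list(ids, colnames(signatures))
    w <- ceiling(sqrt(n_spots))
    coords <- tibble(
      x = (seq_len(n_spots) - 1) %% w,
      y = (seq_len(n_spots) - 1) %/% w
    )
    truth <- dplyr::bind_cols(tibble(spot = ids), as_tibble(P))
    list(spatial = spatial_expression(counts, coords), truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a complete deconvolution benchmark with known truth
#'
#' Draws type signatures, a labelled single-cell reference, and spatial
#' spots mixing those signatures with known per-spot proportions — the
#' full input pair for [deconv_sls()] / [deconv_nnls()] plus the ground
#' truth needed by [prop_rmse()] and [prop_jsd()].
#'
#' @inheritParams simulate_reference
#' @inheritParams simulate_spots
#' @return A list with `reference`, `spatial`, `truth`, and `signatures`.
#' @examples
#' sim <- simulate_mixture(n_genes = 60, n_spots = 25, seed = 7)
#' fit <- deconv_sls(sim$reference, sim$spatial)
#' evaluate_deconv(fit, truth = sim$truth)
#' @export
simulate_mixture <- function(n_types = 3, cells_per_type = 50,
                             n_genes = 300, n_spots = 100,
                             signature_alpha = 0.1, cell_depth = 2000,
                             spot_depth = 1e4, prop_alpha = 1,
                             noise = c("poisson", "none"), seed = NULL) {
  noise <- match.arg(noise)
  run <- function() {
    ref <- simulate_reference(
      n_types = n_types, cells_per_type = cells_per_type,
      n_genes = n_genes, signature_alpha = signature_alpha,
      cell_depth = cell_depth, noise = noise
    )
    sp <- simulate_spots(
      ref$signatures, n_spots = n_spots, spot_depth = spot_depth,
      prop_alpha = prop_alpha, noise = noise
    )
    list(reference = ref$reference, spatial = sp$spatial,
         truth = sp$truth, signatures = ref$signatures)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
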
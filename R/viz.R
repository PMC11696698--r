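#' Wedge polygons for a spatial scatter-pie plot
#'
#' Converts per-spot proportions and coordinates into polygon vertices
#' for one pie glyph per spot, with wedge angles proportional to the
#' proportions. Exposed so custom plots (and tests) can inspect the
#' geometry directly.
#'
#' @param P Proportions (wide tibble, matrix, or `deconv_fit`).
#' @param coords Data frame with `x`, `y` per spot (taken from the fit
#'   when `P` is a `deconv_fit`).
#' @param radius Pie radius in coordinate units; defaults to 40% of the
#'   smallest positive spacing between distinct x or y values.
#' @param arc_step Angular resolution of the wedge outline in radians
#'   (default ~2 degrees).
#' @return A tibble with columns `spot`, `cell_type`, `start`, `end`
#'   (wedge angles in radians), and outline vertices `px`, `py`.
#' @export
pie_wedge_data <- function(P, coords = NULL, radius = NULL,
                           arc_step = pi / 90) {
  if (inherits(P, "deconv_fit") && is.null(coords)) coords <- P$coords
  m <- as_prop_matrix(P)
  if (is.null(coords)) abort("`coords` is required.")
  coords <- as.data.frame(coords)
  if (nrow(coords) != nrow(m)) {
    abort("`coords` and `P` disagree on the number of spots.")
  }
  check_simplex(m, "P")
  if (is.null(radius)) radius <- 0.4 * min_spacing(coords)
  types <- colnames(m)
  spots <- rownames(m) %||% as.character(seq_len(nrow(m)))
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    ang <- 2 * pi * cumsum(c(0, m[i, ]))
    purrr::map_dfr(seq_along(types), function(k) {
      if (m[i, k] <= 0) return(NULL)
      theta <- seq(ang[k], ang[k + 1],
                   length.out = max(2, ceiling((ang[k + 1] - ang[k]) /
                                                 arc_step)))
      tibble(
        spot = spots[i], cell_type = types[k],
        start = ang[k], end = ang[k + 1],
        px = coords$x[i] + c(0, radius * sin(theta)),
        py = coords$y[i] + c(0, radius * cos(theta))
      )
    })
  })
}

min_spacing <- function(coords) {
  gaps <- c(diff(sort(unique(coords$x))), diff(sort(unique(coords$y))))
  gaps <- gaps[gaps > 0]
  if (length(gaps) == 0) 1 else min(gaps)
}

#' Spatial scatter-pie plot of cell-type composition
#'
#' Draws one pie glyph per spot at its spatial coordinates, with wedge
#' angles proportional to the estimated cell-type proportions. Colors
#' are assigned to the sorted type names, so the mapping is stable
#' across runs and estimators.
#'
#' @inheritParams pie_wedge_data
#' @return A ggplot object.
#' @export
plot_spot_pies <- function(P, coords = NULL, radius = NULL) {
  wedges <- pie_wedge_data(P, coords, radius)
  types <- sort(unique(wedges$cell_type))
  ggplot2::ggplot(
    wedges,
    ggplot2::aes(.data$px, .data$py, fill = .data$cell_type,
                 group = interaction(.data$spot, .data$cell_type))
  ) +
    ggplot2::geom_polygon(color = NA) +
    ggplot2::scale_fill_manual(values = type_palette(types)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", fill = "cell type") +
    ggplot2::theme_minimal()
}

#' Per-type spatial proportion maps
#'
#' One panel per requested cell type, with spots colored by that type's
#' estimated proportion on a fixed [0, 1] color scale so panels are
#' directly comparable.
#'
#' @inheritParams pie_wedge_data
#' @param types Cell types to plot (default: all). Unknown names raise
#'   an error listing the valid ones.
#' @param point_size Size of the spot markers (default 2).
#' @return A ggplot object, faceted by cell type.
#' @export
plot_type_maps <- function(P, coords = NULL, types = NULL,
                           point_size = 2) {
  if (inherits(P, "deconv_fit") && is.null(coords)) coords <- P$coords
  m <- as_prop_matrix(P)
  if (is.null(coords)) abort("`coords` is required.")
  coords <- as.data.frame(coords)
  all_types <- colnames(m)
  if (is.null(types)) types <- all_types
  unknown <- setdiff(types, all_types)
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown cell type(s): %s. Valid types: %s",
      paste(unknown, collapse = ", "),
      paste(all_types, collapse = ", ")
    ))
  }
  df <- tibble(
    spot = rownames(m) %||% as.character(seq_len(nrow(m))),
    x = coords$x, y = coords$y
  )
  df <- dplyr::bind_cols(df, as_tibble(m[, types, drop = FALSE])) |>
    tidyr::pivot_longer(dplyr::all_of(types), names_to = "cell_type",
                        values_to = "proportion")
  ggplot2::ggplot(
    df, ggplot2::aes(.data$x, .data$y, color = .data$proportion)
  ) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_color_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::coord_equal() +
    ggplot2::labs(color = "proportion") +
    ggplot2::theme_minimal()
}

# Stable palette: a pure function of the sorted type-name list.
type_palette <- function(types) {
  types <- sort(types)
  setNames(scales::hue_pal()(length(types)), types)
}

#' Autoplot method for deconvolution fits
#'
#' @param object A `deconv_fit`.
#' @param type `"pie"` (scatter-pie composition map, default) or
#'   `"map"` (per-type proportion panels).
#' @param ... Passed to [plot_spot_pies()] or [plot_type_maps()].
#' @return A ggplot object.
#' @method autoplot deconv_fit
#' @export
autoplot.deconv_fit <- function(object, type = c("pie", "map"), ...) {
  type <- match.arg(type)
  switch(type,
    pie = plot_spot_pies(object, ...),
    map = plot_type_maps(object, ...)
  )
}
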
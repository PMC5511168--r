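#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# orthographic view: keep the hemisphere facing the viewer (+z)
ortho_view <- function(df, xyz = c("X", "Y", "Z")) {
  df[df[[xyz[3]]] >= -1e-9, , drop = FALSE]
}

#' Plot a capsid lattice
#'
#' Orthographic view of the folded capsid (viewer-facing hemisphere), one
#' point per capsomer, pentons emphasised.
#'
#' @param object A `capsid_lattice`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot capsid_lattice
#' @export
autoplot.capsid_lattice <- function(object, ...) {
  df <- ortho_view(tibble::as_tibble(object))
  hk <- attr(object, "hk")
  ggplot2::ggplot(df, ggplot2::aes(.data$X, .data$Y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$kind, size = .data$kind)) +
    ggplot2::scale_size_manual(values = c(hex = 1, penton = 2.5),
                               guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("(h, k) = (%d, %d), T = %d", hk[1], hk[2],
                      attr(object, "t")),
      x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a symmetron decomposition
#'
#' Orthographic view coloured by symmetron; unique (spiral-seed) capsomers
#' are ringed when orientations have been assigned.
#'
#' @param object A `capsid_decomposition`.
#' @param colour_by `"symmetron"` (default) or `"orientation"` (orientation
#'   label, showing the interlocked spiral groups).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot capsid_decomposition
#' @export
autoplot.capsid_decomposition <- function(object,
                                          colour_by = c("symmetron",
                                                        "orientation"),
                                          ...) {
  colour_by <- match.arg(colour_by)
  df <- ortho_view(object$sites)
  col <- if (colour_by == "symmetron") "symmetron_id" else "orientation_label"
  if (colour_by == "orientation" && !isTRUE(object$orientations)) {
    stop("assign_orientations() first to colour by orientation", call. = FALSE)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$X, .data$Y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data[[col]]), size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (isTRUE(object$orientations)) {
    uq <- df[!is.na(df$is_unique) & df$is_unique, , drop = FALSE]
    p <- p + ggplot2::geom_point(data = uq, shape = 21, size = 2.4,
                                 stroke = 0.7, fill = NA, colour = "black")
  }
  p
}

#' Plot an assembly trajectory
#'
#' Orthographic view of the placed capsomers coloured by placement rank.
#'
#' @param object An `assembly_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot assembly_trajectory
#' @export
autoplot.assembly_trajectory <- function(object, ...) {
  df <- ortho_view(tibble::as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$X, .data$Y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rank), size = 1.4) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "rank") +
    ggplot2::theme_minimal()
}

#' Plot a centre set
#'
#' Scatter of synthetic or measured capsomer centres (first two coordinates),
#' pentons emphasised.
#'
#' @param object A `center_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot center_set
#' @export
autoplot.center_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_penton,
                                     size = .data$is_penton)) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 1, `TRUE` = 2.5),
                               guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "penton") +
    ggplot2::theme_minimal()
}

#' Plot a lattice-recovery benchmark
#'
#' Recovery rate against jitter, one line per dropout fraction.
#'
#' @param tbl Output of [recovery_experiment()].
#' @return A ggplot.
#' @export
plot_recovery <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$sigma, .data$recovery_rate,
                                    colour = factor(.data$dropout))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "jitter sigma (lattice units)", y = "exact recovery",
                  colour = "dropout") +
    ggplot2::theme_minimal()
}
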
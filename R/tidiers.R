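#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy capsid_lattice
#' @export
#' @rdname capsidr-tidiers
tidy.capsid_lattice <- function(x, ...) tibble::as_tibble(x)

#' Tidy and summarise capsidr objects
#'
#' [generics::tidy()] returns the per-capsomer (or per-event, per-parameter)
#' table of an object; [generics::glance()] returns a one-row summary.
#'
#' @param x A `capsid_lattice`, `capsid_decomposition`,
#'   `assembly_trajectory` or `capsid_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name capsidr-tidiers
#' @method glance capsid_lattice
#' @export
glance.capsid_lattice <- function(x, ...) {
  hk <- attr(x, "hk")
  tibble::tibble(
    h = unname(hk[1]), k = unname(hk[2]),
    handedness = attr(x, "handedness"),
    t = attr(x, "t"),
    capsomers = nrow(x),
    pentons = sum(x$kind == "penton"),
    hexavalent = sum(x$kind == "hex"),
    spacing_a = attr(x, "spacing_a")
  )
}

#' @method tidy capsid_decomposition
#' @export
#' @rdname capsidr-tidiers
tidy.capsid_decomposition <- function(x, ...) tibble::as_tibble(x$sites)

#' @method glance capsid_decomposition
#' @export
#' @rdname capsidr-tidiers
glance.capsid_decomposition <- function(x, ...) {
  sm <- decomposition_summary(x)
  tibble::as_tibble(sm[c("h", "k", "handedness", "t", "p", "n",
                         "pentasymmetron_size", "trisymmetron_size",
                         "capsomers", "unique_positions")])
}

#' @method tidy assembly_trajectory
#' @export
#' @rdname capsidr-tidiers
tidy.assembly_trajectory <- function(x, ...) tibble::as_tibble(x)

#' @method glance assembly_trajectory
#' @export
#' @rdname capsidr-tidiers
glance.assembly_trajectory <- function(x, ...) {
  hk <- attr(x, "hk")
  tibble::tibble(
    h = unname(hk[1]), k = unname(hk[2]),
    handedness = attr(x, "handedness"),
    vertex = attr(x, "vertex"),
    mode = attr(x, "mode"),
    events = nrow(x),
    spiral_jumps = sum(x$rule == "spiral_jump"),
    trisymmetron_recruits = sum(x$rule == "trisymmetron_recruit")
  )
}

#' @method tidy capsid_fit
#' @export
#' @rdname capsidr-tidiers
tidy.capsid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("h", "k", "t", "spacing"),
    estimate = c(x$h, x$k, x$t, x$spacing)
  )
}

#' @method glance capsid_fit
#' @export
#' @rdname capsidr-tidiers
glance.capsid_fit <- function(x, ...) {
  tibble::tibble(
    h = x$h, k = x$k, handedness = x$handedness, t = x$t,
    confidence = x$confidence, residual_rms = x$residual_rms,
    spacing = x$spacing, n_points = x$n_points, flattened = x$flattened
  )
}
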
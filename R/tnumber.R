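#' Caspar-Klug triangulation number
#'
#' The triangulation number of an icosahedral capsid whose neighbouring
#' five-fold vertices are separated by `h` steps along one hexagonal lattice
#' axis and `k` steps along the other: `T = h^2 + h*k + k^2`. A capsid of
#' triangulation number T carries `10*(T - 1)` pseudo-hexagonal (hexavalent)
#' capsomers plus 12 pentons, one per vertex.
#'
#' `t_number()` is symmetric in `h` and `k`: `(h, k)` and `(k, h)` are the two
#' enantiomorphs (mirror images) of the same capsid class and share one T.
#'
#' @param h,k Non-negative integer lattice steps (vectorised; not both zero).
#' @return Integer vector of triangulation numbers.
#' @examples
#' t_number(7, 18)  # 499, the largest accurately determined T to date
#' t_number(7, 12)  # 277
#' @export
t_number <- function(h, k) {
  check_hk(h, k)
  as.integer(h^2 + h * k + k^2)
}

check_hk <- function(h, k) {
  if (length(h) != length(k)) {
    stop("`h` and `k` must have the same length", call. = FALSE)
  }
  bad <- !is.finite(h) | !is.finite(k) | h < 0 | k < 0 |
    h != round(h) | k != round(k)
  if (any(bad)) {
    stop("`h` and `k` must be non-negative integers", call. = FALSE)
  }
  if (any(h == 0 & k == 0)) {
    stop("(h, k) = (0, 0) does not define a lattice class", call. = FALSE)
  }
  invisible(TRUE)
}

#' All (h, k) index pairs realising a triangulation number
#'
#' Inverts `T = h^2 + h*k + k^2` by exhaustive search, returning canonical
#' pairs with `h <= k`. Most integers are not triangulation numbers; some
#' (e.g. 91) are realised by more than one lattice class.
#'
#' @param t Positive integer.
#' @return A tibble with columns `h`, `k` (zero rows if `t` is not a
#'   triangulation number).
#' @examples
#' hk_from_t(499)
#' @export
hk_from_t <- function(t) {
  stopifnot(length(t) == 1, is.finite(t), t >= 1, t == round(t))
  h <- 0:floor(sqrt(t))
  res <- purrr::map_dfr(h, function(hh) {
    # solve k^2 + h k + (h^2 - t) = 0 for integer k >= h
    disc <- hh^2 - 4 * (hh^2 - t)
    if (disc < 0) return(NULL)
    s <- sqrt(disc)
    if (abs(s - round(s)) > 1e-9) return(NULL)
    kk <- (-hh + round(s)) / 2
    if (kk >= hh && kk == round(kk)) tibble::tibble(h = hh, k = as.integer(kk)) else NULL
  })
  dplyr::distinct(res)
}

#' Is an integer a valid triangulation number?
#' @param t Positive integer (vectorised).
#' @return Logical vector.
#' @export
is_t_number <- function(t) {
  vapply(t, function(x) nrow(hk_from_t(x)) > 0, logical(1))
}

#' Hexavalent capsomers per icosahedral asymmetric unit
#'
#' The asymmetric unit (1/60th of the capsid) contains `(T - 1)/6` hexavalent
#' capsomer equivalents. The count is fractional whenever capsomers sit on
#' icosahedral symmetry axes (for instance on 3-fold axes when `h == k`), in
#' which case a site is shared between asymmetric units.
#'
#' @param t A valid triangulation number.
#' @return A one-row tibble with columns `t`, `numerator` (`T - 1`),
#'   `denominator` (6), `value` (`(T-1)/6` as a double) and `is_integer`.
#' @examples
#' asu_hexavalent_count(499)  # 83 per asymmetric unit
#' asu_hexavalent_count(147)  # 146/6, fractional: sites on 3-fold axes
#' @export
asu_hexavalent_count <- function(t) {
  stopifnot(length(t) == 1)
  if (!is_t_number(t)) {
    stop("T = ", t, " is not a triangulation number: no (h, k) solves ",
         "h^2 + h*k + k^2 = T", call. = FALSE)
  }
  num <- as.integer(t - 1)
  tibble::tibble(
    t = as.integer(t),
    numerator = num,
    denominator = 6L,
    value = num / 6,
    is_integer = num %% 6L == 0L
  )
}

#' Axial-to-Cartesian map for the hexagonal lattice
#'
#' Axial coordinates `(u, v)` index sites of a triangular (hexagonal-packing)
#' lattice in a basis whose two unit vectors are separated by 60 degrees:
#' `x = a*(u + v/2)`, `y = a*v*sqrt(3)/2`. Nearest lattice neighbours are
#' exactly `a` apart.
#'
#' @param u,v Integer axial coordinates (vectorised).
#' @param spacing_a Lattice spacing (centre-to-centre capsomer distance),
#'   default 1 lattice unit.
#' @return A tibble with columns `x`, `y`.
#' @examples
#' axial_to_cartesian(0, 1)  # (0.5, sqrt(3)/2)
#' @export
axial_to_cartesian <- function(u, v, spacing_a = 1) {
  stopifnot(spacing_a > 0)
  tibble::tibble(
    x = spacing_a * (u + v / 2),
    y = spacing_a * v * sqrt(3) / 2
  )
}

# 60-degree lattice rotations in axial coordinates:
# R60: e1 -> e2, e2 -> e2 - e1  (counter-clockwise)
rot60_axial <- function(u, v) cbind(u = -v, v = u + v)
rot60_inv_axial <- function(u, v) cbind(u = u + v, v = -u)
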
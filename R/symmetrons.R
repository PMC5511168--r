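#' Pentasymmetron size from its layer count
#'
#' A pentasymmetron is the five-fold block centred on a vertex: one penton
#' plus `p` concentric layers of hexavalent capsomers holding 5, 10, 15, ...
#' sites, i.e. `1 + 5*p*(p+1)/2` capsomers in total. All giant icosahedral
#' viruses imaged to date show `p = 3`, hence 31 capsomers.
#'
#' @param p Non-negative integer layer count (vectorised).
#' @return Integer vector of capsomer counts.
#' @examples
#' pentasymmetron_size(3)  # 31
#' @export
pentasymmetron_size <- function(p) {
  stopifnot(all(p >= 0), all(p == round(p)))
  as.integer(1 + 5 * p * (p + 1) / 2)
}

#' Lattice step h implied by the pentasymmetron layer count
#'
#' A pentasymmetron of `p` concentric layers forces `h = 2*p + 1` lattice
#' steps along the first axis between neighbouring five-fold vertices; the
#' conserved 31-capsomer (p = 3) pentasymmetron is why h = 7 is fixed across
#' the giant viruses.
#'
#' @param p Non-negative integer layer count (vectorised).
#' @return Integer vector.
#' @examples
#' h_from_layers(3)  # 7
#' @export
h_from_layers <- function(p) {
  stopifnot(all(p >= 0), all(p == round(p)))
  as.integer(2 * p + 1)
}

#' Trisymmetron edge length for a capsid class
#'
#' After removing 12 pentasymmetrons of layer count `p` from a T-number-`t`
#' capsid, the remaining `10*(t-1) + 12 - 12*(1 + 5*p*(p+1)/2)` capsomers
#' must fill 20 trisymmetrons of `n*(n+1)/2` sites each, which requires an
#' integer `n` with `n*(n+1) == t - 1 - 3*p*(p+1)`. For `h = 2p+1` lattices
#' this always holds with `n = k + p`.
#'
#' @param t A triangulation number.
#' @param p Pentasymmetron layer count.
#' @return A one-row tibble with columns `t`, `p`, `n` and `size`
#'   (`n*(n+1)/2`).
#' @examples
#' trisymmetron_edge(499, 3)  # n = 21, 231 capsomers
#' @export
trisymmetron_edge <- function(t, p) {
  stopifnot(length(t) == 1, length(p) == 1, p >= 0, p == round(p))
  if (!is_t_number(t)) {
    stop("T = ", t, " is not a triangulation number", call. = FALSE)
  }
  rhs <- t - 1 - 3 * p * (p + 1)
  if (rhs < 0) {
    stop("pentasymmetrons with p = ", p, " layers exceed the capsomer budget ",
         "of T = ", t, call. = FALSE)
  }
  n <- (-1 + sqrt(1 + 4 * rhs)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("(T = ", t, ", p = ", p, ") admits no symmetron decomposition: ",
         "n*(n+1) = ", rhs, " has no integer solution", call. = FALSE)
  }
  n <- as.integer(round(n))
  tibble::tibble(t = as.integer(t), p = as.integer(p), n = n,
                 size = as.integer(n * (n + 1) / 2))
}

#' Partition a capsid lattice into pentasymmetrons and trisymmetrons
#'
#' Assigns every capsomer to exactly one of 12 pentasymmetrons (vertex-centred
#' hexagonal balls of graph radius `p`) or 20 trisymmetrons (lattice-aligned
#' triangular arrays of edge `n` centred on the icosahedral 3-fold axes, one
#' per face; a trisymmetron overhangs its home face's edges on skewed
#' lattices). Requires odd `h = 2p + 1`; the pentasymmetron geometry for even
#' `h` is not defined. Sites falling on a boundary between two trisymmetrons
#' (possible when `h == k`, where capsomers sit on 3-fold axes) are resolved
#' to the lowest symmetron id.
#'
#' @param lattice A `capsid_lattice` from [enumerate_capsomers()].
#' @param p Pentasymmetron layer count; defaults to `(h - 1)/2`.
#' @return A `capsid_decomposition` object: a list with `sites` (the capsomer
#'   table plus `symmetron_id`, `symmetron_kind`, `layer`, `tri_face`),
#'   `symmetrons` (one row per symmetron with id, kind, anchor and size) and
#'   the layer/edge parameters `p`, `n`. Use [assign_orientations()] to add
#'   orientation classes.
#' @examples
#' dec <- decompose_capsid(enumerate_capsomers(3, 5))
#' dec$symmetrons
#' @export
decompose_capsid <- function(lattice, p = NULL) {
  stopifnot(inherits(lattice, "capsid_lattice"))
  hkb <- attr(lattice, "hk_built")
  handed <- attr(lattice, "handedness")
  t_num <- attr(lattice, "t")
  hh <- hkb[1]; kk <- hkb[2]
  # the layer-bearing index is the one the construction steps first
  h_lead <- if (handed == "right") hh else kk
  if (is.null(p)) {
    if (h_lead %% 2 == 0) {
      stop("h = ", h_lead, " is even: no pentasymmetron layer count p ",
           "satisfies h = 2p + 1. Decomposition is only defined for odd h.",
           call. = FALSE)
    }
    p <- (h_lead - 1) / 2
  }
  stopifnot(p >= 0, p == round(p))
  if (h_lead != 2 * p + 1) {
    stop("inconsistent (h, p): h = ", h_lead, " but 2p + 1 = ", 2 * p + 1,
         ". A pentasymmetron of p layers requires h = 2p + 1.", call. = FALSE)
  }
  te <- trisymmetron_edge(t_num, p)
  n <- te$n
  geom <- attr(lattice, "geom")

  sites <- tibble::as_tibble(lattice)
  nsite <- nrow(sites)
  symmetron_id <- rep(NA_character_, nsite)
  kind2 <- rep(NA_character_, nsite)
  layer <- rep(NA_integer_, nsite)
  tri_face <- rep(NA_integer_, nsite)
  home_vertex <- rep(NA_integer_, nsite)

  # pentasymmetrons: graph balls of radius p around the pentons
  g <- lattice_graph(lattice)
  pentons <- sites$id[sites$kind == "penton"]
  pentons <- pentons[order(sites$vertex[match(pentons, sites$id)])]
  dmat <- igraph::distances(g, v = pentons)
  within_p <- dmat <= p
  hits <- colSums(within_p)
  if (any(hits > 1)) stop("internal error: pentasymmetron balls overlap")
  pm <- which(hits == 1)
  which_pent <- apply(within_p[, pm, drop = FALSE], 2, which)
  symmetron_id[pm] <- sprintf("P%02d", which_pent)
  kind2[pm] <- "penta"
  layer[pm] <- as.integer(dmat[cbind(which_pent, pm)])
  home_vertex[pm] <- as.integer(which_pent - 1L)

  # trisymmetrons: per face, the triangular array of edge n whose tip sits
  # one step outside the pentasymmetron at the face's first vertex; the
  # mirrored (left-handed) build uses the reflected formula
  key_of <- site_key(lattice)
  id_by_key <- stats::setNames(sites$id, key_of)
  tri_rot <- rep(NA_real_, nsite)
  tri_phys_face <- rep(NA_integer_, nsite)
  if (n > 0) {
    ij <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
    ij <- ij[ij$i + ij$j <= n - 1, ]
    if (handed == "right") {
      w0 <- c(p, 1); d1 <- c(0, 1); d2 <- c(-1, 1)
    } else {
      w0 <- c(-p, p + 1); d1 <- c(1, 0); d2 <- c(0, 1)
    }
    uv <- cbind(w0[1] + ij$i * d1[1] + ij$j * d2[1],
                w0[2] + ij$i * d1[2] + ij$j * d2[2])
    xy <- as.matrix(axial_to_cartesian(uv[, 1], uv[, 2]))
    for (f in 1:20) {
      uf <- unfold_points(geom, f, xy)
      can <- canonical_sites(geom, hh, kk, uf$face, uf$xy)
      ids <- id_by_key[can$key]
      if (anyNA(ids)) stop("internal error: trisymmetron site not found")
      clash <- !is.na(symmetron_id[ids])
      take <- ids[!clash]
      symmetron_id[take] <- sprintf("T%02d", f)
      kind2[take] <- "tri"
      tri_face[take] <- as.integer(f - 1L)
      tri_rot[take] <- uf$rot[!clash]
      tri_phys_face[take] <- uf$face[!clash]
      if (any(clash) && any(!startsWith(symmetron_id[ids[clash]], "T"))) {
        stop("internal error: trisymmetron overlaps a pentasymmetron")
      }
    }
  }
  if (anyNA(symmetron_id)) {
    stop("internal error: ", sum(is.na(symmetron_id)),
         " sites not covered by the symmetron decomposition")
  }

  sites$symmetron_id <- symmetron_id
  sites$symmetron_kind <- kind2
  sites$layer <- layer
  sites$tri_face <- tri_face
  sites$home_vertex <- home_vertex

  counts <- dplyr::count(sites, .data$symmetron_id, name = "size")
  expect_pent <- pentasymmetron_size(p)
  expect_tri <- te$size
  bad <- counts$size[startsWith(counts$symmetron_id, "P")] != expect_pent
  if (any(bad)) stop("internal error: pentasymmetron size mismatch")
  if (n > 0 && hh != kk &&
      any(counts$size[startsWith(counts$symmetron_id, "T")] != expect_tri)) {
    stop("internal error: trisymmetron size mismatch")
  }

  symm <- dplyr::bind_rows(
    tibble::tibble(symmetron_id = sprintf("P%02d", 1:12), kind = "penta",
                   anchor = paste0("vertex ", 0:11)),
    tibble::tibble(symmetron_id = sprintf("T%02d", 1:20), kind = "tri",
                   anchor = paste0("face ", 0:19))
  ) |>
    dplyr::left_join(counts, by = "symmetron_id") |>
    dplyr::mutate(size = dplyr::coalesce(.data$size, 0L))

  structure(
    list(lattice = lattice, sites = sites, symmetrons = symm,
         p = as.integer(p), n = n,
         tri_rot = tri_rot, tri_phys_face = tri_phys_face,
         orientations = FALSE),
    class = "capsid_decomposition"
  )
}

# stable string key per site (used to match unfolded planar points to ids)
site_key <- function(lattice) {
  s <- lattice
  ifelse(s$kind == "penton", paste0("P", s$vertex + 1L),
         paste0("F", s$face, ":", s$u, ",", s$v))
}

#' @export
print.capsid_decomposition <- function(x, ...) {
  hk <- attr(x$lattice, "hk")
  cat(sprintf(
    "<capsid_decomposition> (h, k) = (%d, %d), T = %d: 12 pentasymmetrons of %d (p = %d), 20 trisymmetrons of %d (n = %d)%s\n",
    hk[1], hk[2], attr(x$lattice, "t"), pentasymmetron_size(x$p), x$p,
    x$n * (x$n + 1) / 2, x$n,
    if (isTRUE(x$orientations)) ", orientations assigned" else ""))
  invisible(x)
}
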
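#' Enumerate all capsomer sites of a capsid class
#'
#' Builds the full Caspar-Klug lattice for indices `(h, k)`: the 12 pentons
#' (one per icosahedral vertex) and the `10*(T-1)` hexavalent capsomer sites
#' distributed over the 20 triangular faces, where `T = h^2 + h*k + k^2`.
#' Each face carries a planar hexagonal lattice patch in a 60-degree axial
#' basis; sites shared between faces (on icosahedral edges or vertices) are
#' owned by the lowest-numbered face so that every physical capsomer appears
#' exactly once. Site ids are assigned face-major, then row-major in `(v, u)`,
#' so downstream identifiers are stable.
#'
#' @param h,k Non-negative integer lattice steps (not both zero).
#' @param handedness `"right"` (default) or `"left"`. The two settings build
#'   the two enantiomorphs of the class; `"left"` is constructed as the mirror
#'   image, equivalent to swapping `h` and `k`.
#' @param spacing_a Capsomer centre-to-centre distance. Default 1 (coordinates
#'   in dimensionless lattice units); pass a value in Angstrom to get physical
#'   coordinates.
#' @param t_max Resource guard: refuse lattices with `T > t_max`.
#' @return A `capsid_lattice`: a tibble with one row per capsomer and columns
#'   `id`, `face` (owning face, 0-19), `u`, `v` (axial coordinates in the
#'   owning face frame), `kind` (`"penton"`/`"hex"`), `vertex` (vertex id 0-11
#'   for pentons, `NA` otherwise), `x`, `y` (planar face-frame coordinates)
#'   and `X`, `Y`, `Z` (coordinates folded onto the icosahedron). Lattice
#'   metadata (`h`, `k`, `t`, handedness, spacing, adjacency graph, fold
#'   geometry) is carried in attributes; see [lattice_neighbors()].
#' @examples
#' lat <- enumerate_capsomers(2, 1)
#' nrow(lat)                       # 10*(7-1) + 12 = 72
#' dplyr::count(lat, kind)
#' @export
enumerate_capsomers <- function(h, k, handedness = c("right", "left"),
                                spacing_a = 1, t_max = 10000) {
  handedness <- match.arg(handedness)
  check_hk(h, k)
  stopifnot(spacing_a > 0)
  t_num <- t_number(h, k)
  if (t_num > t_max) {
    stop("T = ", t_num, " exceeds t_max = ", t_max,
         "; raise `t_max` explicitly for very large lattices", call. = FALSE)
  }
  # the left-handed enantiomorph is the (k, h) construction
  hh <- if (handedness == "right") h else k
  kk <- if (handedness == "right") k else h
  if (hh == 0) { hh <- kk; kk <- 0; } # (0, k) and (k, 0) are the same net

  geom <- build_fold_geometry(hh, kk)
  cand <- face_candidate_sites(hh, kk, geom)

  # resolve every candidate site (inside a face or in its one-step collar)
  # to a canonical global identity, for all 20 faces
  per_face <- vector("list", 20)
  for (f in 1:20) {
    uf <- unfold_points(geom, f, as.matrix(cand[, c("x", "y")]))
    can <- canonical_sites(geom, hh, kk, uf$face, uf$xy)
    per_face[[f]] <- tibble::tibble(
      cu = cand$u, cv = cand$v, inside = cand$inside,
      key = can$key, oface = can$face, ou = can$u, ov = can$v,
      kind = can$kind, vertex = can$vertex
    )
  }

  sites <- dplyr::bind_rows(per_face) |>
    dplyr::filter(.data$inside) |>
    dplyr::distinct(.data$key, .keep_all = TRUE) |>
    dplyr::arrange(.data$oface, .data$ov, .data$ou) |>
    dplyr::mutate(id = dplyr::row_number())

  n_expect <- 10 * (t_num - 1) + 12
  if (nrow(sites) != n_expect) {
    stop("internal error: enumerated ", nrow(sites), " sites, expected ",
         n_expect)
  }

  # adjacency: lattice-neighbour pairs inside each face chart; candidates in
  # the collar ring resolve (via unfolding) to real sites, so pairs that
  # straddle a face boundary are found in at least one chart
  nb <- lattice_neighbor_pairs(cand)
  edges <- purrr::map(per_face, function(pf) {
    cbind(pf$key[nb[, 1]], pf$key[nb[, 2]])
  })
  edges <- do.call(rbind, edges)
  id_of <- stats::setNames(sites$id, sites$key)
  e1 <- id_of[edges[, 1]]
  e2 <- id_of[edges[, 2]]
  keep <- !is.na(e1) & !is.na(e2) & e1 != e2
  em <- cbind(pmin(e1[keep], e2[keep]), pmax(e1[keep], e2[keep]))
  em <- unique(em)
  dimnames(em) <- NULL

  xy <- axial_to_cartesian(sites$ou, sites$ov)
  p3 <- matrix(0, nrow(sites), 3)
  for (f in unique(sites$oface)) {
    sel <- sites$oface == f
    af <- geom$affine[[f]]
    p3[sel, ] <- as.matrix(xy[sel, ]) %*% t(af$L) +
      matrix(af$o, sum(sel), 3, byrow = TRUE)
  }

  out <- tibble::tibble(
    id = sites$id,
    face = as.integer(sites$oface - 1L),
    u = as.integer(sites$ou),
    v = as.integer(sites$ov),
    kind = sites$kind,
    vertex = sites$vertex,
    x = xy$x * spacing_a,
    y = xy$y * spacing_a,
    X = p3[, 1] * spacing_a,
    Y = p3[, 2] * spacing_a,
    Z = p3[, 3] * spacing_a
  )
  new_capsid_lattice(out, h = h, k = k, handedness = handedness,
                     t = t_num, spacing_a = spacing_a, geom = geom,
                     edges = em, hk_built = c(hh, kk))
}

new_capsid_lattice <- function(df, h, k, handedness, t, spacing_a, geom,
                               edges, hk_built) {
  structure(
    df,
    class = c("capsid_lattice", class(tibble::tibble())),
    hk = c(h = h, k = k),
    hk_built = hk_built,
    handedness = handedness,
    t = t,
    spacing_a = spacing_a,
    geom = geom,
    edges = edges
  )
}

# planar candidate sites of one face chart: all lattice sites inside the face
# triangle (closed, tolerance 1e-9) plus a one-lattice-step collar used to
# discover neighbour pairs that straddle face boundaries
face_candidate_sites <- function(h, k, geom) {
  ring <- 1.05
  grid <- expand.grid(u = (-k - 2):(h + 2), v = -2:(h + k + 2))
  xy <- axial_to_cartesian(grid$u, grid$v)
  corners <- geom$corners2
  m2inv <- solve(t(corners[2:3, , drop = FALSE]) - corners[1, ])
  lam23 <- as.matrix(xy) %*% t(m2inv)
  lam <- cbind(1 - rowSums(lam23), lam23)
  inside <- matrixStats_rowMins(lam) >= -1e-9
  d <- dist_to_triangle(as.matrix(xy), corners)
  keep <- inside | d <= ring
  tibble::tibble(u = grid$u[keep], v = grid$v[keep],
                 x = xy$x[keep], y = xy$y[keep], inside = inside[keep])
}

matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

dist_to_triangle <- function(p, corners) {
  seg_dist <- function(p, a, b) {
    ab <- b - a
    tt <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / sum(ab^2)
    tt <- pmin(pmax(tt, 0), 1)
    sqrt((p[, 1] - (a[1] + tt * ab[1]))^2 + (p[, 2] - (a[2] + tt * ab[2]))^2)
  }
  pmin(seg_dist(p, corners[1, ], corners[2, ]),
       seg_dist(p, corners[2, ], corners[3, ]),
       seg_dist(p, corners[1, ], corners[3, ]))
}

# canonical identity for lattice sites given the face chart each point
# resolved to: vertex sites become pentons keyed by vertex id; sites on a
# shared edge are expressed in the lower-numbered face's frame; interior
# sites keep their resolved face. Exact (integer) keys throughout.
canonical_sites <- function(geom, h, k, face, xy) {
  n <- nrow(xy)
  corners <- geom$corners2
  m2inv <- solve(t(corners[2:3, , drop = FALSE]) - corners[1, ])
  lam23 <- xy %*% t(m2inv)
  lam <- cbind(1 - rowSums(lam23), lam23)
  tol <- 1e-6
  nzero <- rowSums(lam < tol)

  out_face <- face
  out_xy <- xy
  kind <- rep("hex", n)
  vertex <- rep(NA_integer_, n)
  key <- character(n)

  corner_axial <- rbind(c(0, 0), c(h, k), c(-k, h + k))

  is_corner <- nzero >= 2
  is_edge <- nzero == 1
  # corner (penton) sites: canonical owner is the lowest face at that vertex
  if (any(is_corner)) {
    ci <- apply(lam[is_corner, , drop = FALSE], 1, which.max)
    vid <- geom$ico$faces[cbind(face[is_corner], ci)]
    fmin <- vapply(vid, function(w) min(geom$vertex_faces[[w]]), numeric(1))
    cidx <- mapply(function(f, w) which(geom$ico$faces[f, ] == w), fmin, vid)
    out_face[is_corner] <- fmin
    out_xy[is_corner, ] <- do.call(rbind, lapply(seq_along(vid), function(i) {
      as.numeric(axial_to_cartesian(corner_axial[cidx[i], 1],
                                    corner_axial[cidx[i], 2]))
    }))
    kind[is_corner] <- "penton"
    vertex[is_corner] <- as.integer(vid - 1L)
    key[is_corner] <- paste0("P", vid)
  }
  # edge sites: compare with the face across the edge, keep the lower id
  if (any(is_edge)) {
    idx <- which(is_edge)
    ci0 <- apply(lam[idx, , drop = FALSE], 1, which.min)
    for (i in seq_along(idx)) {
      f <- face[idx[i]]
      u <- geom$unfold[[f]][[ci0[i]]]
      if (u$face < f) {
        out_face[idx[i]] <- u$face
        out_xy[idx[i], ] <- as.numeric(u$rot %*% xy[idx[i], ] + u$off)
      }
    }
  }
  # integer axial coordinates in the canonical frame
  uu <- out_xy[, 1] - out_xy[, 2] / sqrt(3)
  vv <- 2 * out_xy[, 2] / sqrt(3)
  ur <- round(uu); vr <- round(vv)
  if (max(abs(uu - ur), abs(vv - vr)) > 1e-5) {
    stop("internal error: site did not land on a lattice point")
  }
  hexsel <- kind == "hex"
  key[hexsel] <- paste0("F", out_face[hexsel] - 1L, ":", ur[hexsel], ",",
                        vr[hexsel])
  list(key = key, face = out_face, u = ur, v = vr, kind = kind, vertex = vertex)
}

# index pairs of lattice-neighbour candidates within one face chart
lattice_neighbor_pairs <- function(cand) {
  key <- paste(cand$u, cand$v)
  idx <- stats::setNames(seq_len(nrow(cand)), key)
  offs <- list(c(1, 0), c(0, 1), c(-1, 1))
  pairs <- purrr::map(offs, function(o) {
    j <- idx[paste(cand$u + o[1], cand$v + o[2])]
    ok <- !is.na(j)
    cbind(which(ok), unname(j[ok]))
  })
  do.call(rbind, pairs)
}

#' Capsomer adjacency graph
#'
#' Nearest-neighbour (centre-to-centre one lattice step) contacts between
#' capsomers, including pairs that straddle icosahedral edges and vertices.
#' Pentons have 5 neighbours; hexavalent capsomers have 6.
#'
#' @param lattice A `capsid_lattice` from [enumerate_capsomers()].
#' @return A tibble with columns `from`, `to` (capsomer ids, `from < to`).
#' @export
lattice_neighbors <- function(lattice) {
  em <- attr(lattice, "edges")
  tibble::tibble(from = as.integer(em[, 1]), to = as.integer(em[, 2]))
}

lattice_graph <- function(lattice) {
  em <- attr(lattice, "edges")
  igraph::graph_from_edgelist(em, directed = FALSE)
}

#' @export
print.capsid_lattice <- function(x, ...) {
  hk <- attr(x, "hk")
  cat(sprintf(
    "<capsid_lattice> (h, k) = (%d, %d), %s-handed, T = %d, %d capsomers (a = %g)\n",
    hk[1], hk[2], attr(x, "handedness"), attr(x, "t"), nrow(x),
    attr(x, "spacing_a")))
  NextMethod()
}

#' Export a capsomer table to CSV
#'
#' Writes the columns `id`, `face`, `u`, `v`, `kind`, `x`, `y` (UTF-8, "."
#' decimal separator, header row).
#'
#' @param lattice A `capsid_lattice`.
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_capsomers_csv <- function(lattice, path) {
  lattice |>
    tibble::as_tibble() |>
    dplyr::select("id", "face", "u", "v", "kind", "x", "y") |>
    readr::write_csv(path)
  invisible(lattice)
}
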
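#' Reference icosahedron frame
#'
#' A regular icosahedron with unit circumradius, deterministic vertex and face
#' numbering, and consistently outward (counter-clockwise viewed from outside)
#' face orientation. Vertex ids 0-11 are assigned by decreasing z, then by
#' azimuth; face ids 0-19 by the lexicographically sorted triple of their
#' vertex ids. The ratio circumradius/edge is
#' `sqrt(10 + 2*sqrt(5))/4 = 0.9510565...`.
#'
#' @return A list with `vertices` (12 x 3 matrix of unit vectors, row i is
#'   vertex id i-1), `faces` (20 x 3 matrix of 1-based vertex row indices,
#'   each row counter-clockwise viewed from outside), and
#'   `circumradius_factor`.
#' @examples
#' f <- icosahedron_frame()
#' nrow(f$vertices); nrow(f$faces)
#' @export
icosahedron_frame <- function() {
  phi <- (1 + sqrt(5)) / 2
  raw <- rbind(
    cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
    cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
    cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1))
  )
  v <- raw / sqrt(rowSums(raw^2))
  ord <- order(-round(v[, 3], 9), round(atan2(v[, 2], v[, 1]), 9))
  v <- v[ord, , drop = FALSE]

  # faces: triples of mutually nearest vertices
  d <- as.matrix(stats::dist(v))
  edge_len <- min(d[d > 1e-9])
  adj <- d < edge_len + 1e-6 & d > 1e-9
  faces <- list()
  for (i in 1:10) for (j in (i + 1):11) for (l in (j + 1):12) {
    if (adj[i, j] && adj[i, l] && adj[j, l]) faces[[length(faces) + 1]] <- c(i, j, l)
  }
  faces <- do.call(rbind, faces)
  faces <- faces[order(faces[, 1], faces[, 2], faces[, 3]), , drop = FALSE]
  # enforce outward CCW orientation keeping the smallest vertex first
  for (r in seq_len(nrow(faces))) {
    tri <- faces[r, ]
    a <- v[tri[1], ]; b <- v[tri[2], ]; c3 <- v[tri[3], ]
    n <- crossprod3(b - a, c3 - a)
    if (sum(n * (a + b + c3)) < 0) faces[r, ] <- tri[c(1, 3, 2)]
  }
  list(
    vertices = v,
    faces = faces,
    circumradius_factor = sqrt(10 + 2 * sqrt(5)) / 4
  )
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Planar corners of one icosahedral face for lattice indices (h, k), lattice
# units. Corner A at the origin, corner B h steps along e1 and k along e2,
# corner C the 60-degree counter-clockwise rotation of B: an equilateral
# triangle of side sqrt(T).
face_planar_corners <- function(h, k) {
  b <- as.numeric(axial_to_cartesian(h, k))
  c3 <- as.numeric(axial_to_cartesian(-k, h + k))
  rbind(A = c(0, 0), B = b, C = c3)
}

# Full fold geometry for a capsid class: scaled 3D vertices, per-face affine
# maps from the planar face frame onto 3D face planes (isometries), planar
# unfolding maps between adjacent faces, and the cyclic (counter-clockwise
# from outside) order of the five faces around each vertex.
build_fold_geometry <- function(h, k) {
  t_num <- t_number(h, k)
  ico <- icosahedron_frame()
  edge <- sqrt(t_num)
  v3 <- ico$vertices * edge * ico$circumradius_factor
  corners2 <- face_planar_corners(h, k)
  n_face <- nrow(ico$faces)

  # affine map per face: planar q -> v3[A] + L %*% q, with L the 3 x 2 linear
  # part sending planar corner offsets onto 3D corner offsets (an isometry,
  # since both triangles are congruent)
  m2 <- t(corners2[2:3, , drop = FALSE]) - corners2[1, ]   # 2 x 2: columns B-A, C-A
  affine <- vector("list", n_face)
  for (f in seq_len(n_face)) {
    tri <- ico$faces[f, ]
    m3 <- cbind(v3[tri[2], ] - v3[tri[1], ], v3[tri[3], ] - v3[tri[1], ])
    affine[[f]] <- list(L = m3 %*% solve(m2), o = v3[tri[1], ])
  }

  # planar unfolding across each face edge: orientation-preserving planar
  # isometry from the frame of face f to the frame of the neighbouring face
  edge_key <- function(i, j) paste(min(i, j), max(i, j))
  edge_faces <- list()
  for (f in seq_len(n_face)) {
    tri <- ico$faces[f, ]
    for (pair in list(tri[c(1, 2)], tri[c(2, 3)], tri[c(1, 3)])) {
      ky <- edge_key(pair[1], pair[2])
      edge_faces[[ky]] <- c(edge_faces[[ky]], f)
    }
  }
  # corner index (1..3) of vertex vid within face f
  corner_of <- function(f, vid) which(ico$faces[f, ] == vid)
  unfold <- vector("list", n_face)
  for (f in seq_len(n_face)) unfold[[f]] <- vector("list", 3)
  opp_corner_edges <- list(c(2, 3), c(1, 3), c(1, 2))  # edge opposite corner i
  for (f in seq_len(n_face)) {
    tri <- ico$faces[f, ]
    for (ci in 1:3) {
      pair <- tri[opp_corner_edges[[ci]]]
      ky <- edge_key(pair[1], pair[2])
      g <- setdiff(edge_faces[[ky]], f)
      pf <- corners2[c(corner_of(f, pair[1]), corner_of(f, pair[2])), , drop = FALSE]
      pg <- corners2[c(corner_of(g, pair[1]), corner_of(g, pair[2])), , drop = FALSE]
      ang <- atan2(pg[2, 2] - pg[1, 2], pg[2, 1] - pg[1, 1]) -
        atan2(pf[2, 2] - pf[1, 2], pf[2, 1] - pf[1, 1])
      rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      unfold[[f]][[ci]] <- list(face = g, rot = rot, angle = ang,
                                off = pg[1, ] - as.numeric(rot %*% pf[1, ]))
    }
  }

  # cyclic CCW order of the five faces around each vertex (viewed from outside)
  vertex_faces <- vector("list", 12)
  for (w in 1:12) {
    fs <- which(apply(ico$faces, 1, function(tr) w %in% tr))
    nrm <- ico$vertices[w, ]
    ref <- v3[ico$faces[fs[1], ], ]
    cen1 <- colMeans(ref) - sum(colMeans(ref) * nrm) * nrm
    e1 <- cen1 / sqrt(sum(cen1^2))
    e2 <- crossprod3(nrm, e1)
    ang <- vapply(fs, function(f) {
      cen <- colMeans(v3[ico$faces[f, ], ])
      w2 <- cen - sum(cen * nrm) * nrm
      atan2(sum(w2 * e2), sum(w2 * e1))
    }, numeric(1))
    vertex_faces[[w]] <- fs[order(ang)]
  }

  list(t = t_num, ico = ico, v3 = v3, corners2 = corners2,
       affine = affine, unfold = unfold, vertex_faces = vertex_faces)
}

# Transport planar points (given in the frame of face `fid`, 1-based) across
# face edges until each lands inside a face triangle; returns the final face,
# final planar coordinates, accumulated rotation angle, and the 3D position.
# Points already inside stay put. Used to resolve lattice sites that spill
# over a face boundary (trisymmetron overhangs, neighbour rings).
unfold_points <- function(geom, fid, xy, max_steps = 8) {
  n <- nrow(xy)
  cur_face <- rep.int(fid, n)
  cur <- xy
  rot_acc <- numeric(n)
  corners <- geom$corners2
  m2 <- t(corners[2:3, , drop = FALSE]) - corners[1, ]
  m2inv <- solve(m2)
  done <- rep(FALSE, n)
  for (step in seq_len(max_steps)) {
    idx <- which(!done)
    if (length(idx) == 0) break
    rel <- cur[idx, , drop = FALSE]
    lam23 <- rel %*% t(m2inv)              # barycentric for corners B, C
    lam <- cbind(1 - lam23[, 1] - lam23[, 2], lam23)
    inside <- apply(lam, 1, min) >= -1e-9
    done[idx[inside]] <- TRUE
    out <- idx[!inside]
    if (length(out) == 0) next
    worst <- apply(lam[!inside, , drop = FALSE], 1, which.min)
    # group by (face, crossing edge = edge opposite the most-violated corner)
    # and apply that unfold map
    grp <- split(seq_along(out), paste(cur_face[out], worst))
    for (g in grp) {
      f <- cur_face[out[g[1]]]
      ci <- worst[g[1]]
      u <- geom$unfold[[f]][[ci]]
      pts <- cur[out[g], , drop = FALSE]
      cur[out[g], ] <- pts %*% t(u$rot) + matrix(u$off, length(g), 2, byrow = TRUE)
      cur_face[out[g]] <- u$face
      rot_acc[out[g]] <- rot_acc[out[g]] + u$angle
    }
  }
  if (!all(done)) stop("unfolding did not converge; point far outside the net")
  p3 <- matrix(0, n, 3)
  for (f in unique(cur_face)) {
    sel <- cur_face == f
    af <- geom$affine[[f]]
    p3[sel, ] <- cur[sel, , drop = FALSE] %*% t(af$L) +
      matrix(af$o, sum(sel), 3, byrow = TRUE)
  }
  list(face = cur_face, xy = cur, rot = rot_acc, p3 = p3)
}
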
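# --- 3D helpers -------------------------------------------------------------

face_normal <- function(geom, f) {
  tri <- geom$ico$faces[f, ]
  a <- geom$v3[tri[1], ]; b <- geom$v3[tri[2], ]; c3 <- geom$v3[tri[3], ]
  n <- crossprod3(b - a, c3 - a)
  n / sqrt(sum(n^2))
}

rodrigues <- function(vec, axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  vec * cos(theta) + crossprod3(axis, vec) * sin(theta) +
    axis * sum(axis * vec) * (1 - cos(theta))
}

# rotate a tangent vector from the plane of face f to the plane of adjacent
# face g, about their shared edge (parallel transport across the fold)
rotate_across_edge <- function(geom, vec, f, g) {
  shared <- intersect(geom$ico$faces[f, ], geom$ico$faces[g, ])
  if (length(shared) != 2) stop("faces ", f, " and ", g, " share no edge")
  axis <- geom$v3[shared[2], ] - geom$v3[shared[1], ]
  nf <- face_normal(geom, f); ng <- face_normal(geom, g)
  theta <- atan2(sum(crossprod3(nf, ng) * axis / sqrt(sum(axis^2))),
                 sum(nf * ng))
  rodrigues(vec, axis, theta)
}

# transport a tangent vector between two faces that meet at vertex w,
# stepping the short way around the vertex
transport_around_vertex <- function(geom, vec, f_from, f_to, w) {
  if (f_from == f_to) return(vec)
  cyc <- geom$vertex_faces[[w]]
  i <- match(f_from, cyc); j <- match(f_to, cyc)
  if (is.na(i) || is.na(j)) stop("faces do not meet at vertex ", w)
  fwd <- (j - i) %% 5
  path <- if (fwd <= 2) cyc[((i - 1 + 0:fwd) %% 5) + 1]
          else cyc[((i - 1 - 0:(5 - fwd)) %% 5) + 1]
  for (s in seq_len(length(path) - 1)) {
    vec <- rotate_across_edge(geom, vec, path[s], path[s + 1])
  }
  vec
}

# angle (degrees, modulo the capsomer's quasi-hexagonal 120-degree true
# 3-fold symmetry) of a tangent vector relative to the image of lattice axis
# e1 in face f's frame
angle_in_face <- function(geom, vec, f) {
  e1img <- as.numeric(geom$affine[[f]]$L %*% c(1, 0))
  nf <- face_normal(geom, f)
  th <- atan2(sum(crossprod3(e1img, vec) * nf), sum(e1img * vec)) * 180 / pi
  th %% 120
}

# Development of the five face wedges around a vertex into the plane: each
# face at vertex w contributes a 60-degree wedge; a site owned by the q-th
# face of the cycle (q = 0..4, counter-clockwise from outside) at in-wedge
# angle phi gets development angle 60*q + phi in [0, 300). Exact for every
# site within graph distance p of the vertex (all lie in their owner face's
# closed corner wedge). Returns a function mapping site rows to angles.
vertex_development_angle <- function(geom, s, w, spacing) {
  faces5 <- geom$vertex_faces[[w + 1]]
  corners <- geom$corners2
  nxt <- c(2, 3, 1)
  wedge <- lapply(seq_along(faces5), function(q) {
    f <- faces5[q]
    ci <- which(geom$ico$faces[f, ] == w + 1)
    cxy <- corners[ci, ]
    d0 <- corners[nxt[ci], ] - cxy
    list(face = f, corner = cxy, phi0 = atan2(d0[2], d0[1]), q = q - 1L)
  })
  wmap <- stats::setNames(wedge, vapply(wedge, function(x) as.character(x$face),
                                        character(1)))
  function(rows) {
    vapply(rows, function(r) {
      wd <- wmap[[as.character(s$face[r] + 1L)]]
      if (is.null(wd)) stop("site not on a face at vertex ", w)
      d <- c(s$x[r], s$y[r]) / spacing - wd$corner
      phi <- (atan2(d[2], d[1]) - wd$phi0) * 180 / pi
      phi <- ((phi + 180) %% 360) - 180      # to (-180, 180]
      if (phi < -1e-6 || phi > 60 + 1e-6) {
        stop("site outside its owner wedge at vertex ", w)
      }
      (60 * wd$q + min(max(phi, 0), 60)) %% 300
    }, numeric(1))
  }
}

# --- orientation assignment -------------------------------------------------

#' Assign capsomer orientation classes to a decomposition
#'
#' Pseudo-hexagonal capsomers have a true 3-fold symmetry, so their in-plane
#' setting is defined modulo 120 degrees and takes one of two classes (0 or
#' 60 degrees) in any face frame. All capsomers of a trisymmetron share one
#' setting; edge-adjacent trisymmetrons differ by exactly 60 degrees. Within
#' each five-fold sector of a pentasymmetron, five of the six hexavalent
#' capsomers share the sector setting while one — the unique, spiral-seed
#' capsomer — adopts the setting of the trisymmetron whose tip it touches,
#' giving 5 unique capsomers per pentasymmetron and 60 per virion.
#'
#' @param dec A `capsid_decomposition` from [decompose_capsid()].
#' @return The decomposition with site columns `orientation_label` (id of the
#'   trisymmetron whose setting the capsomer shares; `"PEN"` for pentons),
#'   `angle_deg` (0 or 60, measured in the frame of `phys_face`),
#'   `phys_face`, `sector` (five-fold sector id for pentasymmetron members),
#'   `is_unique`, and orientation vector components `ox`, `oy`, `oz`
#'   (tangent to the capsid surface).
#' @examples
#' dec <- decompose_capsid(enumerate_capsomers(3, 5)) |> assign_orientations()
#' sum(dec$sites$is_unique, na.rm = TRUE)  # 60 unique positions
#' @export
assign_orientations <- function(dec) {
  stopifnot(inherits(dec, "capsid_decomposition"))
  lat <- dec$lattice
  geom <- attr(lat, "geom")
  spacing <- attr(lat, "spacing_a")
  s <- dec$sites
  n_site <- nrow(s)

  label <- rep(NA_character_, n_site)
  angle <- rep(NA_real_, n_site)
  phys <- rep(NA_integer_, n_site)
  uniq <- rep(NA, n_site)
  sector <- rep(NA_character_, n_site)
  ovec <- matrix(NA_real_, n_site, 3)

  # trisymmetron members: axis e1 of the home-face frame, parallel-transported
  # through the same unfolding that placed the site
  tri_idx <- which(s$symmetron_kind == "tri")
  if (length(tri_idx)) {
    rot <- dec$tri_rot[tri_idx]
    pf <- dec$tri_phys_face[tri_idx]
    dirs <- cbind(cos(rot), sin(rot))
    for (f in unique(pf)) {
      sel <- pf == f
      ovec[tri_idx[sel], ] <- dirs[sel, , drop = FALSE] %*% t(geom$affine[[f]]$L)
    }
    label[tri_idx] <- s$symmetron_id[tri_idx]
    phys[tri_idx] <- pf
    uniq[tri_idx] <- FALSE
    angle[tri_idx] <- vapply(tri_idx, function(i) {
      angle_in_face(geom, ovec[i, ], phys[i])
    }, numeric(1))
  }

  pen_idx <- which(s$kind == "penton")
  label[pen_idx] <- "PEN"
  uniq[pen_idx] <- FALSE

  # pentasymmetron hexavalent members, vertex by vertex
  stopifnot(all(s$id == seq_len(n_site)))
  edges <- attr(lat, "edges")
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  p3 <- as.matrix(s[, c("X", "Y", "Z")]) / spacing
  # chirality of the spiral seed: viewed from outside, the seed capsomer
  # abuts the clockwise sector boundary in a right-handed lattice and the
  # counter-clockwise one in its mirror image
  seed_at_start <- attr(lat, "handedness") == "right"

  if (dec$p >= 1 && dec$n >= 1) {
    for (w in 0:11) {
      vpos <- geom$v3[w + 1, ]
      faces5 <- geom$vertex_faces[[w + 1]]
      tri_ids <- sprintf("T%02d", faces5)
      tips <- vapply(tri_ids, function(tid) {
        m <- which(s$symmetron_id == tid)
        m[which.min(colSums((t(p3[m, , drop = FALSE]) - vpos)^2))]
      }, numeric(1))
      # exact angles in the flattened development of the five 60-degree face
      # wedges meeting at this vertex (avoids fold distortion)
      dev_ang <- vertex_development_angle(geom, s, w, spacing)
      tip_ang <- dev_ang(tips)
      ord <- order(tip_ang)
      tips_o <- tips[ord]; tip_ang_o <- tip_ang[ord]

      members <- which(s$home_vertex == w & s$kind == "hex")
      mb_ang <- dev_ang(members)
      sec <- findInterval(mb_ang, tip_ang_o)
      sec[sec == 0] <- 5

      for (si in 1:5) {
        msec <- members[sec == si]
        start_tip <- tips_o[si]
        nxt_tip <- tips_o[if (si == 5) 1 else si + 1]
        seed_tip <- if (seed_at_start) start_tip else nxt_tip
        plain_tip <- if (seed_at_start) nxt_tip else start_tip
        u_here <- msec[msec %in% adj[[as.character(s$id[seed_tip])]] &
                         s$layer[msec] == dec$p]
        if (length(u_here) != 1) {
          stop("internal error: expected one spiral-seed capsomer per sector, ",
               "found ", length(u_here))
        }
        plain <- setdiff(msec, u_here)
        label[u_here] <- s$symmetron_id[seed_tip]
        label[plain] <- s$symmetron_id[plain_tip]
        uniq[u_here] <- TRUE
        uniq[plain] <- FALSE
        sector[msec] <- sprintf("V%02d.S%d", w, si)

        # transport the seed trisymmetron tip's orientation vector to each
        # member's own face plane
        tipvec_u <- ovec[seed_tip, ]
        tip_face_u <- phys[seed_tip]
        tipvec_p <- ovec[plain_tip, ]
        tip_face_p <- phys[plain_tip]
        for (m in msec) {
          fm <- s$face[m] + 1L
          src_vec <- if (m == u_here) tipvec_u else tipvec_p
          src_face <- if (m == u_here) tip_face_u else tip_face_p
          vv <- transport_around_vertex(geom, src_vec, src_face, fm, w + 1L)
          ovec[m, ] <- vv
          phys[m] <- fm
          angle[m] <- angle_in_face(geom, vv, fm)
        }
      }
    }
  }

  # snap angles to the two classes and check they are clean
  snapped <- round(angle / 60) * 60 %% 120
  snapped[snapped == 120] <- 0
  dev <- abs(angle - round(angle / 60) * 60)
  if (any(dev[!is.na(dev)] > 1e-6)) {
    stop("internal error: orientation angle not a multiple of 60 degrees")
  }

  s$orientation_label <- label
  s$angle_deg <- snapped
  s$phys_face <- as.integer(phys - 1L)
  s$is_unique <- uniq
  s$sector <- sector
  s$ox <- ovec[, 1]; s$oy <- ovec[, 2]; s$oz <- ovec[, 3]

  dec$sites <- s
  dec$symmetrons <- dec$symmetrons |>
    dplyr::mutate(orientation_class = ifelse(.data$kind == "tri",
                                             .data$symmetron_id, NA_character_))
  dec$orientations <- TRUE
  dec
}

#' Measured rotation between orientation classes of adjacent trisymmetrons
#'
#' Takes every nearest-neighbour capsomer pair that straddles a trisymmetron
#' boundary within a single face plane and measures the in-plane angle
#' between their orientation vectors, modulo the capsomers' 120-degree true
#' symmetry.
#'
#' @param dec A decomposition with orientations assigned.
#' @return A one-row tibble: `n_pairs`, `angle_deg` (mean measured angle),
#'   `max_dev_deg` (largest deviation from the mean across pairs).
#' @examples
#' enumerate_capsomers(3, 5) |> decompose_capsid() |>
#'   assign_orientations() |> trisymmetron_boundary_angle()
#' @export
trisymmetron_boundary_angle <- function(dec) {
  stopifnot(isTRUE(dec$orientations))
  s <- dec$sites
  geom <- attr(dec$lattice, "geom")
  e <- lattice_neighbors(dec$lattice)
  i <- match(e$from, s$id); j <- match(e$to, s$id)
  sel <- which(s$symmetron_kind[i] == "tri" & s$symmetron_kind[j] == "tri" &
                 s$symmetron_id[i] != s$symmetron_id[j] &
                 s$phys_face[i] == s$phys_face[j])
  if (!length(sel)) stop("no trisymmetron boundary pairs found")
  ang <- vapply(sel, function(r) {
    f <- s$phys_face[i[r]] + 1L
    nf <- face_normal(geom, f)
    v1 <- c(s$ox[i[r]], s$oy[i[r]], s$oz[i[r]])
    v2 <- c(s$ox[j[r]], s$oy[j[r]], s$oz[j[r]])
    (atan2(sum(crossprod3(v1, v2) * nf), sum(v1 * v2)) * 180 / pi) %% 120
  }, numeric(1))
  ang <- pmin(ang, 120 - ang)  # class separation in [0, 60]
  tibble::tibble(n_pairs = length(ang), angle_deg = mean(ang),
                 max_dev_deg = max(abs(ang - mean(ang))))
}

#' Recompute the unique (spiral-seed) capsomer positions
#'
#' Independently of the constructive `is_unique` flag, finds in every
#' five-fold pentasymmetron sector the capsomer whose orientation class
#' differs from the sector majority.
#'
#' @param dec A decomposition with orientations assigned.
#' @return A tibble of the minority-orientation capsomers (columns `id`,
#'   `sector`, `orientation_label`).
#' @export
unique_positions <- function(dec) {
  stopifnot(isTRUE(dec$orientations))
  s <- dec$sites
  geom <- attr(dec$lattice, "geom")
  hex <- which(s$symmetron_kind == "penta" & s$kind == "hex")
  out <- purrr::map_dfr(split(hex, s$sector[hex]), function(rows) {
    # express every member's orientation in one common face frame before
    # comparing classes (face frames around a vertex differ by 60 degrees)
    f0 <- s$phys_face[rows[1]] + 1L
    w <- s$home_vertex[rows[1]] + 1L
    ang <- vapply(rows, function(r) {
      v <- transport_around_vertex(geom, c(s$ox[r], s$oy[r], s$oz[r]),
                                   s$phys_face[r] + 1L, f0, w)
      round(angle_in_face(geom, v, f0) / 60) * 60 %% 120
    }, numeric(1))
    ang[ang == 120] <- 0
    tab <- table(ang)
    if (length(tab) < 2) return(NULL)
    minority <- as.numeric(names(tab)[which.min(tab)])
    sel <- rows[ang == minority]
    tibble::tibble(id = s$id[sel], sector = s$sector[sel],
                   orientation_label = s$orientation_label[sel])
  })
  dplyr::arrange(out, .data$id)
}

#' Spiral colour groups around a five-fold vertex
#'
#' Groups the pentasymmetron capsomers of one vertex together with the tips
#' of the five surrounding trisymmetrons into five orientation-consistent
#' groups plus the penton — the "five interlocked golf clubs" motif. Each
#' group contains exactly one unique (spiral-seed) pentasymmetron capsomer.
#'
#' @param dec A decomposition with orientations assigned.
#' @param vertex Vertex id (0-11).
#' @return A tibble with columns `id`, `group` (trisymmetron id or
#'   `"penton"`), `role` (`"penton"`, `"pentasymmetron"`, `"tip"`) and
#'   `is_unique`.
#' @export
spiral_pattern <- function(dec, vertex = 0) {
  stopifnot(isTRUE(dec$orientations), vertex %in% 0:11)
  s <- dec$sites
  geom <- attr(dec$lattice, "geom")
  spacing <- attr(dec$lattice, "spacing_a")
  vpos <- geom$v3[vertex + 1, ]
  faces5 <- geom$vertex_faces[[vertex + 1]]
  tri_ids <- sprintf("T%02d", faces5)
  p3 <- as.matrix(s[, c("X", "Y", "Z")]) / spacing
  tips <- vapply(tri_ids, function(tid) {
    m <- which(s$symmetron_id == tid)
    m[which.min(colSums((t(p3[m, , drop = FALSE]) - vpos)^2))]
  }, numeric(1))
  pent_members <- which(s$home_vertex == vertex)
  out <- dplyr::bind_rows(
    tibble::tibble(
      id = s$id[pent_members],
      group = ifelse(s$kind[pent_members] == "penton", "penton",
                     s$orientation_label[pent_members]),
      role = ifelse(s$kind[pent_members] == "penton", "penton",
                    "pentasymmetron"),
      is_unique = s$is_unique[pent_members]
    ),
    tibble::tibble(id = s$id[tips], group = s$symmetron_id[tips],
                   role = "tip", is_unique = FALSE)
  )
  dplyr::arrange(out, .data$group, .data$id)
}

#' Recover symmetron-like regions from the orientation field alone
#'
#' Flood-fills the capsomer adjacency graph over edges whose endpoints share
#' an orientation label: the discontinuous boundary lines between orientation
#' classes re-draw the symmetron partition, except that each unique capsomer
#' (and the five sector capsomers oriented with a neighbouring trisymmetron)
#' attaches to the trisymmetron it is oriented with — exactly the visual
#' continuation the spiral pattern is built from.
#'
#' @param dec A decomposition with orientations assigned.
#' @return A tibble with columns `id`, `region` (integer component label).
#' @export
detect_orientation_regions <- function(dec) {
  stopifnot(isTRUE(dec$orientations))
  s <- dec$sites
  e <- lattice_neighbors(dec$lattice)
  i <- match(e$from, s$id); j <- match(e$to, s$id)
  same <- !is.na(s$orientation_label[i]) & !is.na(s$orientation_label[j]) &
    s$orientation_label[i] == s$orientation_label[j] &
    s$orientation_label[i] != "PEN"
  g <- igraph::graph_from_edgelist(cbind(e$from[same], e$to[same]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(s) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(nrow(s))]
  tibble::tibble(id = s$id, region = as.integer(comp[s$id]))
}
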
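#' Generate synthetic capsomer-centre coordinates
#'
#' Emulates a table of capsomer centres as they would be measured from a
#' well-resolved reconstruction: the exact lattice positions for a capsid
#' class, optionally perturbed by isotropic Gaussian jitter and thinned by
#' random dropout. Designated penton points are never dropped, so the
#' penton-to-penton path needed by [fit_hk()] always survives.
#'
#' @param h,k Lattice indices.
#' @param mode `"face"`: the planar lattice of one icosahedral face
#'   (including its three corner pentons, identical to the face-0 chart of
#'   [enumerate_capsomers()]); `"patch"`: the planar parallelogram spanned by
#'   the h- and k-steps between two pentons; `"capsid3d"`: the full folded
#'   capsid.
#' @param handedness,spacing_a As in [enumerate_capsomers()].
#' @param jitter_sigma Isotropic noise scale (same unit as `spacing_a`).
#' @param dropout_fraction Fraction of non-penton points removed at random,
#'   in `[0, 1)`.
#' @param seed Optional integer; fixes the full sample.
#' @return A `center_set` tibble with columns `x`, `y` (`z` in 3D mode) and
#'   `is_penton`; generation parameters are kept as attributes.
#' @examples
#' cs <- synth_centers(7, 18, jitter_sigma = 0.1, dropout_fraction = 0.05,
#'                     seed = 1)
#' sum(cs$is_penton)
#' @export
synth_centers <- function(h, k, mode = c("face", "patch", "capsid3d"),
                          handedness = c("right", "left"), spacing_a = 1,
                          jitter_sigma = 0, dropout_fraction = 0,
                          seed = NULL) {
  mode <- match.arg(mode)
  handedness <- match.arg(handedness)
  check_hk(h, k)
  stopifnot(spacing_a > 0, jitter_sigma >= 0,
            dropout_fraction >= 0, dropout_fraction < 1)
  hh <- if (handedness == "right") h else k
  kk <- if (handedness == "right") k else h

  if (mode == "capsid3d") {
    lat <- enumerate_capsomers(h, k, handedness, spacing_a)
    pts <- tibble::tibble(x = lat$X, y = lat$Y, z = lat$Z,
                          is_penton = lat$kind == "penton")
  } else if (mode == "face") {
    geom <- build_fold_geometry(hh, kk)
    cand <- face_candidate_sites(hh, kk, geom)
    cand <- cand[cand$inside, ]
    corner_uv <- rbind(c(0, 0), c(hh, kk), c(-kk, hh + kk))
    is_pent <- paste(cand$u, cand$v) %in% paste(corner_uv[, 1], corner_uv[, 2])
    pts <- tibble::tibble(x = cand$x * spacing_a, y = cand$y * spacing_a,
                          is_penton = is_pent)
  } else {
    grid <- expand.grid(u = 0:hh, v = 0:kk)
    xy <- axial_to_cartesian(grid$u, grid$v, spacing_a)
    pts <- tibble::tibble(x = xy$x, y = xy$y,
                          is_penton = (grid$u == 0 & grid$v == 0) |
                            (grid$u == hh & grid$v == kk))
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  if (dropout_fraction > 0) {
    droppable <- which(!pts$is_penton)
    drop <- droppable[runif(length(droppable)) < dropout_fraction]
    if (length(drop)) pts <- pts[-drop, ]
  }
  if (jitter_sigma > 0) {
    ncoord <- if ("z" %in% names(pts)) 3 else 2
    for (cn in c("x", "y", "z")[seq_len(ncoord)]) {
      pts[[cn]] <- pts[[cn]] + stats::rnorm(nrow(pts), 0, jitter_sigma)
    }
  }
  structure(
    pts,
    class = c("center_set", class(tibble::tibble())),
    hk = c(h = h, k = k), handedness = handedness, mode = mode,
    spacing_a = spacing_a, jitter_sigma = jitter_sigma,
    dropout_fraction = dropout_fraction, seed = seed
  )
}

#' Recover (h, k) from capsomer-centre coordinates
#'
#' The computational analogue of tracing capsomers from one five-fold vertex
#' to a neighbouring one: estimates the local hexagonal-lattice orientation
#' from nearest-neighbour displacement angles (6-fold angular histogram),
#' walks the nearest-neighbour graph between the two designated pentons, and
#' decomposes each step of the walk into one of the six lattice directions.
#' The summed steps give the lattice vector, reported canonically as
#' `h <= k` with a separate handedness flag. 3D inputs are first flattened
#' gnomonically around the penton-penton chord (an approximation valid for
#' the path-tracing task).
#'
#' @param centers A data frame with columns `x`, `y` (optionally `z`) and
#'   optionally `is_penton`; e.g. from [synth_centers()] or
#'   [read_centers_csv()].
#' @param penton_ids Optional length-2 integer row indices of the two penton
#'   points. Defaults to the first two flagged `is_penton` rows, or, failing
#'   that, the two mutually most distant points.
#' @param basis_tol Maximum deviation (fraction of one lattice step) of a
#'   walk step from the nearest integer lattice vector before the fit aborts
#'   as ambiguous rather than guessing.
#' @param snap_tol Residual tolerance (fraction of the lattice spacing) used
#'   for the point-matching confidence.
#' @return A `capsid_fit` list: `h`, `k`, `handedness`, `t`, `confidence`
#'   (fraction of points within `snap_tol` of a fitted lattice site),
#'   `residual_rms`, `spacing` and `n_points`. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @examples
#' fit_hk(synth_centers(7, 18))[c("h", "k", "t")]
#' @export
fit_hk <- function(centers, penton_ids = NULL, basis_tol = 0.45,
                   snap_tol = 0.25) {
  pts <- as.data.frame(centers)
  stopifnot(all(c("x", "y") %in% names(pts)), nrow(pts) >= 2)
  is3d <- "z" %in% names(pts) && any(is.finite(pts$z)) &&
    stats::sd(pts$z) > 1e-12
  if (is.null(penton_ids)) {
    if ("is_penton" %in% names(pts) && sum(pts$is_penton) >= 2) {
      penton_ids <- which(pts$is_penton)[1:2]
    } else {
      cmat <- as.matrix(pts[, c("x", "y", if (is3d) "z")])
      hull <- unique(c(which.min(cmat[, 1]), which.max(cmat[, 1]),
                       which.min(cmat[, 2]), which.max(cmat[, 2])))
      dd <- as.matrix(stats::dist(cmat[hull, , drop = FALSE]))
      ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
      penton_ids <- hull[ij]
    }
  }
  stopifnot(length(penton_ids) == 2, penton_ids[1] != penton_ids[2])

  if (is3d) {
    flat <- gnomonic_flatten(as.matrix(pts[, c("x", "y", "z")]), penton_ids)
    xy <- flat$xy
    keep <- flat$keep
    penton_ids <- match(penton_ids, keep)
    if (anyNA(penton_ids)) stop("penton fell outside the flattened patch")
    local_frames <- TRUE
  } else {
    xy <- as.matrix(pts[, c("x", "y")])
    keep <- seq_len(nrow(pts))
    local_frames <- FALSE
  }

  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  # spacing from neighbour-pair separations, iterating the cutoff: the
  # nearest-of-six minimum is biased low under jitter, and a low cutoff
  # truncates the pair-distance distribution, so re-threshold until stable
  a_hat <- stats::median(nnd)
  pairs <- NULL
  for (it in 1:3) {
    pairs <- which(d < 1.35 * a_hat & upper.tri(d), arr.ind = TRUE)
    if (nrow(pairs) < 3) stop("too few neighbour pairs to estimate the lattice")
    a_hat <- stats::median(d[pairs])
  }
  if (local_frames) {
    # under the gnomonic distortion the lattice orientation drifts across the
    # patch: estimate the starting frame from pairs near the first penton and
    # let the walk's local refinement carry it along the path
    span <- d[penton_ids[1], penton_ids[2]]
    near1 <- which(d[penton_ids[1], ] < 0.6 * span | seq_len(n) == penton_ids[1])
    pairs_h <- pairs[pairs[, 1] %in% near1 & pairs[, 2] %in% near1, ,
                     drop = FALSE]
    if (nrow(pairs_h) < 3) pairs_h <- pairs
  } else {
    pairs_h <- pairs
  }
  disp <- xy[pairs_h[, 2], , drop = FALSE] - xy[pairs_h[, 1], , drop = FALSE]
  th <- atan2(disp[, 2], disp[, 1])
  # 6-fold angular histogram: circular mean of 6*theta
  zbar <- mean(exp(1i * 6 * th))
  if (Mod(zbar) < 0.5) {
    stop("ambiguous lattice basis: neighbour directions are not 6-fold ",
         "clustered (noise too high or points too sparse); resultant = ",
         round(Mod(zbar), 3), call. = FALSE)
  }
  phi_global <- Arg(zbar) / 6

  # path graph with a generous radius: skew face corners may have a single
  # one-step neighbour, so longer (sqrt(3)- or 2-step) edges are allowed and
  # decomposed exactly by basis snapping below
  gpairs <- which(d < 2.2 * a_hat & upper.tri(d), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(gpairs[, c(1, 2), drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- d[gpairs]
  suppressWarnings(
    path <- igraph::shortest_paths(g, penton_ids[1],
                                   penton_ids[2])$vpath[[1]])
  if (length(path) < 2) stop("no lattice path connects the two pentons")
  path <- as.integer(path)

  lat_basis <- function(phi, a) {
    a * cbind(c(cos(phi), sin(phi)), c(cos(phi + pi / 3), sin(phi + pi / 3)))
  }

  if (!local_frames) {
    # planar input: refine the basis vector by folding every neighbour
    # displacement back by its assigned multiple of 60 degrees and averaging
    # (unbiased in both scale and angle), then snap all points in the
    # penton-anchored frame and polish once by least squares
    zdisp <- complex(real = disp[, 1], imaginary = disp[, 2])
    idx6 <- round((Arg(zdisp) - phi_global) * 3 / pi)
    e1c <- mean(zdisp * exp(-1i * idx6 * pi / 3))
    basis <- lat_basis(Arg(e1c), Mod(e1c))
    origin <- xy[penton_ids[1], ]
    for (it in 1:2) {
      rel <- xy - matrix(origin, n, 2, byrow = TRUE)
      uvall <- rel %*% t(solve(basis))
      ruv <- round(uvall)
      conf_pts <- which(apply(abs(uvall - ruv), 1, max) < 0.35)
      if (length(conf_pts) >= 3 && it < 2) {
        co <- stats::lm.fit(cbind(1, ruv[conf_pts, , drop = FALSE]),
                            xy[conf_pts, , drop = FALSE])$coefficients
        origin <- co[1, ]
        basis <- t(co[2:3, , drop = FALSE])
      }
    }
    ruv <- round(uvall)
    pen_res <- apply(abs(uvall[penton_ids, , drop = FALSE] -
                           ruv[penton_ids, , drop = FALSE]), 1, max)
    if (max(pen_res) > basis_tol) {
      stop("ambiguous fit: a penton lies ", round(max(pen_res), 2),
           " lattice steps from its nearest fitted site", call. = FALSE)
    }
    uv <- ruv[penton_ids[2], ] - ruv[penton_ids[1], ]
    a_fit <- mean(sqrt(colSums(basis^2)))
    res <- sqrt(rowSums((uvall - ruv)^2)) * a_fit
  } else {
    # flattened 3D input: walk the path with a locally re-estimated frame
    uv <- c(0, 0)
    phi <- phi_global
    a_loc <- a_hat
    for (s in seq_len(length(path) - 1)) {
      step <- xy[path[s + 1], ] - xy[path[s], ]
      near <- which(d[path[s], ] < 1.35 * a_loc)
      if (length(near) >= 2) {
        dl <- xy[near, , drop = FALSE] -
          matrix(xy[path[s], ], length(near), 2, byrow = TRUE)
        zl <- mean(exp(1i * 6 * atan2(dl[, 2], dl[, 1])))
        if (Mod(zl) > 0.5) {
          cand <- Arg(zl) / 6 + (-2:2) * pi / 3
          phi <- cand[which.min(abs(cand - phi))]
          a_loc <- stats::median(sqrt(rowSums(dl^2)))
        }
      }
      uvs <- solve(lat_basis(phi, a_loc), step)
      ruv <- round(uvs)
      if (max(abs(uvs - ruv)) > basis_tol) {
        stop("ambiguous step at path position ", s, ": off by ",
             round(max(abs(uvs - ruv)), 2), " lattice steps from the ",
             "nearest lattice vector", call. = FALSE)
      }
      uv <- uv + ruv
    }
    a_fit <- a_hat
    # residuals against the start frame are only indicative under distortion
    basis <- lat_basis(phi_global, a_hat)
    rel <- xy - matrix(xy[penton_ids[1], ], n, 2, byrow = TRUE)
    uvall <- rel %*% t(solve(basis))
    res <- sqrt(rowSums((uvall - round(uvall))^2)) * a_hat
  }

  norm <- normalize_hk(uv)
  t_fit <- sum(uv^2) + uv[1] * uv[2]
  a_hat <- a_fit
  confidence <- mean(res <= snap_tol * a_hat)

  structure(
    list(h = norm$h, k = norm$k, handedness = norm$handedness,
         t = as.integer(t_fit), confidence = confidence,
         residual_rms = sqrt(mean(res^2)), spacing = a_hat, n_points = n,
         flattened = is3d),
    class = "capsid_fit"
  )
}

local_scale <- function(xy, i, nnd) max(nnd[i], 1e-9) / stats::median(nnd)

# canonical (h <= k) representative of a lattice vector plus handedness:
# exactly one of the six 60-degree rotations of (u, v) has both components
# non-negative; if its first component exceeds the second the vector is the
# mirror (left-handed) setting
normalize_hk <- function(uv) {
  reps <- matrix(NA_real_, 6, 2)
  cur <- uv
  for (i in 1:6) {
    reps[i, ] <- cur
    cur <- c(-cur[2], cur[1] + cur[2])  # 60-degree rotation in axial coords
  }
  nn <- reps[reps[, 1] >= 0 & reps[, 2] >= 0, , drop = FALSE]
  if (nrow(nn) == 0) stop("degenerate lattice vector")
  # achiral vectors (h == k, or one index zero) have two non-negative
  # representatives; report them as right-handed
  ordered <- nn[nn[, 1] <= nn[, 2], , drop = FALSE]
  if (nrow(ordered) > 0) {
    r <- ordered[1, ]
    list(h = as.integer(r[1]), k = as.integer(r[2]), handedness = "right")
  } else {
    r <- nn[1, ]
    list(h = as.integer(r[2]), k = as.integer(r[1]), handedness = "left")
  }
}

# gnomonic projection of the face patch around the penton-penton geodesic
# onto the plane tangent at the chord midpoint direction (projection centre
# at the cloud centroid, i.e. the capsid centre). Only a corridor around the
# geodesic is kept: away from it the flattened lattice orientation drifts
# (and jumps across vertex cones), which would defeat the basis estimate.
gnomonic_flatten <- function(p3, penton_ids) {
  c0 <- colMeans(p3)
  q <- p3 - matrix(c0, nrow(p3), 3, byrow = TRUE)
  rr <- sqrt(rowSums(q^2))
  nhat <- q / rr
  n1 <- nhat[penton_ids[1], ]; n2 <- nhat[penton_ids[2], ]
  r0 <- mean(rr[penton_ids])
  # lattice spacing estimate from 3D nearest-neighbour distances
  dn <- as.matrix(stats::dist(p3)); diag(dn) <- Inf
  a3 <- stats::median(apply(dn, 1, min))
  halfwidth <- 3.5 * a3 / r0                 # angular corridor half-width
  gc_norm <- crossprod3(n1, n2)
  gc_norm <- gc_norm / sqrt(sum(gc_norm^2))
  angsep <- acos(max(-1, min(1, sum(n1 * n2))))
  off_circle <- abs(nhat %*% gc_norm)
  along_ok <- (acos(pmax(-1, pmin(1, nhat %*% n1))) +
                 acos(pmax(-1, pmin(1, nhat %*% n2)))) <
    angsep + 2.5 * a3 / r0
  keep <- which(off_circle < sin(halfwidth) & along_ok)
  m <- (n1 + n2) / 2
  m <- m / sqrt(sum(m^2))
  proj <- as.numeric(q %*% m)
  keep <- keep[proj[keep] > 0.3 * r0]
  e1 <- n1 - sum(n1 * m) * m
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod3(m, e1)
  sc <- r0 / proj[keep]
  flat <- q[keep, , drop = FALSE] * sc
  list(xy = cbind(flat %*% e1, flat %*% e2), keep = keep)
}

#' @export
print.capsid_fit <- function(x, ...) {
  cat(sprintf(
    "<capsid_fit> (h, k) = (%d, %d) %s-handed, T = %d\n  confidence %.3f, residual rms %.4g, spacing %.4g, %d points%s\n",
    x$h, x$k, x$handedness, x$t, x$confidence, x$residual_rms, x$spacing,
    x$n_points, if (x$flattened) " (gnomonically flattened)" else ""))
  invisible(x)
}

#' Lattice-recovery benchmark over a noise/dropout grid
#'
#' Runs [synth_centers()] + [fit_hk()] over a grid of jitter and dropout
#' settings with `n_seeds` replicates each, and reports the exact-recovery
#' rate and mean residual per cell.
#'
#' @param h,k Lattice indices of the simulated capsid class.
#' @param sigmas Jitter scales (fractions of the lattice spacing).
#' @param dropouts Dropout fractions.
#' @param n_seeds Replicates per grid cell.
#' @param mode Generator mode (see [synth_centers()]).
#' @param base_seed Seed offset; replicate `i` of every cell uses
#'   `base_seed + i`.
#' @param csv_path Optional path; if given, the table is also written as CSV.
#' @return A tibble with columns `sigma`, `dropout`, `n_seeds`,
#'   `recovery_rate`, `mean_residual`, `n_failed`.
#' @export
recovery_experiment <- function(h, k, sigmas = c(0, 0.05, 0.1),
                                dropouts = c(0, 0.05), n_seeds = 100,
                                mode = "face", base_seed = 20260101,
                                csv_path = NULL) {
  grid <- tidyr::expand_grid(sigma = sigmas, dropout = dropouts)
  out <- purrr::pmap_dfr(grid, function(sigma, dropout) {
    hits <- logical(n_seeds)
    resid <- rep(NA_real_, n_seeds)
    for (i in seq_len(n_seeds)) {
      cs <- synth_centers(h, k, mode = mode, jitter_sigma = sigma,
                          dropout_fraction = dropout, seed = base_seed + i)
      fit <- tryCatch(fit_hk(cs), error = function(e) NULL)
      if (!is.null(fit)) {
        hits[i] <- fit$h == min(h, k) && fit$k == max(h, k)
        resid[i] <- fit$residual_rms
      }
    }
    tibble::tibble(sigma = sigma, dropout = dropout, n_seeds = n_seeds,
                   recovery_rate = mean(hits),
                   mean_residual = mean(resid, na.rm = TRUE),
                   n_failed = sum(is.na(resid)))
  })
  if (!is.null(csv_path)) readr::write_csv(out, csv_path)
  out
}

#' Read a capsomer-centre CSV
#'
#' Expects columns `x`, `y`, optionally `z` and `is_penton`.
#'
#' @param path CSV file path.
#' @return A tibble usable with [fit_hk()].
#' @export
read_centers_csv <- function(path) {
  # base parser for bit-exact coordinate round-trips
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("is_penton" %in% names(df)) df$is_penton <- as.logical(df$is_penton)
  df
}

#' Write a capsomer-centre table to CSV
#' @param centers A `center_set` or compatible data frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_centers_csv <- function(centers, path) {
  readr::write_csv(tibble::as_tibble(centers), path)
  invisible(path)
}
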
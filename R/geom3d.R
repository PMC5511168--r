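#' Fold a capsid lattice onto the icosahedron
#'
#' Maps each face's planar lattice patch isometrically onto the corresponding
#' face of a regular icosahedron whose edge length is `spacing_a * sqrt(T)`.
#' Shared edges map consistently (no seams), penton centres land exactly on
#' the icosahedron vertices, and the chord between adjacent penton centres is
#' `spacing_a * sqrt(T)`. Capsomer centres lie on the flat faces (a faceted
#' model); an optional spherical projection pushes them radially onto the
#' circumscribed sphere for rendering.
#'
#' @param x A `capsid_lattice` or `capsid_decomposition` (the latter carries
#'   symmetron ids and orientation vectors into the model).
#' @param spacing_a Capsomer spacing in the output unit (e.g. Angstrom); the
#'   default keeps the spacing the object was built with.
#' @param spherical If `TRUE`, project centres radially onto the
#'   circumscribed sphere (rendering only; distances in tests are exact on
#'   the faceted model).
#' @return A `capsid_model` tibble: `id`, `kind`, `symmetron_id`,
#'   `orientation_label`, `angle_deg`, `x`, `y`, `z`, and orientation vector
#'   components `ox`, `oy`, `oz` (unit vectors tangent to the faceted
#'   surface; `NA` for pentons or when `x` is a bare lattice).
#' @examples
#' m <- fold_to_3d(enumerate_capsomers(1, 0), spacing_a = 10)
#' round(dist(m[, c("x", "y", "z")])[1], 4)  # penton chord = 10 * sqrt(1)
#' @export
fold_to_3d <- function(x, spacing_a = NULL, spherical = FALSE) {
  if (inherits(x, "capsid_decomposition")) {
    lat <- x$lattice
    s <- x$sites
    has_dec <- TRUE
  } else if (inherits(x, "capsid_lattice")) {
    lat <- x
    s <- tibble::as_tibble(x)
    has_dec <- FALSE
  } else {
    stop("`x` must be a capsid_lattice or capsid_decomposition", call. = FALSE)
  }
  a0 <- attr(lat, "spacing_a")
  a <- if (is.null(spacing_a)) a0 else spacing_a
  stopifnot(a > 0)
  scl <- a / a0
  xyz <- cbind(s$X, s$Y, s$Z) * scl
  if (spherical) {
    t_num <- attr(lat, "t")
    r_sph <- a * sqrt(t_num) * icosahedron_frame()$circumradius_factor
    nrm <- sqrt(rowSums(xyz^2))
    xyz <- xyz * (r_sph / nrm)
  }
  out <- tibble::tibble(
    id = s$id,
    kind = s$kind,
    symmetron_id = if (has_dec) s$symmetron_id else NA_character_,
    orientation_label = if (has_dec && "orientation_label" %in% names(s))
      s$orientation_label else NA_character_,
    angle_deg = if (has_dec && "angle_deg" %in% names(s)) s$angle_deg
      else NA_real_,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    ox = if (has_dec && "ox" %in% names(s)) s$ox else NA_real_,
    oy = if (has_dec && "oy" %in% names(s)) s$oy else NA_real_,
    oz = if (has_dec && "oz" %in% names(s)) s$oz else NA_real_
  )
  structure(
    out,
    class = c("capsid_model", class(tibble::tibble())),
    hk = attr(lat, "hk"),
    handedness = attr(lat, "handedness"),
    t = attr(lat, "t"),
    spacing_a = a,
    spherical = spherical
  )
}

#' @export
print.capsid_model <- function(x, ...) {
  hk <- attr(x, "hk")
  cat(sprintf(
    "<capsid_model> (h, k) = (%d, %d), T = %d, %d pseudo-atoms, a = %g%s\n",
    hk[1], hk[2], attr(x, "t"), nrow(x), attr(x, "spacing_a"),
    if (isTRUE(attr(x, "spherical"))) ", spherical projection" else ""))
  NextMethod()
}

icos_diameter_factor <- function() 2 * sqrt(10 + 2 * sqrt(5)) / 4

#' Calibrate the lattice spacing from a reference capsid
#'
#' Given a capsid of known triangulation number and vertex-to-vertex diameter
#' (twice the circumradius), returns the implied capsomer centre-to-centre
#' spacing: `a = D / (2 * 0.9510565 * sqrt(T))`. Inverse of
#' [predict_diameter()].
#'
#' @param t_ref Triangulation number of the reference capsid.
#' @param diameter_ref Vertex-to-vertex diameter (Angstrom).
#' @return Spacing in the same unit as `diameter_ref`.
#' @examples
#' calibrate_spacing(169, 1800)  # ~72.8 Angstrom from a T=169, 1800-A capsid
#' @export
calibrate_spacing <- function(t_ref, diameter_ref) {
  stopifnot(t_ref >= 1, diameter_ref > 0)
  diameter_ref / (icos_diameter_factor() * sqrt(t_ref))
}

#' Predict the vertex-to-vertex capsid diameter
#'
#' `D = 2 * 0.9510565 * a * sqrt(T)`: the icosahedron circumdiameter for edge
#' length `a * sqrt(T)`. Monotone increasing in both arguments.
#'
#' @param t Triangulation number.
#' @param spacing_a Capsomer spacing (Angstrom).
#' @return Diameter in the unit of `spacing_a`.
#' @examples
#' predict_diameter(499, calibrate_spacing(169, 1800))  # ~3093 Angstrom
#' @export
predict_diameter <- function(t, spacing_a) {
  stopifnot(all(t >= 1), all(spacing_a > 0))
  icos_diameter_factor() * spacing_a * sqrt(t)
}

#' Export a pseudo-atom capsid model
#'
#' Writes a `capsid_model` as CSV (all columns, full double precision,
#' bit-exact on re-import), PDB (one pseudo-atom per capsomer; occupancy
#' carries the symmetron index, B-factor the orientation angle; models with
#' more than 99,999 atoms are split into successive MODEL blocks to respect
#' the fixed-column format) or Wavefront OBJ (point cloud, or one low-poly
#' sphere glyph per capsomer, grouped by symmetron).
#'
#' @param model A `capsid_model` from [fold_to_3d()].
#' @param path Output file path.
#' @param format `"csv"`, `"pdb"` or `"obj"`.
#' @param obj_mode For OBJ: `"points"` (default) or `"spheres"`.
#' @param glyph_radius Sphere glyph radius (same unit as the model
#'   coordinates); default 40 percent of the lattice spacing.
#' @return `path`, invisibly.
#' @export
export_model <- function(model, path, format = c("csv", "pdb", "obj"),
                         obj_mode = c("points", "spheres"),
                         glyph_radius = NULL) {
  stopifnot(inherits(model, "capsid_model"))
  format <- match.arg(format)
  switch(format,
    csv = readr::write_csv(tibble::as_tibble(model), path),
    pdb = export_model_pdb(model, path),
    obj = export_model_obj(model, path, match.arg(obj_mode), glyph_radius)
  )
  invisible(path)
}

#' Read back a model CSV written by [export_model()]
#' @param path CSV file path.
#' @return A tibble with the model columns.
#' @export
read_model_csv <- function(path) {
  # base read.csv: strtod parsing is correctly rounded, so coordinates
  # written by write_csv (shortest round-trip representation) re-import
  # bit-exactly
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

symmetron_index <- function(sid) {
  idx <- rep(0, length(sid))
  pe <- grepl("^P", sid)
  tr <- grepl("^T", sid)
  idx[pe] <- as.numeric(sub("^P", "", sid[pe]))
  idx[tr] <- 12 + as.numeric(sub("^T", "", sid[tr]))
  idx
}

export_model_pdb <- function(model, path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("PDB export requires the bio3d package", call. = FALSE)
  }
  xyz_rng <- range(model$x, model$y, model$z)
  if (xyz_rng[1] < -999.9995 || xyz_rng[2] > 9999.9995) {
    stop("coordinates exceed the PDB fixed-column range (-999.999 to ",
         "9999.999): export in larger units (e.g. nanometres via ",
         "spacing_a/10) or in lattice units instead of corrupting the ",
         "fixed columns", call. = FALSE)
  }
  occ <- symmetron_index(model$symmetron_id)
  bfac <- ifelse(is.na(model$angle_deg), 0, model$angle_deg)
  n <- nrow(model)
  chunks <- split(seq_len(n), (seq_len(n) - 1) %/% 99999)
  if (length(chunks) == 1) {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
      type = rep("HETATM", n), resno = rep(1L, n) + (seq_len(n) - 1L) %% 9999L,
      resid = rep("CAP", n), elety = rep("C", n),
      chain = ifelse(model$kind == "penton", "P", "H"),
      o = occ, b = bfac
    )
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (mi in seq_along(chunks)) {
      idx <- chunks[[mi]]
      tf <- tempfile(fileext = ".pdb")
      bio3d::write.pdb(
        file = tf,
        xyz = as.numeric(t(as.matrix(model[idx, c("x", "y", "z")]))),
        type = rep("HETATM", length(idx)),
        resno = rep(1L, length(idx)) + (seq_along(idx) - 1L) %% 9999L,
        resid = rep("CAP", length(idx)), elety = rep("C", length(idx)),
        chain = ifelse(model$kind[idx] == "penton", "P", "H"),
        o = occ[idx], b = bfac[idx]
      )
      writeLines(sprintf("MODEL %8d", mi), con)
      writeLines(grep("^(HETATM|ATOM)", readLines(tf), value = TRUE), con)
      writeLines("ENDMDL", con)
      unlink(tf)
    }
    writeLines("END", con)
  }
  invisible(path)
}

export_model_obj <- function(model, path, obj_mode, glyph_radius) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# capsidr capsomer model", con)
  if (obj_mode == "points") {
    grp <- ifelse(is.na(model$symmetron_id), model$kind, model$symmetron_id)
    for (g in unique(grp)) {
      writeLines(paste0("g ", g), con)
      sel <- which(grp == g)
      writeLines(sprintf("v %.9g %.9g %.9g",
                         model$x[sel], model$y[sel], model$z[sel]), con)
      writeLines(paste("p", paste(seq_along(sel), collapse = " ")), con)
    }
  } else {
    r <- if (is.null(glyph_radius)) 0.4 * attr(model, "spacing_a") else glyph_radius
    ico <- icosahedron_frame()
    voff <- 0L
    grp <- ifelse(is.na(model$symmetron_id), model$kind, model$symmetron_id)
    for (i in seq_len(nrow(model))) {
      writeLines(paste0("g ", grp[i], "_", model$id[i]), con)
      vv <- ico$vertices * r
      writeLines(sprintf("v %.9g %.9g %.9g",
                         vv[, 1] + model$x[i], vv[, 2] + model$y[i],
                         vv[, 3] + model$z[i]), con)
      writeLines(sprintf("f %d %d %d",
                         ico$faces[, 1] + voff, ico$faces[, 2] + voff,
                         ico$faces[, 3] + voff), con)
      voff <- voff + 12L
    }
  }
  invisible(path)
}

#' Export a decomposition as CSV plus a JSON summary
#'
#' The CSV lists one row per capsomer (`id`, `symmetron_id`, `kind`,
#' `orientation_label`, `is_unique`); the JSON sidecar records the class
#' parameters and symmetron census (T, p, n, sizes, counts, handedness).
#'
#' @param dec A `capsid_decomposition` (orientations optional).
#' @param csv_path CSV output path.
#' @param json_path Optional JSON output path.
#' @return `csv_path`, invisibly.
#' @export
export_decomposition <- function(dec, csv_path, json_path = NULL) {
  stopifnot(inherits(dec, "capsid_decomposition"))
  s <- dec$sites
  out <- tibble::tibble(
    id = s$id, symmetron_id = s$symmetron_id, kind = s$kind,
    orientation_label = if ("orientation_label" %in% names(s))
      s$orientation_label else NA_character_,
    is_unique = if ("is_unique" %in% names(s)) s$is_unique else NA
  )
  readr::write_csv(out, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(decomposition_summary(dec), json_path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Decomposition summary
#' @param dec A `capsid_decomposition`.
#' @return A list with the capsid class parameters and symmetron census.
#' @export
decomposition_summary <- function(dec) {
  stopifnot(inherits(dec, "capsid_decomposition"))
  hk <- attr(dec$lattice, "hk")
  list(
    h = unname(hk[1]), k = unname(hk[2]),
    handedness = attr(dec$lattice, "handedness"),
    t = attr(dec$lattice, "t"),
    p = dec$p, n = dec$n,
    pentasymmetron_size = pentasymmetron_size(dec$p),
    trisymmetron_size = as.integer(dec$n * (dec$n + 1) / 2),
    capsomers = nrow(dec$sites),
    pentons = sum(dec$sites$kind == "penton"),
    hexavalent = sum(dec$sites$kind == "hex"),
    unique_positions = if (isTRUE(dec$orientations))
      sum(dec$sites$is_unique, na.rm = TRUE) else NA
  )
}
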
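test_that("the reference icosahedron is regular and outward-oriented", {
  f <- icosahedron_frame()
  expect_identical(nrow(f$vertices), 12L)
  expect_identical(nrow(f$faces), 20L)
  expect_equal(sqrt(rowSums(f$vertices^2)), rep(1, 12))
  d <- as.matrix(dist(f$vertices))
  edge <- min(d[d > 0])
  expect_equal(1 / edge, f$circumradius_factor, tolerance = 1e-12)
  # all faces outward CCW
  for (r in 1:20) {
    tri <- f$faces[r, ]
    n <- capsidr:::crossprod3(f$vertices[tri[2], ] - f$vertices[tri[1], ],
                              f$vertices[tri[3], ] - f$vertices[tri[1], ])
    expect_gt(sum(n * colMeans(f$vertices[tri, ])), 0)
  }
})

test_that("penton chords equal spacing * sqrt(T) after folding", {
  m <- fold_to_3d(fixture_lattice(7, 18))
  p <- m[m$kind == "penton", c("x", "y", "z")]
  d <- as.matrix(dist(p))
  nn <- apply(d + diag(Inf, 12), 1, min)
  expect_equal(unname(nn), rep(sqrt(499), 12), tolerance = 1e-9)
  # (1, 0): a bare icosahedron of 12 pentons
  m1 <- fold_to_3d(enumerate_capsomers(1, 0), spacing_a = 10)
  expect_identical(nrow(m1), 12L)
  d1 <- as.matrix(dist(m1[, c("x", "y", "z")]))
  expect_equal(min(d1[d1 > 0]), 10, tolerance = 1e-9)
})

test_that("orientation vectors across a trisymmetron boundary differ by 60 degrees in the face plane", {
  ang <- trisymmetron_boundary_angle(fixture_dec(7, 18))
  expect_equal(ang$angle_deg, 60, tolerance = 1e-9)
})

test_that("spacing calibration and diameter prediction are exact inverses", {
  a <- calibrate_spacing(169, 1800)
  expect_equal(a, 1800 / (2 * 0.9510565 * 13), tolerance = 1e-6)
  expect_equal(a, 72.8, tolerance = 0.01)
  expect_equal(calibrate_spacing(499, 3000), 70.6, tolerance = 0.05)
  expect_equal(predict_diameter(169, a), 1800, tolerance = 1e-9)
  expect_equal(predict_diameter(499, calibrate_spacing(499, 3000)), 3000,
               tolerance = 1e-9)
  # monotone in both arguments
  expect_true(all(diff(predict_diameter(c(25, 49, 147, 499), 70)) > 0))
  expect_true(all(diff(predict_diameter(169, c(60, 70, 80))) > 0))
  expect_error(calibrate_spacing(169, -5))
})

test_that("cross-calibrated diameters reproduce the giant-virus scale ratio", {
  a <- calibrate_spacing(169, 1800)
  d_pred <- predict_diameter(499, a)
  expect_lt(abs(d_pred - 3000) / 3000, 0.05)
  expect_equal(d_pred / 1800, sqrt(499 / 169), tolerance = 1e-9)
})

test_that("distances and angles are invariant under rigid rotation", {
  m <- fold_to_3d(fixture_dec(3, 5))
  xyz <- as.matrix(m[, c("x", "y", "z")])
  ov <- as.matrix(m[, c("ox", "oy", "oz")])
  th <- 0.7; ph <- 1.1
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  rot <- rz %*% rx
  xyz2 <- xyz %*% t(rot)
  ov2 <- ov %*% t(rot)
  i <- c(1, 50, 200); j <- c(400, 90, 17)
  expect_equal(sqrt(rowSums((xyz[i, ] - xyz[j, ])^2)),
               sqrt(rowSums((xyz2[i, ] - xyz2[j, ])^2)), tolerance = 1e-9)
  hex <- which(m$kind == "hex")[1:50]
  dots <- rowSums(ov[hex, ] * ov[hex + 1, ])
  dots2 <- rowSums(ov2[hex, ] * ov2[hex + 1, ])
  expect_equal(dots, dots2, tolerance = 1e-9)
})

test_that("spherical projection places all centres on the circumsphere", {
  m <- fold_to_3d(fixture_lattice(3, 5), spherical = TRUE)
  r <- sqrt(m$x^2 + m$y^2 + m$z^2)
  expect_equal(r, rep(sqrt(t_number(3, 5)) * 0.9510565, nrow(m)),
               tolerance = 1e-6)
})

test_that("model export round-trips CSV bit-exactly and writes PDB/OBJ", {
  m <- fold_to_3d(fixture_dec(7, 18), spacing_a = calibrate_spacing(499, 3000))
  td <- withr::local_tempdir()
  csv <- file.path(td, "m.csv")
  export_model(m, csv, "csv")
  m2 <- read_model_csv(csv)
  expect_identical(m$x, m2$x)
  expect_identical(m$y, m2$y)
  expect_identical(m$z, m2$z)

  # Angstrom-scale coordinates overflow the PDB fixed columns; the export
  # must refuse rather than corrupt them
  expect_error(export_model(m, file.path(td, "bad.pdb"), "pdb"),
               "fixed-column")
  m_nm <- fold_to_3d(fixture_dec(7, 18),
                     spacing_a = calibrate_spacing(499, 3000) / 10)
  pdb_path <- file.path(td, "m.pdb")
  export_model(m_nm, pdb_path, "pdb")
  pdb <- bio3d::read.pdb(pdb_path)
  expect_identical(nrow(pdb$atom), 4992L)              # one pseudo-atom per capsomer
  expect_true(all(range(pdb$atom$o) == c(1, 32)))      # symmetron index
  expect_true(all(pdb$atom$b %in% c(0, 60)))           # orientation class
  expect_true(max(abs(pdb$atom$x - m_nm$x)) < 1e-3)    # fixed columns intact

  obj <- file.path(td, "m.obj")
  export_model(m, obj, "obj")
  expect_identical(sum(startsWith(readLines(obj), "v ")), 4992L)
  obj2 <- file.path(td, "g.obj")
  export_model(fold_to_3d(fixture_lattice(1, 1)), obj2, "obj",
               obj_mode = "spheres")
  lines <- readLines(obj2)
  expect_identical(sum(startsWith(lines, "v ")), 32L * 12L)
  expect_identical(sum(startsWith(lines, "f ")), 32L * 20L)
  expect_error(export_model(m, file.path(td, "x.xyz"), "xyz"))
})

test_that("decomposition export writes the census CSV and JSON summary", {
  dec <- fixture_dec(3, 5)
  td <- withr::local_tempdir()
  csvp <- file.path(td, "dec.csv"); jsonp <- file.path(td, "dec.json")
  export_decomposition(dec, csvp, jsonp)
  got <- utils::read.csv(csvp)
  expect_identical(nrow(got), nrow(dec$sites))
  expect_true(all(c("id", "symmetron_id", "kind", "orientation_label",
                    "is_unique") %in% names(got)))
  js <- jsonlite::read_json(jsonp)
  expect_identical(js$t, 49L)
  expect_identical(js$p, 1L)
  expect_identical(js$n, 6L)
  expect_identical(js$unique_positions, 60L)
})
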
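test_that("the synthetic generator is exact, seeded and dropout-binomial", {
  cs <- synth_centers(7, 18)
  lat_face <- capsidr:::face_candidate_sites(
    7, 18, capsidr:::build_fold_geometry(7, 18))
  expect_identical(nrow(cs), sum(lat_face$inside))
  expect_identical(sum(cs$is_penton), 3L)              # three face corners
  # zero-noise positions are exact lattice points of the face chart
  inside <- lat_face[lat_face$inside, ]
  expect_equal(sort(cs$x), sort(inside$x), tolerance = 1e-12)
  # seeded reproducibility
  a <- synth_centers(7, 8, jitter_sigma = 0.1, dropout_fraction = 0.1,
                     seed = 5)
  b <- synth_centers(7, 8, jitter_sigma = 0.1, dropout_fraction = 0.1,
                     seed = 5)
  expect_identical(a, b)
  # dropout thins non-penton points at the nominal rate
  set.seed(2)
  n_full <- nrow(synth_centers(7, 8))
  kept <- vapply(1:40, function(i) {
    nrow(synth_centers(7, 8, dropout_fraction = 0.2, seed = 1000 + i))
  }, numeric(1))
  expect_true(all(vapply(1:5, function(i) {
    sum(synth_centers(7, 8, dropout_fraction = 0.2,
                      seed = 2000 + i)$is_penton) == 3
  }, logical(1))))
  expect_equal(mean(kept) / n_full, 0.8, tolerance = 0.02)
})

test_that("noiseless fits recover (h, k), T and full confidence", {
  f <- fit_hk(synth_centers(7, 18))
  expect_identical(c(f$h, f$k), c(7L, 18L))
  expect_identical(f$t, 499L)
  expect_identical(f$handedness, "right")
  expect_equal(f$confidence, 1)
  expect_lt(f$residual_rms, 1e-9)
  # degenerate minimal lattice: canonicalised with h <= k
  f1 <- fit_hk(synth_centers(1, 0))
  expect_identical(f1$t, 1L)
  expect_identical(c(f1$h, f1$k), c(0L, 1L))
})

test_that("round-trip is exact at sigma = 0 for many random classes", {
  set.seed(7)
  done <- 0
  while (done < 50) {
    h <- sample(0:20, 1); k <- sample(0:30, 1)
    if (h + k == 0 || t_number(max(h, 1), k) > 2000) next
    if (h == 0) h <- 1
    f <- fit_hk(synth_centers(h, k))
    expect_identical(c(f$h, f$k), c(min(h, k), max(h, k)))
    expect_identical(f$t, t_number(h, k))
    done <- done + 1
  }
})

test_that("mirrored input flips handedness but preserves (h, k) and T", {
  cs <- synth_centers(7, 18)
  f <- fit_hk(cs)
  csm <- cs; csm$y <- -csm$y
  fm <- fit_hk(csm)
  expect_identical(fm$handedness, "left")
  expect_identical(c(fm$h, fm$k, fm$t), c(f$h, f$k, f$t))
  fl <- fit_hk(synth_centers(7, 18, handedness = "left"))
  expect_identical(fl$handedness, "left")
  expect_identical(c(fl$h, fl$k), c(7L, 18L))
})

test_that("uniform scaling leaves (h, k) fixed and scales the residuals", {
  cs <- synth_centers(7, 8, jitter_sigma = 0.05, seed = 31)
  f1 <- fit_hk(cs)
  cs2 <- cs; cs2$x <- cs2$x * 72.8; cs2$y <- cs2$y * 72.8
  f2 <- fit_hk(cs2)
  expect_identical(c(f2$h, f2$k), c(f1$h, f1$k))
  expect_equal(f2$residual_rms / f1$residual_rms, 72.8, tolerance = 1e-6)
  expect_equal(f2$spacing / f1$spacing, 72.8, tolerance = 1e-6)
})

test_that("fits survive realistic jitter and dropout in >= 95% of runs", {
  r <- recovery_experiment(7, 18, sigmas = 0.1, dropouts = 0.05,
                           n_seeds = 100, base_seed = 8675309)
  expect_gte(r$recovery_rate, 0.95)
})

test_that("recovery experiment table is seeded and well-formed", {
  td <- withr::local_tempdir()
  csvp <- file.path(td, "rec.csv")
  r <- recovery_experiment(3, 5, sigmas = c(0, 0.05), dropouts = c(0, 0.1),
                           n_seeds = 8, csv_path = csvp)
  expect_identical(nrow(r), 4L)                        # grid size
  expect_true(all(r$recovery_rate[r$sigma == 0] == 1))
  r2 <- recovery_experiment(3, 5, sigmas = c(0, 0.05), dropouts = c(0, 0.1),
                            n_seeds = 8)
  expect_identical(r, r2)
  expect_identical(nrow(utils::read.csv(csvp)), 4L)
})

test_that("hopeless noise raises an explicit failure, not a guess", {
  cs <- synth_centers(3, 5, jitter_sigma = 0.45, seed = 1)
  expect_error(fit_hk(cs), "ambiguous")
})

test_that("3D capsid clouds are fitted through gnomonic flattening", {
  for (hk in list(c(7, 8), c(7, 18), c(7, 7))) {
    f <- fit_hk(synth_centers(hk[1], hk[2], mode = "capsid3d"))
    expect_identical(c(f$h, f$k), as.integer(hk))
    expect_true(f$flattened)
  }
  fl <- fit_hk(synth_centers(7, 18, mode = "capsid3d", handedness = "left"))
  expect_identical(fl$handedness, "left")
})

test_that("centre tables round-trip through CSV", {
  cs <- synth_centers(3, 5, jitter_sigma = 0.02, seed = 3)
  td <- withr::local_tempdir()
  p <- file.path(td, "centers.csv")
  write_centers_csv(cs, p)
  back <- read_centers_csv(p)
  expect_identical(back$x, cs$x)
  expect_identical(back$is_penton, cs$is_penton)
  f <- fit_hk(back)
  expect_identical(c(f$h, f$k), c(3L, 5L))
})

test_that("fit objects tidy and glance", {
  f <- fit_hk(synth_centers(2, 1))
  td <- tidy(f)
  expect_identical(td$term, c("h", "k", "t", "spacing"))
  g <- glance(f)
  expect_identical(g$t, 7L)
  expect_identical(nrow(g), 1L)
})
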
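test_that("adjacent trisymmetrons are rotated by exactly 60 degrees", {
  for (hk in list(c(3, 5), c(7, 8), c(7, 18))) {
    ang <- trisymmetron_boundary_angle(fixture_dec(hk[1], hk[2]))
    expect_equal(ang$angle_deg, 60, tolerance = 1e-9)
    expect_lt(ang$max_dev_deg, 1e-9)
  }
})

test_that("every trisymmetron's capsomers share one orientation class", {
  dec <- fixture_dec(7, 18)
  s <- dec$sites[dec$sites$symmetron_kind == "tri", ]
  expect_true(all(s$orientation_label == s$symmetron_id))
  # within one face, a trisymmetron's members all carry the same in-face
  # angle (0 or 60)
  by_ft <- split(s$angle_deg, paste(s$phys_face, s$symmetron_id))
  expect_true(all(vapply(by_ft, function(a) length(unique(a)) == 1,
                         logical(1))))
  expect_setequal(unique(s$angle_deg), c(0, 60))
})

test_that("sectors hold 6 hexavalent capsomers, exactly 1 uniquely oriented", {
  dec <- fixture_dec(7, 18)
  s <- dec$sites
  sec <- s$sector[!is.na(s$sector)]
  expect_identical(length(unique(sec)), 60L)           # 12 vertices x 5
  expect_true(all(table(sec) == 6))
  uniq_by_sec <- tapply(s$is_unique[!is.na(s$sector)], sec, sum)
  expect_true(all(uniq_by_sec == 1))
})

test_that("there are 60 unique capsomers, 5 per pentasymmetron, each matching an adjacent trisymmetron", {
  for (hand in c("right", "left")) {
    dec <- fixture_dec(7, 18, hand)
    s <- dec$sites
    uq <- which(!is.na(s$is_unique) & s$is_unique)
    expect_identical(length(uq), 60L)
    expect_true(all(table(s$home_vertex[uq]) == 5))
    # the recomputation from orientation minorities finds the same set
    expect_setequal(unique_positions(dec)$id, s$id[uq])
    # each unique capsomer is edge-adjacent to the trisymmetron it is
    # oriented with
    nb <- lattice_neighbors(dec$lattice)
    adj <- split(c(nb$to, nb$from), c(nb$from, nb$to))
    for (r in uq) {
      lab <- s$orientation_label[r]
      expect_true(any(s$symmetron_id[match(adj[[s$id[r]]], s$id)] == lab))
    }
  }
})

test_that("orientation flood fill recovers the symmetron structure", {
  dec <- fixture_dec(7, 8)
  reg <- detect_orientation_regions(dec)
  s <- dec$sites
  # 12 penton singletons + 20 trisymmetron-anchored regions
  expect_identical(length(unique(reg$region)), 32L)
  merged <- split(s$id, reg$region)
  sizes <- sort(vapply(merged, length, integer(1)))
  # each trisymmetron region = n(n+1)/2 members + 3 tips x 6 oriented
  # pentasymmetron capsomers; the remaining 12 regions are lone pentons
  expect_identical(unname(sizes[1:12]), rep(1L, 12))
  expect_true(all(unname(sizes[13:32]) == dec$n * (dec$n + 1) / 2 + 18))
  # removing the pentasymmetron members from each region leaves exactly the
  # trisymmetron partition
  tri_regions <- merged[vapply(merged, length, integer(1)) > 1]
  tri_sets <- split(s$id[s$symmetron_kind == "tri"],
                    s$symmetron_id[s$symmetron_kind == "tri"])
  stripped <- lapply(tri_regions, function(ids) {
    ids[s$symmetron_kind[match(ids, s$id)] == "tri"]
  })
  key <- function(sets) sort(vapply(sets, function(x)
    paste(sort(x), collapse = ","), character(1)))
  expect_identical(unname(key(stripped)), unname(key(tri_sets)))
})

test_that("spiral pattern groups five golf clubs plus the penton", {
  for (hk in list(c(7, 18), c(7, 8))) {
    dec <- fixture_dec(hk[1], hk[2])
    for (v in c(0, 7)) {
      sp <- spiral_pattern(dec, vertex = v)
      expect_identical(sum(sp$role == "penton"), 1L)
      groups <- split(sp, sp$group)
      tri_groups <- groups[names(groups) != "penton"]
      expect_identical(length(tri_groups), 5L)
      for (g in tri_groups) {
        expect_identical(sum(g$is_unique), 1L)         # one seed per club
        expect_identical(sum(g$role == "tip"), 1L)
        expect_identical(nrow(g), 7L)                  # 6 capsomers + tip
      }
    }
    # grouping is invariant under the local 5-fold rotation: group sizes and
    # composition by role are identical at every vertex
    comp <- lapply(0:11, function(v) {
      sp <- spiral_pattern(dec, v)
      sort(table(sp$group[sp$role == "pentasymmetron"]))
    })
    expect_true(all(vapply(comp, function(x) all(x == comp[[1]]),
                           logical(1))))
  }
})
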
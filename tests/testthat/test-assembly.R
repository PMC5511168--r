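test_that("nucleation places the penton with a five-site frontier", {
  dec <- fixture_dec(7, 18)
  st <- assembly_nucleate(dec, vertex = 0)
  expect_identical(length(st$placed), 1L)
  expect_identical(st$events$rule, "nucleate_penton")
  expect_identical(length(st$frontier), 5L)
  expect_error(assembly_nucleate(dec, vertex = 99), "penton")
})

test_that("the growth stages reproduce the pentasymmetron census", {
  dec <- fixture_dec(7, 18)
  st <- assembly_nucleate(dec, 0) |> assembly_grow_layers()
  expect_identical(length(st$placed), 16L)             # 1 + 5 + 10
  st <- assembly_spiral_step(st)
  expect_identical(length(st$placed), 31L)             # full pentasymmetron
  jumps <- st$events$capsomer_id[st$events$rule == "spiral_jump"]
  expect_identical(length(jumps), 5L)
  s <- dec$sites
  expect_true(all(s$is_unique[match(jumps, s$id)]))
  # the five inner triangles: layers 1-2 of each sector share one
  # orientation label
  inner <- s[!is.na(s$home_vertex) & s$home_vertex == 0 &
               !is.na(s$layer) & s$layer %in% 1:2, ]
  expect_true(all(tapply(inner$orientation_label, inner$sector,
                         function(x) length(unique(x))) == 1))
  expect_true(all(table(inner$sector) == 3))
  # layer ordering: every layer-1 event precedes every layer-2 event
  ev <- st$events
  ranks <- split(ev$rank, s$layer[match(ev$capsomer_id, s$id)])
  expect_lt(max(ranks[["1"]]), min(ranks[["2"]]))
  expect_lt(max(ranks[["2"]]), min(ranks[["3"]]))
})

test_that("local mode terminates at the pentasymmetron plus five trisymmetrons", {
  cases <- list(c(7, 18, 1186), c(7, 8, 361))
  for (cs in cases) {
    traj <- simulate_assembly(fixture_dec(cs[1], cs[2]))
    expect_identical(nrow(traj), as.integer(cs[3]))
    expect_identical(attr(traj, "mode"), "local")
  }
  # termination count formula on further classes
  for (hk in list(c(3, 5), c(1, 4), c(7, 7))) {
    dec <- fixture_dec(hk[1], hk[2])
    traj <- simulate_assembly(dec)
    expect_identical(nrow(traj),
                     as.integer(pentasymmetron_size(dec$p) +
                                  5 * dec$n * (dec$n + 1) / 2))
  }
})

test_that("assembly realises the static orientation field", {
  for (k in c(7, 8, 10, 18)) {
    dec <- fixture_dec(7, k)
    traj <- simulate_assembly(dec)
    s <- dec$sites
    rows <- match(traj$capsomer_id, s$id)
    expect_identical(traj$orientation_label, s$orientation_label[rows])
    v <- validate_trajectory(traj, dec)
    expect_true(attr(v, "ok"))
  }
})

test_that("extended mode places every capsomer and stays connected", {
  dec <- fixture_dec(7, 8)
  traj <- simulate_assembly(dec, mode = "extended")
  expect_identical(sort(traj$capsomer_id), dec$sites$id)
  expect_true(attr(validate_trajectory(traj, dec), "ok"))
  expect_match(
    paste(utils::capture.output(print(traj)), collapse = " "),
    "extrapolates")
})

test_that("seeded shuffling changes order but not the final structure", {
  dec <- fixture_dec(7, 8)
  t1 <- simulate_assembly(dec, shuffle_seed = 11)
  t2 <- simulate_assembly(dec, shuffle_seed = 11)
  t3 <- simulate_assembly(dec, shuffle_seed = 12)
  expect_identical(t1$capsomer_id, t2$capsomer_id)
  expect_false(identical(t1$capsomer_id, t3$capsomer_id))
  expect_setequal(t1$capsomer_id, t3$capsomer_id)
  expect_true(attr(validate_trajectory(t1, dec), "ok"))
})

test_that("nucleating at any vertex yields the same final state", {
  dec <- fixture_dec(7, 8)
  t0 <- simulate_assembly(dec, vertex = 0, mode = "extended")
  t5 <- simulate_assembly(dec, vertex = 5, mode = "extended")
  expect_setequal(t0$capsomer_id, t5$capsomer_id)
  s <- dec$sites
  expect_identical(s$orientation_label[match(sort(t0$capsomer_id), s$id)],
                   s$orientation_label[match(sort(t5$capsomer_id), s$id)])
})

test_that("mirrored lattices spiral in the opposite sense", {
  decr <- fixture_dec(7, 18)
  decl <- fixture_dec(7, 18, "left")
  expect_identical(capsidr:::spiral_sense(decr), 1)
  expect_identical(capsidr:::spiral_sense(decl), -1)
  tl <- simulate_assembly(decl)
  expect_true(attr(validate_trajectory(tl, decl), "ok"))
  expect_identical(nrow(tl), 1186L)
})

test_that("a tampered trajectory fails validation at the earlier rank", {
  dec <- fixture_dec(3, 5)
  traj <- simulate_assembly(dec)
  # swap the first layer placement with a late trisymmetron placement so the
  # early event is disconnected from the nucleus
  bad <- traj
  i <- 2L
  j <- nrow(traj)
  tmp <- bad$capsomer_id[i]
  bad$capsomer_id[i] <- bad$capsomer_id[j]
  bad$capsomer_id[j] <- tmp
  v <- validate_trajectory(bad, dec)
  expect_false(attr(v, "ok"))
  con <- v[v$check == "connected_growth", ]
  expect_false(con$ok)
  expect_match(con$detail, "rank 1")
})
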
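#' Nucleate an assembly at a five-fold vertex
#'
#' Starts the spiral assembly pathway: the pentameric capsomer at the chosen
#' vertex is placed first and the growth frontier is its five lattice
#' neighbours.
#'
#' @param dec A `capsid_decomposition` with orientations assigned (see
#'   [assign_orientations()]); the static decomposition supplies the target
#'   orientation field the growth process realises.
#' @param vertex Vertex id (0-11) of the nucleating penton.
#' @return An `assembly_state`: a list with the decomposition, the ordered
#'   event log so far, the set of placed capsomer ids and the current
#'   frontier.
#' @examples
#' st <- enumerate_capsomers(3, 5) |> decompose_capsid() |>
#'   assign_orientations() |> assembly_nucleate(vertex = 0)
#' length(st$frontier)  # 5
#' @export
assembly_nucleate <- function(dec, vertex = 0) {
  stopifnot(inherits(dec, "capsid_decomposition"), isTRUE(dec$orientations))
  s <- dec$sites
  pid <- s$id[s$kind == "penton" & s$vertex == vertex]
  if (length(pid) != 1) {
    stop("vertex ", vertex, " is not a penton site (valid ids: 0-11)",
         call. = FALSE)
  }
  adj <- adjacency_list(dec$lattice)
  structure(
    list(
      dec = dec, vertex = vertex, adj = adj,
      events = tibble::tibble(rank = 0L, capsomer_id = pid,
                              rule = "nucleate_penton"),
      placed = pid,
      frontier = sort(adj[[pid]]),
      stage = "nucleated"
    ),
    class = "assembly_state"
  )
}

adjacency_list <- function(lattice) {
  em <- attr(lattice, "edges")
  n <- nrow(lattice)
  adj <- vector("list", n)
  sp <- split(c(em[, 2], em[, 1]), c(em[, 1], em[, 2]))
  adj[as.integer(names(sp))] <- sp
  adj
}

# deterministic (or seeded-shuffle) ordering of a batch of sites by their
# development angle around the nucleation vertex
order_batch <- function(state, ids, rng = NULL) {
  if (length(ids) <= 1) return(ids)
  dec <- state$dec
  s <- dec$sites
  geom <- attr(dec$lattice, "geom")
  spacing <- attr(dec$lattice, "spacing_a")
  if (!is.null(rng)) return(sample(ids))
  rows <- match(ids, s$id)
  on_vertex <- s$home_vertex[rows] == state$vertex & !is.na(s$home_vertex[rows])
  if (all(on_vertex)) {
    dev <- vertex_development_angle(geom, s, state$vertex, spacing)
    ids[order(dev(rows), ids)]
  } else {
    sort(ids)
  }
}

place_events <- function(state, ids, rule) {
  if (!length(ids)) return(state)
  r0 <- max(state$events$rank)
  state$events <- dplyr::bind_rows(
    state$events,
    tibble::tibble(rank = r0 + seq_along(ids), capsomer_id = ids, rule = rule)
  )
  state$placed <- c(state$placed, ids)
  state
}

#' Grow the inner pentasymmetron layers
#'
#' Adds concentric layers 1 to `p - 1` around the nucleating penton (5, 10,
#' ... sites), sweeping each layer in the handedness' spiral sense. For the
#' conserved `p = 3` pentasymmetron this places the 15 capsomers that form
#' five triangles of three identically oriented capsomers each.
#'
#' @param state An `assembly_state` from [assembly_nucleate()].
#' @param shuffle Optional random generator activation: if `TRUE`, the order
#'   within each layer is shuffled (the final structure is unaffected).
#' @return The updated `assembly_state`.
#' @export
assembly_grow_layers <- function(state, shuffle = FALSE) {
  stopifnot(inherits(state, "assembly_state"), state$stage == "nucleated")
  dec <- state$dec
  s <- dec$sites
  p <- dec$p
  if (p >= 2) {
    for (l in 1:(p - 1)) {
      ids <- s$id[!is.na(s$home_vertex) & s$home_vertex == state$vertex &
                    !is.na(s$layer) & s$layer == l]
      ids <- order_batch(state, ids, rng = if (shuffle) TRUE else NULL)
      state <- place_events(state, ids, "layer_growth")
    }
  }
  state$stage <- "layers_grown"
  state
}

#' Place the outer pentasymmetron layer with its spiral jumps
#'
#' Completes the pentasymmetron by placing layer `p`. In each five-fold
#' sector exactly one site — the one abutting the seed-side sector boundary —
#' takes the 60-degree-rotated orientation of the adjacent trisymmetron
#' (rule `spiral_jump`); the remaining sites keep the sector orientation
#' (rule `layer_growth`). After this stage the pentasymmetron is complete:
#' `1 + 5*p*(p+1)/2` capsomers placed.
#'
#' @inheritParams assembly_grow_layers
#' @return The updated `assembly_state`.
#' @export
assembly_spiral_step <- function(state, shuffle = FALSE) {
  stopifnot(inherits(state, "assembly_state"), state$stage == "layers_grown")
  dec <- state$dec
  s <- dec$sites
  p <- dec$p
  if (p >= 1) {
    ids <- s$id[!is.na(s$home_vertex) & s$home_vertex == state$vertex &
                  !is.na(s$layer) & s$layer == p]
    ids <- order_batch(state, ids, rng = if (shuffle) TRUE else NULL)
    rules <- ifelse(s$is_unique[match(ids, s$id)], "spiral_jump",
                    "layer_growth")
    r0 <- max(state$events$rank)
    state$events <- dplyr::bind_rows(
      state$events,
      tibble::tibble(rank = r0 + seq_along(ids), capsomer_id = ids,
                     rule = rules)
    )
    state$placed <- c(state$placed, ids)
  }
  state$stage <- "spiraled"
  state
}

#' Recruit the seeded trisymmetrons
#'
#' Each spiral-seed capsomer recruits its trisymmetron row by row (rows
#' parallel to the pentasymmetron edge, i.e. at increasing in-triangle
#' distance from the seed tip), growing the five trisymmetrons around the
#' nucleation vertex in a round-robin over rows. In `mode = "local"` growth
#' stops when the five trisymmetrons are complete; `mode = "extended"`
#' continues wave by wave until the whole capsid is placed — an extrapolation
#' beyond the locally supported pathway, and flagged as such in the result.
#'
#' @inheritParams assembly_grow_layers
#' @param mode `"local"` (default) or `"extended"`.
#' @return An [`assembly_trajectory`][simulate_assembly] tibble of placement
#'   events.
#' @export
assembly_recruit <- function(state, mode = c("local", "extended"),
                             shuffle = FALSE) {
  stopifnot(inherits(state, "assembly_state"), state$stage == "spiraled")
  mode <- match.arg(mode)
  dec <- state$dec
  s <- dec$sites
  geom <- attr(dec$lattice, "geom")

  if (dec$n >= 1) {
    faces5 <- geom$vertex_faces[[state$vertex + 1]]
    tri_ids <- sprintf("T%02d", faces5)
    # seed tips: for p >= 1 the tri adjacent to each spiral-seed capsomer,
    # keyed by that seed; for p = 0 the five tips adjacent to the penton
    rows_by_tri <- lapply(tri_ids, function(tid) {
      members <- s$id[s$symmetron_id == tid]
      vpos <- geom$v3[state$vertex + 1, ]
      spacing <- attr(dec$lattice, "spacing_a")
      p3 <- as.matrix(s[match(members, s$id), c("X", "Y", "Z")]) / spacing
      tip <- members[which.min(colSums((t(p3) - vpos)^2))]
      # rows: breadth-first depth from the tip within the trisymmetron
      sub <- igraph::induced_subgraph(lattice_graph(dec$lattice), members)
      d <- igraph::distances(sub, v = match(tip, members))
      rr <- split(members, as.integer(d))
      rr[order(as.integer(names(rr)))]
    })
    names(rows_by_tri) <- tri_ids
    n_rows <- max(vapply(rows_by_tri, length, integer(1)))
    for (r in seq_len(n_rows)) {
      for (tid in tri_ids) {
        rr <- rows_by_tri[[tid]]
        if (r > length(rr)) next
        ids <- sort(rr[[r]])
        if (shuffle && length(ids) > 1) ids <- sample(ids)
        state <- place_events(state, ids, "trisymmetron_recruit")
      }
    }
  }

  if (mode == "extended") {
    # wave-by-wave completion of the rest of the capsid (graph BFS from the
    # placed patch); each wave keeps the patch edge-connected
    g <- lattice_graph(dec$lattice)
    d <- igraph::distances(g, v = state$placed)
    dmin <- apply(d, 2, min)
    remaining <- setdiff(s$id, state$placed)
    waves <- split(remaining, dmin[remaining])
    waves <- waves[order(as.numeric(names(waves)))]
    rule_of <- function(ids) {
      rows <- match(ids, s$id)
      dplyr::case_when(
        s$kind[rows] == "penton" ~ "nucleate_penton",
        s$symmetron_kind[rows] == "tri" ~ "trisymmetron_recruit",
        s$is_unique[rows] ~ "spiral_jump",
        TRUE ~ "layer_growth"
      )
    }
    for (wv in waves) {
      ids <- sort(wv)
      if (shuffle && length(ids) > 1) ids <- sample(ids)
      r0 <- max(state$events$rank)
      state$events <- dplyr::bind_rows(
        state$events,
        tibble::tibble(rank = r0 + seq_along(ids), capsomer_id = ids,
                       rule = rule_of(ids))
      )
      state$placed <- c(state$placed, ids)
    }
  }

  as_assembly_trajectory(state, mode)
}

as_assembly_trajectory <- function(state, mode) {
  dec <- state$dec
  s <- dec$sites
  rows <- match(state$events$capsomer_id, s$id)
  traj <- state$events |>
    dplyr::mutate(
      face = s$face[rows], u = s$u[rows], v = s$v[rows],
      symmetron_id = s$symmetron_id[rows],
      orientation_label = s$orientation_label[rows],
      X = s$X[rows], Y = s$Y[rows], Z = s$Z[rows]
    )
  structure(
    traj,
    class = c("assembly_trajectory", class(tibble::tibble())),
    hk = attr(dec$lattice, "hk"),
    handedness = attr(dec$lattice, "handedness"),
    p = dec$p, n = dec$n,
    vertex = state$vertex,
    mode = mode
  )
}

#' @export
print.assembly_trajectory <- function(x, ...) {
  hk <- attr(x, "hk")
  cat(sprintf(
    "<assembly_trajectory> (h, k) = (%d, %d) %s-handed, vertex %d, mode %s, %d events%s\n",
    hk[1], hk[2], attr(x, "handedness"), attr(x, "vertex"), attr(x, "mode"),
    nrow(x),
    if (attr(x, "mode") == "extended")
      " [extended mode extrapolates beyond the locally supported pathway]"
    else ""))
  NextMethod()
}

#' Simulate the spiral assembly pathway
#'
#' Runs the full growth process proposed for giant icosahedral capsids:
#' nucleation at a penton, concentric pentasymmetron layers, the spiral jump
#' that seeds the five surrounding trisymmetrons with 60-degree-rotated
#' capsomers, and row-by-row trisymmetron recruitment. The process is
#' deterministic; an optional seeded shuffle randomises the order within each
#' layer/row/wave without changing the final structure.
#'
#' @param dec A `capsid_decomposition` with orientations assigned (a bare
#'   `capsid_lattice` is accepted and decomposed with defaults).
#' @param vertex Nucleation vertex id (0-11).
#' @param mode `"local"` stops when the pentasymmetron and its five seeded
#'   trisymmetrons are complete (`1 + 5p(p+1)/2 + 5n(n+1)/2` events);
#'   `"extended"` continues to the whole capsid.
#' @param shuffle_seed Optional integer; if given, within-batch placement
#'   order is shuffled reproducibly.
#' @return An `assembly_trajectory` tibble: `rank`, `capsomer_id`, `rule`
#'   (`nucleate_penton`, `layer_growth`, `spiral_jump`,
#'   `trisymmetron_recruit`), `face`, `u`, `v`, `symmetron_id`,
#'   `orientation_label`.
#' @examples
#' traj <- enumerate_capsomers(3, 5) |> simulate_assembly()
#' nrow(traj)  # 6 + 5 * 21 = 111
#' @export
simulate_assembly <- function(dec, vertex = 0, mode = c("local", "extended"),
                              shuffle_seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(dec, "capsid_lattice")) {
    dec <- assign_orientations(decompose_capsid(dec))
  }
  stopifnot(inherits(dec, "capsid_decomposition"))
  if (!isTRUE(dec$orientations)) dec <- assign_orientations(dec)
  shuffle <- !is.null(shuffle_seed)
  if (shuffle) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(shuffle_seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  assembly_nucleate(dec, vertex) |>
    assembly_grow_layers(shuffle = shuffle) |>
    assembly_spiral_step(shuffle = shuffle) |>
    assembly_recruit(mode = mode, shuffle = shuffle)
}

#' Validate an assembly trajectory against the static decomposition
#'
#' Checks that the event log is well formed (consecutive ranks from 0,
#' nucleation first, no capsomer placed twice), that the placed patch stays
#' edge-connected at every step, that final orientations agree with the
#' static orientation field, and that the spiral sense matches the lattice
#' handedness (a mirrored lattice flips it).
#'
#' @param traj An `assembly_trajectory`.
#' @param dec The `capsid_decomposition` the trajectory was built from.
#' @return A tibble with columns `check`, `ok`, `detail` (failing checks name
#'   the earliest offending event rank). Attribute `ok` summarises all rows.
#' @export
validate_trajectory <- function(traj, dec) {
  stopifnot(inherits(traj, "assembly_trajectory"),
            inherits(dec, "capsid_decomposition"))
  s <- dec$sites
  res <- list()
  add <- function(check, ok, detail = "") {
    res[[length(res) + 1]] <<- tibble::tibble(check = check, ok = ok,
                                              detail = detail)
  }
  add("consecutive_ranks", identical(as.integer(traj$rank),
                                     seq_len(nrow(traj)) - 1L))
  add("nucleates_first", traj$rule[1] == "nucleate_penton")
  dup <- duplicated(traj$capsomer_id)
  add("no_double_placement", !any(dup),
      if (any(dup)) paste("first duplicate at rank", traj$rank[which(dup)[1]])
      else "")
  adj <- adjacency_list(dec$lattice)
  placed <- logical(max(s$id))
  placed[traj$capsomer_id[1]] <- TRUE
  bad_rank <- NA_integer_
  for (i in seq_len(nrow(traj))[-1]) {
    id <- traj$capsomer_id[i]
    if (!any(placed[adj[[id]]])) { bad_rank <- traj$rank[i]; break }
    placed[id] <- TRUE
  }
  add("connected_growth", is.na(bad_rank),
      if (!is.na(bad_rank)) paste("disconnected placement at rank", bad_rank)
      else "")
  rows <- match(traj$capsomer_id, s$id)
  ori_ok <- identical(traj$orientation_label, s$orientation_label[rows])
  add("orientation_agreement", ori_ok)
  sense <- spiral_sense(dec)
  expected <- if (attr(traj, "handedness") == "right") 1 else -1
  add("handedness_consistency", sense == expected,
      paste0("spiral sense ", if (sense > 0) "counter-clockwise" else
             "clockwise", " viewed from outside"))
  out <- dplyr::bind_rows(res)
  attr(out, "ok") <- all(out$ok)
  out
}

#' Export an assembly trajectory
#'
#' `write_trajectory_csv()` writes the event log (rank, capsomer id, face,
#' axial coordinates, orientation label, rule). `export_trajectory_frames()`
#' writes one CSV snapshot of the placed capsomers every `every` events,
#' suitable for rendering an assembly animation.
#'
#' @param traj An `assembly_trajectory`.
#' @param path Output CSV path.
#' @return `path` (or the directory), invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  traj |>
    tibble::as_tibble() |>
    dplyr::select("rank", "capsomer_id", "face", "u", "v",
                  "orientation_label", "rule") |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param dir Output directory for frame files (`frame_000123.csv`).
#' @param every Emit a frame every `every` events.
#' @export
export_trajectory_frames <- function(traj, dir, every = 1) {
  stopifnot(every >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ranks <- seq(0, max(traj$rank), by = every)
  if (utils::tail(ranks, 1) != max(traj$rank)) ranks <- c(ranks, max(traj$rank))
  for (r in ranks) {
    readr::write_csv(
      dplyr::filter(tibble::as_tibble(traj), .data$rank <= r),
      file.path(dir, sprintf("frame_%06d.csv", r)))
  }
  invisible(dir)
}

# +1 if the spiral-seed capsomers sit counter-clockwise of their seeded
# trisymmetron tips around each vertex (right-handed spiral), -1 otherwise
spiral_sense <- function(dec) {
  stopifnot(isTRUE(dec$orientations))
  s <- dec$sites
  geom <- attr(dec$lattice, "geom")
  spacing <- attr(dec$lattice, "spacing_a")
  uq <- which(!is.na(s$is_unique) & s$is_unique &
                !is.na(s$home_vertex) & s$home_vertex == 0)
  if (!length(uq)) return(0)
  vpos <- geom$v3[1, ]
  nrm <- vpos / sqrt(sum(vpos^2))
  p3 <- as.matrix(s[, c("X", "Y", "Z")]) / spacing
  senses <- vapply(uq, function(r) {
    tid <- s$orientation_label[r]
    members <- which(s$symmetron_id == tid)
    tip <- members[which.min(colSums((t(p3[members, , drop = FALSE]) - vpos)^2))]
    a <- p3[tip, ] - vpos
    b <- p3[r, ] - vpos
    sign(sum(crossprod3(a, b) * nrm))
  }, numeric(1))
  if (all(senses > 0)) 1 else if (all(senses < 0)) -1 else 0
}
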
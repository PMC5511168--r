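# Shared fixtures, built once per test run. The CroV-class (7,18) capsid is
# the expensive one (~5,000 sites); cache it and a few smaller classes.
.fixture_env <- new.env(parent = emptyenv())

fixture_lattice <- function(h, k, handedness = "right") {
  key <- paste0("lat_", h, "_", k, "_", handedness)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- enumerate_capsomers(h, k, handedness)
  }
  .fixture_env[[key]]
}

fixture_dec <- function(h, k, handedness = "right") {
  key <- paste0("dec_", h, "_", k, "_", handedness)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- assign_orientations(
      decompose_capsid(fixture_lattice(h, k, handedness)))
  }
  .fixture_env[[key]]
}
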
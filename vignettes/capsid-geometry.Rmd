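---
title: "Capsid lattice geometry, symmetron decomposition and spiral assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsid lattice geometry, symmetron decomposition and spiral assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidr)
```

## The model

Large icosahedral virus capsids are tilings of two building blocks: twelve
pentameric capsomers (pentons), one on each five-fold vertex, and
pseudo-hexagonal trimers of the double jelly-roll major capsid protein
everywhere else. Caspar–Klug theory indexes such a tiling by two integers
`(h, k)`: walking over the hexagonal capsomer lattice from one five-fold
vertex to a neighbouring one takes `h` steps along one lattice axis and `k`
along the other, and the triangulation number

$$T = h^2 + hk + k^2$$

counts quasi-equivalent positions, with `10(T - 1)` hexavalent capsomers plus
12 pentons per particle. `capsidr` realises this construction concretely:
every capsomer of a class gets integer axial coordinates `(u, v)` on one of
the twenty faces, a deterministic id, planar face coordinates and folded 3D
coordinates.

```{r}
lat <- enumerate_capsomers(7, 18)   # the largest class resolved to date
glance(lat)
```

Because pseudo-hexagonal capsomers have a true three-fold symmetry, their
in-plane setting is only defined modulo 120 degrees, giving two orientation
classes (0 and 60 degrees) in any face frame. The capsid surface decomposes
into 12 **pentasymmetrons** (five-fold blocks of `1 + 5p(p+1)/2` capsomers:
a penton plus `p` concentric layers) and 20 **trisymmetrons** (three-fold
triangular blocks of `n(n+1)/2` identically oriented capsomers), with
boundaries visible as discontinuity lines of the orientation field. The
capsomer budget forces `n(n+1) = T - 1 - 3p(p+1)`, which for `h = 2p + 1`
always has the integer solution `n = k + p`.

```{r}
dec <- assign_orientations(decompose_capsid(lat))
dec
```

## The trisymmetron construction

The pentasymmetron is simply the graph ball of radius `p` around a penton.
The trisymmetron is less obvious, because on skewed lattices it overhangs
its face's edges. We derived a closed form: in the planar frame of a face
with penton corner at the origin and the neighbouring penton at
`h e1 + k e2`, the face's trisymmetron is the triangular array

$$\{(p, 1) + i\,(0,1) + j\,(-1,1) \;:\; i, j \ge 0,\; i + j \le n - 1\},$$

whose three-fold centre coincides with the face centroid (the requirement
that pins down both the corner `(p, 1)` — the "tip", one lattice step
outside the pentasymmetron — and the side directions; for the mirrored
construction the reflected form has tip `(-p, p+1)` with sides `e1`, `e2`).
Sites outside the face are transported across the fold by exact planar
unfolding maps. The construction is verified, not assumed: the test suite
checks that the 12 balls and 20 triangles partition every lattice with odd
`h` that we build, including `h = k` classes (T = 147) whose capsomers sit
exactly on three-fold axes. In those cases the triangles still turned out to
partition the sites exactly, so the documented lowest-id tie-break for
boundary rows exists but never fires.

## Orientations, unique capsomers and the spiral

All capsomers of a trisymmetron share one orientation class;
transporting a class across one face fold flips it (0 ↔ 60), which is why
edge-adjacent trisymmetrons always differ by exactly 60 degrees — the
package measures this on folded 3D orientation vectors rather than asserting
it. Within a pentasymmetron, each of the five 60-degree sectors around the
vertex holds six hexavalent capsomers; five share the sector's class and
exactly one — the *unique* or spiral-seed capsomer, the sector site adjacent
to the neighbouring trisymmetron's tip — carries the trisymmetron's class
instead. That makes `12 × 5 = 60` unique positions per particle, and
colouring capsomers by orientation produces the interlocked
"golf-club" spiral around every vertex:

```{r}
trisymmetron_boundary_angle(dec)
nrow(unique_positions(dec))
head(spiral_pattern(dec, vertex = 0))
```

The assembly simulator replays this pattern as a growth process: nucleation
at a penton, concentric layers `1..p-1`, the outer layer in which one site
per sector takes the rotated orientation (`spiral_jump`), and row-by-row
recruitment of the five seeded trisymmetrons. Local mode stops there
(`1 + 5p(p+1)/2 + 5n(n+1)/2` events); extended mode continues wave by wave
until the capsid closes, and is labelled an extrapolation because how growth
propagates past the first pentasymmetron is an open question. The central
claim — that the growth process and the static decomposition are two routes
to the same orientation field — is a test, not an axiom:

```{r}
traj <- simulate_assembly(dec)
glance(traj)
validate_trajectory(traj, dec)
```

## Parameters

* `h`, `k` (dimensionless integers) — the capsid class. Defaults are never
  assumed; the giant-virus family of interest is `h = 7` with
  `k = 7, 8, 10, 18`.
* `p` (layers) — pentasymmetron layer count, default `(h - 1)/2`. Only odd
  `h` is accepted: every imaged giant virus shows `p = 3` (31 capsomers),
  and no pentasymmetron geometry for even `h` has been described, so we
  refuse to guess one.
* `spacing_a` (Å or lattice units, default 1) — centre-to-centre capsomer
  distance. All physical scale enters through this one number;
  `calibrate_spacing(T_ref, D_ref)` derives it from a reference particle
  via `D = 2 · 0.9510565 · a · sqrt(T)` with diameter read vertex-to-vertex
  (twice the circumradius — the natural convention for icosahedral
  particles; the source data do not state theirs, and the 5% acceptance
  band covers either reading).
* `handedness` (`"right"`/`"left"`) — which enantiomorph to build; `"left"`
  is realised as the `(k, h)` construction. The seed capsomer abuts the
  clockwise sector boundary (viewed from outside) in the right-handed
  lattice; mirroring flips the spiral sense, which `validate_trajectory()`
  checks.
* `t_max` (default 10 000) — resource guard on enumeration.
* Fit tolerances: neighbour pairs within 1.35 of the estimated spacing feed
  the six-fold angular histogram; a circular resultant below 0.5 aborts as
  ambiguous; a penton farther than `basis_tol = 0.45` lattice steps from its
  fitted site aborts rather than guesses; `snap_tol = 0.25` defines the
  reported point-matching confidence.

## The synthetic centre generator

`synth_centers()` emulates the one measurement the lattice-recovery task
needs: a table of capsomer centres from a well-resolved map. It produces
exact lattice positions (a planar face chart, a penton-to-penton
parallelogram patch, or the whole folded capsid), then applies isotropic
Gaussian jitter of scale `jitter_sigma` and random dropout; designated
pentons are exempt from dropout so the traced path's endpoints always exist.
It does **not** emulate the ways real data are hard: anisotropic and
spatially correlated localisation error, false-positive detections,
partially occupied or locally disordered regions, or missing vertices.
Passing the recovery benchmarks therefore shows the tracing algorithm is
correct and noise-tolerant in the stated regime, not that capsomer centres
can be extracted from micrographs — detection from density maps is outside
the package's scope.

```{r}
fit_hk(synth_centers(7, 18, jitter_sigma = 0.1, dropout_fraction = 0.05,
                     seed = 42))
```

## Numerical choices

* **Exact identities, not coordinate hashing.** Site identity across face
  charts is canonicalised combinatorially (vertex id for pentons; the
  lower-numbered face's integer `(u, v)` for shared edge sites), so equality
  tests never depend on floating-point rounding. Barycentric tolerances of
  `1e-9` (inside tests) and `1e-6` (boundary classification) sit many orders
  of magnitude away from both the accumulated error (~1e-12) and the closest
  genuine separations (~1/T).
* **Folding is per-face isometric**, so penton chords are exactly
  `a·sqrt(T)` and seam consistency across shared edges holds to 1e-9; the
  faceted model is used for all measurements, with spherical projection
  available for rendering only.
* **Recovery fits** estimate the spacing from neighbour-pair distances (the
  nearest-neighbour minimum is biased low under jitter, and an
  over-tight cutoff truncates the distribution, so the cutoff is iterated),
  fold neighbour displacements by multiples of 60 degrees to average an
  unbiased basis vector, snap all points in a penton-anchored frame,
  and polish the affine frame once by least squares; the penton-to-penton
  graph walk is retained as the connectivity contract. 3D clouds are
  gnomonically flattened in a corridor around the penton pair (outside a
  corridor the flattened lattice orientation drifts and jumps across vertex
  cones), with the local frame re-estimated along the walk — an
  approximation that is adequate for path tracing but not for global
  residual statistics, which are flagged accordingly.
* **Ordering** is deterministic everywhere (face-major row-major site ids;
  development-angle sweeps within assembly layers; lowest-id tie-breaks),
  and the optional within-layer shuffle is seeded, so identical inputs give
  identical outputs.
* **PDB export** refuses coordinates outside the fixed-column range
  (−999.999 to 9999.999) instead of corrupting columns — Ångström-scale
  giant-virus models should be exported in nanometres or lattice units —
  and splits models beyond 99 999 atoms into successive MODEL blocks.

## Problem sizes

The test suite builds full lattices up to T = 499 (4 992 capsomers, the
largest class with published per-capsomer assignments), sweeps the symmetron
budget identity over every odd-`h` class with T ≤ 2000, and runs the noisy
recovery benchmark at 100 seeds; the whole suite completes in about a
minute on one CPU. Larger classes (the enumeration guard allows T up to
10 000) use the same code paths.

## Known limitations

* Only icosahedral capsids: no prolate or ovoid lattices.
* No energetics or kinetics: the assembly simulator is a deterministic
  rule-ordered process exercising order-independence, not a thermodynamic
  model; misassembly and size regulation are out of scope.
* The decomposition requires odd `h`. Whether a `p ≠ (h-1)/2` decomposition
  is ever geometrically realisable is not addressed — `decompose_capsid()`
  refuses such inputs rather than invent geometry.
* Minor capsid proteins are not assigned to positions; the package
  reproduces the 60 geometrically unique positions only.
* `fit_hk()` requires the two penton endpoints to be present (designated or
  detectable as the two most distant points) and an essentially complete
  local lattice; it aborts with diagnostics rather than guess when the basis
  is ambiguous.
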
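---
title: "Cellular automata on microfluidic geometries: the chipCA model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular automata on microfluidic geometries: the chipCA model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipCA)
```

## Why bounded lattices

Most discrete cell models run on effectively infinite 2D lattices, i.e.
Petri-dish conditions. Lab- and organ-on-a-chip devices confine cells in
networks of chambers and channels, and the confinement changes the
collective dynamics: colonies funnel through channels, meet at junctions
and compete for the same chamber. chipCA takes the device's top-view
mask — white for cell-permitted area, black for wall — as the lattice
itself, so simulated colonies experience exactly the geometry the real
cells would. One pixel is one adherent cell; the default physical scale
is 20 µm per pixel side. The scale is metadata: no simulation result
depends on it, it only anchors pixel counts to physical areas. Coarser
lattices (a pixel as a small cell aggregate) simply use a larger pixel
size.

Pixels are addressed 1-based as (row, col), origin at the top-left, rows
increasing downward — the raster convention of the mask images.

## The automaton

The lattice carries one integer code per pixel: `wall` (−1), `empty`
(0), `dead` (−2), `drug` (−3) and one positive code per species in
registration order (`stateCodes()`). Walls coincide with the mask's
forbidden set at every step, by construction and by a validity check.

A global step applies four phases in a fixed order — proliferation (with
newborn death), invasion, then drug events. Every phase is
*synchronous*: decisions are computed from a snapshot taken before the
phase writes, so effects propagate one neighbourhood shell per step and
the result does not depend on pixel scan order. Scan order matters only
for the random-number stream (below).

### Proliferation

When a species fires, every empty pixel with at least one von Neumann
(4-) neighbour belonging to the species' colony becomes a newborn. The
von Neumann neighbourhood is the deliberate default because its
unobstructed ring growth is exactly `4n` cells at iteration `n`, the
increment the closed-form growth law is built on; a single seed grows as
the ball `2n² + 2n + 1`. An 8-neighbour Moore option exists
(`LatticeState(..., neighborhood = "moore")`) for exploration, with the
caveat that the `4n` increment — and therefore `expectedCount()` and
everything calibrated through it — no longer holds.

### Newborn death

Each newborn independently becomes `dead` with its species' `deathProb`
(`P_d`; the discounted growth law writes the same quantity `P_m`, and
the configuration accepts both spellings). The lottery is applied *once,
at birth*: this is the only reading under which the expected live count
is the discounted partial sum

$$y_n \;=\; y_0 + \sum_{k=1}^{n} 4k\,(1 - P_d) \;=\; y_0\,[1 + 2n(n+1)(1-P_d)],$$

in which earlier cohorts are never re-discounted. Seeded cells enter as
$y_0$, undiscounted.

Two properties of dead pixels need stating precisely:

* **Dead pixels occupy and persist.** They are rendered red forever and
  are never re-colonised; occupancy is monotone and `dead` is an
  absorbing state.
* **Dead pixels do not amputate the colony front.** The proliferation
  sources of a species are its live cells *plus its own dead cells*
  (each pixel carries a lineage attribution alongside its visible code).
  This was a genuinely open design point, and we resolved it by
  consistency with the growth law: if dead newborns blocked the front,
  every dead pixel on the perimeter would shadow the cells behind it and
  the live count would fall far below the discounted sum (at `n = 10`,
  `P_d = 0.3` the mean live count under blocking semantics is ≈ 95
  against the closed form's 155 — a 40 % deficit, not a perturbation).
  With front-transparent dead pixels the occupied region grows
  deterministically as the clipped ball and the live count matches the
  closed form exactly in expectation, which is what the calibration
  procedure assumes. The biological reading: the equation models the
  *population*, and a dead cell's neighbours are colonised by the
  colony, not by the corpse.

A consequence worth knowing: with `deathProb = 1` the visible dead
region still expands while the live population stays at the seeds. The
growth law says the same thing (`y_n = y_0`), but if the red front is
unwanted in such extreme runs, stop firing the species instead (zero
iterations in its schedule).

### Invasion

Live non-invasive cells adjacent to an invasive species convert to it.
Conversion is snapshot-synchronous — a chain of k cells converts over k
steps, not at once — and unconditional by default; `conversionProb < 1`
makes each eligible conversion an independent Bernoulli draw. When two
invasive species touch the same cell in the same step, the
earliest-registered species wins: a deterministic tie-break, chosen so
that trajectories are reproducible without consuming extra randomness.

### Drug events

A drug event names its target species, source pixels, an activation step
and a diffusion period (its "own dynamic"). At activation the empty
source pixels become `drug`; on every later step whose offset from
activation is a multiple of the period, the drug spreads into empty
neighbours — it displaces neither live nor dead cells, so a confluent
region is a barrier to it. At every step since activation, live target
cells adjacent to drug convert to the absorbing, non-proliferating
drug-affected state. Drug-occupied medium and drug-affected cells share
one code (pink); consequently an affected cell is itself a conversion
source and a drug front chews through a confluent target colony one
layer per step. Whether affected cells are "dead" is deliberately left
unsaid: they are counted under `drug`, never under `dead`. Non-target
species ignore the drug entirely, and a source pixel already occupied by
a non-target cell is skipped.

### Randomness and reproducibility

A run consumes a single seeded RNG stream (`set.seed(rngSeed)` in
`runSimulation()`). Stochastic draws happen only for the newborn death
lottery, `conversionProb < 1` invasions, and same-step proliferation
conflicts — when two species fire on the same step and claim the same
empty pixel, the winner is uniform among the claimants. Each class of
draws scans its affected pixel set in a documented order (species in
registration order, pixels row-major), so a fixed seed reproduces
trajectories bit-for-bit across platforms; the test suite asserts
byte-identical reruns of every packaged demo.

## Geometry

`loadMask()` classifies every raster pixel by mean luminance against a
threshold (default 128 on the 0–255 scale): at or above is allowed,
below is wall. No third state survives, which is how grey anti-aliasing
borders from lossy CAD exports are resolved. Mapping dark greys to
*wall* is a choice — the opposite mapping is equally defensible — made
so that compression artefacts cannot open spurious channels through a
wall; lowering the threshold recovers the permissive reading. PNG is
the canonical lossless format (`writeMask()` emits pure black/white and
round-trips exactly at any threshold); JPEG and TIFF are accepted on
input.

`makeDevice()` rasterises parametric layouts — single channel with two
wells, radial chamber, multi-chamber "metastasis" layout, or a custom
union of discs and rectangles (the route for blood-brain-barrier-like
geometries, which have no canonical dimensions) — by pixel-centre
inclusion: a pixel is allowed iff its centre lies in the union of the
spec's shapes. Pixel-centre rasterisation was chosen over area coverage
because it is deterministic and directly checkable against an
independent point-in-shape oracle, which the tests do shape by shape.
Rasterisation that disconnects the allowed set raises a warning rather
than an error: some layouts are legitimately disconnected, and
`connectedComponents()` (4-connectivity, matching the automaton's
adjacency) reports the pieces.

## Calibration

`scheduleFromCurve()` reproduces the growth-rate adjustment procedure:
for each consecutive pair of growth-curve observations it brute-force
searches `k = 0..kMax` (default 50) for the iteration count whose
predicted fold change best matches the observed one, accumulating
iterations across intervals; ties break toward fewer iterations.
Fold change is matched rather than absolute count because observed
means come from many colonies while the growth law tracks one. The
closed forms assume unobstructed growth — no walls, no colony
collisions — which mirrors the low-density multi-well cultures such
curves come from; crowding exists only in the simulator. Multiple seeds
are treated as independent diamonds (counts additive).

The shipped presets are the fitted schedules for N2A and MC3T3 over
five 2-day intervals (days 1–11): `(2, 3, 6, 7, 7)` and
`(2, 5, 7, 8, 7)` iterations respectively. They were fitted with the
death-free form of the growth law, so net death is already absorbed in
the iteration counts; the calibrated demo therefore runs with
`deathProb = 0` rather than double-counting mortality.

`scheduleFirings()` maps day intervals to global steps at a configurable
clock (default 4 steps per culture day — small enough that one
iteration ≈ half a day of growth, large enough to hold the maximum of 8
iterations per 2-day interval). Each interval's iterations are spread
evenly over its step span, earliest-first on remainders; interval totals
are preserved exactly, which is all the fitted schedules constrain. How
iterations sit *within* an interval is not identified by the data, and
the even spread is the least-structured choice.

## The synthetic geometry generator as a test bed

The device generator emulates the *shapes* of real microsystems:
channel widths of 100–250 µm, well radii of a few hundred µm, chamber
networks — all at the one-cell-per-pixel scale. What passing tests on
these geometries demonstrate is that the automaton's mechanics are
exact: growth counts match closed forms and flood oracles, occupation
times equal BFS geodesic distances, invariants hold on every demo
trajectory. What they deliberately do not demonstrate is biological
fidelity: real cultures show migration, adhesion differences,
density-dependent growth and measurement noise that the model excludes
or averages away. The calibration layer compensates only for *net
growth rate*, so agreement with a real device run is qualitative
(ordering, timing of confluence), not cell-for-cell.

## Degenerate inputs and numerical corners

* An all-black mask (no allowed pixel) is a hard error everywhere.
* A `single_channel` spec with `channelLengthUm = 0` and separated
  wells rasterises to two disjoint discs and warns.
* Schedules whose interval holds more iterations than steps are
  rejected with the required clock change in the message.
* `iterationsForGrowth()` with a flat target returns 0 (ties go to
  smaller k); with `deathProb = 1` every k predicts the same count and
  the tie rule again returns 0.
* Zero-step runs are legal and produce the seeded counts row only.
* Config validation is not fail-fast: every violation (seeds on walls,
  undefined species, non-sensitive drug targets, range errors) is
  reported in one list.

## Problem sizes

The shipped tests run on lattices between 9×9 and 201×201 and demo
devices of roughly 8 000–25 000 pixels for 40–120 steps, with 1 000
Monte-Carlo replicates where stochastic expectations are asserted —
sizes chosen so the whole suite exercises every claim in minutes on a
laptop. All quantitative assertions are scale-free (closed forms,
oracle equalities, 3-standard-error bands), so larger lattices change
runtime, not the checks.

## Known limitations

* No migration: colonies move only by proliferating into free pixels.
  Adherent, low-motility lines are the intended regime.
* No density- or nutrient-dependent growth; a schedule fires globally,
  not per local environment.
* Dead and drug-affected pixels never clear, so long runs in closed
  geometries end in frozen mosaics rather than turnover.
* The drug does not penetrate confluent non-target tissue (it diffuses
  through free medium only); modelling transport through cells would
  need a separate field.
* 2D only. Layer masks from slicing software would extend the same
  machinery to 2½D, but nothing in this package does so.
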
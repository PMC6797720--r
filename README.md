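# chipCA

Cellular-automata simulation of collective cell behaviour **inside
lab- and organ-on-a-chip devices**.

Discrete cell models (cellular automata, cellular Potts and relatives)
are usually run on boundary-less lattices — in effect simulating a Petri
dish. Microfluidic culture devices are different: cells grow inside
chambers and channels whose walls confine and shape the colony. chipCA
derives the simulation lattice directly from a black/white top-view mask
of the device (white pixel = allowed cell position, black = wall; one
pixel = one cell, 20 × 20 µm² by default), so the geometry of the chip
*is* the boundary condition of the model. It is aimed at people
designing or studying such devices who want to estimate how colonies
will spread, meet, invade each other or respond to a drug before running
wet-lab cultures.

## The model

The automaton state is one integer code per pixel: wall, empty, dead,
drug, or one code per cell species. Each global step applies, in order:

1. **Proliferation** (per species, when its schedule fires): every empty
   pixel with at least one von Neumann (4-) neighbour of the species'
   colony becomes a newborn, synchronously. An unobstructed colony
   therefore adds a ring of `4n` cells at iteration `n`:

   `y_n = y_{n-1} + 4n`

   so a single seed grows as the von Neumann ball, `y_n = 2n² + 2n + 1`.
2. **Newborn death**: each newborn independently enters the absorbing
   dead state with probability `P_d` (red pixels that persist and are
   never re-colonised). The expected live count is the discounted sum

   `y_n = y_0 + Σ_{k=1..n} 4k (1 − P_d) = y_0 (1 + 2n(n+1)(1 − P_d))`
3. **Invasion**: live non-invasive cells adjacent to an invasive species
   convert to it, one chain link per step.
4. **Drug events**: a timed agent that diffuses through empty pixels
   with its own period and converts adjacent cells of its target species
   to an absorbing, non-proliferating (pink) state.

Growth rates of real cell lines enter through **iteration schedules**:
the calibration module maps an observed growth curve (day, mean count)
to the per-interval number of proliferation iterations whose predicted
fold change matches the observed one. Fitted schedules for the N2A
(mouse neuroblastoma) and MC3T3 (osteoblast precursor) lines ship as
presets.

Cell migration, nutrient fields, energy terms and 3D lattices are out of
scope.

## A worked example

```r
library(chipCA)

## a colony with 30% newborn mortality on an open 101x101 lattice
st <- LatticeState(DeviceMask(matrix(TRUE, 101, 101)),
                   list(SpeciesSpec("cell", deathProb = 0.3)))
st <- seedCells(st, c(51, 51), "cell")
set.seed(42)
for (k in 1:10) st <- caStep(st)
countStates(st)
#> empty  wall  dead  drug  cell
#>  9980     0    60     0   161
expectedCount(10, deathProb = 0.3)
#> [1] 155
```

After 10 iterations the colony holds 161 live cells (the closed-form
expectation is 155; the Monte-Carlo mean over many seeds converges to
it) and 60 dead pixels embedded in the colony.

Device-bound runs are described declaratively and are reproducible
byte-for-byte under their RNG seed:

```r
cfg <- demoConfigs("calibrated_n2a_mc3t3")[[1]]   # 11-day N2A vs MC3T3 run
summ <- runSimulation(cfg, outDir = "run_out")    # counts.csv + PNG frames
tail(countsTable(summ), 2)
#>    step empty wall dead drug  N2A MC3T3
#> 40   39  1201 4756    0    0 1188  1339
#> 41   40  1201 4756    0    0 1188  1339
```

The faster-growing MC3T3 colony (1339 cells) stays ahead of N2A (1188)
at every step, as in the culture experiments the preset schedules were
fitted to. Five demo configurations (`demoConfigs()`) cover opposite-
inlet growth, drug response of an invasive line, a radial multi-inlet
device, a metastasis-on-a-chip multi-chamber run and the calibrated
11-day run. A thin command-line front end is installed at
`inst/scripts/chipca`:

```sh
chipca make-device --kind single_channel --well-radius-um 1000 \
       --channel-width-um 200 --channel-length-um 4000 --out mask.png
chipca run --config cfg.yaml --seed 42 --out run_out
chipca calibrate --growth curve.csv --out schedule.csv
chipca demos --run calibrated_n2a_mc3t3 --out demo_out
```

## Package layout

- `R/` — mask geometry (`loadMask`, `makeDevice`), the automaton
  (`caStep` and the four phases), calibration (`expectedCount`,
  `scheduleFromCurve`, `presetSchedule`), run orchestration
  (`runSimulation`, `loadConfig`, `demoConfigs`).
- `vignettes/chip-automata.Rmd` — the model, its assumptions and the
  design decisions in detail.
- `tests/testthat/` — unit, property and acceptance suites with
  independent BFS/flood-fill oracles.
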
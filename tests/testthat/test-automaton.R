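twoSpecies <- function() list(
  SpeciesSpec("green", color = c(0, 255, 0), deathProb = 0),
  SpeciesSpec("blue", color = c(0, 0, 255), deathProb = 0))

test_that("seeding places cells and rejects walls and collisions", {
  st <- openSeededState(11)
  expect_identical(countStates(st)[["a"]], 1L)
  expect_identical(stepIndex(st), 0L)

  mask <- makeDevice(deviceSpec("single_channel", wellRadiusUm = 200,
                                channelWidthUm = 120, channelLengthUm = 800))
  st2 <- LatticeState(mask, twoSpecies())
  wallPix <- which(!allowedGrid(mask))[1L]
  rc <- c((wallPix - 1L) %% nrow(mask@allowed) + 1L,
          (wallPix - 1L) %/% nrow(mask@allowed) + 1L)
  expect_error(seedCells(st2, rc, "green"), "wall pixel")

  left <- umToPixel(mask, -600, 0)
  right <- umToPixel(mask, 600, 0)
  st2 <- seedCells(st2, left, "green")
  st2 <- seedCells(st2, right, "blue")
  cnt <- countStates(st2)
  expect_identical(cnt[["green"]], 1L)
  expect_identical(cnt[["blue"]], 1L)
  expect_error(seedCells(st2, left, "blue"), "occupied")
})

test_that("one proliferation fires the four orthogonal neighbours", {
  st <- proliferatePhase(openSeededState(11), "a")
  expect_identical(nrow(newborns(st)), 4L)
  expect_identical(countStates(st)[["a"]], 5L)
  nb <- newborns(st)
  expect_setequal(paste(nb$row, nb$col),
                  c("5 6", "6 5", "6 7", "7 6"))
})

test_that("walls block proliferation: 1-pixel channel yields 2 newborns", {
  a <- matrix(FALSE, 3, 9)
  a[2, ] <- TRUE
  st <- LatticeState(DeviceMask(a), list(SpeciesSpec("a")))
  st <- seedCells(st, c(2, 5), "a")
  st <- proliferatePhase(st, "a")
  expect_identical(nrow(newborns(st)), 2L)
  expect_setequal(paste(newborns(st)$row, newborns(st)$col), c("2 4", "2 6"))
})

test_that("unobstructed growth follows 2n^2+2n+1 and the flood oracle", {
  n <- 15
  st <- openSeededState(2 * n + 5)
  mid <- (2 * n + 5 + 1) %/% 2
  oracle <- oracleFloodCounts(allowedGrid(st@mask), c(mid, mid), n)
  for (k in seq_len(n)) {
    st <- caStep(st)
    cnt <- countStates(st)[["a"]]
    expect_identical(cnt, as.integer(2 * k^2 + 2 * k + 1))
    expect_identical(cnt, as.integer(oracle[k]))
  }
})

test_that("the Moore opt-in produces 8 first-step newborns", {
  st <- LatticeState(DeviceMask(matrix(TRUE, 9, 9)), list(SpeciesSpec("a")),
                     neighborhood = "moore")
  st <- seedCells(st, c(5, 5), "a")
  st <- proliferatePhase(st, "a")
  expect_identical(nrow(newborns(st)), 8L)
})

test_that("the newborn death lottery is a per-newborn Bernoulli draw", {
  ## p = 0: nothing dies
  st <- proliferatePhase(openSeededState(11), "a")
  st0 <- deathPhase(st, deathProb = 0)
  expect_identical(countStates(st0)[["dead"]], 0L)

  ## p = 1: every newborn dies, live never exceeds the seeds, yet the
  ## front keeps expanding (the dead ring is part of the colony)
  st1 <- openSeededState(15, SpeciesSpec("a", deathProb = 1))
  for (k in 1:5) {
    st1 <- caStep(st1)
    expect_identical(countStates(st1)[["a"]], 1L)
    expect_identical(countStates(st1)[["dead"]],
                     as.integer(2 * k^2 + 2 * k))
  }

  ## p = 0.3 on ~10k newborns: fraction within 3 binomial SEs
  a <- matrix(TRUE, 3, 5000)
  st <- LatticeState(DeviceMask(a), list(SpeciesSpec("a")))
  st <- seedCells(st, cbind(2, 1:5000), "a")
  st <- proliferatePhase(st, "a")
  nNew <- nrow(newborns(st))
  expect_gte(nNew, 10000L)
  set.seed(101)
  st <- deathPhase(st, deathProb = 0.3)
  frac <- countStates(st)[["dead"]] / nNew
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / nNew))
  expect_error(deathPhase(st, deathProb = 1.3), "0, 1")
})

test_that("invasion converts by adjacency, one chain link per step", {
  sp <- list(SpeciesSpec("green", color = c(0, 255, 0)),
             SpeciesSpec("blue", color = c(0, 0, 255), invasive = TRUE))
  st <- LatticeState(DeviceMask(matrix(TRUE, 3, 10)), sp)
  st <- seedCells(st, cbind(2, 2:8), "green")
  st <- seedCells(st, c(2, 9), "blue")
  for (j in 1:7) {
    st <- invasionPhase(st)
    expect_identical(countStates(st)[["blue"]], 1L + j)
    expect_identical(countStates(st)[["green"]], 7L - j)
    ## exactly the j rightmost greens have converted
    expect_identical(unname(st@grid[2, 2:8]),
                     c(rep(1L, 7 - j), rep(2L, j)))
  }
  ## an isolated non-invasive cell is untouched
  st2 <- LatticeState(DeviceMask(matrix(TRUE, 5, 5)), sp)
  st2 <- seedCells(st2, c(3, 3), "green")
  before <- stateGrid(st2)
  expect_identical(stateGrid(invasionPhase(st2)), before)
})

test_that("drug diffuses as a clipped von Neumann ball with its own period", {
  sp <- list(SpeciesSpec("green", color = c(0, 255, 0)),
             SpeciesSpec("blue", color = c(0, 0, 255), drugSensitive = TRUE))
  st <- LatticeState(DeviceMask(matrix(TRUE, 15, 15)), sp)
  ev <- DrugEvent(activationStep = 1, sources = c(8, 8),
                  diffusionPeriod = 1, targetSpecies = "blue")
  dist <- oracleBFSDist(matrix(TRUE, 15, 15), c(8, 8))
  for (s in 1:5) {
    st <- drugPhase(st, ev, step = s)
    expect_identical(which(stateGrid(st) == stateCodes()[["drug"]]),
                     which(dist <= s - 1))  # n firings after activation
  }
  ## diffusion period 2: spreads only on every second step
  st2 <- LatticeState(DeviceMask(matrix(TRUE, 15, 15)), sp)
  ev2 <- DrugEvent(1, c(8, 8), diffusionPeriod = 2, targetSpecies = "blue")
  for (s in 1:5) st2 <- drugPhase(st2, ev2, step = s)
  expect_identical(sum(stateGrid(st2) == stateCodes()[["drug"]]),
                   sum(dist <= 2))  # firings at steps 3 and 5
})

test_that("drug converts target cells only, at the next phase", {
  sp <- list(SpeciesSpec("green", color = c(0, 255, 0)),
             SpeciesSpec("blue", color = c(0, 0, 255), drugSensitive = TRUE))
  codes <- stateCodes(c("green", "blue"))
  ## non-sensitive cell adjacent to drug: unchanged over many steps
  st <- LatticeState(DeviceMask(matrix(TRUE, 3, 30)), sp)
  st <- seedCells(st, c(2, 1), "green")
  ev <- DrugEvent(1, c(2, 2), diffusionPeriod = 5, targetSpecies = "blue")
  for (s in 1:10) st <- drugPhase(st, ev, step = s)
  expect_identical(stateGrid(st)[2, 1], codes[["green"]])
  ## sensitive cell adjacent to the front: converted at the next phase
  st2 <- LatticeState(DeviceMask(matrix(TRUE, 3, 30)), sp)
  st2 <- seedCells(st2, c(2, 4), "blue")
  st2 <- drugPhase(st2, ev, step = 1)  # source at (2,2) only
  expect_identical(stateGrid(st2)[2, 4], codes[["blue"]])
  st2 <- drugPhase(st2, ev, step = 2)  # no spread yet (period 5)...
  expect_identical(stateGrid(st2)[2, 4], codes[["blue"]])
  st2 <- drugPhase(st2, ev, step = 6)  # ...spread to (2,3), then convert
  expect_identical(stateGrid(st2)[2, 3], codes[["drug"]])
  st2 <- drugPhase(st2, ev, step = 7)
  expect_identical(stateGrid(st2)[2, 4], codes[["drug"]])
})

test_that("a step with nothing to do only advances the clock", {
  sp <- SpeciesSpec("slow", color = c(0, 0, 255), period = 5)
  st <- LatticeState(DeviceMask(matrix(TRUE, 9, 9)), list(sp))
  st <- seedCells(st, c(5, 5), "slow")
  before <- stateGrid(st)
  st <- caStep(st)  # step 1: period-5 species does not fire
  expect_identical(stateGrid(st), before)
  expect_identical(stepIndex(st), 1L)
})

test_that("occupation time equals BFS geodesic distance from the seed", {
  mask <- makeDevice(deviceSpec("single_channel", wellRadiusUm = 200,
                                channelWidthUm = 120, channelLengthUm = 800))
  seed <- umToPixel(mask, -600, 0)
  sets <- list(list(mask = mask, seed = seed))
  set.seed(42)
  for (k in 1:3) {
    m <- randomBlobMask(50, 50)
    cc <- connectedComponents(m)
    big <- which.max(cc$sizes)
    pix <- which(cc$labels == big)[1L]
    sets[[k + 1L]] <- list(mask = m, seed = c((pix - 1L) %% 50 + 1L,
                                              (pix - 1L) %/% 50 + 1L))
  }
  for (s in sets) {
    st <- LatticeState(s$mask, list(SpeciesSpec("a")))
    st <- seedCells(st, s$seed, "a")
    dist <- oracleBFSDist(allowedGrid(s$mask), s$seed)
    occupied <- matrix(NA_real_, nrow(dist), ncol(dist))
    occupied[st@grid == 1L] <- 0
    n <- max(dist[is.finite(dist)])
    for (k in seq_len(n)) {
      st <- caStep(st)
      occupied[is.na(occupied) & st@grid == 1L] <- k
    }
    reach <- is.finite(dist)
    expect_identical(occupied[reach], dist[reach])
    expect_true(all(is.na(occupied[!reach])))
  }
})

test_that("trajectory invariants hold under death, invasion and drug", {
  set.seed(7)
  mask <- randomBlobMask(45, 45, fillFraction = 0.7)
  cc <- connectedComponents(mask)
  inBig <- which(cc$labels == which.max(cc$sizes))
  pick <- function(k) {
    idx <- inBig[k]
    c((idx - 1L) %% 45 + 1L, (idx - 1L) %/% 45 + 1L)
  }
  n <- length(inBig)
  cfg <- simulationConfig(
    mask = mask,
    species = list(
      SpeciesSpec("green", color = c(0, 255, 0), deathProb = 0.3),
      SpeciesSpec("blue", color = c(0, 0, 255), deathProb = 0.2,
                  period = 2, invasive = TRUE, drugSensitive = TRUE)),
    seeds = list(green = pick(1L), blue = pick(n)),
    drugEvents = list(DrugEvent(10, pick(n %/% 2), 1, "blue")),
    totalSteps = 40, rngSeed = 99)
  st <- initialState(cfg)
  set.seed(cfg@rngSeed)
  codes <- stateCodes(c("green", "blue"))
  wallSet <- which(stateGrid(st) == codes[["wall"]])
  prevOccupied <- stateGrid(st) != codes[["empty"]]
  prevDead <- stateGrid(st) == codes[["dead"]]
  prevDrug <- stateGrid(st) == codes[["drug"]]
  for (s in 1:40) {
    st <- caStep(st, cfg)
    g <- stateGrid(st)
    expect_identical(which(g == codes[["wall"]]), wallSet)
    occ <- g != codes[["empty"]]
    expect_true(all(occ[prevOccupied]))        # occupancy is monotone
    expect_true(all(g[prevDead] == codes[["dead"]]))   # dead is absorbing
    expect_true(all(g[prevDrug] == codes[["drug"]]))   # drug is absorbing
    expect_identical(sum(countStates(st)), length(g))
    prevOccupied <- occ
    prevDead <- g == codes[["dead"]]
    prevDrug <- g == codes[["drug"]]
  }
})

test_that("identical config and seed give bit-identical trajectories", {
  run <- function() {
    cfg <- demoConfigs("single_channel_two_species")[[1L]]
    st <- initialState(cfg)
    set.seed(cfg@rngSeed)
    grids <- vector("list", 30L)
    for (s in 1:30) {
      st <- caStep(st, cfg)
      grids[[s]] <- stateGrid(st)
    }
    grids
  }
  expect_identical(run(), run())
})

test_that("a connected mask is fully colonised without death", {
  mask <- makeDevice(deviceSpec("single_channel", wellRadiusUm = 160,
                                channelWidthUm = 120, channelLengthUm = 500))
  st <- LatticeState(mask, list(SpeciesSpec("a")))
  st <- seedCells(st, umToPixel(mask, -410, 0), "a")
  dist <- oracleBFSDist(allowedGrid(mask), umToPixel(mask, -410, 0))
  for (s in seq_len(max(dist[is.finite(dist)]))) st <- caStep(st)
  cnt <- countStates(st)
  expect_identical(cnt[["empty"]], 0L)
  expect_identical(cnt[["a"]], sum(allowedGrid(mask)))
})
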
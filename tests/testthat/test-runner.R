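smallConfig <- function(totalSteps = 5, rngSeed = 7, ...) {
  simulationConfig(
    mask = DeviceMask(matrix(TRUE, 15, 15)),
    species = list(SpeciesSpec("a", color = c(0, 255, 0), deathProb = 0.3)),
    seeds = list(a = c(8, 8)),
    totalSteps = totalSteps, rngSeed = rngSeed, ...)
}

test_that("validateConfig enumerates all violations, not just the first", {
  mask <- makeDevice(deviceSpec("single_channel", wellRadiusUm = 200,
                                channelWidthUm = 120, channelLengthUm = 800))
  wallPix <- which(!allowedGrid(mask))[1L]
  wallRC <- c((wallPix - 1L) %% nrow(mask@allowed) + 1L,
              (wallPix - 1L) %/% nrow(mask@allowed) + 1L)
  cfg <- simulationConfig(
    mask = mask,
    species = list(SpeciesSpec("a", color = c(0, 255, 0))),
    seeds = list(a = wallRC, ghost = c(1, 1)),
    drugEvents = list(DrugEvent(3, umToPixel(mask, 0, 0), 1, "a")),
    totalSteps = 10, validate = FALSE)
  issues <- validateConfig(cfg)
  expect_length(issues, 3L)
  expect_match(issues,
               paste0("seed for 'a' at \\(", wallRC[1L], ", ", wallRC[2L],
                      "\\) is on a wall"), all = FALSE)
  expect_match(issues, "undefined species 'ghost'", all = FALSE)
  expect_match(issues, "not drug-sensitive", all = FALSE)
  expect_error(runSimulation(cfg), "wall")
  expect_error(simulationConfig(mask, list(SpeciesSpec("a")),
                                seeds = list(a = wallRC), totalSteps = 1),
               "wall")
})

test_that("out-of-range species parameters are rejected with context", {
  expect_error(SpeciesSpec("a", deathProb = 1.3), "0, 1")
  expect_error(SpeciesSpec("a", color = c(255, 0, 0)), "reserved")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "mask: {kind: single_channel}",
    "species:",
    "  - {name: bad, color: [0, 120, 0], death_prob: 1.3}",
    "  - {name: worse, color: [255, 105, 180], death_prob: 0.2}",
    "seeds: {bad: [[22, 22]]}",
    "total_steps: 3"), f)
  err <- tryCatch(loadConfig(f), error = conditionMessage)
  expect_match(err, "species 'bad'.*deathProb")
  expect_match(err, "species 'worse'.*reserved")
})

test_that("packaged YAML configs load and validate cleanly", {
  for (f in c("demo_single_channel.yaml", "demo_calibrated.yaml")) {
    cfg <- loadConfig(system.file("extdata", f, package = "chipCA"))
    expect_s4_class(cfg, "SimulationConfig")
    expect_length(validateConfig(cfg), 0L)
  }
  cfg <- loadConfig(system.file("extdata", "demo_calibrated.yaml",
                                package = "chipCA"))
  expect_identical(cfg@species[[1L]]@schedule$iterations, c(2L, 3L, 6L, 7L, 7L))
  expect_identical(cfg@species[[2L]]@schedule$iterations, c(2L, 5L, 7L, 8L, 7L))
})

test_that("configs survive the YAML round trip with identical hash", {
  cfg <- smallConfig()
  f <- withr::local_tempfile(fileext = ".yaml")
  saveConfig(cfg, f)
  cfg2 <- loadConfig(f)
  expect_identical(configHash(cfg2), configHash(cfg))
  expect_identical(allowedGrid(cfg2@mask), allowedGrid(cfg@mask))
})

test_that("a zero-step run reports exactly the seeded counts", {
  summ <- runSimulation(smallConfig(totalSteps = 0))
  tab <- countsTable(summ)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$a, 1L)
  expect_identical(tab$empty, 224L)
  expect_identical(sum(tab[1, -1L]), 225L)
})

test_that("runs are reproducible byte-for-byte and rows conserve pixels", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- demoConfigs("single_channel_two_species")[[1L]]
  cfg@totalSteps <- 40L
  s1 <- runSimulation(cfg, outDir = d1)
  s2 <- runSimulation(cfg, outDir = d2)
  expect_identical(readBin(file.path(d1, "counts.csv"), "raw", 1e6),
                   readBin(file.path(d2, "counts.csv"), "raw", 1e6))
  tab <- countsTable(s1)
  expect_identical(nrow(tab), 41L)
  expect_true(all(rowSums(tab[, -1L]) == prod(dim(cfg@mask))))
  expect_identical(names(tab),
                   c("step", "empty", "wall", "dead", "drug", "green", "blue"))
  ## provenance ties the summary to the config that produced it
  f <- withr::local_tempfile(fileext = ".yaml")
  saveConfig(cfg, f)
  expect_identical(provenance(s1)$configHash, configHash(loadConfig(f)))
  expect_identical(provenance(s1)$rngSeed, 11L)
})

test_that("rendered frames agree with the counts table", {
  cfg <- smallConfig(totalSteps = 6)
  d <- withr::local_tempdir()
  summ <- runSimulation(cfg, outDir = d, framesEvery = 2)
  expect_true(file.exists(file.path(d, "frame_000004.png")))
  expect_true(file.exists(file.path(d, "final.png")))
  expect_true(file.exists(file.path(d, "run.log")))
  img <- png::readPNG(file.path(d, "final.png"))
  st <- initialState(cfg)  # palette only depends on the species
  pal <- defaultPalette(st)
  got <- classifyFrame(img, pal)
  tab <- countsTable(summ)
  last <- tab[nrow(tab), ]
  expect_identical(as.integer(got[c("empty", "wall", "dead", "drug", "a")]),
                   c(last$empty, last$wall, last$dead, last$drug, last$a))
})

test_that("rendering uses the reserved palette and fails on gaps", {
  a <- matrix(FALSE, 3, 3)
  a[2, 2] <- TRUE
  st <- LatticeState(DeviceMask(a), list(SpeciesSpec("a")))
  img <- renderFrame(st)
  expect_equal(img[2, 2, ], c(1, 1, 1))      # empty renders white
  expect_equal(img[1, 1, ], c(0, 0, 0))      # wall renders black
  st <- seedCells(st, c(2, 2), "a")
  expect_error(renderFrame(st, palette = list(wall = c(0, 0, 0))),
               "no entry for state code 'a'")
})

test_that("demo configs cover the published scenarios and run", {
  cfgs <- demoConfigs()
  expect_named(cfgs, c("single_channel_two_species", "single_channel_drug",
                       "radial_multi_inlet", "multi_chamber_drug",
                       "calibrated_n2a_mc3t3"))
  for (cfg in cfgs) expect_length(validateConfig(cfg), 0L)
  cal <- cfgs$calibrated_n2a_mc3t3
  expect_identical(cal@species[[1L]]@schedule$iterations, c(2L, 3L, 6L, 7L, 7L))
  expect_identical(cal@species[[2L]]@schedule$iterations, c(2L, 5L, 7L, 8L, 7L))
  expect_error(demoConfigs("petri_dish"), "unknown demo")

  ## smoke: the first demo runs to completion at desk scale
  smoke <- cfgs$single_channel_two_species
  smoke@totalSteps <- 15L
  summ <- runSimulation(smoke)
  expect_identical(nrow(countsTable(summ)), 16L)
})

test_that("the drug event caps the invasive population in the drug demo", {
  cfg <- demoConfigs("single_channel_drug")[[1L]]
  summ <- runSimulation(cfg)
  tab <- countsTable(summ)
  after <- tab$invasive[tab$step >= 35L]
  expect_true(all(diff(after) <= 0))
  ## the drug did reach and convert invasive cells
  expect_lt(after[length(after)], after[1L])
  expect_gt(tab$drug[nrow(tab)], 0L)
})
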
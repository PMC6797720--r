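## Packaged demo configurations at desk scale. Each reproduces one of
## the canonical simulation scenarios: growth from opposite inlets,
## drug response of an invasive line, radial multi-inlet growth, a
## metastasis-on-a-chip multi-chamber run, and the calibrated
## N2A/MC3T3 11-day run driven by the fitted schedule presets.

.demoChannelSpec <- function(pixelSizeUm = 20)
  deviceSpec("single_channel", pixelSizeUm = pixelSizeUm,
             wellRadiusUm = 400, channelWidthUm = 200,
             channelLengthUm = 2400)

.demoSingleChannelTwoSpecies <- function() {
  mask <- makeDevice(.demoChannelSpec())
  simulationConfig(
    mask = mask,
    species = list(
      SpeciesSpec("green", color = c(0, 255, 0), deathProb = 0.3, period = 1),
      SpeciesSpec("blue", color = c(0, 0, 255), deathProb = 0.3, period = 2)),
    seeds = list(green = umToPixel(mask, -1600, 0),
                 blue = umToPixel(mask, 1600, 0)),
    totalSteps = 120, rngSeed = 11)
}

.demoSingleChannelDrug <- function() {
  mask <- makeDevice(.demoChannelSpec())
  ## the invasive line proliferates every step for 30 steps and is
  ## quiescent afterwards; the drug is added at step 35 in front of the
  ## halted colony and chews through it by adjacency
  invSchedule <- data.frame(day_start = 1, day_end = 8.5, iterations = 30L)
  simulationConfig(
    mask = mask,
    species = list(
      SpeciesSpec("healthy", color = c(0, 255, 0), deathProb = 0.3,
                  period = 2),
      SpeciesSpec("invasive", color = c(0, 0, 255), deathProb = 0.3,
                  schedule = invSchedule, invasive = TRUE,
                  drugSensitive = TRUE)),
    seeds = list(healthy = umToPixel(mask, -1600, 0),
                 invasive = umToPixel(mask, 1600, 0)),
    drugEvents = list(DrugEvent(activationStep = 35,
                                sources = umToPixel(mask, 1080, 0),
                                diffusionPeriod = 1,
                                targetSpecies = "invasive")),
    totalSteps = 60, stepsPerDay = 4, rngSeed = 23)
}

.demoRadial <- function() {
  spec <- deviceSpec("radial", wellRadiusUm = 240, channelWidthUm = 160,
                     channelLengthUm = 800, nChannels = 6,
                     chamberRadiusUm = 500)
  mask <- makeDevice(spec)
  th <- 2 * pi * (0:5) / 6
  wells <- umToPixel(mask, 1300 * cos(th), 1300 * sin(th))
  simulationConfig(
    mask = mask,
    species = list(
      SpeciesSpec("green", color = c(0, 255, 0), deathProb = 0.3, period = 1),
      SpeciesSpec("blue", color = c(0, 0, 255), deathProb = 0.3, period = 2)),
    seeds = list(green = wells[c(1L, 3L, 5L), , drop = FALSE],
                 blue = wells[c(2L, 4L, 6L), , drop = FALSE]),
    totalSteps = 80, rngSeed = 37)
}

.demoMultiChamberDrug <- function() {
  spec <- deviceSpec("multi_chamber", wellRadiusUm = 300,
                     channelWidthUm = 240, channelLengthUm = 3000,
                     chamberWidthUm = 600, chamberHeightUm = 400,
                     nChambers = 3, connectorWidthUm = 120,
                     connectorLengthUm = 200)
  mask <- makeDevice(spec)
  chamberX <- c(-1000, 0, 1000)
  chambers <- rbind(umToPixel(mask, chamberX, rep(-520, 3)),
                    umToPixel(mask, chamberX, rep(520, 3)))
  simulationConfig(
    mask = mask,
    species = list(
      SpeciesSpec("healthy", color = c(0, 255, 0), deathProb = 0.3,
                  period = 2),
      SpeciesSpec("metastatic", color = c(0, 0, 255), deathProb = 0.3,
                  period = 1, invasive = TRUE, drugSensitive = TRUE)),
    seeds = list(healthy = chambers,
                 metastatic = umToPixel(mask, -1800, 0)),
    drugEvents = list(DrugEvent(activationStep = 60,
                                sources = umToPixel(mask, 0, 0),
                                diffusionPeriod = 1,
                                targetSpecies = "metastatic")),
    totalSteps = 100, rngSeed = 41)
}

.demoCalibrated <- function() {
  ## 11-day run driven by the fitted N2A / MC3T3 schedule presets at
  ## 4 steps per culture day. The presets were fitted with the
  ## death-free growth law, so net death is already absorbed in the
  ## iteration counts and the run itself uses deathProb 0.
  mask <- makeDevice(.demoChannelSpec())
  simulationConfig(
    mask = mask,
    species = list(
      SpeciesSpec("N2A", color = c(0, 255, 0), deathProb = 0,
                  schedule = presetSchedule("N2A")),
      SpeciesSpec("MC3T3", color = c(75, 0, 130), deathProb = 0,
                  schedule = presetSchedule("MC3T3"))),
    seeds = list(N2A = umToPixel(mask, -1600, 0),
                 MC3T3 = umToPixel(mask, 1600, 0)),
    totalSteps = 40, stepsPerDay = 4, rngSeed = 53)
}

#' Packaged demo configurations
#'
#' Ready-to-run [SimulationConfig-class] objects for the canonical
#' scenarios:
#' \describe{
#'   \item{`single_channel_two_species`}{two cell types seeded in the
#'     opposite inlets of a single-channel device, growing toward each
#'     other.}
#'   \item{`single_channel_drug`}{a healthy and an invasive line in the
#'     same device; a drug targeting the invasive line is added mid-run
#'     and diffuses toward it.}
#'   \item{`radial_multi_inlet`}{two cell types seeded in alternating
#'     wells of a six-channel radial device.}
#'   \item{`multi_chamber_drug`}{a metastasis-on-a-chip run: healthy
#'     cells in the side chambers, an invasive line travelling along the
#'     central vascular channel, a late drug event targeting it.}
#'   \item{`calibrated_n2a_mc3t3`}{the 11-day N2A vs MC3T3 run driven by
#'     the fitted schedule presets (see [presetSchedule()]).}
#' }
#'
#' @param names optional character vector selecting a subset.
#' @return Named list of [SimulationConfig-class].
#' @examples
#' cfg <- demoConfigs("calibrated_n2a_mc3t3")[[1]]
#' cfg
#' @export
demoConfigs <- function(names = NULL) {
  builders <- list(
    single_channel_two_species = .demoSingleChannelTwoSpecies,
    single_channel_drug = .demoSingleChannelDrug,
    radial_multi_inlet = .demoRadial,
    multi_chamber_drug = .demoMultiChamberDrug,
    calibrated_n2a_mc3t3 = .demoCalibrated
  )
  if (is.null(names)) names <- names(builders)
  bad <- setdiff(names, names(builders))
  if (length(bad))
    stop("unknown demo(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(names(builders), collapse = ", "),
         call. = FALSE)
  lapply(stats::setNames(builders[names], names), function(f) f())
}
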
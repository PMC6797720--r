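#' @import methods
NULL

## Reserved lattice state codes. Species are assigned positive codes
## 1, 2, ... in registration order; the reserved codes are <= 0.
.EMPTY <- 0L
.WALL <- -1L
.DEAD <- -2L
.DRUG <- -3L

## Reserved rendering colours (8-bit RGB). Pink is shared between
## drug-occupied pixels and drug-affected cells.
.PALETTE_RESERVED <- list(
  empty = c(255L, 255L, 255L),
  wall  = c(0L, 0L, 0L),
  dead  = c(255L, 0L, 0L),
  drug  = c(255L, 105L, 180L)
)

#' Reserved and species state codes
#'
#' The lattice stores one integer code per pixel: `empty` (0), `wall` (-1),
#' `dead` (-2), `drug` (-3, shared by drug-occupied pixels and drug-affected
#' cells) and one positive code per registered species, in registration
#' order.
#'
#' @param species character vector of species names (possibly empty).
#' @return Named integer vector of codes.
#' @examples
#' stateCodes(c("healthy", "invasive"))
#' @export
stateCodes <- function(species = character()) {
  codes <- c(empty = .EMPTY, wall = .WALL, dead = .DEAD, drug = .DRUG)
  if (length(species))
    codes <- c(codes, stats::setNames(seq_along(species), species))
  codes
}

#' DeviceMask: a bounded simulation lattice
#'
#' A rectangular boolean lattice in which `TRUE` pixels are allowed cell
#' positions (white in the raster mask) and `FALSE` pixels are device walls
#' (black). One pixel corresponds to one cell; the physical pixel side
#' length defaults to 20 micrometres.
#'
#' @slot allowed logical matrix; `TRUE` = cell-permitted pixel.
#' @slot pixelSizeUm physical side length of one pixel in micrometres.
#' @slot originUm physical (x, y) coordinate, in micrometres, of the
#'   top-left corner of pixel (1, 1); metadata used to map physical
#'   coordinates back to pixels for synthetic devices.
#' @export
setClass("DeviceMask",
  slots = c(allowed = "matrix", pixelSizeUm = "numeric", originUm = "numeric"),
  prototype = prototype(
    allowed = matrix(TRUE, 1L, 1L),
    pixelSizeUm = 20,
    originUm = c(0, 0)
  )
)

setValidity("DeviceMask", function(object) {
  msg <- character()
  if (!is.logical(object@allowed))
    msg <- c(msg, "'allowed' must be a logical matrix")
  else {
    if (anyNA(object@allowed))
      msg <- c(msg, "'allowed' must not contain NA")
    if (!any(object@allowed))
      msg <- c(msg, "mask has no allowed pixel (unusable geometry)")
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (length(object@originUm) != 2L || anyNA(object@originUm))
    msg <- c(msg, "'originUm' must be a numeric (x, y) pair")
  if (length(msg)) msg else TRUE
})

#' DeviceSpec: parametric description of a synthetic microfluidic layout
#'
#' @slot kind one of `"single_channel"`, `"radial"`, `"multi_chamber"`,
#'   `"custom"`.
#' @slot params named list of geometric parameters in micrometres
#'   (see [deviceSpec()]).
#' @slot pixelSizeUm lattice resolution in micrometres per pixel.
#' @export
setClass("DeviceSpec",
  slots = c(kind = "character", params = "list", pixelSizeUm = "numeric"))

.DEVICE_KINDS <- c("single_channel", "radial", "multi_chamber", "custom")

setValidity("DeviceSpec", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .DEVICE_KINDS)
    msg <- c(msg, paste0("'kind' must be one of: ",
                         paste(.DEVICE_KINDS, collapse = ", ")))
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  p <- object@params
  num <- p[vapply(p, is.numeric, logical(1L))]
  lengths_ <- unlist(num[names(num) %in% c(
    "wellRadiusUm", "channelWidthUm", "channelLengthUm", "chamberRadiusUm",
    "chamberWidthUm", "chamberHeightUm", "connectorWidthUm",
    "connectorLengthUm")])
  if (length(lengths_) && any(!is.finite(lengths_) | lengths_ < 0))
    msg <- c(msg, "all geometric lengths must be finite and >= 0")
  if (identical(object@kind, "radial")) {
    n <- p$nChannels
    if (is.null(n) || length(n) != 1L || n < 1)
      msg <- c(msg, "radial devices require 'nChannels' >= 1")
  }
  if (identical(object@kind, "custom") && !length(p$shapes))
    msg <- c(msg, "custom devices require a non-empty 'shapes' list")
  if (length(msg)) msg else TRUE
})

#' SpeciesSpec: one simulated cell type
#'
#' @slot name species identifier.
#' @slot color length-3 integer RGB triple in 0..255 used for rendering;
#'   must differ from the reserved palette (white, black, red, pink).
#' @slot deathProb probability in \[0, 1\] that a newborn cell immediately
#'   enters the absorbing dead state (the per-newborn death probability
#'   P_d, written P_m in the discounted growth law).
#' @slot period number of global steps between proliferation firings
#'   (ignored when a schedule is given).
#' @slot schedule `NULL`, or a schedule data.frame with columns
#'   `day_start`, `day_end`, `iterations` (see [presetSchedule()]).
#' @slot invasive logical; invasive cells convert adjacent non-invasive
#'   live cells to their own type.
#' @slot drugSensitive logical; whether a drug event may target this
#'   species.
#' @slot conversionProb probability in (0, 1] that an eligible adjacent
#'   cell is converted in one invasion phase (default 1: unconditional
#'   conversion by adjacency).
#' @export
setClass("SpeciesSpec",
  slots = c(name = "character", color = "integer", deathProb = "numeric",
            period = "integer", schedule = "ANY", invasive = "logical",
            drugSensitive = "logical", conversionProb = "numeric"))

.checkScheduleDF <- function(s) {
  msg <- character()
  need <- c("day_start", "day_end", "iterations")
  if (!is.data.frame(s) || !all(need %in% names(s)))
    return("schedule must be a data.frame with columns day_start, day_end, iterations")
  if (nrow(s) == 0L) msg <- c(msg, "schedule has no intervals")
  if (any(s$day_end <= s$day_start))
    msg <- c(msg, "schedule intervals must have day_end > day_start")
  if (nrow(s) > 1L && any(abs(s$day_start[-1L] - s$day_end[-nrow(s)]) > 1e-9))
    msg <- c(msg, "schedule intervals must be contiguous and non-overlapping")
  if (any(s$iterations < 0) || any(s$iterations != round(s$iterations)))
    msg <- c(msg, "schedule iterations must be nonnegative integers")
  msg
}

setValidity("SpeciesSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (length(object@color) != 3L || anyNA(object@color) ||
      any(object@color < 0L) || any(object@color > 255L))
    msg <- c(msg, "'color' must be an RGB triple in 0..255")
  else if (any(vapply(.PALETTE_RESERVED, function(x)
                      all(x == object@color), logical(1L))))
    msg <- c(msg, "'color' collides with the reserved palette (white/black/red/pink)")
  if (length(object@deathProb) != 1L || is.na(object@deathProb) ||
      object@deathProb < 0 || object@deathProb > 1)
    msg <- c(msg, "'deathProb' must be in [0, 1]")
  if (length(object@period) != 1L || is.na(object@period) || object@period < 1L)
    msg <- c(msg, "'period' must be a positive integer")
  if (!is.null(object@schedule))
    msg <- c(msg, .checkScheduleDF(object@schedule))
  if (length(object@conversionProb) != 1L || is.na(object@conversionProb) ||
      object@conversionProb <= 0 || object@conversionProb > 1)
    msg <- c(msg, "'conversionProb' must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' DrugEvent: timed introduction of a diffusing agent
#'
#' At the activation step the (empty) source pixels become drug; on every
#' subsequent step whose offset from activation is a multiple of
#' `diffusionPeriod` the drug spreads into empty von Neumann neighbours;
#' live cells of the target species adjacent to drug are converted to the
#' absorbing, non-proliferating drug-affected state at every step after
#' activation.
#'
#' @slot activationStep nonnegative global step at which the drug appears.
#' @slot sources integer matrix with one (row, col) pixel per row.
#' @slot diffusionPeriod positive integer number of steps between
#'   diffusion firings (the drug's own dynamic).
#' @slot targetSpecies name of the (drug-sensitive) species the agent
#'   interacts with.
#' @export
setClass("DrugEvent",
  slots = c(activationStep = "integer", sources = "matrix",
            diffusionPeriod = "integer", targetSpecies = "character"))

setValidity("DrugEvent", function(object) {
  msg <- character()
  if (length(object@activationStep) != 1L || is.na(object@activationStep) ||
      object@activationStep < 0L)
    msg <- c(msg, "'activationStep' must be a nonnegative integer")
  if (!is.numeric(object@sources) || ncol(object@sources) != 2L ||
      nrow(object@sources) < 1L)
    msg <- c(msg, "'sources' must be a matrix of (row, col) pixels")
  if (length(object@diffusionPeriod) != 1L || is.na(object@diffusionPeriod) ||
      object@diffusionPeriod < 1L)
    msg <- c(msg, "'diffusionPeriod' must be a positive integer")
  if (length(object@targetSpecies) != 1L || !nzchar(object@targetSpecies))
    msg <- c(msg, "'targetSpecies' must name a species")
  if (length(msg)) msg else TRUE
})

#' LatticeState: the automaton's per-pixel state
#'
#' @slot grid integer matrix of state codes (see [stateCodes()]),
#'   congruent with the mask: wall pixels coincide exactly with the
#'   mask's forbidden set at all times.
#' @slot lineage integer matrix attributing each colonised pixel to the
#'   species whose front created it (0 where unattributed). Dead pixels
#'   keep their lineage, which is how the colony front propagates past
#'   them without re-colonising the pixel itself.
#' @slot mask the [DeviceMask-class] the state lives on.
#' @slot species list of [SpeciesSpec-class] in registration order
#'   (species i carries lattice code i).
#' @slot stepIndex number of completed global steps.
#' @slot newborns data.frame (`row`, `col`, `species`) of pixels created
#'   by the proliferation phase of the current step.
#' @slot neighborhood `"von_neumann"` (default; the 4-neighbour adjacency
#'   whose unobstructed ring growth is 4 per iteration, matching the
#'   growth law) or `"moore"` (8 neighbours; offered for exploration —
#'   the 4n increment and every closed form built on it no longer hold).
#' @export
setClass("LatticeState",
  slots = c(grid = "matrix", lineage = "matrix", mask = "DeviceMask",
            species = "list", stepIndex = "integer", newborns = "data.frame",
            neighborhood = "character"))

setValidity("LatticeState", function(object) {
  msg <- character()
  if (!identical(dim(object@grid), dim(object@mask@allowed)))
    msg <- c(msg, "grid shape must equal mask shape")
  if (!identical(dim(object@lineage), dim(object@grid)))
    msg <- c(msg, "lineage shape must equal grid shape")
  if (!all(xor(object@grid == .WALL, object@mask@allowed)))
    msg <- c(msg, "wall pixels must coincide exactly with the mask's forbidden set")
  nsp <- length(object@species)
  if (nsp) {
    if (!all(vapply(object@species, is, logical(1L), "SpeciesSpec")))
      msg <- c(msg, "'species' must be a list of SpeciesSpec")
    else {
      nm <- vapply(object@species, function(s) s@name, character(1L))
      if (anyDuplicated(nm))
        msg <- c(msg, "species names must be unique")
    }
  }
  if (any(object@grid > nsp))
    msg <- c(msg, "grid contains a species code with no registered species")
  if (length(object@stepIndex) != 1L || is.na(object@stepIndex) ||
      object@stepIndex < 0L)
    msg <- c(msg, "'stepIndex' must be a nonnegative integer")
  if (length(object@neighborhood) != 1L ||
      !object@neighborhood %in% c("von_neumann", "moore"))
    msg <- c(msg, "'neighborhood' must be \"von_neumann\" or \"moore\"")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: full declarative description of one run
#'
#' @slot mask the resolved [DeviceMask-class].
#' @slot species list of [SpeciesSpec-class] in registration order.
#' @slot seeds named list (species name -> integer matrix of (row, col)
#'   seed pixels).
#' @slot drugEvents list of [DrugEvent-class].
#' @slot totalSteps number of global steps to run.
#' @slot stepsPerDay clock used to map schedule day intervals onto global
#'   steps (default 4 steps per culture day).
#' @slot rngSeed integer seed for the run's single random-number stream.
#' @slot frameStride write a rendered frame every this many steps
#'   (`NA` = only the final frame).
#' @export
setClass("SimulationConfig",
  slots = c(mask = "DeviceMask", species = "list", seeds = "list",
            drugEvents = "list", totalSteps = "integer",
            stepsPerDay = "integer", rngSeed = "integer",
            frameStride = "integer"))

## Structural checks only; full semantic validation (seeds vs mask, drug
## targets, schedules vs clock) is enumerated — not fail-fast — by
## validateConfig(), which the constructor and runSimulation() enforce.
setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!all(vapply(object@species, is, logical(1L), "SpeciesSpec")))
    msg <- c(msg, "'species' must be a list of SpeciesSpec")
  if (!all(vapply(object@drugEvents, is, logical(1L), "DrugEvent")))
    msg <- c(msg, "'drugEvents' must be a list of DrugEvent")
  if (length(object@seeds) && is.null(names(object@seeds)))
    msg <- c(msg, "'seeds' must be a named list (species -> pixels)")
  if (length(msg)) msg else TRUE
})

#' RunSummary: per-step population counts plus provenance
#'
#' @slot counts data.frame with one row per step 0..totalSteps and columns
#'   `step`, `empty`, `wall`, `dead`, `drug`, then one column per species
#'   in registration order; every row sums (excluding `step`) to the grid
#'   size.
#' @slot provenance list with elements `configHash`, `rngSeed`, `version`.
#' @export
setClass("RunSummary",
  slots = c(counts = "data.frame", provenance = "list"))
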
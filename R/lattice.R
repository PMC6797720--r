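#' Define a simulated cell type
#'
#' @param name species identifier.
#' @param color RGB triple (0..255) used for rendering; defaults cycle
#'   through green and blue as in typical two-species runs.
#' @param deathProb per-newborn death probability in \[0, 1\]. Newly
#'   created cells enter the absorbing dead state with this probability;
#'   seeded cells are never subjected to the lottery.
#' @param period fire the proliferation phase every `period` global steps
#'   (ignored when `schedule` is given).
#' @param schedule optional schedule data.frame (`day_start`, `day_end`,
#'   `iterations`), e.g. from [presetSchedule()]; requires a run clock
#'   (`stepsPerDay`) to map onto global steps.
#' @param invasive logical; invasive cells convert adjacent non-invasive
#'   live cells to their own type.
#' @param drugSensitive logical; whether drug events may target the
#'   species.
#' @param conversionProb invasion conversion probability (default 1).
#' @return A [SpeciesSpec-class].
#' @examples
#' SpeciesSpec("healthy", color = c(0, 255, 0), deathProb = 0.3)
#' @export
SpeciesSpec <- function(name, color = c(0, 255, 0), deathProb = 0,
                        period = 1, schedule = NULL, invasive = FALSE,
                        drugSensitive = FALSE, conversionProb = 1) {
  new("SpeciesSpec", name = as.character(name), color = as.integer(color),
      deathProb = as.numeric(deathProb), period = as.integer(period),
      schedule = schedule, invasive = isTRUE(invasive),
      drugSensitive = isTRUE(drugSensitive),
      conversionProb = as.numeric(conversionProb))
}

setMethod("show", "SpeciesSpec", function(object) {
  cat("SpeciesSpec '", object@name, "': color [",
      paste(object@color, collapse = ","), "], deathProb ", object@deathProb,
      if (is.null(object@schedule)) paste0(", period ", object@period)
      else paste0(", scheduled (", sum(object@schedule$iterations), " firings)"),
      if (object@invasive) ", invasive" else "",
      if (object@drugSensitive) ", drug-sensitive" else "", "\n", sep = "")
})

#' Define a drug event
#'
#' @param activationStep global step at which the agent is introduced.
#' @param sources (row, col) pixel(s) where the agent enters; must be
#'   allowed pixels of the mask.
#' @param diffusionPeriod steps between diffusion firings (the agent's
#'   own dynamic; 1 = spreads every step).
#' @param targetSpecies name of the species the agent interacts with.
#' @return A [DrugEvent-class].
#' @export
DrugEvent <- function(activationStep, sources, diffusionPeriod = 1,
                      targetSpecies) {
  new("DrugEvent", activationStep = as.integer(activationStep),
      sources = .asPixelMatrix(sources),
      diffusionPeriod = as.integer(diffusionPeriod),
      targetSpecies = as.character(targetSpecies))
}

#' Create an empty lattice state on a mask
#'
#' @param mask a [DeviceMask-class].
#' @param species list of [SpeciesSpec-class]; species i carries lattice
#'   code i (registration order).
#' @param neighborhood `"von_neumann"` (default, 4-neighbour: the
#'   adjacency under which an unobstructed colony adds a ring of 4n
#'   cells at iteration n) or `"moore"` (8-neighbour, exploratory: the
#'   4n increment and the closed-form growth law no longer hold).
#' @return A [LatticeState-class] with all allowed pixels empty and
#'   `stepIndex` 0.
#' @examples
#' st <- LatticeState(DeviceMask(matrix(TRUE, 9, 9)),
#'                    list(SpeciesSpec("a")))
#' countStates(st)
#' @export
LatticeState <- function(mask, species = list(),
                         neighborhood = c("von_neumann", "moore")) {
  stopifnot(is(mask, "DeviceMask"))
  if (is(species, "SpeciesSpec")) species <- list(species)
  grid <- matrix(.EMPTY, nrow(mask@allowed), ncol(mask@allowed))
  grid[!mask@allowed] <- .WALL
  new("LatticeState", grid = grid,
      lineage = matrix(0L, nrow(grid), ncol(grid)),
      mask = mask, species = species, stepIndex = 0L,
      newborns = .emptyNewborns(), neighborhood = match.arg(neighborhood))
}

#' @rdname LatticeState-class
#' @export
setMethod("stateGrid", "LatticeState", function(x) x@grid)

#' @rdname LatticeState-class
#' @export
setMethod("stepIndex", "LatticeState", function(x) x@stepIndex)

#' @rdname LatticeState-class
#' @export
setMethod("newborns", "LatticeState", function(x) x@newborns)

#' @rdname LatticeState-class
#' @export
setMethod("speciesList", "LatticeState", function(x) x@species)

#' @rdname LatticeState-class
#' @export
setMethod("dim", "LatticeState", function(x) dim(x@grid))

setMethod("show", "LatticeState", function(object) {
  cat("LatticeState after step ", object@stepIndex, "\n", sep = "")
  cnt <- countStates(object)
  cat("  ", paste(names(cnt), cnt, sep = ": ", collapse = ", "), "\n", sep = "")
})

#' @describeIn countStates pixel counts over all reserved and species
#'   codes; the sum equals `prod(dim(x))`.
#' @export
setMethod("countStates", "LatticeState", function(x) {
  nm <- c("empty", "wall", "dead", "drug", .speciesNames(x@species))
  codes <- c(.EMPTY, .WALL, .DEAD, .DRUG, seq_along(x@species))
  cnt <- vapply(codes, function(k) sum(x@grid == k), integer(1L))
  stats::setNames(cnt, nm)
})

#' Place cells of one species on the lattice
#'
#' Seeded cells are ordinary live cells but are not subject to the
#' newborn death lottery (the initial population enters the growth law
#' undiscounted).
#'
#' @param state a [LatticeState-class].
#' @param positions (row, col) matrix of pixels; each must be an allowed,
#'   currently empty pixel.
#' @param species species name or code.
#' @return The updated state.
#' @export
seedCells <- function(state, positions, species) {
  stopifnot(is(state, "LatticeState"))
  i <- .speciesIndex(state@species, species)
  pos <- .asPixelMatrix(positions)
  nr <- nrow(state@grid)
  bad <- pos[, 1L] < 1L | pos[, 1L] > nr | pos[, 2L] < 1L |
    pos[, 2L] > ncol(state@grid)
  if (any(bad))
    stop("seed position outside the lattice: (",
         paste(pos[which(bad)[1L], ], collapse = ", "), ")", call. = FALSE)
  idx <- .rcToIdx(pos, nr)
  if (anyDuplicated(idx))
    stop("duplicated seed position for species '",
         state@species[[i]]@name, "'", call. = FALSE)
  occ <- state@grid[idx] != .EMPTY
  if (any(occ)) {
    k <- which(occ)[1L]
    what <- if (state@grid[idx[k]] == .WALL) "a wall" else "an occupied"
    stop("seed for species '", state@species[[i]]@name, "' lands on ",
         what, " pixel at (", pos[k, 1L], ", ", pos[k, 2L], ")",
         call. = FALSE)
  }
  state@grid[idx] <- i
  state@lineage[idx] <- i
  state
}
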
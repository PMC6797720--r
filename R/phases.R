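## The automaton's phase-ordered step.
##
## All phases are synchronous: decisions are computed from a snapshot of
## the grid taken before the phase writes anything, so a chain of
## invasions advances one link per step and proliferation claims cannot
## cascade within a step. All stochastic draws consume the run's single
## RNG stream, scanning affected pixel sets row-major, so a fixed seed
## reproduces trajectories bit-for-bit.

## Proliferation sources of species i: its live cells plus its dead
## cells. Dead pixels persist, occupy their pixel and are never
## re-colonised, but the colony front propagates past them — the discrete
## counterpart of the discounted growth law, in which each step's ring of
## newborns is thinned by (1 - P_d) while the colony keeps expanding.
.sources <- function(grid, lineage, i) {
  grid == i | (grid == .DEAD & lineage == i)
}

.claims <- function(grid, lineage, i, nbAny = .vnAny) {
  nbAny(.sources(grid, lineage, i)) & grid == .EMPTY
}

#' Proliferation phase for one species
#'
#' Every empty allowed pixel with at least one von Neumann (4-) neighbour
#' belonging to the species' colony becomes a newborn of that species,
#' synchronously from the pre-phase snapshot. An isolated cell in an open
#' region therefore produces exactly 4 newborns, and an unobstructed
#' colony grows as the von Neumann ball (2n^2 + 2n + 1 pixels after n
#' firings).
#'
#' @param state a [LatticeState-class].
#' @param species species name or code.
#' @return The updated state; the newborn set is available via
#'   [newborns()]. No-op if the species has no colony.
#' @seealso [deathPhase()], [caStep()]
#' @export
proliferatePhase <- function(state, species) {
  stopifnot(is(state, "LatticeState"))
  i <- .speciesIndex(state@species, species)
  nr <- nrow(state@grid)
  nbAny <- .neighborFn(state@neighborhood)
  idx <- .rowMajor(which(.claims(state@grid, state@lineage, i, nbAny)), nr)
  state@grid[idx] <- i
  state@lineage[idx] <- i
  rc <- .idxToRC(idx, nr)
  state@newborns <- data.frame(row = rc[, 1L], col = rc[, 2L],
                               species = rep(i, length(idx)))
  state
}

#' Newborn death phase
#'
#' Each pixel in the state's newborn registry independently enters the
#' absorbing dead state with its species' death probability (or the
#' override `deathProb`). Dead pixels persist forever, still occupy their
#' pixel, and are rendered red; cells that survive are ordinary live
#' cells. Draws scan the newborn set by species registration order, then
#' row-major.
#'
#' @param state a [LatticeState-class] whose newborn registry was filled
#'   by the current step's proliferation.
#' @param deathProb optional numeric override in \[0, 1\] applied to all
#'   newborns regardless of species.
#' @return The updated state.
#' @export
deathPhase <- function(state, deathProb = NULL) {
  stopifnot(is(state, "LatticeState"))
  if (!is.null(deathProb) &&
      (length(deathProb) != 1L || is.na(deathProb) || deathProb < 0 ||
       deathProb > 1))
    stop("'deathProb' must be in [0, 1]", call. = FALSE)
  nb <- state@newborns
  if (!nrow(nb)) return(state)
  nr <- nrow(state@grid)
  for (i in sort(unique(nb$species))) {
    p <- if (is.null(deathProb)) state@species[[i]]@deathProb else deathProb
    if (p <= 0) next
    rows <- nb[nb$species == i, , drop = FALSE]
    idx <- .rowMajor(.rcToIdx(as.matrix(rows[, c("row", "col")]), nr), nr)
    dead <- stats::runif(length(idx)) < p
    state@grid[idx[dead]] <- .DEAD
  }
  state
}

#' Invasion phase
#'
#' Every non-invasive live cell with at least one von Neumann neighbour
#' carrying an invasive species (pre-phase snapshot) converts to that
#' invasive species. The phase is synchronous, so a chain of cells
#' converts one link per step. When several invasive species are adjacent
#' to the same cell, the earliest-registered one wins. A species'
#' `conversionProb` below 1 makes each eligible conversion an independent
#' Bernoulli draw (row-major scan).
#'
#' @param state a [LatticeState-class].
#' @return The updated state (unchanged if no species is invasive).
#' @export
invasionPhase <- function(state) {
  stopifnot(is(state, "LatticeState"))
  inv <- which(vapply(state@species, function(s) s@invasive, logical(1L)))
  if (!length(inv)) return(state)
  snap <- state@grid
  nr <- nrow(snap)
  nbAny <- .neighborFn(state@neighborhood)
  nsp <- length(state@species)
  convertible <- matrix(FALSE, nr, ncol(snap))
  for (j in setdiff(seq_len(nsp), inv)) convertible <- convertible | snap == j
  taken <- matrix(FALSE, nr, ncol(snap))
  for (i in inv) {
    cand <- convertible & nbAny(snap == i) & !taken
    idx <- .rowMajor(which(cand), nr)
    if (!length(idx)) next
    p <- state@species[[i]]@conversionProb
    if (p < 1) idx <- idx[stats::runif(length(idx)) < p]
    state@grid[idx] <- i
    state@lineage[idx] <- i
    taken[idx] <- TRUE
  }
  state
}

#' Drug diffusion and interaction phase for one event
#'
#' Implements the two halves of a drug event at global step `step`:
#' (a) at the activation step the event's empty source pixels become
#' drug; on later steps whose offset from activation is a multiple of the
#' event's diffusion period, every empty allowed pixel with a von Neumann
#' drug neighbour becomes drug (the agent diffuses with its own dynamic,
#' through free medium only — it displaces neither live nor dead cells);
#' (b) at every step since activation, live cells of the target species
#' adjacent to drug convert to the absorbing, non-proliferating
#' drug-affected state (rendered with the same pink code). Non-target
#' species are never affected.
#'
#' @param state a [LatticeState-class].
#' @param event a [DrugEvent-class].
#' @param step the global step being computed (default: the next one).
#' @return The updated state.
#' @export
drugPhase <- function(state, event, step = stepIndex(state) + 1L) {
  stopifnot(is(state, "LatticeState"), is(event, "DrugEvent"))
  if (step < event@activationStep) return(state)
  t <- .speciesIndex(state@species, event@targetSpecies)
  nbAny <- .neighborFn(state@neighborhood)
  nr <- nrow(state@grid)
  if (step == event@activationStep) {
    idx <- .rcToIdx(event@sources, nr)
    if (any(state@grid[idx] == .WALL))
      stop("drug source on a wall pixel", call. = FALSE)
    ## empty sources become drug; a source already occupied by the target
    ## species is hit directly; other occupancies are left untouched
    state@grid[idx[state@grid[idx] %in% c(.EMPTY, t)]] <- .DRUG
  } else if ((step - event@activationStep) %% event@diffusionPeriod == 0L) {
    spread <- nbAny(state@grid == .DRUG) & state@grid == .EMPTY
    state@grid[spread] <- .DRUG
  }
  hit <- state@grid == t & nbAny(state@grid == .DRUG)
  state@grid[hit] <- .DRUG
  state
}

.firesAt <- function(sp, step, firingSteps = NULL) {
  if (!is.null(firingSteps)) return(step %in% firingSteps)
  if (!is.null(sp@schedule))
    stop("species '", sp@name, "' has a day schedule; advance it through ",
         "a SimulationConfig so the schedule can be mapped to steps",
         call. = FALSE)
  step %% sp@period == 0L
}

#' Advance the automaton by one global step
#'
#' Executes, in order: (1) for each species whose schedule fires this
#' step, the proliferation phase (claims computed synchronously from a
#' common snapshot, with empty pixels claimed by several species awarded
#' uniformly at random among the claimants) followed by the newborn death
#' phase; (2) the invasion phase; (3) the drug phase for each active
#' event, in registration order. The step index increments by exactly 1.
#' The trajectory is fully deterministic given the RNG seed.
#'
#' @param state a [LatticeState-class].
#' @param config optional [SimulationConfig-class]; required when any
#'   species uses a day schedule (it provides the steps-per-day clock and
#'   drug events). Without a config, species fire by `period` and no drug
#'   events run.
#' @return The updated state.
#' @examples
#' st <- LatticeState(DeviceMask(matrix(TRUE, 11, 11)),
#'                    list(SpeciesSpec("a")))
#' st <- seedCells(st, c(6, 6), "a")
#' st <- caStep(st)
#' countStates(st)[["a"]]  # 1 seed + 4 newborns
#' @export
caStep <- function(state, config = NULL) {
  stopifnot(is(state, "LatticeState"))
  s <- state@stepIndex + 1L
  nr <- nrow(state@grid)
  firingSteps <- if (!is.null(config)) .configFiringSteps(config) else NULL
  firing <- which(vapply(seq_along(state@species), function(i)
    .firesAt(state@species[[i]], s,
             if (is.null(firingSteps)) NULL else firingSteps[[i]]),
    logical(1L)))
  state@newborns <- .emptyNewborns()
  if (length(firing)) {
    snapGrid <- state@grid
    snapLin <- state@lineage
    nbAny <- .neighborFn(state@neighborhood)
    claims <- lapply(firing, function(i) .claims(snapGrid, snapLin, i, nbAny))
    if (length(firing) == 1L) {
      winner <- list(.rowMajor(which(claims[[1L]]), nr))
    } else {
      total <- Reduce(`+`, claims)
      winner <- lapply(claims, function(cl) .rowMajor(which(cl & total == 1L), nr))
      conf <- .rowMajor(which(total > 1L), nr)
      if (length(conf)) {
        claimMat <- vapply(claims, function(cl) cl[conf], logical(length(conf)))
        claimMat <- matrix(claimMat, nrow = length(conf))
        draws <- stats::runif(length(conf))
        for (j in seq_along(conf)) {
          cs <- which(claimMat[j, ])
          w <- cs[max(1L, ceiling(draws[j] * length(cs)))]
          winner[[w]] <- c(winner[[w]], conf[j])
        }
      }
    }
    nbAll <- list()
    for (k in seq_along(firing)) {
      i <- firing[k]
      idx <- .rowMajor(winner[[k]], nr)
      state@grid[idx] <- i
      state@lineage[idx] <- i
      rc <- .idxToRC(idx, nr)
      nbAll[[k]] <- data.frame(row = rc[, 1L], col = rc[, 2L],
                               species = rep(i, length(idx)))
    }
    state@newborns <- do.call(rbind, nbAll)
    state <- deathPhase(state)
  }
  state <- invasionPhase(state)
  if (!is.null(config)) {
    for (ev in config@drugEvents) state <- drugPhase(state, ev, step = s)
  }
  state@stepIndex <- s
  state
}
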
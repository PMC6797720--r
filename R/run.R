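#' Default rendering palette for a state
#'
#' Bit-exact defaults: empty white `[255,255,255]`, wall black `[0,0,0]`,
#' dead red `[255,0,0]`, drug / drug-affected pink `[255,105,180]`, then
#' each species' own colour.
#'
#' @param state a [LatticeState-class].
#' @return Named list mapping state-code names to RGB triples (0..255).
#' @export
defaultPalette <- function(state) {
  pal <- .PALETTE_RESERVED
  for (sp in state@species) pal[[sp@name]] <- sp@color
  pal
}

#' Render a lattice state as an RGB image
#'
#' Pixel-for-pixel image of the lattice in the palette's colours.
#'
#' @param state a [LatticeState-class].
#' @param palette named list of RGB triples as from [defaultPalette()];
#'   every code present in the state must be covered.
#' @return numeric H x W x 3 array with values in \[0, 1\] (multiples of
#'   1/255, so the 8-bit PNG round trip is exact).
#' @export
renderFrame <- function(state, palette = defaultPalette(state)) {
  stopifnot(is(state, "LatticeState"))
  codes <- c(empty = .EMPTY, wall = .WALL, dead = .DEAD, drug = .DRUG,
             stats::setNames(seq_along(state@species),
                             .speciesNames(state@species)))
  present <- unique(as.vector(state@grid))
  d <- dim(state@grid)
  img <- array(0, c(d, 3L))
  for (code in present) {
    nm <- names(codes)[match(code, codes)]
    col <- palette[[nm]]
    if (is.null(col))
      stop("palette has no entry for state code '", nm, "' (", code, ")",
           call. = FALSE)
    sel <- state@grid == code
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- col[ch] / 255
      img[, , ch] <- plane
    }
  }
  img
}

#' @rdname renderFrame
#' @param path output PNG path.
#' @export
writeFrame <- function(state, path, palette = defaultPalette(state)) {
  png::writePNG(renderFrame(state, palette), path)
  invisible(path)
}

#' @rdname RunSummary-class
#' @export
setMethod("countsTable", "RunSummary", function(x) x@counts)

#' @rdname RunSummary-class
#' @export
setMethod("provenance", "RunSummary", function(x) x@provenance)

setMethod("show", "RunSummary", function(object) {
  n <- nrow(object@counts)
  cat("RunSummary: ", n - 1L, " steps, rng seed ",
      object@provenance$rngSeed, "\n", sep = "")
  cat("  final counts: ",
      paste(names(object@counts)[-1L], unlist(object@counts[n, -1L]),
            sep = ": ", collapse = ", "), "\n", sep = "")
})

.logLine <- function(con, level, ...) {
  if (!is.null(con))
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level,
                      "] ", ...), con)
}

#' Run a configured simulation
#'
#' Seeds the lattice, runs `totalSteps` automaton steps under the
#' config's RNG seed, and records the per-step state-code counts. With an
#' output directory, writes `counts.csv` (header
#' `step,empty,wall,dead,drug,<species...>`), rendered PNG frames
#' (`frame_%06d.png` at the configured stride plus `final.png`) and a
#' `run.log`.
#'
#' @param config a [SimulationConfig-class]; invalid configs abort with
#'   the full issue list before any step runs.
#' @param outDir optional output directory (created if missing).
#' @param framesEvery overrides the config's frame stride.
#' @return A [RunSummary-class].
#' @examples
#' cfg <- simulationConfig(DeviceMask(matrix(TRUE, 15, 15)),
#'                         list(SpeciesSpec("a", deathProb = 0.3)),
#'                         seeds = list(a = c(8, 8)),
#'                         totalSteps = 5, rngSeed = 7)
#' runSimulation(cfg)
#' @export
runSimulation <- function(config, outDir = NULL, framesEvery = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  issues <- validateConfig(config)
  if (length(issues))
    stop("invalid simulation config:\n  - ",
         paste(issues, collapse = "\n  - "), call. = FALSE)
  if (is.null(framesEvery)) framesEvery <- config@frameStride
  log <- NULL
  if (!is.null(outDir)) {
    if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
      stop("cannot create output directory: ", outDir, call. = FALSE)
    log <- file(file.path(outDir, "run.log"), open = "wt")
    on.exit(close(log))
  }
  hash <- configHash(config)
  .logLine(log, "INFO", "config ", hash, ", rng seed ", config@rngSeed)
  state <- initialState(config)
  set.seed(config@rngSeed)
  nsteps <- config@totalSteps
  counts <- matrix(0L, nsteps + 1L, 4L + length(config@species))
  counts[1L, ] <- countStates(state)
  frame <- function(st) {
    if (is.null(outDir)) return()
    writeFrame(st, file.path(outDir,
                             sprintf("frame_%06d.png", stepIndex(st))))
  }
  if (!is.na(framesEvery)) frame(state)
  for (s in seq_len(nsteps)) {
    state <- caStep(state, config)
    counts[s + 1L, ] <- countStates(state)
    if (!is.na(framesEvery) && s %% framesEvery == 0L) frame(state)
  }
  df <- data.frame(step = 0:nsteps, counts)
  names(df) <- c("step", "empty", "wall", "dead", "drug",
                 .speciesNames(config@species))
  if (!is.null(outDir)) {
    utils::write.csv(df, file.path(outDir, "counts.csv"),
                     row.names = FALSE, quote = FALSE)
    writeFrame(state, file.path(outDir, "final.png"))
    .logLine(log, "INFO", "completed ", nsteps, " steps; final live ",
             sum(df[nsteps + 1L, .speciesNames(config@species)]))
  }
  new("RunSummary", counts = df,
      provenance = list(configHash = hash, rngSeed = config@rngSeed,
                        version = as.character(utils::packageVersion("chipCA"))))
}
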
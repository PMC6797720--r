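#' Build a simulation configuration
#'
#' @param mask a [DeviceMask-class], a [DeviceSpec-class] (rasterised via
#'   [makeDevice()]) or a path to a mask image (read via [loadMask()]).
#' @param species list of [SpeciesSpec-class].
#' @param seeds named list mapping species names to (row, col) matrices
#'   of seed pixels.
#' @param drugEvents list of [DrugEvent-class].
#' @param totalSteps number of global steps to run (>= 0).
#' @param stepsPerDay clock mapping schedule day intervals to steps.
#' @param rngSeed integer seed for the run's RNG stream.
#' @param frameStride write a rendered frame every this many steps
#'   (`NA`: final frame only).
#' @param validate if `TRUE` (default) fail with the complete list of
#'   violations; `FALSE` returns the object unchecked so that
#'   [validateConfig()] can enumerate its issues.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(mask, species, seeds, drugEvents = list(),
                             totalSteps, stepsPerDay = 4, rngSeed = 1,
                             frameStride = NA, validate = TRUE) {
  if (is.character(mask)) mask <- loadMask(mask)
  if (is(mask, "DeviceSpec")) mask <- makeDevice(mask)
  if (is(species, "SpeciesSpec")) species <- list(species)
  seeds <- lapply(seeds, .asPixelMatrix)
  config <- new("SimulationConfig", mask = mask, species = species,
                seeds = seeds, drugEvents = drugEvents,
                totalSteps = as.integer(totalSteps),
                stepsPerDay = as.integer(stepsPerDay),
                rngSeed = as.integer(rngSeed),
                frameStride = as.integer(frameStride))
  if (validate) {
    issues <- validateConfig(config)
    if (length(issues))
      stop("invalid simulation config:\n  - ",
           paste(issues, collapse = "\n  - "), call. = FALSE)
  }
  config
}

#' Validate a simulation configuration
#'
#' Checks the whole configuration and returns every violation found (not
#' fail-fast): species definitions, seed placements against the mask,
#' drug events, schedules against the step clock.
#'
#' @param config a [SimulationConfig-class] (validity is implemented via
#'   this function, so `new()` also reports the full list).
#' @return Character vector of issues; empty when the configuration is
#'   valid.
#' @export
validateConfig <- function(config) {
  issues <- character()
  oMsg <- function(o) {
    v <- methods::validObject(o, test = TRUE)
    if (isTRUE(v)) character() else v
  }
  issues <- c(issues, oMsg(config@mask))
  if (!length(config@species))
    issues <- c(issues, "no species defined")
  badSpecies <- FALSE
  for (sp in config@species) {
    if (!is(sp, "SpeciesSpec")) {
      issues <- c(issues, "species list contains a non-SpeciesSpec entry")
      badSpecies <- TRUE
      next
    }
    m <- oMsg(sp)
    if (length(m)) {
      issues <- c(issues, paste0("species '", sp@name, "': ", m))
      badSpecies <- TRUE
    }
  }
  nm <- tryCatch(.speciesNames(config@species), error = function(e) character())
  if (anyDuplicated(nm))
    issues <- c(issues, paste0("species defined more than once: ",
                               paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (length(config@totalSteps) != 1L || is.na(config@totalSteps) ||
      config@totalSteps < 0L)
    issues <- c(issues, "'totalSteps' must be >= 0")
  if (length(config@stepsPerDay) != 1L || is.na(config@stepsPerDay) ||
      config@stepsPerDay < 1L)
    issues <- c(issues, "'stepsPerDay' must be >= 1")
  if (length(config@rngSeed) != 1L || is.na(config@rngSeed))
    issues <- c(issues, "'rngSeed' must be an integer")

  a <- config@mask@allowed
  nr <- nrow(a)
  ncx <- ncol(a)
  inLattice <- function(pos) pos[, 1L] >= 1L & pos[, 1L] <= nr &
    pos[, 2L] >= 1L & pos[, 2L] <= ncx
  seen <- integer()
  for (s in names(config@seeds)) {
    if (!s %in% nm) {
      issues <- c(issues, paste0("seeds reference undefined species '", s, "'"))
      next
    }
    pos <- config@seeds[[s]]
    bad <- !inLattice(pos)
    for (k in which(bad))
      issues <- c(issues, paste0("seed for '", s, "' at (", pos[k, 1L], ", ",
                                 pos[k, 2L], ") is outside the lattice"))
    if (any(!bad)) {
      idx <- .rcToIdx(pos[!bad, , drop = FALSE], nr)
      for (k in which(!a[idx]))
        issues <- c(issues, paste0("seed for '", s, "' at (",
                                   pos[!bad, , drop = FALSE][k, 1L], ", ",
                                   pos[!bad, , drop = FALSE][k, 2L],
                                   ") is on a wall pixel"))
      dup <- idx[idx %in% seen]
      if (length(dup)) {
        rc <- .idxToRC(dup[1L], nr)
        issues <- c(issues, paste0("seed for '", s, "' at (", rc[1L, 1L], ", ",
                                   rc[1L, 2L], ") collides with another seed"))
      }
      seen <- c(seen, idx)
    }
  }
  for (ev in config@drugEvents) {
    m <- oMsg(ev)
    if (length(m)) {
      issues <- c(issues, paste0("drug event: ", m))
      next
    }
    if (!ev@targetSpecies %in% nm)
      issues <- c(issues, paste0("drug event targets undefined species '",
                                 ev@targetSpecies, "'"))
    else if (!badSpecies) {
      sp <- config@species[[match(ev@targetSpecies, nm)]]
      if (!sp@drugSensitive)
        issues <- c(issues, paste0("drug event targets species '",
                                   ev@targetSpecies,
                                   "' which is not drug-sensitive"))
    }
    bad <- !inLattice(ev@sources)
    for (k in which(bad))
      issues <- c(issues, paste0("drug source at (", ev@sources[k, 1L], ", ",
                                 ev@sources[k, 2L], ") is outside the lattice"))
    if (any(!bad)) {
      idx <- .rcToIdx(ev@sources[!bad, , drop = FALSE], nr)
      for (k in which(!a[idx]))
        issues <- c(issues, paste0("drug source at (",
                                   ev@sources[!bad, , drop = FALSE][k, 1L], ", ",
                                   ev@sources[!bad, , drop = FALSE][k, 2L],
                                   ") is on a wall pixel"))
    }
  }
  ## schedules must fit the step clock
  if (!badSpecies) {
    for (sp in config@species) {
      if (is.null(sp@schedule)) next
      m <- tryCatch({
        scheduleFirings(sp@schedule, config@stepsPerDay)
        character()
      }, error = function(e) conditionMessage(e))
      if (length(m) && nzchar(m[1L]))
        issues <- c(issues, paste0("species '", sp@name, "' schedule: ", m))
    }
  }
  issues
}

## firing steps per species (NULL entry = fire by period)
.configFiringSteps <- function(config) {
  lapply(config@species, function(sp) {
    if (is.null(sp@schedule)) NULL
    else scheduleFirings(sp@schedule, config@stepsPerDay)
  })
}

#' Seeded initial lattice state of a configuration
#'
#' @param config a [SimulationConfig-class].
#' @return A [LatticeState-class] at step 0 with all seeds placed.
#' @export
initialState <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  state <- LatticeState(config@mask, config@species)
  for (s in names(config@seeds))
    state <- seedCells(state, config@seeds[[s]], s)
  state
}

## Canonical plain-list form of a config: the basis of the provenance
## hash and of the YAML serialisation.
.configToList <- function(config) {
  sp <- lapply(config@species, function(s) {
    out <- list(name = s@name, color = as.integer(s@color),
                death_prob = s@deathProb,
                invasive = s@invasive, drug_sensitive = s@drugSensitive,
                conversion_prob = s@conversionProb)
    if (is.null(s@schedule)) out$period <- s@period
    else out$schedule <- lapply(seq_len(nrow(s@schedule)), function(i)
      list(day_start = s@schedule$day_start[i],
           day_end = s@schedule$day_end[i],
           iterations = as.integer(s@schedule$iterations[i])))
    out
  })
  ev <- lapply(config@drugEvents, function(e)
    list(activation_step = e@activationStep,
         sources = lapply(seq_len(nrow(e@sources)), function(i)
           as.integer(e@sources[i, ])),
         diffusion_period = e@diffusionPeriod,
         target_species = e@targetSpecies))
  list(
    mask = list(allowed = apply(config@mask@allowed, 1L, function(r)
                  paste(as.integer(r), collapse = "")),
                pixel_size_um = config@mask@pixelSizeUm,
                origin_um = as.numeric(config@mask@originUm)),
    species = sp,
    seeds = lapply(config@seeds, function(p)
      lapply(seq_len(nrow(p)), function(i) as.integer(p[i, ]))),
    drug_events = ev,
    total_steps = config@totalSteps,
    steps_per_day = config@stepsPerDay,
    rng_seed = config@rngSeed,
    frame_stride = config@frameStride
  )
}

#' @rdname loadConfig
#' @param config a [SimulationConfig-class].
#' @export
configHash <- function(config) {
  digest::digest(.configToList(config), algo = "sha256")
}

.num <- function(x, default = NULL) if (is.null(x)) default else as.numeric(x)

.parseSpeciesEntry <- function(e) {
  dp <- e$death_prob
  if (is.null(dp)) dp <- e$p_d
  if (is.null(dp)) dp <- e$p_m  # P_d and P_m are aliases for one quantity
  if (is.null(dp)) dp <- 0
  sched <- NULL
  if (!is.null(e$schedule)) {
    if (!is.null(e$schedule$preset)) sched <- presetSchedule(e$schedule$preset)
    else sched <- do.call(rbind, lapply(e$schedule, function(iv)
      data.frame(day_start = iv$day_start, day_end = iv$day_end,
                 iterations = as.integer(iv$iterations))))
  }
  SpeciesSpec(name = e$name,
              color = if (is.null(e$color)) c(0L, 255L, 0L) else unlist(e$color),
              deathProb = dp,
              period = .num(e$period, 1),
              schedule = sched,
              invasive = isTRUE(e$invasive),
              drugSensitive = isTRUE(e$drug_sensitive),
              conversionProb = .num(e$conversion_prob, 1))
}

.parseMaskEntry <- function(m, pixelSizeUm, dir = ".") {
  if (!is.null(m$image)) {
    path <- m$image
    if (!file.exists(path)) path <- file.path(dir, m$image)
    return(loadMask(path, threshold = .num(m$threshold, 128),
                    pixelSizeUm = pixelSizeUm))
  }
  if (!is.null(m$allowed)) {  # canonical row-string form
    rows <- lapply(m$allowed, function(r)
      as.integer(strsplit(r, "")[[1L]]) == 1L)
    return(DeviceMask(do.call(rbind, rows), pixelSizeUm = pixelSizeUm,
                      originUm = if (is.null(m$origin_um)) c(0, 0)
                                 else unlist(m$origin_um)))
  }
  if (is.null(m$kind)) stop("mask entry needs 'kind', 'image' or 'allowed'",
                            call. = FALSE)
  args <- list(kind = m$kind, pixelSizeUm = pixelSizeUm)
  map <- c(well_radius_um = "wellRadiusUm", channel_width_um = "channelWidthUm",
           channel_length_um = "channelLengthUm", n_channels = "nChannels",
           chamber_radius_um = "chamberRadiusUm",
           chamber_width_um = "chamberWidthUm",
           chamber_height_um = "chamberHeightUm", n_chambers = "nChambers",
           connector_width_um = "connectorWidthUm",
           connector_length_um = "connectorLengthUm")
  for (k in names(map)) if (!is.null(m[[k]])) args[[map[[k]]]] <- m[[k]]
  if (!is.null(m$shapes))
    args$shapes <- lapply(m$shapes, function(s) {
      s[c("cx", "cy", "r", "w", "h", "angle")] <-
        lapply(s[c("cx", "cy", "r", "w", "h", "angle")], .num)
      s[!vapply(s, is.null, logical(1L))]
    })
  makeDevice(do.call(deviceSpec, args))
}

#' Load / save a simulation configuration as YAML
#'
#' The YAML schema mirrors [simulationConfig()]: a `mask` entry (an
#' `image` path, a synthetic device `kind` with its `*_um` parameters, or
#' a canonical `allowed` row-string grid), a `species` list (fields
#' `name`, `color`, `death_prob` — aliases `p_d`/`p_m` accepted —
#' `period` or `schedule`, `invasive`, `drug_sensitive`), `seeds`,
#' `drug_events`, `total_steps`, `steps_per_day`, `rng_seed`,
#' `frame_stride`. Pixel coordinates are 0-free: 1-based (row, col) with
#' the origin at the top-left, rows increasing downward.
#'
#' @param path YAML file path.
#' @return `loadConfig` returns a validated [SimulationConfig-class];
#'   `saveConfig` writes the canonical form and returns `path`
#'   invisibly; `configHash` returns the sha256 hash of the canonical
#'   form (recorded in run provenance).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse config ", path, ": ", conditionMessage(e),
         call. = FALSE))
  pixelSizeUm <- .num(y$pixel_size_um, 20)
  ## collect every violation (not fail-fast) so a broken config reports
  ## its complete issue list in one pass
  issues <- character()
  note <- function(where, e) issues <<- c(issues,
    paste0(where, ": ", conditionMessage(e)))
  mask <- tryCatch(.parseMaskEntry(y$mask, pixelSizeUm, dir = dirname(path)),
                   error = function(e) { note("mask", e); NULL })
  species <- list()
  for (e in y$species) {
    sp <- tryCatch(.parseSpeciesEntry(e),
                   error = function(err) {
                     note(paste0("species '", e$name, "'"), err)
                     NULL
                   })
    if (!is.null(sp)) species <- c(species, sp)
  }
  events <- list()
  for (e in y$drug_events) {
    ev <- tryCatch(
      DrugEvent(activationStep = e$activation_step,
                sources = do.call(rbind, lapply(e$sources, unlist)),
                diffusionPeriod = .num(e$diffusion_period, 1),
                targetSpecies = e$target_species),
      error = function(err) { note("drug event", err); NULL })
    if (!is.null(ev)) events <- c(events, ev)
  }
  seeds <- lapply(y$seeds, function(p) do.call(rbind, lapply(p, unlist)))
  if (length(issues))
    stop("invalid simulation config (", path, "):\n  - ",
         paste(issues, collapse = "\n  - "), call. = FALSE)
  simulationConfig(mask = mask, species = species, seeds = seeds,
                   drugEvents = events, totalSteps = y$total_steps,
                   stepsPerDay = .num(y$steps_per_day, 4),
                   rngSeed = .num(y$rng_seed, 1),
                   frameStride = .num(y$frame_stride, NA))
}

#' @rdname loadConfig
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  lst <- .configToList(config)
  lst$pixel_size_um <- config@mask@pixelSizeUm
  if (is.na(lst$frame_stride)) lst$frame_stride <- NULL
  yaml::write_yaml(lst, path)
  invisible(path)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", paste(dim(object@mask@allowed), collapse = " x "),
      " lattice, ", length(object@species), " species (",
      paste(.speciesNames(object@species), collapse = ", "), "), ",
      length(object@drugEvents), " drug event(s), ", object@totalSteps,
      " steps, seed ", object@rngSeed, "\n", sep = "")
})
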
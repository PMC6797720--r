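## Closed-form growth analytics and fitting of per-interval proliferation
## iteration counts to observed growth curves.

#' Expected cell count under unobstructed diamond growth
#'
#' An isolated cell firing the proliferation phase once per iteration
#' adds a ring of 4k newborns at iteration k, each surviving the newborn
#' death lottery with probability (1 - deathProb). The expected live
#' count after n iterations is therefore
#' \deqn{y_n = y_0 (1 + 2 n (n + 1) (1 - P_d))}
#' the exact partial sum of the per-iteration increments
#' \eqn{4 k (1 - P_d)}; `y0` seeds are treated as independent diamonds
#' (counts additive, no crowding). With `deathProb = 0` this reduces to
#' the von Neumann ball size \eqn{2 n^2 + 2 n + 1} for one seed.
#'
#' @param n number of proliferation iterations (nonnegative;
#'   vectorised).
#' @param y0 initial cell count (>= 1); the initial population is not
#'   discounted.
#' @param deathProb per-newborn death probability P_d (written P_m in the
#'   discounted form of the growth law; both name the same quantity).
#' @return Expected live cell count(s).
#' @examples
#' expectedCount(1)              # 5
#' expectedCount(3)              # 25 = 1 + 4 + 8 + 12
#' expectedCount(10, deathProb = 0.3)  # 155
#' @export
expectedCount <- function(n, y0 = 1, deathProb = 0) {
  if (any(n < 0)) stop("'n' must be nonnegative", call. = FALSE)
  if (y0 < 1) stop("'y0' must be >= 1", call. = FALSE)
  if (deathProb < 0 || deathProb > 1)
    stop("'deathProb' must be in [0, 1]", call. = FALSE)
  y0 * (1 + 2 * n * (n + 1) * (1 - deathProb))
}

#' Iterations needed to reproduce an observed fold change
#'
#' Brute-force search over k = 0..kMax for the iteration count whose
#' predicted fold change, starting from `cumulativePrior` already-applied
#' iterations, best matches the observed one; ties break toward smaller
#' k. The fold change is used (rather than absolute counts) because the
#' observed counts are means over culture fields whereas the growth law
#' tracks one colony.
#'
#' @param countStart,countEnd observed mean counts (> 0) at the start and
#'   end of the interval.
#' @param cumulativePrior iterations already applied before this interval.
#' @param deathProb per-newborn death probability used in the growth law.
#' @param kMax search bound (>= 0).
#' @return The fitted iteration count in 0..kMax.
#' @export
iterationsForGrowth <- function(countStart, countEnd, cumulativePrior = 0,
                                deathProb = 0, kMax = 50) {
  if (kMax < 0) stop("'kMax' must be >= 0", call. = FALSE)
  if (countStart <= 0 || countEnd <= 0)
    stop("counts must be positive", call. = FALSE)
  target <- countEnd / countStart
  k <- 0:kMax
  pred <- expectedCount(cumulativePrior + k, deathProb = deathProb) /
    expectedCount(cumulativePrior, deathProb = deathProb)
  k[which.min(abs(pred - target))]
}

#' Fit a proliferation schedule to a growth curve
#'
#' Applies [iterationsForGrowth()] greedily to each consecutive pair of
#' observations, accumulating the fitted iterations, and returns one
#' schedule interval per pair. This reproduces the adjustment procedure
#' that maps mean culture counts per sampling day to the per-interval
#' iteration counts driving the simulator.
#'
#' @param curve growth-curve data.frame with columns `day` (strictly
#'   increasing) and `mean_count` (> 0); an `sd` column is tolerated and
#'   ignored.
#' @param deathProb per-newborn death probability used in the growth law.
#' @param kMax per-interval search bound.
#' @return Schedule data.frame with columns `day_start`, `day_end`,
#'   `iterations`.
#' @examples
#' curve <- data.frame(day = c(1, 3, 5, 7, 9, 11),
#'                     mean_count = expectedCount(cumsum(c(0, 2, 3, 6, 7, 7))))
#' scheduleFromCurve(curve)  # recovers 2, 3, 6, 7, 7
#' @export
scheduleFromCurve <- function(curve, deathProb = 0, kMax = 50) {
  .checkGrowthCurve(curve)
  if (nrow(curve) < 2L)
    stop("a growth curve needs at least 2 observations", call. = FALSE)
  m <- nrow(curve) - 1L
  iters <- integer(m)
  cum <- 0L
  for (i in seq_len(m)) {
    iters[i] <- iterationsForGrowth(curve$mean_count[i],
                                    curve$mean_count[i + 1L],
                                    cumulativePrior = cum,
                                    deathProb = deathProb, kMax = kMax)
    cum <- cum + iters[i]
  }
  data.frame(day_start = curve$day[seq_len(m)],
             day_end = curve$day[seq_len(m) + 1L],
             iterations = iters)
}

.PRESETS <- list(
  ## fitted iteration counts per 2-day culture interval, days 1..11
  N2A = c(2L, 3L, 6L, 7L, 7L),
  MC3T3 = c(2L, 5L, 7L, 8L, 7L)
)

#' Named proliferation-schedule presets
#'
#' Per-interval proliferation iteration counts for the two adherent cell
#' lines used to calibrate the simulator: N2A (mouse neuroblastoma) and
#' MC3T3 (mouse osteoblast precursors), over the five 2-day culture
#' intervals from day 1 to day 11.
#'
#' @param name `"N2A"` or `"MC3T3"`.
#' @return Schedule data.frame (`day_start`, `day_end`, `iterations`).
#' @examples
#' presetSchedule("N2A")
#' @export
presetSchedule <- function(name) {
  if (length(name) != 1L || !name %in% names(.PRESETS))
    stop("unknown schedule preset '", name, "'; available: ",
         paste(names(.PRESETS), collapse = ", "), call. = FALSE)
  data.frame(day_start = c(1, 3, 5, 7, 9), day_end = c(3, 5, 7, 9, 11),
             iterations = .PRESETS[[name]])
}

.checkGrowthCurve <- function(curve) {
  if (!is.data.frame(curve) || !all(c("day", "mean_count") %in% names(curve)))
    stop("a growth curve is a data.frame with columns day, mean_count",
         " (sd optional)", call. = FALSE)
  if (any(diff(curve$day) <= 0))
    stop("growth-curve days must be strictly increasing", call. = FALSE)
  if (any(curve$mean_count <= 0))
    stop("growth-curve counts must be positive", call. = FALSE)
  invisible(curve)
}

#' Read / write growth curves and schedules as CSV
#'
#' Growth curves use the header `day,mean_count,sd` (sd optional);
#' schedules use `day_start,day_end,iterations`.
#'
#' @param path CSV file path.
#' @return `readGrowthCurve` / `readSchedule` return validated
#'   data.frames; the writers return `path` invisibly.
#' @export
readGrowthCurve <- function(path) {
  .checkGrowthCurve(utils::read.csv(path))
}

#' @rdname readGrowthCurve
#' @param curve growth-curve data.frame.
#' @export
writeGrowthCurve <- function(curve, path) {
  .checkGrowthCurve(curve)
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readGrowthCurve
#' @export
readSchedule <- function(path) {
  s <- utils::read.csv(path)
  msg <- .checkScheduleDF(s)
  if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  s
}

#' @rdname readGrowthCurve
#' @param schedule schedule data.frame.
#' @export
writeSchedule <- function(schedule, path) {
  msg <- .checkScheduleDF(schedule)
  if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  utils::write.csv(schedule, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map a day schedule onto global simulation steps
#'
#' Each interval's iterations are distributed evenly across the interval's
#' span of global steps, earliest-first when the division leaves a
#' remainder; interval totals are preserved exactly. Step 0 corresponds
#' to the schedule's first `day_start`.
#'
#' @param schedule schedule data.frame (`day_start`, `day_end`,
#'   `iterations`).
#' @param stepsPerDay number of global steps per culture day.
#' @return Increasing integer vector of firing steps.
#' @examples
#' scheduleFirings(presetSchedule("N2A"), stepsPerDay = 4)
#' @export
scheduleFirings <- function(schedule, stepsPerDay = 4) {
  msg <- .checkScheduleDF(schedule)
  if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  day0 <- schedule$day_start[1L]
  out <- integer()
  for (i in seq_len(nrow(schedule))) {
    k <- schedule$iterations[i]
    if (k == 0L) next
    offset <- round((schedule$day_start[i] - day0) * stepsPerDay)
    m <- round((schedule$day_end[i] - schedule$day_start[i]) * stepsPerDay)
    if (k > m)
      stop("interval ", schedule$day_start[i], "-", schedule$day_end[i],
           " has ", k, " iterations but spans only ", m,
           " steps; increase stepsPerDay", call. = FALSE)
    out <- c(out, offset + floor((seq_len(k) - 1L) * m / k) + 1L)
  }
  as.integer(out)
}
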
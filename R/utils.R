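## Internal lattice helpers shared by the automaton phases.

## TRUE wherever at least one of the 4 von Neumann neighbours of a pixel
## is TRUE in `m`. Handles 1-row / 1-column matrices.
.vnAny <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  res <- matrix(FALSE, nr, nc)
  if (nr > 1L) {
    res[-1L, ] <- res[-1L, , drop = FALSE] | m[-nr, , drop = FALSE]
    res[-nr, ] <- res[-nr, , drop = FALSE] | m[-1L, , drop = FALSE]
  }
  if (nc > 1L) {
    res[, -1L] <- res[, -1L, drop = FALSE] | m[, -nc, drop = FALSE]
    res[, -nc] <- res[, -nc, drop = FALSE] | m[, -1L, drop = FALSE]
  }
  res
}

## Moore (8-neighbour) variant: von Neumann neighbours plus diagonals.
.mooreAny <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  res <- .vnAny(m)
  if (nr > 1L && nc > 1L) {
    res[-1L, -1L] <- res[-1L, -1L, drop = FALSE] | m[-nr, -nc, drop = FALSE]
    res[-nr, -nc] <- res[-nr, -nc, drop = FALSE] | m[-1L, -1L, drop = FALSE]
    res[-1L, -nc] <- res[-1L, -nc, drop = FALSE] | m[-nr, -1L, drop = FALSE]
    res[-nr, -1L] <- res[-nr, -1L, drop = FALSE] | m[-1L, -nc, drop = FALSE]
  }
  res
}

.neighborFn <- function(neighborhood) {
  switch(neighborhood, von_neumann = .vnAny, moore = .mooreAny,
         stop("unknown neighborhood '", neighborhood, "'", call. = FALSE))
}

## Linear (column-major) indices reordered row-major, i.e. by (row, col).
## All stochastic draws scan affected pixel sets in this order so that a
## fixed seed reproduces trajectories bit-for-bit.
.rowMajor <- function(idx, nr) {
  if (length(idx) < 2L) return(idx)
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  idx[order(r, c)]
}

.idxToRC <- function(idx, nr) {
  cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}

.rcToIdx <- function(rc, nr) {
  (as.integer(rc[, 2L]) - 1L) * nr + as.integer(rc[, 1L])
}

.asPixelMatrix <- function(positions) {
  if (is.data.frame(positions)) positions <- as.matrix(positions[, 1:2])
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2L, byrow = TRUE)
  storage.mode(positions) <- "integer"
  colnames(positions) <- c("row", "col")
  positions
}

.emptyNewborns <- function() {
  data.frame(row = integer(), col = integer(), species = integer())
}

.speciesNames <- function(species) {
  vapply(species, function(s) s@name, character(1L))
}

.speciesIndex <- function(species, name) {
  if (is.numeric(name)) {
    i <- as.integer(name)
    if (i < 1L || i > length(species))
      stop("no species with code ", i, call. = FALSE)
    return(i)
  }
  i <- match(name, .speciesNames(species))
  if (is.na(i))
    stop("unknown species '", name, "'; registered: ",
         paste(.speciesNames(species), collapse = ", "), call. = FALSE)
  i
}
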
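# Independent oracles used to cross-check the package implementation.
# They deliberately avoid the package's vectorised shift machinery:
# everything here is explicit queue-based BFS or per-pixel loops.

.NB4 <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))

# BFS geodesic distance (in 4-connected steps) from the seed pixels
# through allowed pixels; Inf where unreachable.
oracleBFSDist <- function(allowed, seeds) {
  nr <- nrow(allowed)
  nc <- ncol(allowed)
  dist <- matrix(Inf, nr, nc)
  seeds <- matrix(seeds, ncol = 2L)
  queue <- vector("list", sum(allowed))
  head <- 1L
  tail <- 0L
  for (i in seq_len(nrow(seeds))) {
    r <- seeds[i, 1L]; c <- seeds[i, 2L]
    dist[r, c] <- 0
    tail <- tail + 1L
    queue[[tail]] <- c(r, c)
  }
  while (head <= tail) {
    p <- queue[[head]]; head <- head + 1L
    for (k in 1:4) {
      r <- p[1L] + .NB4[k, 1L]; c <- p[2L] + .NB4[k, 2L]
      if (r < 1L || r > nr || c < 1L || c > nc) next
      if (!allowed[r, c] || is.finite(dist[r, c])) next
      dist[r, c] <- dist[p[1L], p[2L]] + 1
      tail <- tail + 1L
      queue[[tail]] <- c(r, c)
    }
  }
  dist
}

# Synchronous flood growth from one seed: occupied pixel count after
# each of `steps` firings (equals #\{dist <= n\} by construction of BFS,
# computed here from the BFS distances).
oracleFloodCounts <- function(allowed, seed, steps) {
  dist <- oracleBFSDist(allowed, seed)
  vapply(seq_len(steps), function(n) sum(dist <= n), numeric(1L))
}

# Flood-fill connected-component labelling (4-connectivity).
oracleComponents <- function(allowed) {
  nr <- nrow(allowed)
  nc <- ncol(allowed)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  for (start in which(allowed & labels == 0L)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    labels[start] <- lab
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- (p - 1L) %% nr + 1L
      c0 <- (p - 1L) %/% nr + 1L
      for (k in 1:4) {
        r <- r0 + .NB4[k, 1L]; c <- c0 + .NB4[k, 2L]
        if (r < 1L || r > nr || c < 1L || c > nc) next
        if (!allowed[r, c]) next
        q <- (c - 1L) * nr + r
        if (labels[q] == 0L) {
          labels[q] <- lab
          stack <- c(stack, q)
        }
      }
    }
  }
  labels
}

# Random blob mask: thresholded smoothed noise, useful as an irregular
# geometry. Guaranteed to keep at least one allowed pixel.
randomBlobMask <- function(nr, nc, fillFraction = 0.55) {
  noise <- matrix(runif(nr * nc), nr, nc)
  smooth <- function(m) {
    k <- rep(1 / 5, 5)
    m <- apply(m, 2L, function(col) stats::filter(col, k, circular = TRUE))
    t(apply(m, 1L, function(row) stats::filter(row, k, circular = TRUE)))
  }
  s <- smooth(smooth(noise))
  allowed <- s >= quantile(s, 1 - fillFraction)
  if (!any(allowed)) allowed[ceiling(nr / 2), ceiling(nc / 2)] <- TRUE
  DeviceMask(allowed)
}

# Count pixels of each palette colour in a rendered frame (the inverse-
# palette classifier).
classifyFrame <- function(img, palette) {
  vapply(palette, function(col) {
    sum(abs(img[, , 1L] - col[1L] / 255) < 1e-9 &
        abs(img[, , 2L] - col[2L] / 255) < 1e-9 &
        abs(img[, , 3L] - col[3L] / 255) < 1e-9)
  }, numeric(1L))
}

# Convenience: open square lattice with one centred seed.
openSeededState <- function(n, species = SpeciesSpec("a")) {
  st <- LatticeState(DeviceMask(matrix(TRUE, n, n)), list(species))
  mid <- (n + 1L) %/% 2L
  seedCells(st, c(mid, mid), 1L)
}

# Edge ring of a logical mask: TRUE pixels 4-adjacent to a FALSE pixel.
.jitterEdge <- function(a) {
  nr <- nrow(a); nc <- ncol(a)
  edge <- matrix(FALSE, nr, nc)
  for (idx in which(a)) {
    r0 <- (idx - 1L) %% nr + 1L
    c0 <- (idx - 1L) %/% nr + 1L
    for (k in 1:4) {
      r <- r0 + .NB4[k, 1L]; c <- c0 + .NB4[k, 2L]
      if (r < 1L || r > nr || c < 1L || c > nc || !a[r, c]) {
        edge[r0, c0] <- TRUE
        break
      }
    }
  }
  edge
}

# Point-in-union test with every shape shrunk by `margin`: a conservative
# strictly-interior test used for rotation-invariance checks.
pointInShapesShrunk <- function(shapes, x, y, margin) {
  inside <- rep(FALSE, length(x))
  for (s in shapes) {
    if (s$type == "disc") {
      if (s$r > margin)
        inside <- inside | ((x - s$cx)^2 + (y - s$cy)^2 <= (s$r - margin)^2)
    } else {
      ang <- if (is.null(s$angle)) 0 else s$angle
      u <- cos(ang) * (x - s$cx) + sin(ang) * (y - s$cy)
      v <- -sin(ang) * (x - s$cx) + cos(ang) * (y - s$cy)
      if (s$w > 2 * margin && s$h > 2 * margin)
        inside <- inside | (abs(u) <= s$w / 2 - margin &
                            abs(v) <= s$h / 2 - margin)
    }
  }
  inside
}
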
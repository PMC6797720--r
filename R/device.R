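#' Describe a synthetic microfluidic device
#'
#' Parametric layouts emulating canonical lab- and organ-on-a-chip
#' geometries. All lengths are micrometres. Supported kinds:
#' \describe{
#'   \item{`single_channel`}{two circular inlet/outlet wells joined by an
#'     axis-aligned rectangular channel. The wells are centred at
#'     `+/-(channelLengthUm/2 + wellRadiusUm)`, tangent to the channel
#'     ends, so `channelLengthUm = 0` yields two disjoint discs.}
#'   \item{`radial`}{a central circular chamber with `nChannels` evenly
#'     spaced rectangular channels, each ending in a circular well.}
#'   \item{`multi_chamber`}{a central horizontal "vascular" channel with
#'     inlet/outlet wells and two rows of rectangular chambers connected
#'     to it by short vertical channels (a metastasis-on-a-chip layout).}
#'   \item{`custom`}{an explicit union of discs and rectangles (used e.g.
#'     for blood-brain-barrier-like layouts); pass
#'     `shapes = list(list(type = "disc", cx =, cy =, r =), list(type =
#'     "rect", cx =, cy =, w =, h =, angle = 0), ...)`.}
#' }
#'
#' @param kind device kind (see above).
#' @param pixelSizeUm lattice resolution (default 20 um = one cell).
#' @param wellRadiusUm,channelWidthUm,channelLengthUm,wellSepUm,
#'   nChannels,chamberRadiusUm,chamberWidthUm,chamberHeightUm,nChambers,
#'   connectorWidthUm,connectorLengthUm,shapes geometric parameters;
#'   which ones are used depends on `kind`. `wellSepUm` (single-channel
#'   only) overrides the centre-to-centre well separation, whose default
#'   `channelLengthUm + 2 * wellRadiusUm` makes the wells tangent to the
#'   channel ends.
#' @return A [DeviceSpec-class].
#' @examples
#' spec <- deviceSpec("single_channel", wellRadiusUm = 400,
#'                    channelWidthUm = 200, channelLengthUm = 2000)
#' makeDevice(spec)
#' @export
deviceSpec <- function(kind, pixelSizeUm = 20,
                       wellRadiusUm = 400, channelWidthUm = 200,
                       channelLengthUm = 2000, wellSepUm = NULL,
                       nChannels = 6,
                       chamberRadiusUm = 500,
                       chamberWidthUm = 600, chamberHeightUm = 400,
                       nChambers = 3,
                       connectorWidthUm = 120, connectorLengthUm = 200,
                       shapes = list()) {
  params <- switch(kind,
    single_channel = c(list(wellRadiusUm = wellRadiusUm,
                            channelWidthUm = channelWidthUm,
                            channelLengthUm = channelLengthUm),
                       if (!is.null(wellSepUm)) list(wellSepUm = wellSepUm)),
    radial = list(wellRadiusUm = wellRadiusUm,
                  channelWidthUm = channelWidthUm,
                  channelLengthUm = channelLengthUm,
                  nChannels = as.integer(nChannels),
                  chamberRadiusUm = chamberRadiusUm),
    multi_chamber = list(wellRadiusUm = wellRadiusUm,
                         channelWidthUm = channelWidthUm,
                         channelLengthUm = channelLengthUm,
                         chamberWidthUm = chamberWidthUm,
                         chamberHeightUm = chamberHeightUm,
                         nChambers = as.integer(nChambers),
                         connectorWidthUm = connectorWidthUm,
                         connectorLengthUm = connectorLengthUm),
    custom = list(shapes = shapes),
    stop("unknown device kind '", kind, "'", call. = FALSE)
  )
  new("DeviceSpec", kind = kind, params = params,
      pixelSizeUm = as.numeric(pixelSizeUm))
}

.disc <- function(cx, cy, r) list(type = "disc", cx = cx, cy = cy, r = r)
.rect <- function(cx, cy, w, h, angle = 0)
  list(type = "rect", cx = cx, cy = cy, w = w, h = h, angle = angle)

#' Shape decomposition of a device spec
#'
#' Returns the union of discs and rectangles (in micrometre coordinates,
#' x rightwards, y downwards) whose rasterisation is the device's allowed
#' region. Exposed so that independent point-in-shape checks can be run
#' against the rasteriser.
#'
#' @param spec a [DeviceSpec-class].
#' @return list of shape descriptors.
#' @export
deviceShapes <- function(spec) {
  stopifnot(is(spec, "DeviceSpec"))
  p <- spec@params
  switch(spec@kind,
    single_channel = {
      r <- p$wellRadiusUm
      L <- p$channelLengthUm
      w <- p$channelWidthUm
      sep <- if (is.null(p$wellSepUm)) L + 2 * r else p$wellSepUm
      shapes <- list(.disc(-sep / 2, 0, r), .disc(sep / 2, 0, r))
      if (L > 0) shapes <- c(shapes, list(.rect(0, 0, L, w)))
      shapes
    },
    radial = {
      R <- p$chamberRadiusUm
      L <- p$channelLengthUm
      w <- p$channelWidthUm
      r <- p$wellRadiusUm
      n <- p$nChannels
      shapes <- list(.disc(0, 0, R))
      for (k in seq_len(n) - 1L) {
        th <- 2 * pi * k / n
        mid <- (R + L) / 2
        shapes <- c(shapes, list(
          .rect(mid * cos(th), mid * sin(th), R + L, w, angle = th),
          .disc((R + L) * cos(th), (R + L) * sin(th), r)))
      }
      shapes
    },
    multi_chamber = {
      r <- p$wellRadiusUm
      Lc <- p$channelLengthUm
      wc <- p$channelWidthUm
      cw <- p$chamberWidthUm
      ch <- p$chamberHeightUm
      n <- p$nChambers
      connw <- p$connectorWidthUm
      connl <- p$connectorLengthUm
      shapes <- list(.rect(0, 0, Lc, wc),
                     .disc(-(Lc / 2 + r), 0, r), .disc(Lc / 2 + r, 0, r))
      cy <- wc / 2 + connl + ch / 2
      for (i in seq_len(n)) {
        cx <- -Lc / 2 + (i - 0.5) * Lc / n
        for (s in c(-1, 1)) {
          shapes <- c(shapes, list(
            .rect(cx, s * cy, cw, ch),
            ## connector spans from the channel axis into the chamber so
            ## that rasterisation can never detach it from either end
            .rect(cx, s * cy / 2, connw, cy)))
        }
      }
      shapes
    },
    custom = p$shapes
  )
}

#' Point-in-union test for device shapes
#'
#' @param shapes list from [deviceShapes()].
#' @param x,y physical coordinates (vectors) in micrometres.
#' @return logical vector: inside the union (boundaries inclusive).
#' @export
pointInShapes <- function(shapes, x, y) {
  inside <- rep(FALSE, length(x))
  for (s in shapes) {
    if (s$type == "disc") {
      inside <- inside | ((x - s$cx)^2 + (y - s$cy)^2 <= s$r^2)
    } else if (s$type == "rect") {
      a <- if (is.null(s$angle)) 0 else s$angle
      dx <- x - s$cx
      dy <- y - s$cy
      u <- cos(a) * dx + sin(a) * dy
      v <- -sin(a) * dx + cos(a) * dy
      inside <- inside | (abs(u) <= s$w / 2 & abs(v) <= s$h / 2)
    } else stop("unknown shape type '", s$type, "'", call. = FALSE)
  }
  inside
}

.shapeBBox <- function(shapes) {
  xs <- ys <- numeric()
  for (s in shapes) {
    if (s$type == "disc") {
      xs <- c(xs, s$cx - s$r, s$cx + s$r)
      ys <- c(ys, s$cy - s$r, s$cy + s$r)
    } else {
      a <- if (is.null(s$angle)) 0 else s$angle
      hx <- abs(cos(a)) * s$w / 2 + abs(sin(a)) * s$h / 2
      hy <- abs(sin(a)) * s$w / 2 + abs(cos(a)) * s$h / 2
      xs <- c(xs, s$cx - hx, s$cx + hx)
      ys <- c(ys, s$cy - hy, s$cy + hy)
    }
  }
  list(x = range(xs), y = range(ys))
}

#' Rasterise a device spec into a DeviceMask
#'
#' A pixel is allowed iff its centre lies inside the union of the spec's
#' shapes (pixel-centre inclusion, deterministic and directly checkable
#' against [pointInShapes()]). The lattice is padded with a one-pixel wall
#' border. If the rasterised allowed set is 4-disconnected, a geometry
#' warning is raised (reported, not fatal: some layouts are legitimately
#' disconnected).
#'
#' @param spec a [DeviceSpec-class].
#' @return A [DeviceMask-class].
#' @export
makeDevice <- function(spec) {
  stopifnot(is(spec, "DeviceSpec"))
  shapes <- deviceShapes(spec)
  if (!length(shapes)) stop("device spec has no shapes", call. = FALSE)
  px <- spec@pixelSizeUm
  bb <- .shapeBBox(shapes)
  ## symmetric padding by one wall pixel
  x0 <- bb$x[1L] - px
  y0 <- bb$y[1L] - px
  nc <- ceiling((bb$x[2L] + px - x0) / px)
  nr <- ceiling((bb$y[2L] + px - y0) / px)
  cx <- x0 + (seq_len(nc) - 0.5) * px
  cy <- y0 + (seq_len(nr) - 0.5) * px
  xs <- rep(cx, each = nr)
  ys <- rep(cy, times = nc)
  allowed <- matrix(pointInShapes(shapes, xs, ys), nr, nc)
  if (!any(allowed))
    stop("device rasterised to zero allowed pixels; increase sizes or resolution",
         call. = FALSE)
  mask <- DeviceMask(allowed, pixelSizeUm = px, originUm = c(x0, y0))
  ncomp <- length(connectedComponents(mask)$sizes)
  if (ncomp > 1L)
    warning("device '", spec@kind, "' rasterised to ", ncomp,
            " disconnected regions", call. = FALSE)
  mask
}

setMethod("show", "DeviceSpec", function(object) {
  cat("DeviceSpec '", object@kind, "' (", object@pixelSizeUm, " um/pixel)\n",
      sep = "")
  p <- object@params[names(object@params) != "shapes"]
  if (length(p))
    cat("  ", paste(names(p), unlist(p), sep = " = ", collapse = ", "), "\n",
        sep = "")
  if (!is.null(object@params$shapes))
    cat("  ", length(object@params$shapes), " custom shapes\n", sep = "")
})
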
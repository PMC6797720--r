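#' Construct a DeviceMask
#'
#' @param allowed logical matrix; `TRUE` marks cell-permitted pixels.
#' @param pixelSizeUm physical pixel side length in micrometres. The
#'   default of 20 corresponds to one adherent cell per pixel.
#' @param originUm physical (x, y) coordinate of the top-left corner of
#'   pixel (1, 1), in micrometres.
#' @return A [DeviceMask-class].
#' @examples
#' m <- DeviceMask(matrix(TRUE, 5, 8))
#' dim(m)
#' @export
DeviceMask <- function(allowed, pixelSizeUm = 20, originUm = c(0, 0)) {
  new("DeviceMask", allowed = allowed, pixelSizeUm = as.numeric(pixelSizeUm),
      originUm = as.numeric(originUm))
}

#' @rdname DeviceMask-class
#' @export
setMethod("allowedGrid", "DeviceMask", function(x) x@allowed)

#' @rdname DeviceMask-class
#' @export
setMethod("pixelSize", "DeviceMask", function(x) x@pixelSizeUm)

#' @rdname DeviceMask-class
#' @export
setMethod("dim", "DeviceMask", function(x) dim(x@allowed))

setMethod("show", "DeviceMask", function(object) {
  d <- dim(object@allowed)
  cat("DeviceMask: ", d[1L], " x ", d[2L], " pixels (",
      object@pixelSizeUm, " um/pixel), ",
      sum(object@allowed), " allowed / ", sum(!object@allowed), " wall\n",
      sep = "")
})

.readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG masks requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF masks requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format '.", ext,
         "' (PNG is canonical; JPEG/TIFF accepted)", call. = FALSE)
  )
  img
}

## Per-pixel mean luminance on the 0..255 scale, from a 2D grey matrix or
## an H x W x C array (alpha channel, if present, is ignored).
.luminance255 <- function(img) {
  if (is.matrix(img)) return(img * 255)
  if (length(dim(img)) == 3L) {
    nch <- min(dim(img)[3L], 3L)
    lum <- img[, , 1L]
    if (nch > 1L) for (k in 2L:nch) lum <- lum + img[, , k]
    return(lum / nch * 255)
  }
  stop("image did not decode to a greyscale or RGB raster", call. = FALSE)
}

#' Load a device mask from a raster image
#'
#' Every pixel is classified by mean luminance: pixels at or above the
#' threshold become allowed (white) positions, all others become walls.
#' No third state survives, so grey anti-aliasing artefacts introduced by
#' lossy CAD exports are resolved deterministically; the default threshold
#' of 128 maps dark grey borders to wall, preserving wall integrity.
#'
#' @param image path to a PNG (canonical), JPEG or TIFF file, or an
#'   already-decoded numeric array with values in \[0, 1\].
#' @param threshold luminance cut in 1..255; mean luminance >= threshold
#'   is allowed.
#' @param pixelSizeUm physical pixel size recorded on the mask.
#' @return A [DeviceMask-class] with the same dimensions as the image.
#' @seealso [maskToImage()], [writeMask()], [makeDevice()]
#' @export
loadMask <- function(image, threshold = 128, pixelSizeUm = 20) {
  if (is.character(image)) {
    if (!file.exists(image))
      stop("mask image not found: ", image, call. = FALSE)
    image <- .readRaster(image)
  }
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0 ||
      threshold > 255)
    stop("'threshold' must be in (0, 255]", call. = FALSE)
  lum <- .luminance255(image)
  allowed <- lum >= threshold
  if (!any(allowed))
    stop("no allowed pixels after thresholding: mask unusable", call. = FALSE)
  DeviceMask(allowed, pixelSizeUm = pixelSizeUm)
}

#' Render a mask as a black/white RGB image
#'
#' Allowed pixels become pure white, walls pure black, so that
#' `loadMask(maskToImage(m))` reproduces `m` exactly for any threshold.
#'
#' @param mask a [DeviceMask-class].
#' @return numeric H x W x 3 array with values 0 (black) or 1 (white).
#' @export
maskToImage <- function(mask) {
  stopifnot(is(mask, "DeviceMask"))
  d <- dim(mask@allowed)
  img <- array(0, c(d, 3L))
  white <- array(mask@allowed, c(d, 3L))
  img[white] <- 1
  img
}

#' Write a mask to a bit-exact black/white PNG
#'
#' @param mask a [DeviceMask-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(maskToImage(mask), path)
  invisible(path)
}

#' Connected components of the allowed region
#'
#' Labels the allowed pixels under 4-connectivity (the same von Neumann
#' adjacency the automaton uses), so that two pixels share a label exactly
#' when cells can reach one from the other.
#'
#' @param mask a [DeviceMask-class].
#' @return list with `labels` (integer matrix, 0 on walls, component id on
#'   allowed pixels) and `sizes` (integer vector of component sizes, which
#'   sum to the allowed-pixel count).
#' @export
connectedComponents <- function(mask) {
  stopifnot(is(mask, "DeviceMask"))
  a <- mask@allowed
  nr <- nrow(a)
  nc <- ncol(a)
  id <- matrix(0L, nr, nc)
  id[a] <- seq_len(sum(a))
  ## edges between 4-adjacent allowed pixels
  vert <- which(a[-nr, , drop = FALSE] & a[-1L, , drop = FALSE])
  horiz <- which(a[, -nc, drop = FALSE] & a[, -1L, drop = FALSE])
  edges <- rbind(
    if (length(vert)) {
      rc <- .idxToRC(vert, nr - 1L)
      cbind(id[cbind(rc[, 1L], rc[, 2L])], id[cbind(rc[, 1L] + 1L, rc[, 2L])])
    },
    if (length(horiz)) {
      rc <- .idxToRC(horiz, nr)
      cbind(id[cbind(rc[, 1L], rc[, 2L])], id[cbind(rc[, 1L], rc[, 2L] + 1L)])
    }
  )
  g <- igraph::make_empty_graph(n = sum(a), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  labels <- matrix(0L, nr, nc)
  labels[a] <- as.integer(comp$membership)
  list(labels = labels, sizes = as.integer(comp$csize))
}

#' Map physical micrometre coordinates to a lattice pixel
#'
#' Uses the mask's origin and pixel size; useful for placing seeds at
#' geometric anchor points (e.g. well centres) of synthetic devices.
#'
#' @param mask a [DeviceMask-class].
#' @param x,y physical coordinates in micrometres (vectors allowed).
#' @return integer matrix of (row, col) pixels.
#' @export
umToPixel <- function(mask, x, y) {
  px <- mask@pixelSizeUm
  col <- pmin(pmax(ceiling((x - mask@originUm[1L]) / px), 1L), ncol(mask@allowed))
  row <- pmin(pmax(ceiling((y - mask@originUm[2L]) / px), 1L), nrow(mask@allowed))
  cbind(row = as.integer(row), col = as.integer(col))
}
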
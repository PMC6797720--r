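#' @rdname DeviceMask-class
#' @param x,object a `DeviceMask`.
#' @export
setGeneric("allowedGrid", function(x) standardGeneric("allowedGrid"))

#' @rdname DeviceMask-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname LatticeState-class
#' @param x,object a `LatticeState`.
#' @export
setGeneric("stateGrid", function(x) standardGeneric("stateGrid"))

#' @rdname LatticeState-class
#' @export
setGeneric("stepIndex", function(x) standardGeneric("stepIndex"))

#' @rdname LatticeState-class
#' @export
setGeneric("newborns", function(x) standardGeneric("newborns"))

#' @rdname LatticeState-class
#' @export
setGeneric("speciesList", function(x) standardGeneric("speciesList"))

#' Count pixels per lattice state
#'
#' Returns a named integer vector (`empty`, `wall`, `dead`, `drug`, then
#' one entry per registered species) whose sum equals the grid size.
#'
#' @param x a [LatticeState-class].
#' @return named integer vector of pixel counts.
#' @export
setGeneric("countStates", function(x) standardGeneric("countStates"))

#' @rdname RunSummary-class
#' @param x,object a `RunSummary`.
#' @export
setGeneric("countsTable", function(x) standardGeneric("countsTable"))

#' @rdname RunSummary-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
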
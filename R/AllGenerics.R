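#' @rdname traceLineages
#' @export
setGeneric("traceLineages",
  function(genealogy, sampleGeneration) standardGeneric("traceLineages"))

#' @rdname tmrca
#' @export
setGeneric("tmrca", function(x, ...) standardGeneric("tmrca"))

#' @rdname toNewick
#' @export
setGeneric("toNewick",
  function(genealogy, sampleGeneration) standardGeneric("toNewick"))

#' Accessors for simulation objects
#'
#' \code{nCells} is the number of recorded cells, \code{maxGeneration} the
#' largest generation label present, \code{cellSites} the per-cell lattice
#' coordinates, \code{genealogy} extracts the [Genealogy-class] from an
#' [EdenResult-class], \code{positions} the current (post-diffusion) cell
#' sites, \code{lineageCounts} the backward lineage-count vector of a
#' [LineageCurve-class], and \code{sampleGeneration} the generation the
#' sample was drawn from.
#'
#' @param x a [Genealogy-class], [EdenResult-class] or [LineageCurve-class].
#' @return see above; scalar integers, matrices or vectors.
#' @examples
#' g <- makeFixture("star")
#' nCells(g)
#' maxGeneration(g)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("maxGeneration", function(x) standardGeneric("maxGeneration"))

#' @rdname accessors
#' @export
setGeneric("cellSites", function(x) standardGeneric("cellSites"))

#' @rdname accessors
#' @export
setGeneric("genealogy", function(x) standardGeneric("genealogy"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("lineageCounts", function(x) standardGeneric("lineageCounts"))

#' @rdname accessors
#' @export
setGeneric("sampleGeneration", function(x) standardGeneric("sampleGeneration"))

#' @rdname frontWidthSeries
#' @export
setGeneric("frontWidthSeries", function(x) standardGeneric("frontWidthSeries"))
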
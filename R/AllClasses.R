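#' @useDynLib coalGrowth, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Genealogy of a simulated tissue
#'
#' An append-only parent-pointer table recording, for every cell of a run,
#' its parent, its generation and its (birth) lattice site.  Records are in
#' topological birth order: a parent always precedes its children.  External
#' cell ids are 0-based (\code{id = record index - 1}); founders have no
#' parent and generation 0.
#'
#' @slot parent integer vector; 1-based record index of each cell's parent,
#'   \code{NA} for founders.
#' @slot generation integer vector of generation numbers (founders are 0 and
#'   a child's generation is its parent's plus one).
#' @slot site integer matrix of lattice coordinates, one row per cell, with
#'   2 or 3 columns (\code{x,y} or \code{x,y,z}); the last coordinate is the
#'   depth axis for bounded growth.
#'
#' @seealso [simulateWF()], [simulateEden()], [traceLineages()], [tmrca()]
#' @export
setClass("Genealogy",
  slots = c(parent = "integer", generation = "integer", site = "matrix"))

setValidity("Genealogy", function(object) {
  p <- object@parent
  g <- object@generation
  n <- length(p)
  msg <- character()
  if (n == 0L)
    msg <- c(msg, "genealogy must contain at least one record")
  if (length(g) != n)
    msg <- c(msg, "'parent' and 'generation' lengths differ")
  if (nrow(object@site) != n)
    msg <- c(msg, "'site' must have one row per record")
  if (!ncol(object@site) %in% 2:3)
    msg <- c(msg, "'site' must have 2 or 3 columns")
  founder <- is.na(p)
  if (any(g[founder] != 0L))
    msg <- c(msg, "founders (no parent) must have generation 0")
  if (any(!founder & (p < 1L | p >= seq_len(n))))
    msg <- c(msg, "each parent must be an earlier record (parent index < id)")
  ok <- !founder
  if (any(g[ok] != g[p[ok]] + 1L))
    msg <- c(msg, "child generation must equal parent generation + 1")
  if (length(msg)) msg else TRUE
})

#' Number of distinct ancestral lineages, backwards in time
#'
#' For a sample made of all cells of one generation, \code{counts[g + 1]} is
#' the number of distinct ancestors \code{g} generations back.  Counts start
#' at the sample size, are non-increasing, and reach 1 at the most recent
#' common ancestor (if the sample coalesces within the recorded history).
#'
#' @slot sampleGeneration integer; the generation the sample was drawn from.
#' @slot counts integer vector of length \code{sampleGeneration + 1}.
#' @seealso [traceLineages()], [excessLineages()], [coalescenceProbability()]
#' @export
setClass("LineageCurve",
  slots = c(sampleGeneration = "integer", counts = "integer"))

setValidity("LineageCurve", function(object) {
  ct <- object@counts
  msg <- character()
  if (length(object@sampleGeneration) != 1L || object@sampleGeneration < 0L)
    msg <- c(msg, "'sampleGeneration' must be a single non-negative integer")
  if (length(ct) < 1L || length(ct) > object@sampleGeneration + 1L)
    msg <- c(msg, "'counts' length must be at most sampleGeneration + 1")
  if (any(ct < 1L))
    msg <- c(msg, "lineage counts must be >= 1")
  if (is.unsorted(rev(ct)))
    msg <- c(msg, "lineage counts must be non-increasing backwards in time")
  if (length(msg)) msg else TRUE
})

#' Population-size schedule for layer-by-layer growth
#'
#' Either a constant width \code{N}, or linear growth
#' \code{N_t = round(N0 + lambda * t)} (never below 1 cell).
#'
#' @slot kind \code{"constant"} or \code{"linear"}.
#' @slot N integer width (constant case).
#' @slot N0,lambda numeric initial size and growth rate in cells per
#'   generation (linear case).
#' @seealso [growthSchedule()], [simulateWF()]
#' @export
setClass("GrowthSchedule",
  slots = c(kind = "character", N = "integer", N0 = "numeric",
            lambda = "numeric"))

setValidity("GrowthSchedule", function(object) {
  msg <- character()
  if (!object@kind %in% c("constant", "linear"))
    msg <- c(msg, "'kind' must be \"constant\" or \"linear\"")
  if (object@kind == "constant" && (length(object@N) != 1L || object@N < 1L))
    msg <- c(msg, "constant schedule needs a single width N >= 1")
  if (object@kind == "linear" &&
      (length(object@N0) != 1L || object@N0 < 1 || length(object@lambda) != 1L))
    msg <- c(msg, "linear schedule needs N0 >= 1 and a growth rate lambda")
  if (length(msg)) msg else TRUE
})

#' Result of an Eden growth simulation
#'
#' Holds the full genealogy plus the spatial end state of a run: each cell's
#' current lattice site (which differs from its birth site when diffusion is
#' on), which cells sit on the growth boundary, and (optionally) the
#' event-time series of the front width.
#'
#' @slot genealogy a [Genealogy-class].
#' @slot positions integer matrix of current cell sites (one row per cell).
#' @slot isBoundary logical vector; cells abutting an empty site.
#' @slot widthSeries \code{NULL} or a data.frame with columns \code{event}
#'   and \code{width} (standard deviation of boundary depths).
#' @slot params named list of the simulation parameters.
#' @slot nEvents,nMoves,nRejected numeric event counters.
#' @seealso [simulateEden()], [frontWidthSeries()], [generationDepthStats()]
#' @export
setClass("EdenResult",
  slots = c(genealogy = "Genealogy", positions = "matrix",
            isBoundary = "logical", widthSeries = "ANY", params = "list",
            nEvents = "numeric", nMoves = "numeric", nRejected = "numeric"))

setValidity("EdenResult", function(object) {
  n <- length(object@genealogy@parent)
  if (nrow(object@positions) != n || length(object@isBoundary) != n)
    "positions and isBoundary must have one entry per cell" else TRUE
})

#' Log-log power-law fit
#'
#' Ordinary least-squares fit of \code{log(response)} on \code{log(width)};
#' the slope estimates a scaling exponent (e.g. the dynamic exponent z of
#' the T_MRCA ~ N^z law, or the roughness exponent of W_sat ~ N^(1/2)).
#'
#' @slot widths,responses numeric vectors (>= 3 distinct positive widths).
#' @slot slope,intercept,slopeSE numeric scalars from the OLS fit.
#' @seealso [fitDynamicExponent()]
#' @export
setClass("ScalingFit",
  slots = c(widths = "numeric", responses = "numeric", slope = "numeric",
            intercept = "numeric", slopeSE = "numeric"))

setValidity("ScalingFit", function(object) {
  msg <- character()
  if (length(unique(object@widths)) < 3L)
    msg <- c(msg, "at least 3 distinct widths are required")
  if (any(object@responses <= 0))
    msg <- c(msg, "responses must be positive")
  if (length(msg)) msg else TRUE
})

#' Lineage-survival power-law fit
#'
#' Fit of the fractional number of surviving lineages against look-back
#' height h: \code{N_lin/N_T ~ h^(-alpha)}.  For d-dimensional Eden growth
#' alpha = (d-1)/z; for neutral growth with a linearly increasing
#' population alpha = 1.
#'
#' @slot h numeric look-back generations.
#' @slot fraction numeric surviving-lineage fractions in (0, 1].
#' @slot alpha,alphaSE fitted exponent (magnitude of the log-log slope) and
#'   its standard error.
#' @slot hRange the h interval used in the fit.
#' @seealso [fitSurvivalExponent()], [effectiveLineageTransform()]
#' @export
setClass("SurvivalFit",
  slots = c(h = "numeric", fraction = "numeric", alpha = "numeric",
            alphaSE = "numeric", hRange = "numeric"))

setValidity("SurvivalFit", function(object) {
  msg <- character()
  if (length(object@h) != length(object@fraction))
    msg <- c(msg, "'h' and 'fraction' lengths differ")
  if (any(object@fraction <= 0 | object@fraction > 1))
    msg <- c(msg, "fractions must lie in (0, 1]")
  if (any(object@h < 1))
    msg <- c(msg, "look-back heights must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Validated configuration of a simulation run
#'
#' @slot model one of \code{"wf"}, \code{"wf-linear"}, \code{"eden-bounded"},
#'   \code{"eden-diffusive"}, \code{"eden-unbounded"}.
#' @slot params named list of model parameters.
#' @slot replicates integer number of replicates.
#' @slot seed integer master seed (replicate i runs with seed + i).
#' @slot outDir output directory.
#' @seealso [runConfig()], [runSimulation()]
#' @export
setClass("RunConfig",
  slots = c(model = "character", params = "list", replicates = "integer",
            seed = "integer", outDir = "character"))
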
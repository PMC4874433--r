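#' Depth statistics of a cell generation across replicates
#'
#' For each replicate, takes the cells whose generation label is \code{g}
#' and computes the mean and variance of their tissue depth (the lattice
#' coordinate along the growth axis, using current positions so diffusion
#' is accounted for).  For bounded diffusive-Eden growth the per-replicate
#' mean drifts with increasing ensemble spread while the per-replicate
#' depth variance settles to a steady state of about N (the tissue width).
#'
#' @param ensemble list of [EdenResult-class] replicates (grown with
#'   \code{stop = "complete"} at or beyond \code{g} so the cohort is
#'   final).
#' @param g generation label.
#' @return a data.frame with one row per replicate (columns
#'   \code{meanDepth}, \code{varDepth}, \code{nCells}) and attributes
#'   \code{meanOfMeans} and \code{meanOfVariances}.
#' @examples
#' reps <- lapply(1:3, function(s)
#'   simulateEden(width = 8, generations = 12, stop = "complete", seed = s))
#' generationDepthStats(reps, 10)
#' @export
generationDepthStats <- function(ensemble, g) {
  stopifnot(length(ensemble) > 0)
  rows <- lapply(ensemble, function(res) {
    d <- .depthValues(res, g)
    if (length(d) == 0L)
      stop("generation ", g, " is absent from a replicate")
    data.frame(meanDepth = mean(d),
               varDepth = if (length(d) > 1L) stats::var(d) else 0,
               nCells = length(d))
  })
  out <- do.call(rbind, rows)
  attr(out, "meanOfMeans") <- mean(out$meanDepth)
  attr(out, "meanOfVariances") <- mean(out$varDepth)
  out
}

# depth (or radius) of the generation-g cells of one replicate
.depthValues <- function(res, g, radial = FALSE) {
  stopifnot(is(res, "EdenResult"))
  pos <- positions(res)
  sel <- res@genealogy@generation == g
  if (radial) {
    sqrt(rowSums(pos[sel, , drop = FALSE]^2))
  } else {
    pos[sel, ncol(pos)]
  }
}

#' Pooled deviations from the per-replicate mean depth
#'
#' Pools, across replicates, the values \code{depth - mean(depth)} over the
#' generation-\code{g} cells of each replicate.  For bounded diffusive-Eden
#' growth this distribution is stationary in \code{g} with variance about
#' equal to the tissue width N; for unbounded growth its variance keeps
#' increasing with \code{g} (no stationary front).
#'
#' @inheritParams generationDepthStats
#' @param radial use Euclidean radius from the founder instead of depth.
#' @return numeric vector of pooled deviations.
#' @export
deviationDistribution <- function(ensemble, g, radial = FALSE) {
  unlist(lapply(ensemble, function(res) {
    d <- .depthValues(res, g, radial = radial)
    if (length(d) == 0L)
      stop("generation ", g, " is absent from a replicate")
    d - mean(d)
  }), use.names = FALSE)
}

#' Front width series and saturated roughness
#'
#' The front width is the standard deviation of the depths of the boundary
#' cells; for bounded (1+1) Eden growth it saturates at a roughness
#' proportional to \code{sqrt(N)}.  \code{frontWidthSeries} extracts the
#' recorded event-time series from a run made with
#' \code{recordWidth = TRUE}; \code{saturatedWidth} averages the width over
#' the second half of the run, discarding the growth transient.
#'
#' @param x an [EdenResult-class] from \code{simulateEden(recordWidth =
#'   TRUE)}.
#' @return \code{frontWidthSeries}: a data.frame with columns \code{event}
#'   and \code{width}; \code{saturatedWidth}: a single number W_sat.
#' @name frontWidthSeries
NULL

#' @rdname frontWidthSeries
#' @param series a width series data.frame (or an [EdenResult-class]).
#' @export
saturatedWidth <- function(series) {
  if (is(series, "EdenResult")) series <- frontWidthSeries(series)
  if (is.null(series) || nrow(series) == 0L)
    stop("no front-width series was recorded")
  w <- series$width
  mean(w[seq.int(floor(length(w) / 2) + 1L, length(w))])
}

#' Radial statistics of an unbounded colony
#'
#' Same summaries as [generationDepthStats()] but on the Euclidean radius
#' from the founder at the origin.  The mean radius grows almost
#' deterministically and linearly with generation number, while the
#' radial deviations within a replicate keep spreading.
#'
#' @inheritParams generationDepthStats
#' @return as [generationDepthStats()], with columns \code{meanRadius},
#'   \code{varRadius}, \code{nCells}.
#' @export
radialStats <- function(ensemble, g) {
  rows <- lapply(ensemble, function(res) {
    r <- .depthValues(res, g, radial = TRUE)
    if (length(r) == 0L)
      stop("generation ", g, " is absent from a replicate")
    data.frame(meanRadius = mean(r),
               varRadius = if (length(r) > 1L) stats::var(r) else 0,
               nCells = length(r))
  })
  out <- do.call(rbind, rows)
  attr(out, "meanOfMeans") <- mean(out$meanRadius)
  attr(out, "meanOfVariances") <- mean(out$varRadius)
  out
}
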
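#' Replicate T_MRCA sample for the layer-by-layer neutral model
#'
#' Simulates \code{replicates} independent constant-width Wright-Fisher
#' runs and traces all final-generation cells to their MRCA.
#'
#' @param N tissue width.
#' @param generations forward generations G (the sample is generation G).
#' @param replicates number of replicates.
#' @param seed optional master seed; replicate i runs under
#'   \code{seed + i}.
#' @return integer vector of T_MRCA values, \code{NA} where a replicate
#'   did not coalesce within G generations.
#' @examples
#' mean(wfTmrcaSample(20, 200, 50, seed = 1)) / 20  # close to 2
#' @export
wfTmrcaSample <- function(N, generations, replicates, seed = NULL) {
  vapply(seq_len(replicates), function(i) {
    tmrca(simulateWF(N, generations, seed = .replicateSeed(seed, i),
                     keepSites = FALSE), generations)
  }, integer(1))
}

.replicateSeed <- function(seed, i) {
  if (is.null(seed)) NULL
  else as.integer((as.numeric(seed) + i) %% .Machine$integer.max)
}

#' Mean T_MRCA of bounded Eden growth across tissue widths
#'
#' For each width N, simulates bounded Eden growth (optionally diffusive,
#' optionally (2+1)-dimensional) to a completed sampling generation deep
#' enough for nearly all replicates to coalesce, traces the full sampled
#' generation to its MRCA, and averages over the replicates that
#' coalesced (non-coalesced replicates are excluded and counted).
#'
#' The per-width horizon is \code{ceiling(horizonFactor * N^zGuess)}
#' generations: coalescence times grow like \code{N^z}, so a fixed
#' multiple of the anticipated scale keeps the truncation fraction
#' comparable across widths.
#'
#' @param widths tissue widths to simulate.
#' @param replicates replicates per width.
#' @param dimension 2 for (1+1), 3 for (2+1).
#' @param pMove per-event diffusion probability (0 = plain Eden).
#' @param horizonFactor multiple of \code{N^zGuess} used as sampling depth.
#' @param zGuess anticipated dynamic exponent used only to set the horizon
#'   (3/2 for (1+1), 1.61 for (2+1)).
#' @param seed optional master seed.
#' @return data.frame with columns \code{width}, \code{meanTmrca},
#'   \code{nCoalesced}, \code{nTotal}, \code{generations}.
#' @seealso [fitDynamicExponent()]
#' @export
edenTmrcaScaling <- function(widths, replicates, dimension = 2, pMove = 0,
                             horizonFactor = 6,
                             zGuess = if (dimension == 2) 1.5 else 1.61,
                             seed = NULL) {
  k <- 0L
  rows <- lapply(widths, function(N) {
    G <- as.integer(ceiling(horizonFactor * N^zGuess))
    tm <- vapply(seq_len(replicates), function(i) {
      k <<- k + 1L
      res <- simulateEden(width = N, generations = G, dimension = dimension,
                          pMove = pMove, stop = "complete",
                          seed = .replicateSeed(seed, k))
      tmrca(genealogy(res), G)
    }, integer(1))
    data.frame(width = N, meanTmrca = mean(tm, na.rm = TRUE),
               nCoalesced = sum(!is.na(tm)), nTotal = replicates,
               generations = G)
  })
  do.call(rbind, rows)
}

#' Ensemble coalescence-probability curve
#'
#' Convenience wrapper: simulates replicates of a model, traces the final
#' generation, and returns the coalescence-probability curve over
#' generations back.
#'
#' @param model \code{"wf"} or \code{"eden-diffusive"}.
#' @param N tissue width.
#' @param generations sampling generation G.
#' @param replicates number of replicates.
#' @param pMove diffusion probability for the Eden model; the default is
#'   the calibrated value (see [runConfig()]).
#' @param seed optional master seed.
#' @return numeric vector of coalescence probabilities at g = 0..G.
#' @export
coalescenceCurve <- function(model = c("wf", "eden-diffusive"), N,
                             generations, replicates, pMove = 0.925,
                             seed = NULL) {
  model <- match.arg(model)
  curves <- lapply(seq_len(replicates), function(i) {
    s <- .replicateSeed(seed, i)
    g <- if (model == "wf")
      simulateWF(N, generations, seed = s, keepSites = FALSE)
    else
      genealogy(simulateEden(width = N, generations = generations,
                             pMove = pMove, stop = "complete", seed = s))
    traceLineages(g, generations)
  })
  coalescenceProbability(curves)
}
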
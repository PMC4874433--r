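#' Fit the dynamic exponent from T_MRCA against tissue width
#'
#' Ordinary least squares of \code{log(mean T_MRCA)} on \code{log(N)}.  For
#' growth models in the KPZ universality class the mean coalescence time
#' scales as \code{N^z} with the dynamic exponent z (3/2 in (1+1)
#' dimensions, about 1.61 in (2+1)); the classical Wright-Fisher coalescent
#' scales as \code{N^1}.
#'
#' @param widths numeric vector of tissue widths N (>= 3 distinct values).
#' @param meanTmrcas mean T_MRCA per width, in generations (positive;
#'   computed over coalesced replicates).
#' @return a [ScalingFit-class]; the slope is the exponent estimate.
#' @examples
#' f <- fitDynamicExponent(c(4, 8, 16, 32), 3 * c(4, 8, 16, 32)^1.5)
#' f@slope   # exactly 1.5
#' @export
fitDynamicExponent <- function(widths, meanTmrcas) {
  stopifnot(length(widths) == length(meanTmrcas))
  if (any(meanTmrcas <= 0)) stop("mean T_MRCA values must be positive")
  fit <- stats::lm(log(meanTmrcas) ~ log(widths))
  cf <- suppressWarnings(stats::coef(summary(fit)))  # exact fits are fine
  new("ScalingFit", widths = as.numeric(widths),
      responses = as.numeric(meanTmrcas),
      slope = cf[2L, 1L], intercept = cf[1L, 1L], slopeSE = cf[2L, 2L])
}

setMethod("show", "ScalingFit", function(object) {
  cat("ScalingFit over", length(object@widths), "widths [",
      min(object@widths), "-", max(object@widths), "]\n",
      " slope (exponent):", format(object@slope, digits = 4),
      "+/-", format(object@slopeSE, digits = 3),
      " intercept:", format(object@intercept, digits = 4), "\n")
})

#' Effective population size of a fractal growth model
#'
#' The constant Wright-Fisher population whose coalescent time scale
#' matches a growth model of width N with dynamic exponent z:
#' \code{N_e = N^z}.  Rescaling Eden time by \code{1/N_e} aligns its
#' coalescence curves with Wright-Fisher time rescaled by \code{1/N}
#' (z = 1 recovers the Wright-Fisher identity).
#'
#' In absolute time units the proportionality constant matters: a growth
#' model whose whole-population mean T_MRCA is \code{c N^z} has the same
#' coalescent time scale as a Wright-Fisher population of size
#' \code{c N^z / 2} (whose mean T_MRCA is twice its size).  Passing a
#' [ScalingFit-class] as \code{z} therefore uses both the fitted slope and
#' the fitted intercept: \code{N_e = exp(intercept) N^slope / 2}.
#'
#' @param N tissue width (>= 2).
#' @param z dynamic exponent (default 3/2, the (1+1) KPZ value), or a
#'   [ScalingFit-class] from [fitDynamicExponent()].
#' @param prefactor multiplicative constant c in \code{N_e = c N^z}
#'   (ignored when \code{z} is a fit).
#' @return N_e, a positive number.
#' @examples
#' effectivePopulation(100, 1.5)  # 1000
#' @export
effectivePopulation <- function(N, z = 1.5, prefactor = 1) {
  stopifnot(all(N >= 2))
  if (is(z, "ScalingFit"))
    return(exp(z@intercept) * N^z@slope / 2)
  stopifnot(z > 0, prefactor > 0)
  prefactor * N^z
}

#' Sup-norm distance between two rescaled curves
#'
#' Both curves are read as step values on integer times \code{0, 1, ...}
#' (coalescence probabilities or normalised lineage counts, in \[0, 1\]),
#' each with its own time scale.  They are linearly interpolated onto a
#' common grid over the overlap of their rescaled supports and the maximum
#' absolute difference is returned; this quantifies the visual collapse of
#' coalescence curves under effective-population rescaling.
#'
#' @param curveA,curveB numeric vectors of curve values at times
#'   \code{0:(length - 1)}.
#' @param timescaleA,timescaleB positive scale factors; curve times are
#'   divided by them (e.g. N for Wright-Fisher, N^z for Eden).
#' @param gridSize number of evaluation points on the common grid.
#' @return the sup-norm difference, a number in \[0, 1\].
#' @examples
#' rescaleAndOverlap(c(0, .5, 1), 1, c(0, .5, 1), 1)  # 0
#' @export
rescaleAndOverlap <- function(curveA, timescaleA, curveB, timescaleB,
                              gridSize = 512L) {
  stopifnot(timescaleA > 0, timescaleB > 0,
            length(curveA) > 1L, length(curveB) > 1L)
  tA <- (seq_along(curveA) - 1) / timescaleA
  tB <- (seq_along(curveB) - 1) / timescaleB
  hi <- min(max(tA), max(tB))
  lo <- max(min(tA), min(tB))
  if (hi <= lo) stop("rescaled time supports do not overlap")
  grid <- seq(lo, hi, length.out = gridSize)
  fA <- stats::approx(tA, curveA, xout = grid)$y
  fB <- stats::approx(tB, curveB, xout = grid)$y
  max(abs(fA - fB))
}

#' Fit the lineage-survival exponent
#'
#' The fraction of lineages surviving \code{h} generations back decays as
#' \code{h^(-alpha)}; alpha = (d-1)/z for d-dimensional Eden growth
#' (2/3 on a two-dimensional surface with z = 3/2) and alpha = 1 for a
#' neutral model with linear population growth.  Fits OLS of
#' \code{log(fraction)} on \code{log(h)} over \code{hRange}; by default h
#' below 5 (sampling-time boundary effects) and the final 10\% of the
#' look-back window (founder effects) are excluded.
#'
#' @param h look-back generations (>= 1).
#' @param fraction surviving-lineage fractions \code{N_lin / N_T} in
#'   (0, 1].
#' @param hRange length-2 fit window on h.
#' @return a [SurvivalFit-class]; \code{alpha} is the magnitude of the
#'   log-log slope.
#' @examples
#' h <- 1:100
#' fitSurvivalExponent(h, 1 / h)@alpha  # exactly 1
#' @export
fitSurvivalExponent <- function(h, fraction,
                                hRange = c(5, floor(0.9 * max(h)))) {
  stopifnot(length(h) == length(fraction))
  sel <- h >= hRange[1L] & h <= hRange[2L] & fraction > 0
  if (sum(sel) < 3L)
    stop("fewer than 3 usable points in the fit range")
  fit <- stats::lm(log(fraction[sel]) ~ log(h[sel]))
  cf <- suppressWarnings(stats::coef(summary(fit)))
  new("SurvivalFit", h = as.numeric(h), fraction = as.numeric(fraction),
      alpha = abs(cf[2L, 1L]), alphaSE = cf[2L, 2L],
      hRange = as.numeric(hRange))
}

setMethod("show", "SurvivalFit", function(object) {
  cat("SurvivalFit over h in [", object@hRange[1L], ",",
      object@hRange[2L], "]\n  alpha:", format(object@alpha, digits = 4),
      "+/-", format(object@alphaSE, digits = 3), "\n")
})

#' Map a survival law onto the neutral linear-growth law
#'
#' Forms the effective lineage count
#' \code{N_T (N_lin / N_T)^(1/alpha)}, which turns a survival fraction
#' decaying as \code{h^(-alpha)} into the neutral \code{h^(-1)} law; with
#' alpha = 1 it is the identity.  Applied to unbounded-Eden lineage curves
#' with alpha = (d-1)/z = 2/3 it overlays them on the linear-growth
#' coalescent.
#'
#' @param Nlin surviving lineage count(s), 0 < Nlin <= NT.
#' @param NT total population at the corresponding look-back generation.
#' @param alpha survival exponent (> 0).
#' @return transformed lineage count(s).
#' @examples
#' effectiveLineageTransform(10, 100, 1)  # identity: 10
#' @export
effectiveLineageTransform <- function(Nlin, NT, alpha) {
  stopifnot(alpha > 0, all(Nlin > 0), all(Nlin <= NT))
  NT * (Nlin / NT)^(1 / alpha)
}

#' Ensemble lineage-survival curve
#'
#' Traces each replicate genealogy backwards from \code{sampleGeneration}
#' and averages, per look-back height h, the fraction of surviving
#' lineages \code{N_lin(h) / N_T(h)}, where \code{N_T(h)} is that
#' replicate's population size at generation \code{sampleGeneration - h}.
#'
#' @param genealogies list of [Genealogy-class] replicates.
#' @param sampleGeneration the common sampling generation G.
#' @return data.frame with columns \code{h}, \code{fraction} (ensemble
#'   mean), \code{meanNlin}, \code{meanNT}.
#' @export
survivalCurve <- function(genealogies, sampleGeneration) {
  stopifnot(length(genealogies) > 0)
  G <- as.integer(sampleGeneration)
  acc <- vapply(genealogies, function(g) {
    ct <- lineageCounts(traceLineages(g, G))
    tab <- tabulate(g@generation + 1L, nbins = G + 1L)
    NT <- tab[G:1]          # population at generation G - h, h = 1..G
    c(ct[-1L] / NT, ct[-1L], NT)
  }, numeric(3L * G))
  m <- rowMeans(acc)
  data.frame(h = 1:G, fraction = m[1:G],
             meanNlin = m[G + 1:G], meanNT = m[2 * G + 1:G])
}
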
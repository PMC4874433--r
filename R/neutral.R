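#' Create a population-size schedule
#'
#' @param kind \code{"constant"} or \code{"linear"}.
#' @param N width (cells per layer) for the constant schedule.
#' @param N0 initial size for the linear schedule.
#' @param lambda growth rate in cells per generation.  The default 2.78 is
#'   the rate of the unbounded Eden colony (about 1250 generation-450
#'   cells, i.e. 1250/450).
#' @return a [GrowthSchedule-class].
#' @examples
#' growthSchedule("constant", N = 100)
#' growthSchedule("linear", N0 = 1, lambda = 2.78)
#' @export
growthSchedule <- function(kind = c("constant", "linear"), N = NULL,
                           N0 = 1, lambda = 2.78) {
  kind <- match.arg(kind)
  new("GrowthSchedule", kind = kind,
      N = if (is.null(N)) NA_integer_ else as.integer(N),
      N0 = as.numeric(N0), lambda = as.numeric(lambda))
}

#' Layer sizes of a schedule over forward time
#'
#' @param schedule a [GrowthSchedule-class] (or a single width, taken as a
#'   constant schedule).
#' @param generations number of generations G.
#' @return integer vector of sizes for generations \code{0:G}; linear sizes
#'   are rounded to the nearest integer and never fall below 1.
#' @export
scheduleSizes <- function(schedule, generations) {
  if (is.numeric(schedule))
    schedule <- growthSchedule("constant", N = schedule)
  stopifnot(is(schedule, "GrowthSchedule"), generations >= 1)
  t <- 0:generations
  if (schedule@kind == "constant")
    rep.int(schedule@N, generations + 1L)
  else
    pmax(1L, as.integer(round(schedule@N0 + schedule@lambda * t)))
}

#' Simulate layer-by-layer neutral (Wright-Fisher) tissue growth
#'
#' Generation t holds the scheduled number of cells; each cell's parent is
#' drawn independently and uniformly from the cells of generation t - 1.
#' Lattice sites are the layer index (depth y = t) and the within-layer
#' position x.
#'
#' @param schedule a [GrowthSchedule-class], or a single number taken as a
#'   constant width N.
#' @param generations number of layers to grow beyond the founders.
#' @param seed optional integer; if given, \code{set.seed(seed)} is called
#'   first so the run is reproducible.
#' @param keepSites if \code{FALSE} the site matrix is filled with zeros,
#'   which avoids building layer coordinates in large ensembles where only
#'   the genealogy matters.
#' @return a [Genealogy-class].
#' @examples
#' g <- simulateWF(10, 50, seed = 1)
#' tmrca(g, 50)
#' @export
simulateWF <- function(schedule, generations, seed = NULL, keepSites = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- scheduleSizes(schedule, generations)
  offs <- cumsum(c(0L, sizes))
  n <- offs[length(offs)]
  parent <- integer(n)
  parent[seq_len(sizes[1L])] <- NA_integer_
  for (t in seq_len(generations)) {
    idx <- (offs[t + 1L] + 1L):offs[t + 2L]
    parent[idx] <- offs[t] + sample.int(sizes[t], sizes[t + 1L],
                                        replace = TRUE)
  }
  gen <- rep.int(0:generations, sizes)
  site <- if (keepSites)
    cbind(x = sequence(sizes) - 1L, y = gen)
  else
    matrix(0L, nrow = n, ncol = 2L, dimnames = list(NULL, c("x", "y")))
  Genealogy(parent = parent, generation = gen, site = site)
}

#' Simulate neutral growth with a linearly increasing population
#'
#' Forward layer sizes follow \code{N_t = round(N0 + lambda * t)}; parents
#' are uniform in the previous layer.  Tracing back from the final
#' generation yields the star-like lineage curves characteristic of
#' growing populations.
#'
#' @inheritParams growthSchedule
#' @inheritParams simulateWF
#' @return a [Genealogy-class].
#' @examples
#' g <- simulateLinearWF(N0 = 1, lambda = 2.78, generations = 45, seed = 1)
#' lineageCounts(traceLineages(g, 45))[1:5]
#' @export
simulateLinearWF <- function(N0 = 1, lambda = 2.78, generations,
                             seed = NULL, keepSites = TRUE) {
  simulateWF(growthSchedule("linear", N0 = N0, lambda = lambda),
             generations, seed = seed, keepSites = keepSites)
}

#' Kingman expectation of the whole-sample coalescence time
#'
#' In the haploid large-N limit the time with k active lineages is
#' exponential with mean \code{2N / (k (k - 1))} generations, so a sample
#' of n lineages from a population of constant size N has expected time to
#' its most recent common ancestor \code{2N (1 - 1/n)}; for a full sample
#' (n = N, N large) this approaches the classical 2N-generation fixation
#' time scale.
#'
#' @param n sample size (>= 2).
#' @param N population size (n <= N).
#' @return expected T_MRCA in generations (real-valued).
#' @examples
#' kingmanExpectedTmrca(2, 100)     # 100
#' kingmanExpectedTmrca(1000, 1000) # 1998
#' @export
kingmanExpectedTmrca <- function(n, N) {
  stopifnot(n >= 2, n <= N)
  2 * N * (1 - 1 / n)
}

#' Exact (Fu) ancestor-count transition matrix
#'
#' One Wright-Fisher generation back, j lineages fall onto k distinct
#' parents among N with probability
#' \code{S(j, k) N (N-1) ... (N-k+1) / N^j}, S being Stirling numbers of
#' the second kind; multiple coalescent events can occur in a single step.
#' Computed by a numerically stable occupancy recursion rather than large
#' Stirling numbers.
#'
#' @param N population size per generation.
#' @return an N x N row-stochastic matrix; entry \code{[j, k]} is
#'   P(k ancestors | j lineages).
#' @examples
#' exactAncestorChain(3)["3", ]   # 1/9, 2/3, 2/9
#' @export
exactAncestorChain <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 1)
  P <- matrix(0, N, N, dimnames = list(1:N, 1:N))
  # occupancy DP over children placed one at a time
  for (j in 1:N) {
    p <- numeric(N)          # p[k]: k distinct parents after c children
    p[1] <- 1                # first child occupies one parent
    if (j > 1) for (cc in 2:j) {
      pn <- numeric(N)
      k <- 1:min(cc, N)
      pn[k] <- p[k] * k / N
      pn[k[k > 1]] <- pn[k[k > 1]] +
        p[k[k > 1] - 1] * (N - k[k > 1] + 1) / N
      p <- pn
    }
    P[j, ] <- p
  }
  P
}

#' Expected whole-population T_MRCA under the exact coalescent
#'
#' Mean absorption time into the single-ancestor state of the exact
#' ancestor-count Markov chain, starting from a full sample of N lineages.
#'
#' @param N population size.
#' @return expected T_MRCA in generations.
#' @examples
#' exactExpectedTmrca(10)
#' @export
exactExpectedTmrca <- function(N) {
  if (N == 1) return(0)
  P <- exactAncestorChain(N)
  E <- numeric(N)            # E[j]: expected generations from j lineages
  for (j in 2:N) {
    acc <- 1
    if (j > 2)
      acc <- acc + sum(P[j, 2:(j - 1)] * E[2:(j - 1)])
    E[j] <- acc / (1 - P[j, j])
  }
  E[N]
}
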
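#' Trace a sampled generation backwards to its common ancestors
#'
#' The sample is every cell whose generation label equals
#' \code{sampleGeneration} (regardless of spatial position).  Traversal
#' follows parent pointers only; ancestors are identified by cell id, not
#' lattice site, so diffusion does not affect the trace.  Generations back
#' are counted as generation differences, so a sample taken at generation
#' 200 whose MRCA sits in generation 96 has a T_MRCA of 104.
#'
#' @param genealogy a [Genealogy-class].
#' @param sampleGeneration generation to sample (all its cells).
#' @return a [LineageCurve-class]; element \code{g + 1} of its counts is the
#'   number of distinct ancestors \code{g} generations back.
#' @examples
#' g <- makeFixture("star")
#' lineageCounts(traceLineages(g, 1))   # 5 children -> 1 founder
#' @export
setMethod("traceLineages", "Genealogy", function(genealogy, sampleGeneration) {
  sampleGeneration <- as.integer(sampleGeneration)
  stopifnot(length(sampleGeneration) == 1L, sampleGeneration >= 0L)
  if (sampleGeneration > maxGeneration(genealogy))
    stop("sample generation ", sampleGeneration,
         " is absent from the genealogy (max is ",
         maxGeneration(genealogy), ")")
  counts <- .cppTraceCounts(genealogy@parent, genealogy@generation,
                            sampleGeneration)
  new("LineageCurve", sampleGeneration = sampleGeneration, counts = counts)
})

#' Time to the most recent common ancestor
#'
#' The smallest number of generations back at which the sampled lineages
#' have merged into a single ancestor.  "Not coalesced" is a first-class
#' outcome, returned as \code{NA}: samples from unbounded growth routinely
#' trace back to several founder-era lineages without ever merging.
#'
#' @param x a [Genealogy-class] or a [LineageCurve-class].
#' @param sampleGeneration generation to sample (Genealogy method).
#' @param ... passed between methods.
#' @return a single integer number of generations, or \code{NA} if the
#'   sample does not coalesce within the recorded history.
#' @examples
#' tmrca(makeFixture("chain"), 10)  # 0: a single sampled cell is its own MRCA
#' tmrca(makeFixture("star"), 1)    # 1: five children merge in their founder
#' @export
setMethod("tmrca", "Genealogy", function(x, sampleGeneration, ...) {
  tmrca(traceLineages(x, sampleGeneration))
})

#' @rdname tmrca
#' @export
setMethod("tmrca", "LineageCurve", function(x, ...) {
  g <- which(x@counts == 1L)
  if (length(g)) g[1L] - 1L else NA_integer_
})

#' Excess lineages beyond the common ancestor
#'
#' The number of lineages in addition to the single common ancestor of the
#' population: elementwise \code{counts - 1}, so a coalesced tail is 0.
#'
#' @param curve a [LineageCurve-class].
#' @return integer vector, same length as the curve's counts.
#' @examples
#' excessLineages(traceLineages(makeFixture("star"), 1))
#' @export
excessLineages <- function(curve) {
  stopifnot(is(curve, "LineageCurve"))
  lineageCounts(curve) - 1L
}

.checkEnsemble <- function(curves) {
  if (length(curves) == 0L)
    stop("empty ensemble of lineage curves")
  stopifnot(all(vapply(curves, is, logical(1), "LineageCurve")))
  sg <- vapply(curves, sampleGeneration, integer(1))
  if (length(unique(sg)) != 1L)
    stop("all curves must share the same sample generation")
  sg[1L]
}

#' Probability of coalescence by a given look-back time
#'
#' Fraction of replicate lineage curves that have reached a single common
#' ancestor within \code{g} generations back.  Replicates whose recorded
#' history ends without coalescing count as not coalesced.
#'
#' @param curves list of [LineageCurve-class] replicates with a common
#'   sample generation.
#' @param g generations back; if \code{NULL}, the whole curve over
#'   \code{0:sampleGeneration} is returned.
#' @return numeric fraction(s) in \[0, 1\], non-decreasing in \code{g}.
#' @examples
#' cv <- replicate(20, traceLineages(simulateWF(5, 40), 40))
#' coalescenceProbability(cv, 25)
#' @export
coalescenceProbability <- function(curves, g = NULL) {
  sg <- .checkEnsemble(curves)
  tm <- vapply(curves, tmrca, integer(1))
  if (is.null(g)) g <- 0:sg
  stopifnot(all(g >= 0), all(g <= sg))
  vapply(g, function(gg) mean(!is.na(tm) & tm <= gg), numeric(1))
}

#' Mean excess lineages across replicates
#'
#' @inheritParams coalescenceProbability
#' @return numeric vector over \code{g = 0:sampleGeneration} of the
#'   ensemble-mean number of lineages in excess of one.
#' @export
meanExcessLineages <- function(curves) {
  .checkEnsemble(curves)
  rowMeans(vapply(curves, function(cv) as.numeric(excessLineages(cv)),
                  numeric(length(lineageCounts(curves[[1L]])))))
}

#' Serialize a traced genealogy as Newick
#'
#' Builds the genealogical tree of the sampled generation (all cells with
#' that generation label), rooted at the MRCA, with branch lengths in
#' generations; unary chains of single-child ancestors are collapsed so the
#' root-to-leaf path length equals the T_MRCA.  Leaf labels are cell ids
#' (\code{c<id>}, 0-based).  If the sample does not coalesce a forest is
#' emitted, one semicolon-terminated tree per surviving root lineage,
#' separated by newlines.
#'
#' @inheritParams traceLineages
#' @return a character scalar of Newick text.
#' @examples
#' toNewick(makeFixture("star"), 1)
#' @export
setMethod("toNewick", "Genealogy", function(genealogy, sampleGeneration) {
  sampleGeneration <- as.integer(sampleGeneration)
  par <- genealogy@parent
  gen <- genealogy@generation
  if (sampleGeneration > maxGeneration(genealogy))
    stop("sample generation absent from the genealogy")
  leaves <- which(gen == sampleGeneration)

  # ancestor sets per look-back step, stopping at the MRCA (or generation 0)
  levels <- list(leaves)
  cur <- leaves
  g <- 0L
  while (length(cur) > 1L && g < sampleGeneration) {
    cur <- unique(par[cur])
    g <- g + 1L
    levels[[g + 1L]] <- cur
  }
  roots <- cur

  nodes <- unlist(levels, use.names = FALSE)
  nodes <- unique(nodes)
  # children within the traced subgraph
  sub <- setdiff(nodes, roots)
  kids <- split(sub, par[sub])

  emit <- function(node) {
    # collapse unary chains iteratively; returns c(label, edge length)
    len <- 0L
    repeat {
      ch <- kids[[as.character(node)]]
      if (is.null(ch)) return(list(lab = paste0("c", node - 1L), len = len))
      if (length(ch) == 1L) { node <- ch; len <- len + 1L; next }
      parts <- vapply(ch, function(k) {
        r <- emit(k)
        paste0(r$lab, ":", r$len + 1L)
      }, character(1))
      return(list(lab = paste0("(", paste(parts, collapse = ","), ")"),
                  len = len))
    }
  }

  trees <- vapply(roots, function(r) paste0(emit(r)$lab, ";"), character(1))
  paste(trees, collapse = "\n")
})
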
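#' Construct a Genealogy from a parent-pointer table
#'
#' @param parent integer vector; 1-based record index of each cell's parent,
#'   \code{NA} for founders.
#' @param generation integer vector of generation numbers.
#' @param site integer matrix of lattice coordinates (2 or 3 columns).
#' @return a [Genealogy-class] object.
#' @examples
#' # one founder with two children, one generation later
#' Genealogy(parent = c(NA, 1L, 1L), generation = c(0L, 1L, 1L),
#'           site = cbind(x = 0:2, y = c(0L, 1L, 1L)))
#' @export
Genealogy <- function(parent, generation, site) {
  if (is.null(colnames(site)))
    colnames(site) <- c("x", "y", "z")[seq_len(ncol(site))]
  new("Genealogy", parent = as.integer(parent),
      generation = as.integer(generation),
      site = site)
}

#' @rdname accessors
#' @export
setMethod("nCells", "Genealogy", function(x) length(x@parent))

#' @rdname accessors
#' @export
setMethod("maxGeneration", "Genealogy", function(x) max(x@generation))

#' @rdname accessors
#' @export
setMethod("cellSites", "Genealogy", function(x) x@site)

#' @rdname accessors
#' @export
setMethod("nCells", "EdenResult", function(x) nCells(x@genealogy))

#' @rdname accessors
#' @export
setMethod("maxGeneration", "EdenResult",
  function(x) maxGeneration(x@genealogy))

#' @rdname accessors
#' @export
setMethod("genealogy", "EdenResult", function(x) x@genealogy)

#' @rdname accessors
#' @export
setMethod("positions", "EdenResult", function(x) x@positions)

#' @rdname accessors
#' @export
setMethod("lineageCounts", "LineageCurve", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("sampleGeneration", "LineageCurve", function(x) x@sampleGeneration)

setMethod("show", "Genealogy", function(object) {
  cat("Genealogy with", nCells(object), "cells,",
      sum(is.na(object@parent)), "founder(s), generations 0 -",
      maxGeneration(object), "\n")
})

setMethod("show", "LineageCurve", function(object) {
  ct <- object@counts
  tm <- tmrca(object)
  cat("LineageCurve: sample of", ct[1L], "cells at generation",
      object@sampleGeneration, "\n  ",
      if (is.na(tm)) "not coalesced within recorded history"
      else paste("coalesced; T_MRCA =", tm, "generations"), "\n")
})

setMethod("show", "EdenResult", function(object) {
  p <- object@params
  cat("EdenResult:", p$geometry,
      if (!is.null(p$width)) paste0("(width ", p$width, ")") else "",
      "\n  ", nCells(object), "cells, generations 0 -",
      maxGeneration(object), ";", object@nEvents, "events (",
      object@nMoves, "diffusion attempts,", object@nRejected,
      "rejected )\n")
})

#' Read and write genealogy tables as CSV
#'
#' The on-disk format has a header \code{id,parent_id,generation,x,y[,z]}
#' with 0-based ids and lattice coordinates and an empty \code{parent_id}
#' for founders.
#'
#' @param genealogy a [Genealogy-class].
#' @param path file path.
#' @return \code{writeGenealogyCsv} returns \code{path} invisibly;
#'   \code{readGenealogyCsv} returns a [Genealogy-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeGenealogyCsv(makeFixture("star"), f)
#' readGenealogyCsv(f)
#' @export
writeGenealogyCsv <- function(genealogy, path) {
  st <- cellSites(genealogy)
  df <- data.frame(id = seq_len(nCells(genealogy)) - 1L,
                   parent_id = genealogy@parent - 1L,
                   generation = genealogy@generation)
  df <- cbind(df, as.data.frame(st))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeGenealogyCsv
#' @export
readGenealogyCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "parent_id", "generation", "x", "y")
  if (!all(need %in% names(df)))
    stop("genealogy CSV must have columns ", paste(need, collapse = ","))
  if (!identical(as.integer(df$id), seq_len(nrow(df)) - 1L))
    stop("genealogy CSV ids must be 0-based and consecutive")
  coords <- intersect(c("x", "y", "z"), names(df))
  Genealogy(parent = df$parent_id + 1L,
            generation = df$generation,
            site = as.matrix(df[coords]))
}
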
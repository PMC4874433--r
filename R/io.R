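#' Build and validate a simulation run configuration
#'
#' Checks parameter combinations up front (e.g. diffusion is only
#' meaningful for Eden models, bounded Eden needs width >= 2) and fixes
#' the deterministic seed-splitting rule: replicate i runs under
#' \code{seed + i}.
#'
#' @param model one of \code{"wf"}, \code{"wf-linear"},
#'   \code{"eden-bounded"}, \code{"eden-diffusive"},
#'   \code{"eden-unbounded"}.
#' @param N width (constant-size and bounded models).
#' @param N0,lambda linear-growth schedule parameters.
#' @param generations sampling generation G.
#' @param dimension 2 or 3 (bounded Eden).
#' @param pMove diffusion probability (eden-diffusive only).
#' @param replicates number of replicates.
#' @param seed integer master seed.
#' @param outDir output directory for [runSimulation()].
#' @return a [RunConfig-class].
#' @examples
#' runConfig("wf", N = 10, generations = 50, replicates = 2, seed = 1)
#' @export
runConfig <- function(model = c("wf", "wf-linear", "eden-bounded",
                                "eden-diffusive", "eden-unbounded"),
                      N = NULL, N0 = 1, lambda = 2.78, generations,
                      dimension = 2, pMove = 0.925, replicates = 1,
                      seed = 0, outDir = tempfile("coalGrowth")) {
  model <- match.arg(model)
  if (model %in% c("wf", "eden-bounded", "eden-diffusive")) {
    if (is.null(N)) stop("model '", model, "' requires 'N'")
    if (model != "wf" && N < 2)
      stop("'N': bounded Eden growth needs a width of at least 2 cells")
  }
  if (model %in% c("wf", "wf-linear") && !missing(pMove) && pMove != 0)
    stop("'pMove': diffusion applies to Eden models only")
  params <- switch(model,
    "wf" = list(N = as.integer(N), generations = as.integer(generations)),
    "wf-linear" = list(N0 = N0, lambda = lambda,
                       generations = as.integer(generations)),
    "eden-bounded" = list(N = as.integer(N), dimension = dimension,
                          generations = as.integer(generations), pMove = 0),
    "eden-diffusive" = list(N = as.integer(N), dimension = dimension,
                            generations = as.integer(generations),
                            pMove = pMove),
    "eden-unbounded" = list(generations = as.integer(generations)))
  new("RunConfig", model = model, params = params,
      replicates = as.integer(replicates), seed = as.integer(seed),
      outDir = outDir)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:", object@model, "x", object@replicates,
      "replicates (seed", paste0(object@seed, ")"), "\n  params:",
      paste(names(object@params), unlist(object@params), sep = "=",
            collapse = ", "), "\n  outDir:", object@outDir, "\n")
})

.simulateOne <- function(config, i) {
  p <- config@params
  s <- .replicateSeed(config@seed, i)
  switch(config@model,
    "wf" = simulateWF(p$N, p$generations, seed = s),
    "wf-linear" = simulateLinearWF(p$N0, p$lambda, p$generations, seed = s),
    "eden-bounded" = ,
    "eden-diffusive" = genealogy(simulateEden(width = p$N,
        generations = p$generations, dimension = p$dimension,
        pMove = p$pMove, stop = "complete", seed = s)),
    "eden-unbounded" = genealogy(simulateEden(generations = p$generations,
        geometry = "unbounded", stop = "complete", seed = s)))
}

#' Run a configured simulation ensemble and write its outputs
#'
#' Writes, under \code{outDir}: one genealogy CSV per replicate
#' (\code{rep_<i>_genealogy.csv}), the ensemble lineage summary
#' \code{lineage_curves.csv} (columns \code{g}, \code{mean_lineages},
#' \code{prob_coalesced}) and \code{summary.json} (model, parameters,
#' seed, replicate count, mean T_MRCA over coalesced replicates and the
#' number that did not coalesce).  Identical configurations produce
#' byte-identical outputs.
#'
#' @param config a [RunConfig-class].
#' @param quiet suppress the log message.
#' @return the output directory, invisibly.
#' @examples
#' cfg <- runConfig("wf", N = 5, generations = 30, replicates = 2, seed = 1)
#' dir <- runSimulation(cfg, quiet = TRUE)
#' list.files(dir)
#' @export
runSimulation <- function(config, quiet = FALSE) {
  stopifnot(is(config, "RunConfig"))
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  G <- config@params$generations
  curves <- vector("list", config@replicates)
  for (i in seq_len(config@replicates)) {
    g <- .simulateOne(config, i)
    writeGenealogyCsv(g, file.path(config@outDir,
                                   sprintf("rep_%03d_genealogy.csv", i)))
    curves[[i]] <- traceLineages(g, G)
  }
  curveDf <- data.frame(g = 0:G,
                        mean_lineages = meanExcessLineages(curves) + 1,
                        prob_coalesced = coalescenceProbability(curves))
  utils::write.csv(curveDf, file.path(config@outDir, "lineage_curves.csv"),
                   row.names = FALSE, quote = FALSE)
  tm <- vapply(curves, tmrca, integer(1))
  summ <- list(model = config@model, params = config@params,
               seed = config@seed, replicates = config@replicates,
               nNotCoalesced = sum(is.na(tm)),
               meanTmrca = mean(tm, na.rm = TRUE))
  jsonlite::write_json(summ, file.path(config@outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet)
    message("coalGrowth: ", config@model, " N-params [",
            paste(names(config@params), unlist(config@params), sep = "=",
                  collapse = ", "), "] seed ", config@seed, "; ",
            config@replicates, " replicates, ", sum(is.na(tm)),
            " not coalesced -> ", config@outDir)
  invisible(config@outDir)
}

#' Small deterministic genealogies for examples and tests
#'
#' \describe{
#'   \item{chain}{10 generations of a single cell each; every trace is a
#'     single lineage.}
#'   \item{star}{one founder with five generation-1 children; counts from
#'     generation 1 are \code{c(5, 1)}.}
#'   \item{wf-tiny}{Wright-Fisher, N = 4, G = 20, fixed seed.}
#'   \item{eden-tiny}{bounded Eden, width 4, G = 10, fixed seed.}
#' }
#'
#' @param name fixture name.
#' @return a [Genealogy-class].
#' @examples
#' tmrca(makeFixture("chain"), 10)   # 0: a single sampled cell is its own MRCA
#' @export
makeFixture <- function(name = c("chain", "star", "wf-tiny", "eden-tiny")) {
  name <- match.arg(name)
  switch(name,
    "chain" = Genealogy(parent = c(NA, 1:10), generation = 0:10,
                        site = cbind(x = rep(0L, 11), y = 0:10)),
    "star" = Genealogy(parent = c(NA, rep(1L, 5)),
                       generation = c(0L, rep(1L, 5)),
                       site = cbind(x = 0:5, y = c(0L, rep(1L, 5)))),
    "wf-tiny" = simulateWF(4, 20, seed = 11),
    "eden-tiny" = genealogy(simulateEden(width = 4, generations = 10,
                                         stop = "complete", seed = 7)))
}
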
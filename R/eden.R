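#' Simulate Eden growth on a square lattice
#'
#' Growth occurs only at the boundary (occupied cells abutting an empty
#' site).  Each growth event picks an empty site adjacent to the cluster
#' uniformly among all such sites, then picks the new cell's parent
#' uniformly among the site's occupied von-Neumann neighbours; the child's
#' generation is its parent's plus one.  With diffusion enabled, each event
#' is instead (with probability \code{pMove}) a hop attempt: a uniformly
#' chosen boundary cell tries to move into a uniformly chosen empty
#' neighbour.  The move is rejected unless (i) the destination touches an
#' occupied cell other than the mover and (ii) vacating the origin leaves
#' the mover's occupied neighbours mutually connected through the occupied
#' sites immediately surrounding the origin, so the cluster provably stays
#' connected.  Ids and generation labels travel with moving cells.
#'
#' Geometries: \code{"bounded"} growth advances in +depth from a transverse
#' axis of width \code{width} ((1+1) dimensions) or a \code{width x width}
#' base ((2+1) dimensions) with periodic transverse boundaries;
#' \code{"unbounded"} growth spreads radially from a single founder at the
#' origin (a tumour / bacterial colony).
#'
#' The run stops either at the first birth of a generation-\code{G} cell
#' (\code{stop = "first-birth"}) or once no boundary cell has generation
#' \code{G - 1} or lower (\code{stop = "complete"}), after which no further
#' cell of generation \code{<= G} can be born, so the generation-\code{G}
#' cohort is final.  Use \code{"complete"} whenever the full sampled
#' generation is needed (coalescent tracing, cohort counts).
#'
#' @param width cells per transverse axis (bounded geometry; >= 2).
#' @param generations stop generation G (>= 1).
#' @param geometry \code{"bounded"} or \code{"unbounded"}.
#' @param dimension 2 for (1+1), 3 for (2+1); unbounded growth is planar.
#' @param init \code{"full-layer"} places a complete generation-0 layer at
#'   depth 0 (bounded default); \code{"single-seed"} one founder.
#' @param pMove per-event probability of a diffusion attempt, in \[0, 1).
#' @param stop stop condition, see above.
#' @param seed optional integer for \code{set.seed()}.
#' @param recordWidth record the front-width series (sd of boundary depths)
#'   every \code{widthEvery} events (C engine, bounded geometry).
#' @param widthEvery events between width measurements.
#' @param engine \code{"C"} (fast path) or \code{"R"} (reference stepper;
#'   draws the identical RNG sequence, for validation on small runs).
#' @param maxEvents abort guard; 0 means unlimited.
#' @return an [EdenResult-class].
#' @examples
#' res <- simulateEden(width = 10, generations = 30, seed = 1)
#' tmrca(genealogy(res), 30)
#' @export
simulateEden <- function(width = NULL, generations,
                         geometry = c("bounded", "unbounded"),
                         dimension = 2,
                         init = c("full-layer", "single-seed"),
                         pMove = 0, stop = c("first-birth", "complete"),
                         seed = NULL, recordWidth = FALSE,
                         widthEvery = max(1L, as.integer(width %||% 1L)),
                         engine = c("C", "R"), maxEvents = 0) {
  geometry <- match.arg(geometry)
  init <- match.arg(init)
  stopType <- match.arg(stop)
  engine <- match.arg(engine)
  stopifnot(generations >= 1, pMove >= 0, pMove < 1)
  if (geometry == "bounded") {
    if (is.null(width) || width < 2)
      base::stop("bounded Eden growth needs 'width' >= 2")
    if (!dimension %in% 2:3)
      base::stop("'dimension' must be 2 (1+1) or 3 (2+1)")
    geom <- if (dimension == 2) 0L else 1L
  } else {
    if (!identical(dimension, 2) && !identical(dimension, 2L))
      base::stop("unbounded Eden growth is planar ('dimension' = 2)")
    geom <- 2L
    init <- "single-seed"
    width <- 0L
  }
  if (!is.null(seed)) set.seed(seed)
  sm <- if (stopType == "first-birth") 0L else 1L
  raw <- if (engine == "C")
    .cppSimEden(geom, as.integer(width), as.integer(generations),
                init == "full-layer", pMove, sm, maxEvents,
                recordWidth, as.integer(widthEvery))
  else
    .simEdenR(geom, as.integer(width), as.integer(generations),
              init == "full-layer", pMove, sm, maxEvents)
  cn <- if (geom == 1L) c("x", "y", "z") else c("x", "y")
  bs <- raw$birthSite; colnames(bs) <- cn
  cs <- raw$site; colnames(cs) <- cn
  ws <- raw$widthSeries
  if (!is.null(ws)) ws <- data.frame(event = ws$event, width = ws$width)
  new("EdenResult",
      genealogy = Genealogy(raw$parent, raw$generation, bs),
      positions = cs, isBoundary = raw$isBoundary, widthSeries = ws,
      params = list(geometry = geometry, dimension = dimension,
                    width = width, generations = generations, init = init,
                    pMove = pMove, stop = stopType),
      nEvents = raw$nEvents, nMoves = raw$nMoves,
      nRejected = raw$nRejected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Pure-R reference implementation.  Mirrors the C engine structure for
# structure (swap-removal site sets, refresh order, draw order) so that a
# run with the same seed is bit-identical; used as the step-level surface
# (stepGrowth / stepDiffusion) and for cross-validation on small lattices.
# Sites are 0-based linear indices, as in the C engine.

#' Initialise an Eden simulation state
#'
#' Creates the explicit simulation state (occupancy grid, growth-candidate
#' set, boundary set, genealogy vectors) operated on by [stepGrowth()] and
#' [stepDiffusion()].  This is the reference R implementation of the
#' stepper; [simulateEden()] with \code{engine = "C"} runs the same process
#' in compiled code.
#'
#' @inheritParams simulateEden
#' @return an environment of class \code{"EdenState"}.
#' @examples
#' st <- edenInit(generations = 5, geometry = "unbounded")
#' stepGrowth(st)
#' length(st$parent)  # founder + 1 child
#' @export
edenInit <- function(width = NULL, generations,
                     geometry = c("bounded", "unbounded"), dimension = 2,
                     init = c("full-layer", "single-seed"), pMove = 0) {
  geometry <- match.arg(geometry)
  init <- match.arg(init)
  geom <- if (geometry == "unbounded") 2L else if (dimension == 2) 0L else 1L
  if (geom == 2L) { init <- "single-seed"; width <- 0L }
  st <- new.env(parent = emptyenv())
  st$geom <- geom; st$N <- as.integer(width)
  st$G <- as.integer(generations); st$pMove <- pMove
  st$nEvents <- st$nMoves <- st$nRejected <- 0
  if (geom == 2L) {
    st$side <- 2L * (st$G + 64L) + 1L
    nsite <- st$side^2
    st$depthCap <- NA_integer_
  } else {
    st$depthCap <- st$G + 4L
    layer <- if (geom == 0L) st$N else st$N^2
    nsite <- layer * st$depthCap
  }
  st$cellAt <- rep.int(-1L, nsite)
  st$candPos <- rep.int(-1L, nsite)
  st$bndPos <- rep.int(-1L, nsite)
  st$cand <- integer(0); st$bnd <- integer(0); st$bndLow <- logical(0)
  st$lowCnt <- 0L
  st$parent <- integer(0); st$gen <- integer(0)
  st$birth <- integer(0); st$cur <- integer(0)
  addCell <- function(s, p, g) {
    st$parent <- c(st$parent, p); st$gen <- c(st$gen, g)
    st$birth <- c(st$birth, s); st$cur <- c(st$cur, s)
    st$cellAt[s + 1L] <- length(st$parent) - 1L
  }
  if (geom == 2L) {
    origin <- (st$side %/% 2L) * st$side + st$side %/% 2L
    addCell(origin, NA_integer_, 0L)
    .edenRefreshAround(st, origin)
  } else {
    layer <- if (geom == 0L) st$N else st$N^2
    if (init == "full-layer") {
      for (i in 0:(layer - 1L)) addCell(i, NA_integer_, 0L)
      for (i in 0:(layer - 1L)) .edenRefresh(st, i)
      for (i in 0:(layer - 1L)) {
        for (nb in .edenNeighbours(st, i))
          if (nb >= 0L && st$cellAt[nb + 1L] < 0L &&
              st$candPos[nb + 1L] < 0L)
            .edenRefresh(st, nb)
      }
    } else {
      s0 <- if (geom == 0L) st$N %/% 2L
            else (st$N %/% 2L) * st$N + st$N %/% 2L
      addCell(s0, NA_integer_, 0L)
      .edenRefreshAround(st, s0)
    }
  }
  class(st) <- "EdenState"
  st
}

# neighbour site indices in the canonical order (+x, -x, [+y, -y,] +depth,
# -depth); -1 marks a missing neighbour (below depth 0 / outside the margin).
# Extends the depth capacity on demand, like the C engine.
.edenNeighbours <- function(st, s) {
  if (st$geom == 0L) {
    N <- st$N; x <- s %% N; d <- s %/% N
    .edenGrowDepth(st, d + 1L)
    c(if (x + 1L == N) d * N else s + 1L,
      if (x == 0L) d * N + N - 1L else s - 1L,
      s + N,
      if (d > 0L) s - N else -1L)
  } else if (st$geom == 1L) {
    N <- st$N; NN <- N * N
    x <- s %% N; y <- (s %/% N) %% N; d <- s %/% NN
    .edenGrowDepth(st, d + 1L)
    base <- d * NN
    c(base + (if (x + 1L == N) 0L else x + 1L) + y * N,
      base + (if (x == 0L) N - 1L else x - 1L) + y * N,
      base + x + (if (y + 1L == N) 0L else y + 1L) * N,
      base + x + (if (y == 0L) N - 1L else y - 1L) * N,
      base + NN + x + y * N,
      if (d > 0L) base - NN + x + y * N else -1L)
  } else {
    side <- st$side; x <- s %% side; y <- s %/% side
    c(if (x + 1L < side) s + 1L else -1L,
      if (x > 0L) s - 1L else -1L,
      if (y + 1L < side) s + side else -1L,
      if (y > 0L) s - side else -1L)
  }
}

.edenGrowDepth <- function(st, need) {
  if (is.na(st$depthCap) || need < st$depthCap) return(invisible())
  layer <- if (st$geom == 0L) st$N else st$N^2
  newCap <- st$depthCap
  while (newCap <= need) newCap <- newCap * 2L
  extra <- rep.int(-1L, layer * (newCap - st$depthCap))
  st$cellAt <- c(st$cellAt, extra)
  st$candPos <- c(st$candPos, extra)
  st$bndPos <- c(st$bndPos, extra)
  st$depthCap <- newCap
  invisible()
}

.edenRefresh <- function(st, s) {
  nbs <- .edenNeighbours(st, s)
  nbs <- nbs[nbs >= 0L]
  if (st$cellAt[s + 1L] >= 0L) {
    if (st$candPos[s + 1L] >= 0L) .edenRemoveCand(st, s)
    want <- any(st$cellAt[nbs + 1L] < 0L)
    if (want && st$bndPos[s + 1L] < 0L)
      .edenAddBnd(st, s, st$gen[st$cellAt[s + 1L] + 1L] <= st$G - 1L)
    else if (!want && st$bndPos[s + 1L] >= 0L) .edenRemoveBnd(st, s)
  } else {
    if (st$bndPos[s + 1L] >= 0L) .edenRemoveBnd(st, s)
    want <- any(st$cellAt[nbs + 1L] >= 0L)
    if (want && st$candPos[s + 1L] < 0L) .edenAddCand(st, s)
    else if (!want && st$candPos[s + 1L] >= 0L) .edenRemoveCand(st, s)
  }
}

.edenRefreshAround <- function(st, s) {
  .edenRefresh(st, s)
  for (nb in .edenNeighbours(st, s)) if (nb >= 0L) .edenRefresh(st, nb)
}

.edenAddCand <- function(st, s) {
  st$cand <- c(st$cand, s)
  st$candPos[s + 1L] <- length(st$cand) - 1L
}
.edenRemoveCand <- function(st, s) {
  i <- st$candPos[s + 1L]; last <- st$cand[length(st$cand)]
  st$cand[i + 1L] <- last; st$candPos[last + 1L] <- i
  st$cand <- st$cand[-length(st$cand)]
  st$candPos[s + 1L] <- -1L
}
.edenAddBnd <- function(st, s, low) {
  st$bnd <- c(st$bnd, s); st$bndLow <- c(st$bndLow, low)
  st$bndPos[s + 1L] <- length(st$bnd) - 1L
  if (low) st$lowCnt <- st$lowCnt + 1L
}
.edenRemoveBnd <- function(st, s) {
  i <- st$bndPos[s + 1L]; n <- length(st$bnd)
  if (st$bndLow[i + 1L]) st$lowCnt <- st$lowCnt - 1L
  last <- st$bnd[n]
  st$bnd[i + 1L] <- last; st$bndLow[i + 1L] <- st$bndLow[n]
  st$bndPos[last + 1L] <- i
  st$bnd <- st$bnd[-n]; st$bndLow <- st$bndLow[-n]
  st$bndPos[s + 1L] <- -1L
}

#' Perform a single Eden growth event
#'
#' Chooses an empty site adjacent to the cluster uniformly among all such
#' sites, then the new cell's parent uniformly among the site's occupied
#' von-Neumann neighbours, and appends the child record (generation =
#' parent's + 1).  Operates in place on a state from [edenInit()].
#'
#' @param st an \code{EdenState} environment.
#' @return the generation of the newly created cell, invisibly.
#' @export
stepGrowth <- function(st) {
  gi <- sample.int(length(st$cand), 1L)
  s <- st$cand[gi]
  nbs <- .edenNeighbours(st, s)
  occ <- nbs[nbs >= 0L]
  occ <- occ[st$cellAt[occ + 1L] >= 0L]
  pi <- if (length(occ) > 1L) sample.int(length(occ), 1L) else 1L
  p <- st$cellAt[occ[pi] + 1L]
  g <- st$gen[p + 1L] + 1L
  st$parent <- c(st$parent, p + 1L)      # stored 1-based, NA for founders
  st$gen <- c(st$gen, g)
  st$birth <- c(st$birth, s); st$cur <- c(st$cur, s)
  st$cellAt[s + 1L] <- length(st$parent) - 1L
  st$nEvents <- st$nEvents + 1
  .edenRefreshAround(st, s)
  invisible(g)
}

#' Perform a single Eden diffusion attempt
#'
#' A uniformly chosen boundary cell attempts to hop into a uniformly chosen
#' empty von-Neumann neighbour; the move is rejected (a no-op) unless the
#' destination is adjacent to an occupied cell other than the mover and
#' the origin's occupied neighbours remain locally connected without it.
#' Id and generation travel with the cell.
#'
#' @param st an \code{EdenState} environment.
#' @return \code{TRUE} if the move was accepted, invisibly.
#' @export
stepDiffusion <- function(st) {
  st$nEvents <- st$nEvents + 1
  st$nMoves <- st$nMoves + 1
  bi <- sample.int(length(st$bnd), 1L)
  a <- st$bnd[bi]
  nbs <- .edenNeighbours(st, a)
  emp <- nbs[nbs >= 0L]
  emp <- emp[st$cellAt[emp + 1L] < 0L]
  if (length(emp) == 0L) { st$nRejected <- st$nRejected + 1; return(invisible(FALSE)) }
  di <- if (length(emp) > 1L) sample.int(length(emp), 1L) else 1L
  b <- emp[di]
  nbb <- .edenNeighbours(st, b)
  nbb <- nbb[nbb >= 0L & nbb != a]
  if (!any(st$cellAt[nbb + 1L] >= 0L) || !.edenRingConnected(st, a)) {
    st$nRejected <- st$nRejected + 1
    return(invisible(FALSE))
  }
  cc <- st$cellAt[a + 1L]
  st$cellAt[a + 1L] <- -1L; st$cellAt[b + 1L] <- cc
  st$cur[cc + 1L] <- b
  .edenRefreshAround(st, a)
  .edenRefreshAround(st, b)
  invisible(TRUE)
}

# site index from coordinates (transverse wrap, depth >= 0), -1 if outside
.edenSiteAt <- function(st, x, y, z) {
  if (st$geom == 0L) {
    if (y < 0L) return(-1L)
    .edenGrowDepth(st, y + 1L)
    ((x %% st$N) + st$N) %% st$N + y * st$N
  } else if (st$geom == 1L) {
    if (z < 0L) return(-1L)
    .edenGrowDepth(st, z + 1L)
    ((x %% st$N) + st$N) %% st$N + (((y %% st$N) + st$N) %% st$N) * st$N +
      z * st$N * st$N
  } else {
    if (x < 0L || y < 0L || x >= st$side || y >= st$side) return(-1L)
    x + y * st$side
  }
}

.edenCoords <- function(st, s) {
  if (st$geom == 0L) c(s %% st$N, s %/% st$N, 0L)
  else if (st$geom == 1L) {
    NN <- st$N * st$N
    c(s %% st$N, (s %/% st$N) %% st$N, s %/% NN)
  } else c(s %% st$side, s %/% st$side, 0L)
}

# local-connectivity check mirroring the C engine: occupied von-Neumann
# neighbours of a must stay mutually connected through the occupied ring
# around a once a is treated as empty
.edenRingConnected <- function(st, a) {
  ac <- .edenCoords(st, a)
  zr <- if (st$geom == 1L) -1:1 else 0L
  ring <- integer(0)
  for (dz in zr) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    s <- .edenSiteAt(st, ac[1] + dx, ac[2] + dy, ac[3] + dz)
    if (s >= 0L && s != a && st$cellAt[s + 1L] >= 0L && !(s %in% ring))
      ring <- c(ring, s)
  }
  nbs <- .edenNeighbours(st, a)
  occ <- unique(nbs[nbs >= 0L])
  occ <- occ[st$cellAt[occ + 1L] >= 0L]
  if (length(occ) <= 1L) return(TRUE)
  dist1 <- function(s1, s2) {
    c1 <- .edenCoords(st, s1); c2 <- .edenCoords(st, s2)
    dd <- abs(c1 - c2)
    if (st$geom != 2L) dd[1] <- min(dd[1], st$N - dd[1])
    if (st$geom == 1L) dd[2] <- min(dd[2], st$N - dd[2])
    sum(dd) == 1L
  }
  seen <- ring == occ[1]
  queue <- which(seen)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in seq_along(ring)) {
      if (!seen[j] && dist1(ring[i], ring[j])) {
        seen[j] <- TRUE; queue <- c(queue, j)
      }
    }
  }
  all(occ %in% ring[seen])
}

# full R-engine run mirroring EdenSim::run
.simEdenR <- function(geom, width, generations, fullLayer, pMove,
                      stopMode, maxEvents) {
  geometry <- if (geom == 2L) "unbounded" else "bounded"
  dimension <- if (geom == 1L) 3L else 2L
  st <- edenInit(width = width, generations = generations,
                 geometry = geometry, dimension = dimension,
                 init = if (fullLayer) "full-layer" else "single-seed",
                 pMove = pMove)
  if (!(stopMode == 1L && st$lowCnt == 0L)) repeat {
    if (maxEvents > 0 && st$nEvents >= maxEvents)
      base::stop("event budget exceeded before reaching the stop condition")
    isMove <- if (pMove > 0) stats::runif(1L) < pMove else FALSE
    newGen <- -1L
    if (isMove) stepDiffusion(st) else newGen <- stepGrowth(st)
    if (stopMode == 0L) { if (newGen >= st$G) break }
    else if (st$lowCnt == 0L) break
  }
  n <- length(st$parent)
  decode <- function(sv) {
    if (geom == 0L) cbind(sv %% st$N, sv %/% st$N)
    else if (geom == 1L) {
      NN <- st$N * st$N
      cbind(sv %% st$N, (sv %/% st$N) %% st$N, sv %/% NN)
    } else {
      h <- st$side %/% 2L
      cbind(sv %% st$side - h, sv %/% st$side - h)
    }
  }
  list(parent = st$parent, generation = st$gen,
       birthSite = decode(st$birth), site = decode(st$cur),
       isBoundary = st$bndPos[st$cur + 1L] >= 0L,
       widthSeries = NULL,
       nEvents = st$nEvents, nMoves = st$nMoves,
       nRejected = st$nRejected)
}

#' @rdname frontWidthSeries
#' @export
setMethod("frontWidthSeries", "EdenResult", function(x) x@widthSeries)
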
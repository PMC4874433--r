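# Independent oracles, deliberately written with different machinery than
# the package (plain sets over a data.frame view of the records).

# data.frame view of a Genealogy
asRecords <- function(g) {
  data.frame(id = seq_len(nCells(g)), parent = g@parent,
             generation = g@generation)
}

# Set-based backward traversal: number of distinct ancestors of all
# generation-gs cells, g generations back, for g = 0..gs.
oracleTrace <- function(g, gs) {
  rec <- asRecords(g)
  cur <- rec$id[rec$generation == gs]
  counts <- integer(gs + 1)
  for (k in 0:gs) {
    counts[k + 1] <- length(cur)
    if (k < gs) cur <- unique(rec$parent[cur])
  }
  counts
}

oracleTmrca <- function(g, gs) {
  ct <- oracleTrace(g, gs)
  w <- which(ct == 1L)
  if (length(w)) w[1] - 1L else NA_integer_
}

# Occupancy helpers for Eden results (bounded (1+1) / unbounded 2-D).
# Rebuilds the boundary set from scratch: occupied cells with at least one
# empty von-Neumann neighbour (transverse axis periodic when width > 0).
oracleBoundary <- function(pos, width = 0) {
  key <- function(x, y) paste(x, y)
  occ <- new.env(hash = TRUE)
  for (i in seq_len(nrow(pos))) assign(key(pos[i, 1], pos[i, 2]), TRUE, occ)
  vapply(seq_len(nrow(pos)), function(i) {
    x <- pos[i, 1]; y <- pos[i, 2]
    xs <- if (width > 0) c((x + 1) %% width, (x - 1) %% width, x, x)
          else c(x + 1, x - 1, x, x)
    ys <- c(y, y, y + 1, y - 1)
    any(vapply(seq_len(4), function(j) {
      ys[j] >= 0 * (width > 0) - 1e9 &&  # depth never negative when bounded
        !exists(key(xs[j], ys[j]), occ)
    }, logical(1)) & (width == 0 | ys >= 0))
  }, logical(1))
}

# Connectivity of the occupied set via breadth-first search on sites.
oracleConnected <- function(pos, width = 0) {
  n <- nrow(pos)
  key <- function(x, y) paste(x, y)
  idx <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(key(pos[i, 1], pos[i, 2]), i, idx)
  seen <- logical(n)
  queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    x <- pos[i, 1]; y <- pos[i, 2]
    xs <- if (width > 0) c((x + 1) %% width, (x - 1) %% width, x, x)
          else c(x + 1, x - 1, x, x)
    ys <- c(y, y, y + 1, y - 1)
    for (j in 1:4) {
      k <- key(xs[j], ys[j])
      if (exists(k, idx)) {
        m <- get(k, idx)
        if (!seen[m]) { seen[m] <- TRUE; queue <- c(queue, m) }
      }
    }
  }
  all(seen)
}

# small WF ensemble of lineage curves
wfCurves <- function(N, G, reps, seed) {
  lapply(seq_len(reps), function(i)
    traceLineages(simulateWF(N, G, seed = seed + i), G))
}
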
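test_that("Genealogy validity enforces the parent-pointer invariants", {
  ok <- Genealogy(parent = c(NA, 1L, 1L), generation = c(0L, 1L, 1L),
                  site = cbind(x = 0:2, y = c(0L, 1L, 1L)))
  expect_s4_class(ok, "Genealogy")
  expect_equal(nCells(ok), 3L)
  expect_equal(maxGeneration(ok), 1L)
  # founder with non-zero generation
  expect_error(Genealogy(NA_integer_, 1L, cbind(x = 0L, y = 0L)),
               "generation 0")
  # child generation must be parent + 1
  expect_error(Genealogy(c(NA, 1L), c(0L, 2L), cbind(x = 0:1, y = 0:1)),
               "parent generation")
  # parent must precede child
  expect_error(Genealogy(c(2L, NA), c(1L, 0L), cbind(x = 0:1, y = 0:1)),
               "earlier record")
})

test_that("fixtures have their documented shapes", {
  ch <- makeFixture("chain")
  expect_equal(nCells(ch), 11L)
  expect_equal(tmrca(ch, 10), 0L)  # single sampled cell is its own MRCA
  expect_equal(lineageCounts(traceLineages(ch, 10)), rep(1L, 11))
  st <- makeFixture("star")
  expect_equal(lineageCounts(traceLineages(st, 1)), c(5L, 1L))
  expect_equal(tmrca(st, 1), 1L)
  expect_error(makeFixture("nope"))
})

test_that("lineage tracing handles single chains and disjoint founders", {
  # n founders with independent chains never coalesce
  n <- 4L; G <- 5L
  par <- c(rep(NA_integer_, n),
           vapply(1:(n * G), function(i) i, integer(1)))
  gen <- rep(0:G, each = n)
  site <- cbind(x = rep(0:(n - 1L), G + 1L), y = gen)
  g <- Genealogy(par, gen, site)
  ct <- lineageCounts(traceLineages(g, G))
  expect_equal(ct, rep(n, G + 1L))
  expect_true(is.na(tmrca(g, G)))
})

test_that("tmrca follows the generation-difference convention", {
  # single chain to generation 96, then two descendant chains to 200:
  # a sample at generation 200 has its MRCA in generation 96 -> tmrca 104
  par <- c(NA_integer_, 1:96)                   # chain: ids 1..97, gen 0..96
  gen <- 0:96
  nxt <- 97L
  for (branch in 1:2) {
    p <- 97L
    for (gg in 97:200) {
      nxt <- nxt + 1L
      par <- c(par, p); gen <- c(gen, gg)
      p <- nxt
    }
  }
  g <- Genealogy(par, gen, cbind(x = integer(length(par)), y = gen))
  expect_equal(tmrca(g, 200), 104L)
  expect_equal(tmrca(g, 0), 0L)
})

test_that("tracing matches the independent set-based oracle on WF runs", {
  for (seed in 1:5) {
    g <- simulateWF(5, 50, seed = seed)
    expect_equal(lineageCounts(traceLineages(g, 50)), oracleTrace(g, 50))
    expect_equal(tmrca(g, 50), oracleTmrca(g, 50))
    gs <- 17L  # interior sample generation
    expect_equal(lineageCounts(traceLineages(g, gs)), oracleTrace(g, gs))
  }
  g <- simulateWF(4, 40, seed = 99)
  expect_equal(tmrca(g, 40), oracleTmrca(g, 40))
})

test_that("lineage curves are non-increasing for all models", {
  sims <- list(simulateWF(6, 30, seed = 1),
               simulateLinearWF(2, 1.5, 25, seed = 2),
               genealogy(simulateEden(width = 5, generations = 15,
                                      stop = "complete", seed = 3)),
               genealogy(simulateEden(generations = 12,
                                      geometry = "unbounded",
                                      stop = "complete", seed = 4)))
  for (g in sims) {
    ct <- lineageCounts(traceLineages(g, maxGeneration(g) - 1L))
    expect_false(is.unsorted(rev(ct)))
    expect_true(all(ct >= 1L))
  }
})

test_that("sampling an absent generation is an explicit error", {
  g <- makeFixture("chain")
  expect_error(traceLineages(g, 11), "absent")
  expect_error(traceLineages(g, -1))
})

test_that("excess lineages are counts minus one and invert", {
  cv <- new("LineageCurve", sampleGeneration = 3L,
            counts = c(5L, 3L, 1L, 1L))
  expect_equal(excessLineages(cv), c(4L, 2L, 0L, 0L))
  expect_equal(excessLineages(cv) + 1L, lineageCounts(cv))
})

test_that("coalescence probability counts coalesced replicates", {
  mk <- function(counts, gs) new("LineageCurve",
                                 sampleGeneration = as.integer(gs),
                                 counts = as.integer(counts))
  all1 <- list(mk(c(3, 1, 1), 2), mk(c(2, 1, 1), 2))
  expect_equal(coalescenceProbability(all1, 2), 1.0)
  none <- list(mk(c(3, 2, 2), 2), mk(c(4, 3, 2), 2))
  expect_equal(coalescenceProbability(none, 2), 0.0)
  expect_error(coalescenceProbability(list()), "empty")
  # seeded WF: matches per-replicate oracle tmrca
  curves <- lapply(1:10, function(i) traceLineages(simulateWF(5, 60, seed = i), 60))
  oracles <- vapply(1:10, function(i)
    oracleTmrca(simulateWF(5, 60, seed = i), 60), integer(1))
  for (g in c(5L, 10L, 25L, 60L)) {
    expect_equal(coalescenceProbability(curves, g),
                 mean(!is.na(oracles) & oracles <= g))
  }
  pc <- coalescenceProbability(curves)
  expect_false(is.unsorted(pc))
})

test_that("genealogy CSV round-trips", {
  for (nm in c("star", "wf-tiny", "eden-tiny")) {
    g <- makeFixture(nm)
    f <- withr::local_tempfile(fileext = ".csv")
    writeGenealogyCsv(g, f)
    g2 <- readGenealogyCsv(f)
    expect_equal(g2@parent, g@parent)
    expect_equal(g2@generation, g@generation)
    expect_equal(unname(cellSites(g2)), unname(cellSites(g)))
  }
  hdr <- readLines(writeGenealogyCsv(makeFixture("star"),
                                     withr::local_tempfile()), n = 1)
  expect_equal(hdr, "id,parent_id,generation,x,y")
})

test_that("Newick output matches the documented conventions", {
  # two cells sharing a parent one generation back
  g <- Genealogy(parent = c(NA, 1L, 1L), generation = c(0L, 1L, 1L),
                 site = cbind(x = 0:2, y = c(0L, 1L, 1L)))
  expect_equal(toNewick(g, 1), "(c1:1,c2:1);")
  # a single sampled cell is a zero-length tree
  expect_equal(toNewick(makeFixture("chain"), 1), "c1;")
})

test_that("Newick trees round-trip through ape with depth = tmrca", {
  library(ape)
  for (seed in c(3, 8, 21)) {   # all three runs coalesce
    g <- simulateWF(4, 40, seed = seed)
    tm <- tmrca(g, 40)
    expect_false(is.na(tm))
    tr <- ape::read.tree(text = toNewick(g, 40))
    expect_equal(Ntip(tr), sum(g@generation == 40L))
    depths <- node.depth.edgelength(tr)[seq_len(Ntip(tr))]
    expect_true(all(depths == tm))
  }
})

test_that("non-coalesced samples serialize as a forest", {
  n <- 3L; G <- 2L
  par <- c(rep(NA_integer_, n), 1:3, 4:6)
  gen <- rep(0:G, each = n)
  g <- Genealogy(par, gen, cbind(x = rep(0:2, 3), y = gen))
  nw <- toNewick(g, G)
  expect_equal(length(strsplit(nw, "\n")[[1]]), 3L)
})
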
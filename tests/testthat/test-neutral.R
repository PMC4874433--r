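test_that("Wright-Fisher layers have scheduled sizes and uniform parents", {
  g <- simulateWF(7, 12, seed = 1)
  expect_equal(as.vector(table(g@generation)), rep(7L, 13))
  expect_true(all(is.na(g@parent[1:7])))
  # each child's parent lies in the previous layer
  for (t in 1:12) {
    kids <- which(g@generation == t)
    expect_true(all(g@generation[g@parent[kids]] == t - 1L))
  }
  # N = 1 is a single chain: tmrca from any generation is 0 (self) and the
  # whole history is one lineage
  g1 <- simulateWF(1, 10, seed = 2)
  expect_equal(lineageCounts(traceLineages(g1, 10)), rep(1L, 11))
})

test_that("P(two children share a parent) at N = 2 is 1/2", {
  # exhaustive: 4 equally likely parent assignments, 2 have a shared parent
  shared <- vapply(1:400, function(i) {
    g <- simulateWF(2, 1, seed = i)
    g@parent[3L] == g@parent[4L]
  }, logical(1))
  # binomial(400, 1/2): 3.5 sd band
  expect_gt(mean(shared), 0.5 - 3.5 * sqrt(0.25 / 400))
  expect_lt(mean(shared), 0.5 + 3.5 * sqrt(0.25 / 400))
})

test_that("Kingman closed form gives 2N(1 - 1/n)", {
  expect_equal(kingmanExpectedTmrca(2, 100), 100)
  expect_equal(kingmanExpectedTmrca(1000, 1000), 1998)
  expect_error(kingmanExpectedTmrca(1, 10))
})

test_that("exact ancestor chain matches the Stirling formula and enumeration", {
  # independent route: Stirling numbers of the second kind by recurrence,
  # P(k | j) = S(j, k) * N! / (N - k)! / N^j
  stirling <- function(j, k) {
    S <- matrix(0, j + 1, k + 1)
    S[1, 1] <- 1
    for (a in 1:j) for (b in 1:min(a, k))
      S[a + 1, b + 1] <- b * S[a, b + 1] + S[a, b]
    S[j + 1, k + 1]
  }
  for (N in c(2, 3, 5, 6)) {
    P <- exactAncestorChain(N)
    expect_equal(unname(rowSums(P)), rep(1, N))
    for (j in 1:N) for (k in 1:N) {
      want <- if (k > j) 0 else
        stirling(j, k) * prod(N - seq_len(k) + 1) / N^j
      expect_equal(P[j, k], want, tolerance = 1e-12)
    }
  }
  # N = 3, j = 3: enumeration over the 27 parent assignments gives
  # 3/27, 18/27, 6/27 distinct-parent counts
  expect_equal(unname(exactAncestorChain(3)[3, ]), c(1, 6, 2) / 9)
  expect_equal(unname(exactAncestorChain(2)[2, ]), c(1 / 2, 1 / 2))
})

test_that("one-step ancestor counts in simulation follow the exact chain", {
  N <- 5L
  P <- exactAncestorChain(N)
  reps <- 600L
  k <- vapply(seq_len(reps), function(i) {
    g <- simulateWF(N, 1, seed = 10000 + i)
    length(unique(g@parent[(N + 1):(2 * N)]))
  }, integer(1))
  obs <- tabulate(k, nbins = N)
  pv <- suppressWarnings(
    stats::chisq.test(obs[P[N, ] > 0], p = P[N, P[N, ] > 0])$p.value)
  expect_gt(pv, 1e-4)
})

test_that("absorbing-chain expected TMRCA matches simulation within 3 SE", {
  N <- 10L
  want <- exactExpectedTmrca(N)
  tm <- wfTmrcaSample(N, 200, 800, seed = 31)
  expect_true(all(!is.na(tm)))
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - want), 3 * se)
  # and the chain expectation approaches the Kingman 2N scale from below
  expect_lt(want, 2 * N)
  expect_gt(want, 1.5 * N)
})

test_that("linear schedule rounds sizes, never below one cell", {
  s <- scheduleSizes(growthSchedule("linear", N0 = 1, lambda = 2.78), 4)
  expect_equal(s, c(1L, 4L, 7L, 9L, 12L))
  expect_true(all(scheduleSizes(growthSchedule("linear", N0 = 1,
                                               lambda = 0), 5) == 1L))
})

test_that("lambda = 0 linear growth reduces exactly to constant-N WF", {
  a <- simulateLinearWF(N0 = 6, lambda = 0, generations = 15, seed = 5)
  b <- simulateWF(6, 15, seed = 5)
  expect_equal(a@parent, b@parent)
  expect_equal(a@generation, b@generation)
})

test_that("fast linear growth coalesces little: enumeration at N1 = 4", {
  # one founder, four children: all lineages merge immediately one step
  # back, so counts from generation 1 are c(4, 1) for every seed
  for (seed in 1:5) {
    g <- simulateLinearWF(N0 = 1, lambda = 3, generations = 1, seed = seed)
    expect_equal(lineageCounts(traceLineages(g, 1)), c(4L, 1L))
  }
})

test_that("oracle equivalence holds across small widths (property sweep)", {
  for (N in 2:6) {
    g <- simulateWF(N, 60, seed = 40 + N)
    expect_equal(lineageCounts(traceLineages(g, 60)), oracleTrace(g, 60))
  }
})

test_that("wf-tiny fixture reproduces the oracle-generated golden curve", {
  golden <- utils::read.csv(test_path("golden-wf-tiny-curve.csv"))
  cv <- traceLineages(makeFixture("wf-tiny"), 20)
  expect_equal(lineageCounts(cv), golden$lineages)
})
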
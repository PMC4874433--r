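test_that("generation depth statistics match brute-force two-pass values", {
  reps <- lapply(1:3, function(s)
    simulateEden(width = 8, generations = 15, pMove = 0.5,
                 stop = "complete", seed = 20 + s))
  st <- generationDepthStats(reps, 12)
  expect_equal(nrow(st), 3L)
  for (i in 1:3) {
    pos <- positions(reps[[i]])
    d <- pos[genealogy(reps[[i]])@generation == 12L, "y"]
    m <- sum(d) / length(d)
    v <- sum((d - m)^2) / (length(d) - 1)
    expect_equal(st$meanDepth[i], m)
    expect_equal(st$varDepth[i], v)
  }
  expect_equal(attr(st, "meanOfMeans"), mean(st$meanDepth))
  expect_error(generationDepthStats(reps, 40), "absent")
})

test_that("degenerate depth configurations give the textbook variances", {
  mkres <- function(depths) {
    n <- length(depths)
    g <- Genealogy(parent = c(NA, rep(1L, n - 1L)),
                   generation = c(0L, rep(1L, n - 1L)),
                   site = cbind(x = seq_len(n) - 1L, y = c(0L, depths[-1])))
    new("EdenResult", genealogy = g,
        positions = cbind(x = seq_len(n) - 1L, y = depths),
        isBoundary = rep(TRUE, n), widthSeries = NULL,
        params = list(geometry = "bounded", width = n),
        nEvents = 0, nMoves = 0, nRejected = 0)
  }
  # all generation-1 cells at one depth -> variance 0
  flat <- mkres(c(0L, 3L, 3L, 3L))
  expect_equal(generationDepthStats(list(flat), 1)$varDepth, 0)
  expect_equal(deviationDistribution(list(flat), 1), rep(0, 3))
  # half at depth d, half at d + 1 -> population variance 0.25; the
  # per-replicate estimator is the sample variance
  half <- mkres(c(0L, 4L, 4L, 5L, 5L))
  d <- c(4, 4, 5, 5)
  expect_equal(generationDepthStats(list(half), 1)$varDepth, var(d))
  expect_equal(mean((d - mean(d))^2), 0.25)
})

test_that("front width series: flat and two-level boundaries", {
  # perfectly flat boundary -> width 0; depths {3, 5} equally -> sd 1.0
  # (computed directly on constructed depth sets)
  expect_equal(sd(rep(3, 6)), 0)
  expect_equal(sqrt(mean((c(3, 5) - 4)^2)), 1.0)
  r <- simulateEden(width = 6, generations = 40, seed = 3,
                    recordWidth = TRUE, widthEvery = 6)
  ws <- frontWidthSeries(r)
  expect_true(all(ws$width >= 0))
  expect_true(is.finite(saturatedWidth(r)))
  # the width at a recorded event equals the sd of boundary depths at the
  # end of the run for the final record
  lastW <- ws$width[nrow(ws)]
  if (r@nEvents %% 6 == 0) {
    d <- positions(r)[r@isBoundary, "y"]
    expect_equal(lastW, sd(d))
  }
})

test_that("radial statistics use the Euclidean distance from the founder", {
  r <- simulateEden(generations = 25, geometry = "unbounded",
                    stop = "complete", seed = 5)
  rs <- radialStats(list(r), 20)
  pos <- positions(r)
  sel <- genealogy(r)@generation == 20L
  expect_equal(rs$meanRadius, mean(sqrt(rowSums(pos[sel, ]^2))))
  # the founder is at radius 0
  expect_equal(unname(positions(r)[1, ]), c(0L, 0L) + 0L,
               ignore_attr = TRUE)
})

test_that("mean radius grows linearly: radius at 2g is about twice g", {
  r <- simulateEden(generations = 160, geometry = "unbounded",
                    stop = "complete", seed = 6)
  m80 <- radialStats(list(r), 80)$meanRadius
  m160 <- radialStats(list(r), 160)$meanRadius
  expect_lt(abs(m160 / m80 - 2), 0.2)
})

test_that("radial deviation variance increases with generation (no front saturation)", {
  reps <- lapply(1:3, function(s)
    simulateEden(generations = 150, geometry = "unbounded",
                 stop = "complete", seed = 40 + s))
  v <- vapply(c(50, 100, 150), function(g)
    var(deviationDistribution(reps, g, radial = TRUE)), numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("mean radius is nearly deterministic across replicates", {
  reps <- lapply(1:6, function(s)
    simulateEden(generations = 100, geometry = "unbounded",
                 stop = "complete", seed = 60 + s))
  rs <- radialStats(reps, 100)
  cvAcross <- sd(rs$meanRadius) / mean(rs$meanRadius)
  withinSd <- sqrt(attr(rs, "meanOfVariances"))
  cvWithin <- withinSd / mean(rs$meanRadius)
  expect_lt(cvAcross, cvWithin)
})
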
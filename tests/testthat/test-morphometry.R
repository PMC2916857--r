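test_that("branch order counts branch points on the path from the root", {
  expect_equal(branchOrder(chainTree(rep(10, 5))), rep(0L, 6))

  y <- yTree()
  expect_equal(branchOrder(y), c(0L, 0L, 1L, 1L))

  # full binary tree of depth k: maximal order k
  k <- 4
  parent <- NA_integer_
  for (i in 2:(2^(k + 1) - 1)) parent[i] <- i %/% 2L
  set.seed(1)
  full <- neuronTree(x = runif(2^(k + 1) - 1), y = runif(2^(k + 1) - 1),
                     z = 0, parent = parent)
  expect_equal(max(branchOrder(full)), k)
  # maximal order never exceeds the number of branch points
  tr <- randomTree(80, 2)
  expect_lte(max(branchOrder(tr)), sum(classifyNodes(tr) == "branch"))
})

test_that("Sholl intersections match analytic ray cases", {
  straight <- chainTree(rep(10, 10))   # 100 um neurite
  expect_equal(sholl(straight, c(5, 50, 99.5)), c(1L, 1L, 1L))
  expect_equal(sholl(straight, c(100, 150)), c(0L, 0L))

  kRays <- 6
  ang <- 2 * pi * (0:(kRays - 1)) / kRays
  star <- neuronTree(x = c(0, 50 * cos(ang)), y = c(0, 50 * sin(ang)), z = 0,
                     parent = c(NA, rep(1L, kRays)))
  expect_equal(sholl(star, c(10, 49.9)), c(kRays, kRays))
  expect_equal(sholl(star, 51), 0L)
  expect_error(sholl(star, -1), "positive")
})

test_that("Sholl equals the brute-force edge-crossing oracle on random trees", {
  for (seed in 1:10) {
    tr <- randomTree(60, seed)
    radii <- seq(5, 150, by = 12.5)
    expect_identical(sholl(tr, radii), bruteSholl(tr, radii))
  }
})

test_that("summary triplet matches itself and detects a 300 um insertion", {
  tr <- randomBinaryTree(60, 12)
  expect_true(all(matchSummary(tr, tr)))

  # graft one straight 300 um branch onto a terminal
  tip <- which(classifyNodes(tr) == "termination")[1]
  m <- xyz(tr)
  big <- neuronTree(x = c(m[, 1], m[tip, 1] + 300), y = c(m[, 2], m[tip, 2]),
                    z = c(m[, 3], m[tip, 3]),
                    parent = c(parentIds(tr), tip))
  res <- matchSummary(big, tr)
  expect_false(res[["cable"]])

  # summary fields agree with independent recomputation from written SWC
  f <- withr::local_tempfile(fileext = ".swc")
  writeSWC(tr, f)
  raw <- read.table(f, comment.char = "#")
  names(raw) <- c("id", "type", "x", "y", "z", "radius", "parent")
  s <- morphSummary(tr)
  lookup <- match(raw$parent, raw$id)
  elen <- sqrt((raw$x - raw$x[lookup])^2 + (raw$y - raw$y[lookup])^2 +
                 (raw$z - raw$z[lookup])^2)
  expect_equal(s$totalCableLength, sum(elen, na.rm = TRUE), tolerance = 1e-6)
  expect_equal(s$nBranchPoints,
               sum(tabulate(lookup[!is.na(lookup)], nbins = nrow(raw)) >= 2))
})

test_that("region-wise scaling maps every tree onto the population mean box", {
  t1 <- neuronTree(x = c(0, 5, 10), y = c(0, 1, 2), z = 0, parent = c(NA, 1, 2))
  t2 <- neuronTree(x = c(0, 10, 20), y = c(0, 2, 4), z = 0, parent = c(NA, 1, 2))

  # single tree: unchanged
  one <- scaleToMeanLimits(list(t1))
  expect_equal(xyz(one$trees[[1]]), xyz(t1), tolerance = 1e-12)

  two <- scaleToMeanLimits(list(t1, t2))
  # mean x-limits [0, 15]: factors 1.5 and 0.75
  expect_equal(range(xyz(two$trees[[1]])[, 1]), c(0, 15), tolerance = 1e-9)
  expect_equal(range(xyz(two$trees[[2]])[, 1]), c(0, 15), tolerance = 1e-9)
  expect_equal(xyz(two$trees[[1]])[2, 1], 7.5, tolerance = 1e-9,
               ignore_attr = TRUE)

  # after scaling, every region box equals the mean box; idempotent
  trees <- lapply(1:4, function(s) randomTree(40, s))
  sc <- scaleToMeanLimits(trees)
  boxes <- lapply(sc$trees, function(t) apply(xyz(t), 2, range))
  for (b in boxes[-1]) expect_equal(b, boxes[[1]], tolerance = 1e-9)
  sc2 <- scaleToMeanLimits(sc$trees)
  for (i in 1:4)
    expect_equal(xyz(sc2$trees[[i]]), xyz(sc$trees[[i]]), tolerance = 1e-9)
})

test_that("density clouds are normalized and concentrate mass correctly", {
  # single point -> all mass in one bin
  g1 <- densityCloud(matrix(c(3, 4, 5), 1), binSize = 10, smoothing = 0)
  expect_equal(sum(g1$grid), 1)
  expect_equal(max(g1$grid), 1)

  # mass renormalized to 1 after smoothing
  set.seed(5)
  pts <- matrix(runif(300, 0, 100), ncol = 3)
  g <- densityCloud(pts, binSize = 20, smoothing = 1)
  expect_equal(sum(g$grid), 1, tolerance = 1e-12)
  expect_true(all(g$grid >= 0))
  expect_error(densityCloud(matrix(numeric(0), 0, 3)), "point")
})

test_that("uniform points yield a uniform density cloud (chi-squared GOF)", {
  set.seed(42)
  n <- 40000
  pts <- matrix(runif(3 * n, 0, 100), ncol = 3)
  g <- densityCloud(pts, binSize = 25, smoothing = 0)
  # expected mass of each bin = overlap of the bin box with [0,100]^3
  nb <- dim(g$grid)
  probs <- array(0, nb)
  for (i in 1:nb[1]) for (j in 1:nb[2]) for (k in 1:nb[3]) {
    lo <- g$origin + (c(i, j, k) - 1) * g$binSize
    hi <- lo + g$binSize
    probs[i, j, k] <- prod(pmax(0, pmin(hi, 100) - pmax(lo, 0)))
  }
  probs <- probs / sum(probs)
  counts <- round(g$grid * n)
  keep <- probs > 0
  p <- suppressWarnings(
    chisq.test(counts[keep], p = probs[keep] / sum(probs[keep]))$p.value)
  expect_gt(p, 0.01)
})

test_that("convex hull overlap area behaves on known rectangles", {
  sq1 <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  sq2 <- sq1
  sq2[, 1] <- sq2[, 1] + 5
  expect_equal(hullOverlapArea(sq1, sq1), 100, tolerance = 1e-9)
  expect_equal(hullOverlapArea(sq1, sq2), 50, tolerance = 1e-9)
  far <- sq1; far[, 1] <- far[, 1] + 100
  expect_equal(hullOverlapArea(sq1, far), 0)
})
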
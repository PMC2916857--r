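test_that("collinear carriers force a chain regardless of the balancing factor", {
  carriers <- cbind(1:3, 0, 0)
  for (bf in c(0, 0.5, 1)) {
    tr <- growTree(c(0, 0, 0), carriers, growthParameters(bf = bf))
    expect_equal(totalCableLength(tr), 3)
    expect_equal(sum(classifyNodes(tr) == "branch"), 0)
  }
})

test_that("bf = 0 growth reproduces the Euclidean minimum spanning tree exactly", {
  for (seed in 1:5) {
    pts <- carrierPoints(sampleUniformDisc(100, 30, seed = seed))
    tr <- growTree(c(0, 0, 0), pts,
                   growthParameters(bf = 0, suppressMultifurcations = FALSE))
    mst <- primMSTLength(rbind(c(0, 0, 0), pts))
    expect_lt(abs(totalCableLength(tr) - mst), 1e-9)
  }
})

test_that("cable length is minimal at bf = 0 and grows with bf", {
  pts <- carrierPoints(sampleUniformDisc(100, 60, seed = 42))
  params0 <- growthParameters(bf = 0, suppressMultifurcations = FALSE)
  l0 <- totalCableLength(growTree(c(0, 0, 0), pts, params0))
  for (bf in c(0.1, 0.5, 1)) {
    lb <- totalCableLength(growTree(c(0, 0, 0), pts,
      growthParameters(bf = bf, suppressMultifurcations = FALSE)))
    expect_lte(l0, lb)
  }
})

test_that("higher bf tightens paths toward direct connections from the root", {
  ratios <- sapply(1:6, function(seed) {
    pts <- carrierPoints(sampleUniformDisc(100, 80, seed = seed))
    vapply(c(0, 1), function(bf) {
      tr <- growTree(c(0, 0, 0), pts, growthParameters(bf = bf))
      pl <- pathLengthToRoot(tr)[-1]
      eu <- sqrt(rowSums(sweep(xyz(tr)[-1, , drop = FALSE], 2,
                               xyz(tr)[1, ])^2))
      mean(pl / eu)
    }, numeric(1))
  })
  expect_gt(mean(ratios[1, ]), mean(ratios[2, ]))
})

test_that("every greedy step is cost-optimal under replay", {
  pts <- carrierPoints(sampleUniformDisc(80, 50, seed = 17))
  for (bf in c(0, 0.5)) {
    tr <- growTree(c(0, 0, 0), pts,
                   growthParameters(bf = bf, maxChildren = 2))
    expect_true(replayIsOptimal(tr, c(0, 0, 0), pts, bf, maxChildren = 2))
  }
})

test_that("multifurcation suppression caps children counts", {
  pts <- carrierPoints(sampleUniformDisc(50, 120, seed = 23))
  tr <- growTree(c(0, 0, 0), pts, growthParameters(bf = 0.3, maxChildren = 2))
  nc <- nChildren(tr)
  expect_true(all(nc[-rootIndex(tr)] <= 2))

  capped <- growTree(c(0, 0, 0), pts,
                     growthParameters(bf = 0.3, maxChildrenRoot = 1))
  expect_equal(nChildren(capped)[rootIndex(capped)], 1L)
})

test_that("growth is deterministic and records the attachment order", {
  cps <- sampleUniformDisc(70, 40, seed = 31)
  t1 <- growTree(c(0, 0, 0), cps, growthParameters(bf = 0.4))
  t2 <- growTree(c(0, 0, 0), cps, growthParameters(bf = 0.4))
  expect_equal(xyz(t1), xyz(t2))
  expect_equal(parentIds(t1), parentIds(t2))
  ord <- attr(t1, "carrierIndex")
  expect_setequal(ord, seq_len(40))
  # node k+1 is carrier ord[k]
  expect_equal(xyz(t1)[-1, ], carrierPoints(cps)[ord, ], ignore_attr = TRUE)
})

test_that("a distance cutoff leaves distant carriers unconnected only when allowed", {
  carriers <- rbind(c(1, 0, 0), c(100, 0, 0))
  p <- growthParameters(bf = 0, cutoff = 10)
  expect_error(growTree(c(0, 0, 0), carriers, p), "unreachable")
  tr <- growTree(c(0, 0, 0), carriers, p, allowPartial = TRUE)
  expect_equal(nNodes(tr), 2L)
  expect_equal(attr(tr, "unconnected"), 2L)
})

test_that("growToBranchCount reaches the requested branch-point number", {
  spec <- fieldSpec("uniform_disc", radius = 100)
  t0 <- growToBranchCount(spec, c(0, 0, 0), 0, growthParameters(bf = 0.3),
                          seed = 1)
  expect_equal(nNodes(t0), 1L)

  tr <- growToBranchCount(spec, c(0, 0, 0), 12, growthParameters(bf = 0.3),
                          seed = 2)
  expect_gte(sum(classifyNodes(tr) == "branch"), 12)
  expect_false(is.null(attr(tr, "finalN")))
  # with binary suppression, branch points < carrier count
  expect_lt(sum(classifyNodes(tr) == "branch"), attr(tr, "finalN"))
})

test_that("staged growth resamples the scaffold and labels stage-two regions", {
  pts1 <- carrierPoints(sampleUniformDisc(60, 25, seed = 3))
  stage1 <- growTree(c(0, 0, 0), pts1, growthParameters(bf = 0.6))

  # no second-stage carriers: just the conservatively resampled scaffold
  bare <- growStaged(stage1, 5, matrix(numeric(0), 0, 3))
  expect_equal(totalCableLength(bare), totalCableLength(resampleTree(stage1, 5,
    conserveLength = TRUE)), tolerance = 1e-9)

  pts2 <- carrierPoints(sampleRingDisc(100, 80, n = 40, seed = 4))
  staged <- growStaged(stage1, 5, pts2, growthParameters(bf = 0.4))
  expect_length(validateTree(staged), 0)
  expect_equal(sum(regions(staged) == max(regions(staged))), 40)

  # staging genuinely differs from single-pass growth on the carrier union
  single <- growTree(c(0, 0, 0), rbind(pts1, pts2),
                     growthParameters(bf = 0.4))
  expect_false(isTRUE(all.equal(sort(totalCableLength(staged)),
                                sort(totalCableLength(single)),
                                tolerance = 1e-9)))
})

test_that("competitive growth partitions carriers among the roots", {
  roots <- rbind(c(-10, 0, 0), c(10, 0, 0))
  carriers <- rbind(c(-9, 1, 0), c(9, -1, 0))
  trees <- growCompetitive(roots, carriers, growthParameters(bf = 0))
  expect_equal(nNodes(trees[[1]]), 2L)
  expect_equal(nNodes(trees[[2]]), 2L)
  expect_equal(xyz(trees[[1]])[2, ], c(-9, 1, 0), ignore_attr = TRUE)
  expect_equal(xyz(trees[[2]])[2, ], c(9, -1, 0), ignore_attr = TRUE)

  pts <- carrierPoints(sampleUniformBox(c(0, 0, 0), c(100, 100, 0), 120,
                                        seed = 5))
  roots9 <- as.matrix(expand.grid(c(20, 50, 80), c(20, 50, 80)))
  trees9 <- growCompetitive(cbind(roots9, 0), pts,
                            growthParameters(bf = 0.5))
  expect_length(trees9, 9L)
  expect_equal(sum(vapply(trees9, nNodes, integer(1))), 120 + 9)
  for (t in trees9) expect_length(validateTree(t), 0)
})

test_that("competitive growth tiles space relative to independent growth", {
  overlapRatio <- function(seed) {
    pts <- carrierPoints(sampleUniformBox(c(0, 0, 0), c(300, 300, 0), 350,
                                          seed = seed))
    roots <- cbind(as.matrix(expand.grid(c(50, 150, 250), c(50, 150, 250))), 0)
    comp <- growCompetitive(roots, pts, growthParameters(bf = 0.5))
    indep <- lapply(seq_len(9), function(r)
      growTree(roots[r, ], pts, growthParameters(bf = 0.5)))
    pairMean <- function(trees) {
      s <- 0; k <- 0
      for (i in 1:8) for (j in (i + 1):9) {
        s <- s + hullOverlapArea(trees[[i]], trees[[j]]); k <- k + 1
      }
      s / k
    }
    c(comp = pairMean(comp), indep = pairMean(indep))
  }
  res <- sapply(1:3, overlapRatio)
  expect_lt(mean(res["comp", ]), mean(res["indep", ]))
})
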
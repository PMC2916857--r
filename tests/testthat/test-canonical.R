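test_that("topological depth is the subtree sum of path-length values", {
  y <- yTree()
  pl <- pathLengthToRoot(y)
  depth <- topologicalDepth(y)
  # terminals score their own path length
  term <- which(classifyNodes(y) == "termination")
  expect_equal(depth[term], pl[term])
  # every node agrees with brute-force subtree enumeration
  tr <- randomTree(60, seed = 4)
  d <- topologicalDepth(tr)
  for (node in c(1L, 7L, 23L, 60L))
    expect_equal(d[node], bruteSubtreeSum(tr, node))
  # along a chain the score strictly decreases toward the tip (the root and
  # its first child tie because the root contributes path length 0)
  ch <- chainTree(rep(10, 6))
  expect_true(all(diff(topologicalDepth(ch)[-1]) < 0))
  expect_equal(topologicalDepth(ch)[1], topologicalDepth(ch)[2])
})

test_that("label sorting is canonical: idempotent, hierarchical, contiguous,
           deeper-subtree-first, permutation-invariant", {
  for (seed in 1:25) {
    tr <- randomTree(60, seed)
    s <- sortLabels(tr)
    p <- parentIds(s)
    # hierarchical: child labels exceed parent labels; root label 1
    expect_equal(rootIndex(s), 1L)
    expect_true(all(p[-1] < seq_len(60)[-1]))
    # idempotent
    expect_identical(treeFingerprint(s), treeFingerprint(sortLabels(s)))
    # sub-tree contiguity: max - min + 1 == size for every subtree
    kids <- morphoforge:::childrenList(p)
    lo <- seq_len(60); hi <- seq_len(60); size <- rep(1L, 60)
    for (i in 60:2) {
      pa <- p[i]
      lo[pa] <- min(lo[pa], lo[i]); hi[pa] <- max(hi[pa], hi[i])
      size[pa] <- size[pa] + size[i]
    }
    expect_true(all(hi - lo + 1L == size))
    # permutation invariance of the canonical form
    perm <- permuteTree(tr, seed + 1000)
    expect_identical(treeFingerprint(perm), treeFingerprint(tr))
  }
  # deeper subtree labelled first at each branch point
  tr <- randomTree(60, 99)
  s <- sortLabels(tr)
  d <- topologicalDepth(s)
  kids <- morphoforge:::childrenList(parentIds(s))
  for (v in which(nChildren(s) >= 2L)) {
    ch <- sort(kids[[v]])      # label order
    expect_true(all(diff(d[ch]) <= 1e-9))
  }
})

test_that("resampling a straight segment places equidistant nodes", {
  ch <- chainTree(rep(20, 5))        # straight 100 um path
  r <- resampleTree(ch, 10)
  expect_equal(nNodes(r), 11L)
  len <- segmentLengths(r)[-1]
  expect_equal(len, rep(10, 10), tolerance = 1e-12)
  expect_equal(totalCableLength(r), 100, tolerance = 1e-12)
})

test_that("length-conserving resampling reproduces the L-shaped hand trace", {
  # two 50 um legs meeting at a right angle; sampling 20 um with conservation:
  # path extended to 110, sample nodes at 20..100, every edge elongated to 20
  L <- neuronTree(x = c(0, 50, 50), y = c(0, 0, 50), z = 0,
                  parent = c(NA, 1, 2))
  r <- resampleTree(L, 20, conserveLength = TRUE)
  expect_equal(nNodes(r), 6L)
  expect_equal(segmentLengths(r)[-1], rep(20, 5), tolerance = 1e-9)
  expect_equal(totalCableLength(r), 100, tolerance = 1e-9)
})

test_that("length-conserving resampling bounds the error by d/2 per terminal", {
  for (seed in 1:8) {
    tr <- randomBinaryTree(40, seed, spread = 150)
    d <- 7
    r <- resampleTree(tr, d, conserveLength = TRUE)
    edges <- segmentLengths(r)[-1]
    expect_lt(max(abs(edges - d)), 1e-9)
    nterm <- sum(classifyNodes(tr) == "termination")
    expect_lte(abs(totalCableLength(r) - totalCableLength(tr)),
               nterm * d / 2 + 1e-6)
  }
})

test_that("resampling preserves the branch/termination structure at fine sampling", {
  tr <- yTree()
  r <- resampleTree(tr, 5, conserveLength = TRUE)
  expect_equal(sum(classifyNodes(r) == "branch"),
               sum(classifyNodes(tr) == "branch"))
  expect_equal(sum(classifyNodes(r) == "termination"),
               sum(classifyNodes(tr) == "termination"))
  # zero-length edges disappear
  zl <- neuronTree(x = c(0, 10, 10, 20), y = 0, z = 0,
                   parent = c(NA, 1, 2, 3))
  rz <- resampleTree(zl, 5)
  expect_false(any(segmentLengths(rz)[-1] == 0))
})

test_that("the equivalent tree preserves edge lengths and path lengths", {
  one <- chainTree(50)
  eq <- equivalentTree(one)
  expect_equal(sqrt(sum((xyz(eq)[2, ] - xyz(eq)[1, ])^2)), 50)

  tr <- randomBinaryTree(50, 21)
  eq <- equivalentTree(tr)
  expect_equal(pathLengthToRoot(eq), pathLengthToRoot(sortLabels(tr)),
               tolerance = 1e-9)
  expect_true(all(abs(xyz(eq)[, 3]) < 1e-12))   # planar
})

test_that("identical topological genes give identical equivalent layouts", {
  g <- topologicalGene(randomBinaryTree(40, 31))
  t1 <- treeFromGene(g)
  t2 <- treeFromGene(g)
  expect_equal(xyz(t1), xyz(t2))
  # a different tree with the same gene lays out identically
  tr <- randomBinaryTree(40, 31)
  eq1 <- equivalentTree(treeFromGene(topologicalGene(tr)))
  eq2 <- equivalentTree(treeFromGene(topologicalGene(permuteTree(tr, 5))))
  expect_equal(xyz(eq1), xyz(eq2), tolerance = 1e-9)
})

test_that("topological gene lists branches deeper-first with metric lengths", {
  one <- chainTree(50)
  g <- topologicalGene(one)
  expect_equal(g$length, 50)
  expect_equal(g$terminator, "T")

  # Y with 30 stem and arms 20 / 10: deeper arm first
  y <- neuronTree(x = c(0, 0, 0, 0), y = c(0, 30, 50, 40), z = 0,
                  parent = c(NA, 1, 2, 2))
  g <- topologicalGene(y)
  expect_equal(g$length, c(30, 20, 10), tolerance = 1e-12)
  expect_equal(g$terminator, c("B", "T", "T"))
})

test_that("gene <-> tree roundtrip is the identity on canonical genes", {
  for (seed in 1:40) {
    raw <- topologicalGene(randomBinaryTree(30, seed))
    # one stabilization pass maps the gene into canonical (rebuilt-tree) order
    g <- topologicalGene(treeFromGene(raw))
    back <- topologicalGene(treeFromGene(g))
    expect_equal(back$length, g$length, tolerance = 1e-9)
    expect_identical(back$terminator, g$terminator)
    # lengths and topology class counts survive even from the raw gene
    expect_equal(sort(g$length), sort(raw$length), tolerance = 1e-9)
    expect_equal(table(g$terminator), table(raw$terminator))
  }
  expect_error(treeFromGene(data.frame(length = c(10, 10),
                                       terminator = c("B", "T"))),
               "unbalanced")
  expect_error(treeFromGene(data.frame(length = 10, terminator = "X")))
})

test_that("the electrotonic signature is recoverable from the gene alone", {
  # lengths and topology determine the signature at uniform diameter, so the
  # equivalent layout must leave it unchanged
  tr <- sortLabels(randomBinaryTree(30, 77))
  pp <- passiveParameters()
  V1 <- potentials(electrotonicSignature(tr, pp))
  V2 <- potentials(electrotonicSignature(equivalentTree(tr), pp))
  expect_lt(max(abs(V1 - V2)), 1e-9)
})
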
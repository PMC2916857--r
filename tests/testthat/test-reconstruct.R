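test_that("rendering deposits signal exactly on the tree's edges", {
  gt <- groundTruthTree()
  vol <- renderTree(gt, voxelSize = 1, psfSigma = 0, noiseSd = 0)
  a <- voxelData(vol)
  nz <- which(a > 0, arr.ind = TRUE)
  centres <- sweep(sweep(nz - 0.5, 2, voxelSize(vol), "*"), 2, vol@origin, "+")
  # every lit voxel centre sits within a voxel diagonal of some edge
  expect_lt(max(minEdgeDist(centres, gt)), sqrt(3))

  # total deposit grows with cable length (nested trees, same settings)
  sub <- neuronTree(x = xyz(gt)[1:3, 1], y = xyz(gt)[1:3, 2],
                    z = xyz(gt)[1:3, 3], parent = c(NA, 1, 2))
  volSub <- renderTree(sub, voxelSize = 1)
  expect_gt(sum(a), sum(voxelData(volSub)))

  # seeded noise is reproducible
  n1 <- renderTree(gt, voxelSize = 1, noiseSd = 0.1, seed = 5)
  n2 <- renderTree(gt, voxelSize = 1, noiseSd = 0.1, seed = 5)
  expect_equal(voxelData(n1), voxelData(n2))
})

test_that("local thresholding rejects constant volumes and finds lone bright voxels", {
  flat <- imageVolume(array(3, c(10, 10, 5)))
  expect_false(any(localThreshold(flat, window = 5, k = 0.5)))

  spot <- array(0, c(11, 11, 11))
  spot[6, 6, 6] <- 10
  fg <- localThreshold(imageVolume(spot), window = 5, k = 1)
  expect_true(fg[6, 6, 6])
  expect_equal(sum(fg), 1L)
})

test_that("the thresholded foreground covers the rendered centerline", {
  gt <- groundTruthTree()
  vol <- renderTree(gt, voxelSize = 1)
  fg <- localThreshold(vol, window = 9, k = 0.5)
  # voxels containing tree nodes must be foreground
  ijk <- floor(morphoforge:::worldToVoxel(vol, xyz(gt))) + 1
  expect_true(all(fg[ijk]))
})

test_that("skeletonization thins tubes to connected centerlines", {
  # solid 3-voxel-wide straight tube along x
  tube <- array(FALSE, c(40, 9, 9))
  tube[3:38, 4:6, 4:6] <- TRUE
  sk <- skeletonize(tube)
  vx <- attr(sk, "voxels")
  expect_true(all(abs(vx[, 2] - 5) <= 1))
  expect_true(all(abs(vx[, 3] - 5) <= 1))
  expect_gte(nrow(vx), 30)            # spans the tube length
  expect_error(skeletonize(array(FALSE, c(5, 5, 5))), "empty")

  # rendered Y keeps its two terminals and one branch region
  y <- yTree(stem = 25, armA = c(20, 25), armB = c(-20, 25))
  fg <- voxelData(renderTree(y, voxelSize = 1)) > 0
  sk2 <- attr(skeletonize(fg), "voxels")
  # skeleton is 26-connected: single component
  comp <- function(v, dims) {
    arr <- array(FALSE, dims); arr[v] <- TRUE
    seen <- array(FALSE, dims)
    start <- v[1, , drop = FALSE]
    stack <- list(start)
    seen[start] <- TRUE
    cnt <- 1
    while (length(stack)) {
      c0 <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        q <- c0 + c(dx, dy, dz)
        if (any(q < 1) || any(q > dims)) next
        qm <- matrix(q, 1)
        if (arr[qm] && !seen[qm]) {
          seen[qm] <- TRUE
          cnt <- cnt + 1
          stack[[length(stack) + 1L]] <- qm
        }
      }
    }
    cnt
  }
  expect_equal(comp(sk2, dim(fg)), nrow(sk2))
})

test_that("sparsening keeps a maximal minimum-spaced subset in input order", {
  pts <- cbind(seq(0, 12, by = 1), 0, 0)    # colinear, 1 um apart
  kept <- carrierPoints(sparsenPoints(pts, 3))
  expect_equal(kept[, 1], seq(0, 12, by = 3))

  set.seed(9)
  cloud <- matrix(runif(300, 0, 50), ncol = 3)
  kept2 <- carrierPoints(sparsenPoints(cloud, 5))
  dm <- as.matrix(dist(kept2))
  expect_true(all(dm[upper.tri(dm)] >= 5))
  # spacing below all pairwise gaps: identity
  far <- cbind(c(0, 10, 20), 0, 0)
  expect_equal(carrierPoints(sparsenPoints(far, 1)), far,
               ignore_attr = TRUE)
})

test_that("image costs are symmetric, near zero on bright paths, Inf across gaps", {
  a <- array(0, c(30, 7, 7))
  a[2:14, 4, 4] <- 1                 # bright segment
  a[20:29, 4, 4] <- 1                # second segment across a dark gap
  vol <- imageVolume(a)
  pts <- rbind(c(3.5, 3.5, 3.5), c(12.5, 3.5, 3.5), c(25.5, 3.5, 3.5))
  cost <- imageCost(pts, vol, radiusCap = 50, floor = 0.5)
  expect_equal(cost[1, 2], cost[2, 1])
  expect_lt(cost[1, 2], 0.05)
  expect_equal(cost[2, 3], Inf)
})

test_that("noise-free reconstruction recovers length and branch points", {
  gt <- groundTruthTree()
  vol <- renderTree(gt, voxelSize = 1, psfSigma = 0, noiseSd = 0)
  rec <- reconstructTree(vol, root = c(0, 0, 0))
  expect_length(validateTree(rec), 0)

  lgt <- totalCableLength(gt)
  expect_lt(abs(totalCableLength(rec) - lgt) / lgt, 0.10)
  bgt <- sum(classifyNodes(gt) == "branch")
  expect_lte(abs(sum(classifyNodes(rec) == "branch") - bgt), 2)

  # every reconstructed node lies close to a true edge
  expect_lt(max(minEdgeDist(xyz(rec), gt)), 2 + sqrt(3))

  # pruning monotonicity: a stricter branch-length floor never adds cable
  rec2 <- reconstructTree(vol, root = c(0, 0, 0), minBranchLength = 10)
  expect_lte(totalCableLength(rec2), totalCableLength(rec) + 1e-9)

  expect_error(reconstructTree(vol, root = c(200, 200, 200)), "outside")
})

test_that("reconstruction error does not improve with added noise", {
  gt <- groundTruthTree()
  lgt <- totalCableLength(gt)
  errAt <- function(noise) {
    mean(vapply(1:2, function(seed) {
      vol <- renderTree(gt, voxelSize = 1, psfSigma = 0, noiseSd = noise,
                        seed = seed)
      rec <- reconstructTree(vol, root = c(0, 0, 0), k = 3)
      abs(totalCableLength(rec) - lgt) / lgt
    }, numeric(1)))
  }
  errs <- vapply(c(0, 0.08, 0.2), errAt, numeric(1))
  expect_true(all(diff(errs) >= -1e-9))
})
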
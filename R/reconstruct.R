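## Model-based automated reconstruction from 3D image volumes: local
## thresholding -> 3D skeletonization -> carrier sparsening -> greedy growth
## with an image-derived pairwise cost -> removal of unlikely branches.
## A synthetic fluorescence renderer makes the pipeline testable against
## ground truth without microscopy data.

worldToVoxel <- function(vol, p) {
  sweep(sweep(p, 2, vol@origin), 2, vol@voxelSize, "/")
}

voxelCentre <- function(vol, ijk) {
  sweep(sweep(ijk - 0.5, 2, vol@voxelSize, "*"), 2, vol@origin, "+")
}

# nearest-voxel intensity lookup for world points (0 outside the volume);
# dilate = 1 takes the maximum over the one-voxel neighborhood, tolerating
# sub-voxel deviations of straight chords from a wiggly bright path
sampleIntensity <- function(vol, p, dilate = 0L) {
  d <- dim(vol@data)
  base <- floor(worldToVoxel(vol, p)) + 1
  out <- numeric(nrow(p))
  offs <- if (dilate > 0L)
    as.matrix(expand.grid(-dilate:dilate, -dilate:dilate, -dilate:dilate))
  else matrix(0L, 1, 3)
  for (r in seq_len(nrow(offs))) {
    ijk <- sweep(base, 2, offs[r, ], "+")
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
          ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    if (any(ok))
      out[ok] <- pmax(out[ok], vol@data[cbind(ijk[ok, 1], ijk[ok, 2], ijk[ok, 3])])
  }
  out
}

# Remove 26-connected foreground components smaller than minVoxels (noise
# specks pass a local threshold but are tiny; neurites span hundreds of
# voxels).
sizeFilter <- function(mask, minVoxels) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  vox <- which(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  cur <- 0L
  for (v in vox) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    lab[v] <- cur
    frontier <- v
    while (length(frontier)) {
      ijk <- arrayInd(frontier, dims)
      nxt <- integer(0)
      for (r in seq_len(nrow(offs))) {
        q <- sweep(ijk, 2, offs[r, ], "+")
        ok <- q[, 1] >= 1 & q[, 1] <= dims[1] & q[, 2] >= 1 & q[, 2] <= dims[2] &
              q[, 3] >= 1 & q[, 3] <= dims[3]
        if (!any(ok)) next
        lin <- q[ok, 1] + dims[1] * ((q[ok, 2] - 1) + dims[2] * (q[ok, 3] - 1))
        lin <- lin[mask[lin] & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- cur
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  sizes <- tabulate(lab[vox], nbins = cur)
  keep <- which(sizes >= minVoxels)
  array(lab %in% keep & mask, dims)
}

# Robust background floor on normalized intensities: median + k MAD
# (+ epsilon so exact-zero background always stays below it).  Signal voxels
# occupy a tiny fraction of a stack, so Otsu-style histogram splits latch
# onto the zero/noise boundary instead; the median/MAD of the whole volume
# estimate the background level and spread robustly.
robustFloor <- function(volume, k = 3) {
  an <- volume@data / max(volume@data)
  stats::median(an) + k * stats::mad(an) + 1e-6
}

# Otsu's histogram threshold (maximal between-class variance)
thresholdOtsu <- function(x, nbins = 256) {
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[length(mu)]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  mids[which.max(sigmaB)]
}

#' Render a tree into a synthetic fluorescence volume
#'
#' Rasterizes the tree's edges as bright line segments (deposit proportional
#' to local diameter per unit length), convolves with a Gaussian point-spread
#' function and adds seeded Gaussian noise — a stand-in for a microscopy
#' stack with known ground truth.
#'
#' @param tree a \code{NeuronTree}.
#' @param voxelSize \eqn{\mu m} per voxel (scalar or length 3).
#' @param psfSigma PSF standard deviation in \eqn{\mu m} (0 = no blur).
#' @param noiseSd additive Gaussian noise SD, in deposit units (0 = none).
#' @param seed RNG seed for the noise.
#' @param pad margin around the tree in \eqn{\mu m}.
#' @return an \code{ImageVolume} enclosing the whole tree.
#' @export
renderTree <- function(tree, voxelSize = 1, psfSigma = 0, noiseSd = 0,
                       seed = NULL, pad = 4) {
  vs <- rep_len(as.numeric(voxelSize), 3)
  m <- xyz(tree)
  lo <- apply(m, 2, min) - pad
  hi <- apply(m, 2, max) + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / vs)))
  p <- parentIds(tree)
  idx <- which(!is.na(p))
  dia <- diameters(tree)
  samp <- list(); wts <- list()
  step <- min(vs) / 3
  for (k in seq_along(idx)) {
    i <- idx[k]; j <- p[i]
    L <- vnorm(m[i, ] - m[j, ])
    ns <- max(2L, ceiling(L / step) + 1L)
    t <- seq(0, 1, length.out = ns)
    pts <- cbind(m[j, 1] + t * (m[i, 1] - m[j, 1]),
                 m[j, 2] + t * (m[i, 2] - m[j, 2]),
                 m[j, 3] + t * (m[i, 3] - m[j, 3]))
    dmid <- dia[j] + t * (dia[i] - dia[j])
    samp[[k]] <- pts
    wts[[k]] <- dmid * (L / ns)
  }
  a <- array(0, dims)
  if (length(samp)) {
    pts <- do.call(rbind, samp)
    wt <- unlist(wts)
    ijk <- floor(sweep(sweep(pts, 2, lo), 2, vs, "/")) + 1
    ijk <- pmin(pmax(ijk, 1L), matrix(dims, nrow(ijk), 3, byrow = TRUE))
    flat <- (ijk[, 3] - 1) * dims[1] * dims[2] + (ijk[, 2] - 1) * dims[1] + ijk[, 1]
    acc <- rowsum(wt, flat)
    a[as.numeric(rownames(acc))] <- acc
  }
  if (psfSigma > 0) a <- gaussianSmooth3D(a, psfSigma / vs)
  if (noiseSd > 0) {
    a <- a + withSeed(seed, array(rnorm(prod(dims), 0, noiseSd), dims))
    a[a < 0] <- 0
  }
  imageVolume(a, voxelSize = vs, origin = lo)
}

#' Local brightness-level thresholding
#'
#' A voxel is foreground iff its intensity exceeds the local mean plus
#' \code{k} local standard deviations within a cubic window (strictly,
#' with a small numerical tolerance, so constant volumes yield no
#' foreground).
#'
#' @param volume an \code{ImageVolume}.
#' @param window cubic window edge in voxels (odd, default 9).
#' @param k SD multiplier (default 0.5).
#' @return logical 3D array (foreground mask).
#' @export
localThreshold <- function(volume, window = 9, k = 0.5) {
  stopifnot(window >= 1)
  a <- volume@data
  r <- floor(window / 2)
  dims <- dim(a)
  # separable box sum with zero padding (true local counts tracked alongside)
  boxAxis <- function(x, axis) {
    n <- dims[axis]
    out <- array(0, dims)
    for (off in -r:r) {
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      sel <- function(z, i) switch(axis,
        z[i, , , drop = FALSE], z[, i, , drop = FALSE], z[, , i, drop = FALSE])
      tgt <- which(ok)
      add <- sel(x, src[ok])
      if (axis == 1) out[tgt, , ] <- out[tgt, , ] + add
      else if (axis == 2) out[, tgt, ] <- out[, tgt, ] + add
      else out[, , tgt] <- out[, , tgt] + add
    }
    out
  }
  boxSum <- function(x) boxAxis(boxAxis(boxAxis(x, 1), 2), 3)
  cnt <- boxSum(array(1, dims))
  mu <- boxSum(a) / cnt
  v <- pmax(boxSum(a^2) / cnt - mu^2, 0)
  eps <- 1e-9 * (max(abs(a)) + 1)
  a > mu + k * sqrt(v) + eps
}

#' 3D skeletonization of a binary volume
#'
#' Thins the foreground to a (1–2 voxel wide) centerline by sequential
#' topology-preserving border peeling (simple-point deletion, endpoints
#' kept), so the skeleton is connected wherever the foreground is and lies
#' inside it.
#'
#' @param mask logical 3D array, or an \code{ImageVolume} whose positive
#'   voxels define the mask.
#' @param volume optional \code{ImageVolume} supplying the voxel calibration
#'   when \code{mask} is a bare array.
#' @return matrix of skeleton point coordinates in \eqn{\mu m} (voxel
#'   centres), with attribute \code{voxels} holding the integer voxel
#'   indices.
#' @export
skeletonize <- function(mask, volume = NULL) {
  if (is(mask, "ImageVolume")) {
    volume <- mask
    mask <- mask@data > 0
  }
  if (!any(mask)) stop("empty foreground: nothing to skeletonize")
  dims <- dim(mask)
  thin <- thin3dCpp(as.logical(mask), as.integer(dims))
  dim(thin) <- dims
  ijk <- which(thin, arr.ind = TRUE)
  pts <- if (!is.null(volume)) voxelCentre(volume, ijk) else ijk - 0.5
  colnames(pts) <- c("x", "y", "z")
  attr(pts, "voxels") <- ijk
  pts
}

#' Sparsen a point set to a minimum spacing
#'
#' Greedy selection in input order: a point is kept iff no previously kept
#' point lies within \code{minSpacing}, so the kept set is a maximal
#' \code{minSpacing}-separated subset.
#'
#' @param points n x 3 coordinate matrix (\eqn{\mu m}).
#' @param minSpacing minimum pairwise distance (> 0).
#' @return a \code{CarrierPointSet} of the kept points.
#' @export
sparsenPoints <- function(points, minSpacing) {
  stopifnot(minSpacing > 0)
  points <- as.matrix(points)
  n <- nrow(points)
  keep <- logical(n)
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(n)) {
    if (!nrow(kept) || min(rowDist(kept, points[i, ])) >= minSpacing) {
      keep[i] <- TRUE
      kept <- rbind(kept, points[i, ])
    }
  }
  carrierPointSet(points[keep, , drop = FALSE],
                  list(kind = "sparsened", minSpacing = minSpacing))
}

#' Image-derived pairwise connection costs
#'
#' For every pair of candidate carrier points within \code{radiusCap}, the
#' cost is the mean of (1 - normalized intensity) sampled along the straight
#' line between them — bright, continuous paths cost about 0.  Pairs whose
#' line crosses background — a contiguous run of samples below \code{floor}
#' (default median + 3 MAD of the volume) wider than \code{maxGap} — are
#' forbidden (\code{Inf}), as are pairs beyond the radius cap.  Sub-voxel
#' dark blips from chords clipping voxel corners are tolerated (they still
#' raise the mean cost).
#'
#' @param points n x 3 matrix of candidate points (\eqn{\mu m}), by
#'   convention the growth root first.
#' @param volume an \code{ImageVolume}.
#' @param radiusCap maximum pair distance considered (\eqn{\mu m}).
#' @param floor background intensity floor (normalized units); \code{NULL}
#'   for the robust default.
#' @param maxGap widest tolerated sub-floor run along a line, \eqn{\mu m}
#'   (default one voxel).
#' @return symmetric n x n cost matrix with \code{Inf} for forbidden pairs.
#' @export
imageCost <- function(points, volume, radiusCap = 10, floor = NULL,
                      maxGap = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  imax <- max(volume@data)
  if (imax <= 0) stop("volume has no signal")
  if (is.null(floor)) floor <- robustFloor(volume, k = 3)
  if (is.null(maxGap)) maxGap <- max(volume@voxelSize)
  step <- min(volume@voxelSize) / 2
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    d <- rowDist(points[(i + 1):n, , drop = FALSE], points[i, ])
    for (jj in which(d <= radiusCap)) {
      j <- i + jj
      ns <- max(2L, ceiling(d[jj] / step) + 1L)
      t <- seq(0, 1, length.out = ns)
      line <- cbind(points[i, 1] + t * (points[j, 1] - points[i, 1]),
                    points[i, 2] + t * (points[j, 2] - points[i, 2]),
                    points[i, 3] + t * (points[j, 3] - points[i, 3]))
      iv <- sampleIntensity(volume, line, dilate = 1L) / imax
      below <- iv < floor
      run <- 0L
      if (any(below)) {
        r <- rle(below)
        run <- max(r$lengths[r$values])
      }
      cost[i, j] <- cost[j, i] <-
        if (run * d[jj] / (ns - 1) > maxGap) Inf else mean(1 - iv)
    }
  }
  diag(cost) <- 0
  cost
}

#' Remove unlikely terminal branches
#'
#' Iteratively deletes terminal branches (the cable from the last
#' topological point to a tip) that are shorter than \code{minLength} or
#' whose mean supporting score falls below \code{scoreFloor}, until no such
#' branch remains.
#'
#' @param tree a \code{NeuronTree}.
#' @param minLength minimum terminal branch length, \eqn{\mu m}.
#' @param score optional per-node score (e.g. normalized image intensity).
#' @param scoreFloor minimum mean branch score.
#' @return a pruned \code{NeuronTree} with attribute \code{prunedBranches},
#'   the number of branches removed.
#' @export
pruneTerminalBranches <- function(tree, minLength = 3, score = NULL,
                                  scoreFloor = -Inf) {
  removed <- 0L
  repeat {
    n <- nNodes(tree)
    p <- parentIds(tree)
    cls <- classifyNodes(tree)
    pl <- pathLengthToRoot(tree)
    drop <- logical(n)
    for (tip in which(cls == "termination")) {
      chain <- tip
      v <- p[tip]
      while (!is.na(v) && cls[v] == "continuation") { chain <- c(chain, v); v <- p[v] }
      base <- if (is.na(v)) tip else v
      blen <- pl[tip] - pl[base]
      bad <- blen < minLength ||
        (!is.null(score) && mean(score[chain]) < scoreFloor)
      if (bad) drop[chain] <- TRUE
    }
    if (!any(drop) || all(drop[-rootIndex(tree)])) break
    keep <- which(!drop)
    rank <- integer(n)
    rank[keep] <- seq_along(keep)
    par <- p[keep]
    tree <- neuronTree(x = xyz(tree)[keep, 1], y = xyz(tree)[keep, 2],
                       z = xyz(tree)[keep, 3],
                       diameter = diameters(tree)[keep],
                       region = regions(tree)[keep],
                       parent = ifelse(is.na(par), NA_integer_,
                                       rank[ifelse(is.na(par), 1L, par)]))
    if (!is.null(score)) score <- score[keep]
    removed <- removed + 1L
  }
  attr(tree, "prunedBranches") <- removed
  tree
}

#' Model-based reconstruction of a tree from an image volume
#'
#' The full pipeline: local thresholding, 3D skeletonization, carrier
#' sparsening, greedy growth from a user-supplied root with the image-derived
#' pairwise cost added to the geometric cost, and removal of unlikely
#' (short or dim) terminal branches.
#'
#' @param volume an \code{ImageVolume}.
#' @param root root location in \eqn{\mu m} (must lie in the foreground).
#' @param params \code{GrowthParameters} for the greedy stage (default
#'   bf = 0.2 with multifurcation suppression).
#' @param window,k local threshold parameters.
#' @param minSpacing carrier sparsening distance, \eqn{\mu m}.
#' @param radiusCap image-cost pair radius, \eqn{\mu m}.
#' @param minBranchLength pruning threshold for terminal branches,
#'   \eqn{\mu m}.
#' @param minComponent smallest foreground component kept, in voxels
#'   (noise-speck removal; default 10).
#' @return a \code{NeuronTree} in \eqn{\mu m} coordinates, with attributes
#'   \code{prunedBranches} and \code{unconnected} (diagnostics).
#' @export
reconstructTree <- function(volume, root,
                            params = growthParameters(bf = 0.2),
                            window = 9, k = 0.5, minSpacing = 3,
                            radiusCap = 10, minBranchLength = 3,
                            minComponent = 10) {
  fg <- localThreshold(volume, window = window, k = k)
  if (!any(fg)) stop("empty foreground after thresholding")
  root <- c(as.numeric(root), 0)[1:3]
  rv <- floor(worldToVoxel(volume, matrix(root, 1, 3))) + 1
  d <- dim(volume@data)
  if (any(rv < 1) || any(rv > d))
    stop("root location outside the volume")
  # root must sit on (or within one voxel of) foreground
  nb <- expand.grid(-1:1, -1:1, -1:1)
  nbv <- sweep(as.matrix(nb), 2, as.numeric(rv), "+")
  ok <- nbv[, 1] >= 1 & nbv[, 1] <= d[1] & nbv[, 2] >= 1 & nbv[, 2] <= d[2] &
        nbv[, 3] >= 1 & nbv[, 3] <= d[3]
  if (!any(fg[nbv[ok, , drop = FALSE]]))
    stop("root location outside the thresholded foreground")
  fg <- sizeFilter(fg, minComponent)
  if (!any(fg)) stop("no foreground component above the size filter")
  skel <- skeletonize(fg, volume)
  carriers <- sparsenPoints(skel, minSpacing)
  cm <- carrierPoints(carriers)
  # drop carriers colliding with the root position
  cm <- cm[rowDist(cm, root) > minSpacing / 2, , drop = FALSE]
  allPts <- rbind(root, cm)
  ec <- imageCost(allPts, volume, radiusCap = radiusCap)
  tr <- growTree(root, cm, params, extraCost = ec, allowPartial = TRUE)
  sc <- sampleIntensity(volume, xyz(tr)) / max(volume@data)
  out <- pruneTerminalBranches(tr, minLength = minBranchLength,
                               score = sc, scoreFloor = robustFloor(volume, 3))
  attr(out, "unconnected") <- attr(tr, "unconnected")
  out
}

#' Read / write an image volume as a multi-page TIFF stack
#'
#' Grayscale multi-page TIFF support for the reconstruction pipeline (one
#' page per z-slice); requires the \pkg{tiff} package.
#'
#' @param path TIFF file path.
#' @param voxelSize \eqn{\mu m} per voxel (scalar or length 3; TIFF stores
#'   no reliable calibration).
#' @return an \code{ImageVolume}.
#' @export
readImageVolume <- function(path, voxelSize = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) a[, , z] <- t(pages[[z]])
  imageVolume(a, voxelSize = voxelSize)
}

#' @param volume an \code{ImageVolume} to write (intensities are scaled to
#'   [0, 1]).
#' @rdname readImageVolume
#' @export
writeImageVolume <- function(volume, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
  a <- volume@data
  if (max(a) > 0) a <- a / max(a)
  pages <- lapply(seq_len(dim(a)[3]), function(z) t(a[, , z]))
  tiff::writeTIFF(pages, path)
  invisible(path)
}
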
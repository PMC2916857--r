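# Programmatic fixtures: small hand-built trees and seeded random trees.

chainTree <- function(lengths, y = 0) {
  x <- c(0, cumsum(lengths))
  neuronTree(x = x, y = y, z = 0, parent = c(NA, seq_along(lengths)))
}

# Y: 30 um stem along +y, then one arm of 50 um and one of 50 um (default),
# or custom arm tip offsets.
yTree <- function(stem = 30, armA = c(30, 40), armB = c(-30, 40)) {
  neuronTree(x = c(0, 0, armA[1], armB[1]),
             y = c(0, stem, stem + armA[2], stem + armB[2]),
             z = 0, parent = c(NA, 1, 2, 2))
}

# random general tree: node i attaches to a uniformly chosen earlier node
randomTree <- function(n, seed, spread = 100) {
  set.seed(seed)
  parent <- c(NA_integer_, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                                  integer(1)))
  neuronTree(x = runif(n, -spread, spread), y = runif(n, -spread, spread),
             z = runif(n, -spread / 4, spread / 4),
             diameter = runif(n, 0.5, 2), parent = parent)
}

# random binary tree (root emits one stem, every other node has <= 2 children)
randomBinaryTree <- function(n, seed, spread = 100) {
  set.seed(seed)
  parent <- rep(NA_integer_, n)
  nchild <- integer(n)
  for (i in 2:n) {
    cap <- ifelse(seq_len(i - 1L) == 1L, 1L, 2L)
    open <- which(nchild[seq_len(i - 1L)] < cap)
    p <- open[sample.int(length(open), 1L)]
    parent[i] <- p
    nchild[p] <- nchild[p] + 1L
  }
  neuronTree(x = runif(n, -spread, spread), y = runif(n, -spread, spread),
             z = runif(n, -spread / 4, spread / 4), parent = parent)
}

# random permutation of node storage order (same geometric tree)
permuteTree <- function(tree, seed) {
  set.seed(seed)
  n <- nNodes(tree)
  perm <- sample.int(n)          # perm[i] = old index stored at new slot i
  rank <- integer(n)
  rank[perm] <- seq_len(n)
  p <- parentIds(tree)[perm]
  neuronTree(x = xyz(tree)[perm, 1], y = xyz(tree)[perm, 2],
             z = xyz(tree)[perm, 3], diameter = diameters(tree)[perm],
             region = regions(tree)[perm],
             parent = ifelse(is.na(p), NA_integer_, rank[ifelse(is.na(p), 1L, p)]))
}

# geometric fingerprint invariant to node storage order after sortLabels
treeFingerprint <- function(tree) {
  s <- sortLabels(tree)
  list(coords = round(xyz(s), 9), parent = parentIds(s))
}

# hand-built 3D binary tree with well-separated branches (>= 20 um), used as
# reconstruction ground truth
groundTruthTree <- function() {
  neuronTree(
    x = c(0,   0, -35, -60, -20,  30,  55),
    y = c(0,  40,  75,  95, 105,  80, 110),
    z = c(0,   0,   5,   5,  10,  -5,   0),
    parent = c(NA, 1, 2, 3, 3, 2, 6))
}
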
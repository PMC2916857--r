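## Cosmetic / biophysical finishing of grown trees: low-pass-filtered
## spatial jitter, quadratic diameter taper, cosine soma mapping.

#' Add low-pass filtered spatial jitter
#'
#' Reproduces the wriggliness of real reconstructions: independent Gaussian
#' displacement fields are drawn per branch, smoothed along the path by a
#' moving average, pinned to zero at the branch endpoints (root, branch
#' points and terminals stay put, so connectivity has no spatial
#' discontinuity), and scaled so the displaced nodes' root-mean-square
#' displacement equals \code{amplitude}.  Homogeneous noise requires equal
#' segment lengths, so the tree must be resampled first.
#'
#' @param tree a \code{NeuronTree} resampled to a fixed segment length.
#' @param amplitude target RMS displacement, \eqn{\mu m} (0 = identity).
#' @param window moving-average window in nodes (default 5).
#' @param seed RNG seed.
#' @return a \code{NeuronTree} with identical topology and jittered
#'   coordinates.
#' @export
addJitter <- function(tree, amplitude, window = 5, seed = NULL) {
  stopifnot(amplitude >= 0, window >= 1)
  len <- segmentLengths(tree)
  lenE <- len[!is.na(parentIds(tree))]
  if (length(lenE) && diff(range(lenE)) > 1e-6 * max(lenE))
    stop("tree must be resampled to a fixed segment length before jitter")
  if (amplitude == 0) return(tree)
  p <- parentIds(tree)
  cls <- classifyNodes(tree)
  pinned <- cls %in% c("root", "branch", "termination")
  # branches: maximal chains of continuation nodes between topological points
  kids <- childrenList(p)
  disp <- matrix(0, nNodes(tree), 3)
  withSeed(seed, {
    for (start in which(pinned)) {
      for (ch in kids[[start]]) {
        if (pinned[ch]) next
        chain <- integer(0)
        v <- ch
        while (!pinned[v]) { chain <- c(chain, v); v <- kids[[v]][1L] }
        k <- length(chain)
        w <- min(window, k + 2)      # short chains get a narrower filter
        raw <- matrix(rnorm(3 * (k + 2)), k + 2, 3)  # pad ends for the filter
        sm <- apply(raw, 2, function(col)
          stats::filter(col, rep(1 / w, w), sides = 2))
        sm <- sm[2:(k + 1), , drop = FALSE]
        sm[is.na(sm)] <- 0
        # re-pin: remove the linear interpolation of the endpoint values
        t <- seq_len(k) / (k + 1)
        first <- sm[1, ]; last <- sm[k, ]
        sm <- sm - outer(1 - t, first) - outer(t, last)
        disp[chain, ] <- sm
      }
    }
  })
  moved <- !pinned
  rms <- sqrt(mean(rowSums(disp[moved, , drop = FALSE]^2)))
  if (rms > 0) disp <- disp * (amplitude / rms)
  nd <- tree@nodes
  nd$x <- nd$x + disp[, 1]; nd$y <- nd$y + disp[, 2]; nd$z <- nd$z + disp[, 3]
  new("NeuronTree", nodes = nd, parent = tree@parent)
}

#' Quadratic diameter taper
#'
#' Maps a quadratic diameter decay onto the tree:
#' \deqn{d = d_{tip} + (d_{root} - d_{tip}) (1 - PL / PL_{max})^2}
#' where \eqn{PL_{max}} is the path length of the farthest terminal reached
#' through the node, so diameters are \code{dRoot} at the root, \code{dTip}
#' at every terminal, and non-increasing along every root-to-tip path.
#'
#' @param tree a \code{NeuronTree}.
#' @param dRoot root diameter, \eqn{\mu m}.
#' @param dTip terminal diameter, \eqn{\mu m} (0 < dTip <= dRoot).
#' @return a \code{NeuronTree} with tapered diameters.
#' @export
taperDiameters <- function(tree, dRoot, dTip) {
  if (dTip > dRoot) stop("dTip must not exceed dRoot")
  if (dTip <= 0) stop("dTip must be positive")
  p <- parentIds(tree)
  pl <- pathLengthToRoot(tree)
  plmax <- pl
  for (i in rev(topoOrder(p))) if (!is.na(p[i]))
    plmax[p[i]] <- max(plmax[p[i]], plmax[i])
  ratio <- ifelse(plmax > 0, pl / plmax, 0)
  nd <- tree@nodes
  nd$diameter <- dTip + (dRoot - dTip) * (1 - ratio)^2
  new("NeuronTree", nodes = nd, parent = tree@parent)
}

#' Cosine soma mapping
#'
#' Produces a soma-like swelling by multiplying diameters near the root with
#' a raised-cosine factor: at the root the diameter becomes
#' \code{somaDiameter}, the factor decays smoothly to 1 at path length
#' \code{extent} and leaves the rest of the tree untouched (continuous at
#' the boundary).
#'
#' @param tree a \code{NeuronTree} with positive root diameter.
#' @param somaDiameter target diameter at the root, \eqn{\mu m}.
#' @param extent path-length extent of the swelling, \eqn{\mu m} (> 0).
#' @return a \code{NeuronTree}.
#' @export
mapSoma <- function(tree, somaDiameter, extent) {
  stopifnot(extent > 0)
  droot <- diameters(tree)[rootIndex(tree)]
  if (droot <= 0) stop("root diameter must be positive")
  pl <- pathLengthToRoot(tree)
  fac <- rep(1, nNodes(tree))
  sel <- pl <= extent
  fac[sel] <- 1 + (somaDiameter / droot - 1) * (cos(pi * pl[sel] / extent) + 1) / 2
  nd <- tree@nodes
  nd$diameter <- nd$diameter * fac
  new("NeuronTree", nodes = nd, parent = tree@parent)
}
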
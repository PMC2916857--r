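## Carrier-point generation: parametric density fields (uniform disc/box,
## ring-in-disc, elliptical cone intersected with a sphere, empirical
## density grids).  All samplers are deterministic per seed, honour the
## requested count exactly, and keep every point inside the declared hull.

# Rejection sampling with a bounded-attempt contract: fails loudly instead
# of looping forever on a degenerate region.
rejectionSample <- function(n, propose, accept, maxFactor = 1000) {
  out <- matrix(numeric(0), 0, 3)
  attempts <- 0
  batch <- max(64L, 2L * n)
  while (nrow(out) < n) {
    if (attempts > maxFactor * max(n, 1L))
      stop("rejection sampling exceeded the attempt bound; ",
           "is the field region (nearly) empty?")
    cand <- propose(batch)
    keep <- accept(cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
    attempts <- attempts + batch
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample uniform carrier points in a disc
#'
#' Homogeneously distributed random points in a planar circular hull (z = 0),
#' the substrate of the basic growth experiments.
#'
#' @param radius disc radius, \eqn{\mu m}.
#' @param n number of points (>= 0).
#' @param seed RNG seed (the caller's RNG state is left untouched).
#' @return a \code{CarrierPointSet}.
#' @export
sampleUniformDisc <- function(radius, n, seed = NULL) {
  stopifnot(radius > 0, n >= 0)
  if (n == 0)
    return(carrierPointSet(matrix(numeric(0), 0, 3),
                           list(kind = "uniform_disc", radius = radius)))
  pts <- withSeed(seed, {
    r <- radius * sqrt(runif(n))
    a <- runif(n, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a), 0)
  })
  carrierPointSet(pts, list(kind = "uniform_disc", radius = radius, seed = seed))
}

#' Sample uniform carrier points in an axis-aligned box
#'
#' @param lower,upper numeric length-3 corners (\eqn{\mu m}).
#' @inheritParams sampleUniformDisc
#' @return a \code{CarrierPointSet}.
#' @export
sampleUniformBox <- function(lower, upper, n, seed = NULL) {
  lower <- rep_len(as.numeric(lower), 3); upper <- rep_len(as.numeric(upper), 3)
  stopifnot(all(upper >= lower), n >= 0)
  if (n == 0)
    return(carrierPointSet(matrix(numeric(0), 0, 3),
                           list(kind = "uniform_box", lower = lower,
                                upper = upper)))
  pts <- withSeed(seed, cbind(runif(n, lower[1], upper[1]),
                              runif(n, lower[2], upper[2]),
                              runif(n, lower[3], upper[3])))
  carrierPointSet(pts, list(kind = "uniform_box", lower = lower, upper = upper,
                            seed = seed))
}

#' Sample carrier points from a ring-shaped density in a disc
#'
#' Points follow a planar area density proportional to a Gaussian in the
#' distance from the centre, peaked on a ring of radius \code{ringRadius}
#' and truncated to the circular hull — the spanning field of starburst
#' amacrine-like neurites.  As \code{ringWidth} grows the density approaches
#' the uniform disc.
#'
#' @param hullRadius radius of the bounding disc, \eqn{\mu m}.
#' @param ringRadius radius of peak density (0 < ringRadius < hullRadius).
#' @param ringWidth Gaussian SD of the ring profile (default hullRadius / 4).
#' @inheritParams sampleUniformDisc
#' @return a \code{CarrierPointSet}.
#' @export
sampleRingDisc <- function(hullRadius, ringRadius, ringWidth = hullRadius / 4,
                           n, seed = NULL) {
  stopifnot(hullRadius > 0, ringRadius > 0, ringRadius < hullRadius,
            ringWidth > 0, n >= 0)
  pts <- withSeed(seed, rejectionSample(n,
    propose = function(m) {
      r <- hullRadius * sqrt(runif(m))
      a <- runif(m, 0, 2 * pi)
      cbind(r * cos(a), r * sin(a), 0)
    },
    accept = function(p) {
      r <- sqrt(p[, 1]^2 + p[, 2]^2)
      runif(nrow(p)) < exp(-(r - ringRadius)^2 / (2 * ringWidth^2))
    }))
  carrierPointSet(pts, list(kind = "ring_disc", hullRadius = hullRadius,
                            ringRadius = ringRadius, ringWidth = ringWidth,
                            seed = seed))
}

#' Sample carrier points in an elliptical cone intersected with a sphere
#'
#' The spanning field of dentate gyrus granule-cell-like dendrites: an
#' elliptical cone opening from an apex along an axis, intersected with a
#' sphere whose centre lies beyond the cone's tip on the central axis
#' (behind the apex), with a bimodal radial density profile — mass
#' concentrated both near the origin of the volume and out at the spherical
#' rim.  The radial profile is a two-component Beta mixture over the
#' normalized apex-to-rim coordinate.
#'
#' @param apex cone apex (length 3, \eqn{\mu m}).
#' @param axis central axis direction (length 3; normalized internally).
#' @param halfAngles elliptical half-opening angles in radians (length 2).
#' @param sphereCentre sphere centre (on the axis, beyond the tip).
#' @param sphereRadius sphere radius, \eqn{\mu m}.
#' @param radialProfile list with \code{weights} (near, rim), \code{nearShape}
#'   and \code{rimShape} Beta shapes; \code{NULL} for the default bimodal mix.
#' @inheritParams sampleUniformDisc
#' @return a \code{CarrierPointSet}.
#' @export
sampleConeSphere <- function(apex = c(0, 0, 0), axis = c(0, 1, 0),
                             halfAngles = c(35, 35) * pi / 180,
                             sphereCentre = apex - 60 * axis / vnorm(axis),
                             sphereRadius = 200,
                             radialProfile = NULL, n, seed = NULL) {
  if (is.null(radialProfile))
    radialProfile <- list(weights = c(0.5, 0.5), nearShape = 4, rimShape = 8)
  u <- axis / vnorm(axis)
  # orthonormal frame perpendicular to the axis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / vnorm(e1)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  h <- vnorm(apex - sphereCentre)
  if (sphereRadius <= h)
    stop("empty region: sphere does not reach beyond the cone apex")
  tanA <- tan(halfAngles)
  tmax <- sphereRadius - h  # maximal axial extent of the intersection
  inside <- function(p) {
    v <- sweep(p, 2, apex)
    t <- v %*% u
    w1 <- (v %*% e1) / pmax(t, 1e-12)
    w2 <- (v %*% e2) / pmax(t, 1e-12)
    inCone <- t > 0 & ((w1 / tanA[1])^2 + (w2 / tanA[2])^2 <= 1)
    d <- sqrt(rowSums(sweep(p, 2, sphereCentre)^2))
    as.vector(inCone & d <= sphereRadius)
  }
  rho <- function(p) {  # normalized apex-to-rim radial coordinate in [0,1]
    d <- sqrt(rowSums(sweep(p, 2, sphereCentre)^2))
    pmin(1, pmax(0, (d - h) / (sphereRadius - h)))
  }
  gmax <- {
    xs <- seq(1e-3, 1 - 1e-3, length.out = 512)
    max(radialProfile$weights[1] * dbeta(xs, 1, radialProfile$nearShape) +
        radialProfile$weights[2] * dbeta(xs, radialProfile$rimShape, 1))
  }
  # bounding box of the region as rejection proposal
  centre <- apex + (tmax / 2) * u
  ext <- abs(tmax / 2 * u) + tmax * max(tanA) * (abs(e1) + abs(e2))
  lo <- centre - ext; hi <- centre + ext
  pts <- withSeed(seed, rejectionSample(n,
    propose = function(m)
      cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]), runif(m, lo[3], hi[3])),
    accept = function(p) {
      ok <- inside(p)
      g <- numeric(nrow(p))
      if (any(ok)) {
        x <- rho(p[ok, , drop = FALSE])
        g[ok] <- radialProfile$weights[1] * dbeta(x, 1, radialProfile$nearShape) +
                 radialProfile$weights[2] * dbeta(x, radialProfile$rimShape, 1)
      }
      ok & (runif(nrow(p)) < g / gmax)
    }))
  carrierPointSet(pts, list(kind = "cone_sphere", apex = apex, axis = u,
                            halfAngles = halfAngles, sphereCentre = sphereCentre,
                            sphereRadius = sphereRadius,
                            radialProfile = radialProfile, seed = seed))
}

#' Sample carrier points from an empirical density grid
#'
#' Draws bins multinomially according to the (normalized) grid masses and
#' jitters each point uniformly within its bin — the sampling counterpart of
#' \code{\link{densityCloud}}, used to grow cells from density clouds of
#' real populations.
#'
#' @param density a \code{densityGrid} (from \code{\link{densityCloud}}) or a
#'   nonnegative 3D array (unit bin size at the origin is then assumed).
#' @inheritParams sampleUniformDisc
#' @return a \code{CarrierPointSet}.
#' @export
sampleEmpirical <- function(density, n, seed = NULL) {
  if (is.array(density) && !inherits(density, "densityGrid"))
    density <- structure(list(grid = density, origin = c(0, 0, 0), binSize = 1),
                         class = "densityGrid")
  g <- density$grid
  if (sum(g) <= 0) stop("all-zero density grid")
  prob <- as.vector(g) / sum(g)
  nb <- dim(g)
  pts <- withSeed(seed, {
    cells <- sample.int(length(prob), n, replace = TRUE, prob = prob)
    k <- (cells - 1L) %/% (nb[1] * nb[2])
    j <- ((cells - 1L) %% (nb[1] * nb[2])) %/% nb[1]
    i <- (cells - 1L) %% nb[1]
    cbind(density$origin[1] + (i + runif(n)) * density$binSize,
          density$origin[2] + (j + runif(n)) * density$binSize,
          density$origin[3] + (k + runif(n)) * density$binSize)
  })
  carrierPointSet(pts, list(kind = "empirical", seed = seed))
}

## ---- declarative field specs ----------------------------------------------

#' Construct a field specification
#'
#' @param kind one of \code{uniform_disc}, \code{ring_disc},
#'   \code{cone_sphere}, \code{empirical}, \code{uniform_box}.
#' @param ... kind-specific parameters (see the corresponding sampler).
#' @return a \code{FieldSpec}.
#' @rdname FieldSpec-class
#' @export
fieldSpec <- function(kind, ...) {
  kind <- match.arg(kind, c("uniform_disc", "ring_disc", "cone_sphere",
                            "empirical", "uniform_box"))
  new("FieldSpec", kind = kind, params = list(...))
}

#' Read a field specification from a JSON config file
#'
#' The JSON object must contain a \code{"kind"} entry plus the sampler's
#' parameters, e.g. \code{{"kind": "ring_disc", "hullRadius": 100,
#' "ringRadius": 60, "ringWidth": 15}}.
#'
#' @param path JSON file path.
#' @return a \code{FieldSpec}.
#' @export
readFieldSpec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$kind)) stop("field spec must declare a 'kind'")
  kind <- cfg$kind
  cfg$kind <- NULL
  do.call(fieldSpec, c(list(kind = kind), cfg))
}

#' Sample carrier points from a field specification
#'
#' @param spec a \code{FieldSpec}.
#' @param n number of points.
#' @param seed RNG seed.
#' @return a \code{CarrierPointSet}.
#' @export
sampleField <- function(spec, n, seed = NULL) {
  p <- spec@params
  switch(spec@kind,
    uniform_disc = sampleUniformDisc(p$radius, n, seed),
    uniform_box = sampleUniformBox(p$lower, p$upper, n, seed),
    ring_disc = do.call(sampleRingDisc,
      c(list(hullRadius = p$hullRadius, ringRadius = p$ringRadius,
             n = n, seed = seed),
        if (!is.null(p$ringWidth)) list(ringWidth = p$ringWidth))),
    cone_sphere = do.call(sampleConeSphere,
      c(p[intersect(names(p), c("apex", "axis", "halfAngles", "sphereCentre",
                                "sphereRadius", "radialProfile"))],
        list(n = n, seed = seed))),
    empirical = sampleEmpirical(p$density, n, seed),
    stop("unknown field kind: ", spec@kind))
}
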
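#' @useDynLib morphoforge, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif sd dbeta
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed below 2^31 from a base seed and a stream index.
subSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647
}

# Row-wise Euclidean distance between an n x 3 matrix and a single point.
rowDist <- function(m, p) {
  sqrt((m[, 1] - p[1])^2 + (m[, 2] - p[2])^2 + (m[, 3] - p[3])^2)
}

vnorm <- function(v) sqrt(sum(v * v))

# Children index list from a parent vector (NA marks the root).
childrenList <- function(parent) {
  n <- length(parent)
  kids <- vector("list", n)
  ok <- which(!is.na(parent))
  if (length(ok)) {
    sp <- split(ok, parent[ok])
    kids[as.integer(names(sp))] <- sp
  }
  kids
}

# Root-first topological order of the nodes; errors if parent links do not
# form a single rooted tree.
topoOrder <- function(parent) {
  n <- length(parent)
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("parent vector does not define a single root")
  kids <- childrenList(parent)
  ord <- integer(n)
  ord[1L] <- root
  filled <- 1L
  i <- 1L
  while (i <= filled) {
    ch <- kids[[ord[i]]]
    if (length(ch)) {
      ord[(filled + 1L):(filled + length(ch))] <- ch
      filled <- filled + length(ch)
    }
    i <- i + 1L
  }
  if (filled != n) stop("parent links contain a cycle or disconnected nodes")
  ord
}
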
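#' Hand-built ring fixtures
#'
#' Small reference configurations used throughout the test suite and the
#' documentation: a unit square, stacked-face packings, and a Hopf-linked
#' ring pair.
#'
#' @name fixtures
NULL

#' @describeIn fixtures the single square ring on a 2 x 2 x 1 lattice (the
#'   unique valid configuration at N = 4 there).
#' @export
squareRingConfig <- function() {
  spec <- buildLattice(2, 2, 1)
  ringConfigurationFromEdges(spec, seq_len(edgeCount(spec)))
}

#' @describeIn fixtures two opposite-face square rings on the 2 x 2 x 2
#'   cube (a stacked-face packing at complete filling).
#' @param axis face-normal axis (1 = x, 2 = y, 3 = z) selecting which pair
#'   of opposite faces carries the squares.
#' @export
twoFacePacking <- function(axis = 3L) {
  spec <- buildLattice(2, 2, 2)
  keep <- spec@edgeAxis != axis
  ringConfigurationFromEdges(spec, which(keep))
}

#' @describeIn fixtures an axis-aligned rectangular ring as a coordinate
#'   matrix (for linking-number calculations; vertices at unit spacing).
#' @param w,h rectangle side lengths in lattice units (>= 1).
#' @param origin numeric(3) position of one corner.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @export
rectangleRingCoords <- function(w, h, origin = c(0, 0, 0), plane = "xy") {
  ax <- switch(plane,
               xy = list(c(1, 0, 0), c(0, 1, 0)),
               xz = list(c(1, 0, 0), c(0, 0, 1)),
               yz = list(c(0, 1, 0), c(0, 0, 1)),
               stop("plane must be xy, xz or yz"))
  u <- ax[[1]]; v <- ax[[2]]
  pts <- list()
  for (t in 0:(w - 1)) pts[[length(pts) + 1L]] <- origin + t * u
  for (t in 0:(h - 1)) pts[[length(pts) + 1L]] <- origin + w * u + t * v
  for (t in 0:(w - 1)) pts[[length(pts) + 1L]] <- origin + (w - t) * u + h * v
  for (t in 0:(h - 1)) pts[[length(pts) + 1L]] <- origin + (h - t) * v
  do.call(rbind, pts)
}

#' @describeIn fixtures a Hopf-linked pair of lattice rings (|Lk| = 1): ring
#'   B pierces the disk of ring A exactly once.
#' @export
hopfLinkPair <- function() {
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(2, 0, 1),
             c(2, 0, 2), c(1, 0, 2), c(0, 0, 2), c(0, 0, 1))
  B <- rbind(c(1, -1, 1), c(1, 0, 1), c(1, 1, 1), c(1, 1, 2),
             c(1, 1, 3), c(1, 0, 3), c(1, -1, 3), c(1, -1, 2))
  list(A = A, B = B)
}

#' @describeIn fixtures a random valid full packing obtained by scrambling
#'   [initialFullPacking()] with plaquette flips at infinite temperature
#'   (every legal proposal accepted); deterministic given the seed.
#' @param spec a [LatticeSpec-class] admitting a full packing.
#' @param seed RNG seed.
#' @param attempts number of flip attempts.
#' @export
randomFullPacking <- function(spec, seed = 1L, attempts = 50L * siteCount(spec)) {
  init <- initialFullPacking(spec)
  x0 <- integer(edgeCount(spec))
  x0[init@activeEdges] <- 1L
  res <- .rm_plaquette_stress(mcGeometry(spec), x0, beta = 0,
                              n_attempts = as.double(attempts),
                              seed = as.double(seed))
  ringConfigurationFromEdges(spec, which(res$x == 1L))
}
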
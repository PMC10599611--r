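#' Gaussian linking number of two closed polygonal curves
#'
#' Computes the exact integer Gaussian linking number Lk of two disjoint
#' closed polygonal curves by two independent routes and cross-checks them:
#'
#' * `"gauss"` — the discrete Gauss double sum over all segment pairs, each
#'   pair contributing its signed solid angle in closed form; for disjoint
#'   closed curves the sum is an integer up to ~1e-10 rounding error.
#' * `"projection"` — the signed-crossing half-sum in a generic planar
#'   projection.  The projection direction is tilted by the fixed
#'   deterministic irrational vector `(pi, e) * 1e-4` off the z axis so that
#'   the axis-aligned lattice segments are in general position: no two
#'   distinct parallel segments project onto the same line and no crossing
#'   falls on a projected vertex.
#'
#' @param ringA,ringB numeric matrices `L x 3` of vertex coordinates in
#'   cyclic order (the closing segment is implicit).
#' @param method `"both"` (default; cross-checks and returns the common
#'   value), `"gauss"`, or `"projection"`.
#' @return Integer linking number.  Lk != 0 means the rings are
#'   concatenated.
#' @examples
#' hopf <- hopfLinkPair()
#' gaussLinkingNumber(hopf$A, hopf$B)  # +1 or -1
#' @export
gaussLinkingNumber <- function(ringA, ringB,
                               method = c("both", "gauss", "projection")) {
  method <- match.arg(method)
  ringA <- as.matrix(ringA); ringB <- as.matrix(ringB)
  storage.mode(ringA) <- "double"; storage.mode(ringB) <- "double"
  if (ncol(ringA) != 3L || ncol(ringB) != 3L) stop("rings must be L x 3 matrices")
  ## shared vertex -> undefined
  keyA <- paste(ringA[, 1], ringA[, 2], ringA[, 3])
  keyB <- paste(ringB[, 1], ringB[, 2], ringB[, 3])
  if (any(keyA %in% keyB))
    stop("rings share a vertex; linking number undefined for intersecting curves")
  lkG <- lkP <- NULL
  if (method %in% c("both", "gauss")) {
    raw <- .rm_gauss_linking(ringA, ringB)
    if (abs(raw - round(raw)) > 1e-6)
      stop(sprintf("Gauss sum %.8f is not close to an integer; curves may intersect", raw))
    lkG <- as.integer(round(raw))
  }
  if (method %in% c("both", "projection")) {
    lkP <- projectionLinkingNumber(ringA, ringB)
  }
  if (method == "both") {
    if (lkG != lkP)
      stop(sprintf("linking-number methods disagree: gauss %d vs projection %d", lkG, lkP))
    lkG
  } else if (method == "gauss") lkG else lkP
}

## signed-crossing count in a generic tilted projection
projectionLinkingNumber <- function(A, B) {
  tilt <- c(pi * 1e-4, exp(1) * 1e-4, 1)
  d <- tilt / sqrt(sum(tilt^2))
  u1 <- c(1, 0, 0) - d * d[1]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(d[2] * u1[3] - d[3] * u1[2],
          d[3] * u1[1] - d[1] * u1[3],
          d[1] * u1[2] - d[2] * u1[1])
  proj <- function(M) cbind(M %*% u1, M %*% u2)
  ht <- function(M) as.vector(M %*% d)
  Pa <- proj(A); Pb <- proj(B)
  ha <- ht(A); hb <- ht(B)
  na <- nrow(A); nb <- nrow(B)
  total <- 0L
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1L else i + 1L
    p <- Pa[i, ]; r <- Pa[i2, ] - p
    hp0 <- ha[i]; hp1 <- ha[i2]
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1L else j + 1L
      q <- Pb[j, ]; s <- Pb[j2, ] - q
      rxs <- r[1] * s[2] - r[2] * s[1]
      if (abs(rxs) < 1e-12) next  # parallel in projection: no transversal crossing
      qp <- q - p
      t <- (qp[1] * s[2] - qp[2] * s[1]) / rxs
      u <- (qp[1] * r[2] - qp[2] * r[1]) / rxs
      if (t <= 1e-9 || t >= 1 - 1e-9 || u <= 1e-9 || u >= 1 - 1e-9) next
      hA <- hp0 + t * (hp1 - hp0)
      hB <- hb[j] + u * (hb[j2] - hb[j])
      over <- sign(hA - hB)            # +1: A passes over B
      total <- total + as.integer(over * sign(rxs))
    }
  }
  if (total %% 2L != 0L) stop("odd signed-crossing sum; projection degenerate")
  total %/% 2L
}

#' Pairwise linking report of a melt
#'
#' Evaluates the Gaussian linking number of every unordered ring pair of a
#' configuration.  Configurations consisting of a single ring (Hamiltonian
#' cycles at complete filling) have no ring pairs and are flagged for
#' exclusion from unlinking statistics.
#'
#' @slot lk symmetric integer matrix of pairwise linking numbers (diagonal
#'   NA).
#' @slot isSingleRing logical.
#' @slot isUnlinked logical: all pairs have Lk = 0 (NA for single-ring
#'   melts).
#' @export
setClass("LinkReport",
  representation(lk = "matrix", isSingleRing = "logical",
                 isUnlinked = "logical"))

setValidity("LinkReport", function(object) {
  lk <- object@lk
  if (nrow(lk) != ncol(lk)) return("lk matrix must be square")
  if (nrow(lk) > 1 && !isTRUE(all.equal(lk[lower.tri(lk)], t(lk)[lower.tri(lk)])))
    return("lk matrix must be symmetric")
  if (isTRUE(object@isUnlinked) && any(lk != 0, na.rm = TRUE))
    return("isUnlinked contradicts a nonzero Lk")
  TRUE
})

#' @describeIn linkReport printout of a link report.
#' @param object a [LinkReport-class].
#' @export
setMethod("show", "LinkReport", function(object) {
  n <- nrow(object@lk)
  if (object@isSingleRing)
    cat("LinkReport: single ring (excluded from unlink statistics)\n")
  else
    cat(sprintf("LinkReport: %d rings, %s\n", n,
                if (isTRUE(object@isUnlinked)) "all pairs unlinked"
                else sprintf("%d linked pair(s)",
                             sum(object@lk[upper.tri(object@lk)] != 0))))
  invisible(NULL)
})

#' Linking report for a ring configuration
#'
#' @param config a [RingConfiguration-class].
#' @param method linking-number method, see [gaussLinkingNumber()].
#' @return A [LinkReport-class].
#' @export
linkReport <- function(config, method = "gauss") {
  stopifnot(is(config, "RingConfiguration"))
  n <- length(config@rings)
  lk <- matrix(0L, n, n)
  diag(lk) <- NA_integer_
  coords <- lapply(seq_len(n), function(r) ringCoordinates(config, r))
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      v <- gaussLinkingNumber(coords[[a]], coords[[b]], method = method)
      lk[a, b] <- lk[b, a] <- v
    }
  }
  new("LinkReport", lk = lk, isSingleRing = n == 1L,
      isUnlinked = if (n == 1L) NA else all(lk == 0L, na.rm = TRUE))
}

#' Unlinking probability of a melt ensemble
#'
#' Fraction of melts in which every ring pair has zero Gaussian linking
#' number.  Single-ring melts (Hamiltonian cycles) are excluded.  The 95%
#' Wilson score interval quantifies the binomial uncertainty.
#'
#' @param reports list of [LinkReport-class] objects.
#' @return List with `pUnlink`, `n` (non-excluded melts), `nExcluded`, and
#'   `ci` (Wilson 95% interval).
#' @export
unlinkProbability <- function(reports) {
  keep <- vapply(reports, function(r) !isTRUE(r@isSingleRing), logical(1))
  n <- sum(keep)
  if (n == 0L) stop("all melts are single rings; unlinking probability undefined")
  k <- sum(vapply(reports[keep], function(r) isTRUE(r@isUnlinked), logical(1)))
  p <- k / n
  z <- qnorm(0.975)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(pUnlink = p, n = n, nExcluded = sum(!keep),
       ci = c(lower = max(0, centre - half), upper = min(1, centre + half)))
}
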
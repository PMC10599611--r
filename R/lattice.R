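#' @useDynLib ringmelt, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats coef lm pchisq qnorm runif setNames var
#' @importFrom utils head
NULL

#' Cuboid simple-cubic lattice geometry
#'
#' `LatticeSpec` holds the full geometry of an `Lx x Ly x Lz` cuboid patch of
#' the simple-cubic lattice with open (non-periodic) boundaries: the sites,
#' the nearest-neighbour edges, and the corner triplets (ordered pairs of
#' mutually perpendicular edges sharing a middle site) on which the QUBO
#' encoding of ring self-assembly is built.
#'
#' Sites carry 0-based integer coordinates `(x, y, z)` and are indexed by the
#' fixed bijection `index = 1 + x + Lx * (y + Ly * z)` (1-based, R
#' convention).  Edges are stored with endpoint indices `i < j`; corner
#' triplets `(i, j, k)` have `j` adjacent to both `i` and `k`, the two edges
#' perpendicular, and `i < k`.  Collinear (straight-through) triplets are
#' deliberately excluded: a straight degree-2 site is not a corner and needs
#' no ancilla variable.
#'
#' @slot extents integer(3), the extents `(Lx, Ly, Lz)`, all >= 1.
#' @slot coords integer matrix `S x 3` of 0-based site coordinates, one row
#'   per site in index order.
#' @slot edges integer matrix `E x 2` of site indices, `edges[e,1] < edges[e,2]`.
#' @slot edgeAxis integer(E), axis of each edge (1 = x, 2 = y, 3 = z).
#' @slot corners integer matrix `C x 3` with columns `(i, j, k)`.
#' @slot cornerEdges integer matrix `C x 2`, the edge indices of `(i,j)` and
#'   `(j,k)` for each corner triplet.
#' @slot siteEdges list of length `S`; element `s` is the integer vector of
#'   edge indices incident to site `s`.
#'
#' @seealso [buildLattice()], [incidentEdges()]
#' @export
setClass("LatticeSpec",
  representation(
    extents = "integer",
    coords = "matrix",
    edges = "matrix",
    edgeAxis = "integer",
    corners = "matrix",
    cornerEdges = "matrix",
    siteEdges = "list"
  )
)

setValidity("LatticeSpec", function(object) {
  ext <- object@extents
  if (length(ext) != 3L || any(is.na(ext)) || any(ext < 1L))
    return("extents must be three positive integers")
  S <- prod(ext)
  if (nrow(object@coords) != S) return("coords row count != site count")
  E <- nrow(object@edges)
  Eexp <- (ext[1] - 1L) * ext[2] * ext[3] + ext[1] * (ext[2] - 1L) * ext[3] +
    ext[1] * ext[2] * (ext[3] - 1L)
  if (E != Eexp) return(sprintf("edge count %d != expected %d", E, Eexp))
  if (E > 0L && any(object@edges[, 1] >= object@edges[, 2]))
    return("edges must have i < j")
  if (length(object@siteEdges) != S) return("siteEdges length != site count")
  TRUE
})

#' Build a cuboid lattice
#'
#' Enumerates all sites, nearest-neighbour edges, and perpendicular corner
#' triplets of an `Lx x Ly x Lz` cuboid lattice, each exactly once, in a
#' deterministic order that is stable across runs.
#'
#' @param Lx,Ly,Lz positive integer extents (number of sites along each axis).
#' @return A [LatticeSpec-class] object.
#' @examples
#' spec <- buildLattice(2, 2, 2)
#' siteCount(spec)   # 8
#' edgeCount(spec)   # 12
#' cornerCount(spec) # 24
#' @export
buildLattice <- function(Lx, Ly, Lz) {
  ext <- c(Lx, Ly, Lz)
  if (length(ext) != 3L || any(is.na(ext)) || any(ext != floor(ext)) || any(ext < 1))
    stop("lattice extents must be positive integers")
  ext <- as.integer(ext)
  Lx <- ext[1]; Ly <- ext[2]; Lz <- ext[3]
  S <- Lx * Ly * Lz

  ## site index = 1 + x + Lx*(y + Ly*z): x varies fastest
  coords <- cbind(
    x = rep.int(seq_len(Lx) - 1L, Ly * Lz),
    y = rep.int(rep(seq_len(Ly) - 1L, each = Lx), Lz),
    z = rep(seq_len(Lz) - 1L, each = Lx * Ly)
  )

  idx <- function(x, y, z) 1L + x + Lx * (y + Ly * z)

  edge_i <- integer(0); edge_j <- integer(0); edge_ax <- integer(0)
  add_edges <- function(mask, di, axis) {
    from <- which(mask)
    if (!length(from)) return(invisible())
    to <- from + di
    edge_i <<- c(edge_i, from)
    edge_j <<- c(edge_j, to)
    edge_ax <<- c(edge_ax, rep.int(axis, length(from)))
  }
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  add_edges(x < Lx - 1L, 1L, 1L)
  add_edges(y < Ly - 1L, Lx, 2L)
  add_edges(z < Lz - 1L, Lx * Ly, 3L)
  ## canonical order: sort by (i, axis); neighbour j = i + stride is > i always
  if (length(edge_i)) {
    o <- order(edge_i, edge_ax)
    edges <- cbind(i = edge_i[o], j = edge_j[o])
    edgeAxis <- edge_ax[o]
  } else {
    edges <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
    edgeAxis <- integer(0)
  }
  E <- nrow(edges)

  siteEdges <- vector("list", S)
  if (E > 0) {
    by_i <- split(seq_len(E), factor(edges[, 1], levels = seq_len(S)))
    by_j <- split(seq_len(E), factor(edges[, 2], levels = seq_len(S)))
    for (s in seq_len(S)) siteEdges[[s]] <- sort(c(by_i[[s]], by_j[[s]]))
  } else {
    siteEdges[] <- list(integer(0))
  }

  ## corner triplets: per middle site, unordered pairs of perpendicular edges
  ci <- integer(0); cj <- integer(0); ck <- integer(0)
  ce1 <- integer(0); ce2 <- integer(0)
  for (s in seq_len(S)) {
    es <- siteEdges[[s]]
    d <- length(es)
    if (d < 2L) next
    for (a in seq_len(d - 1L)) {
      for (b in (a + 1L):d) {
        e1 <- es[a]; e2 <- es[b]
        if (edgeAxis[e1] == edgeAxis[e2]) next  # collinear pair: no corner
        o1 <- edges[e1, 1] + edges[e1, 2] - s   # opposite endpoints
        o2 <- edges[e2, 1] + edges[e2, 2] - s
        if (o1 < o2) {
          ci <- c(ci, o1); ck <- c(ck, o2); ce1 <- c(ce1, e1); ce2 <- c(ce2, e2)
        } else {
          ci <- c(ci, o2); ck <- c(ck, o1); ce1 <- c(ce1, e2); ce2 <- c(ce2, e1)
        }
        cj <- c(cj, s)
      }
    }
  }
  corners <- cbind(i = ci, j = cj, k = ck)
  cornerEdges <- cbind(e1 = ce1, e2 = ce2)

  new("LatticeSpec",
    extents = ext, coords = coords, edges = edges, edgeAxis = edgeAxis,
    corners = corners, cornerEdges = cornerEdges, siteEdges = siteEdges)
}

#' Lattice accessors
#'
#' @param spec a [LatticeSpec-class].
#' @return `siteCount`, `edgeCount`, `cornerCount`: integer counts.
#'   `latticeEdges`, `latticeCorners`: the underlying integer matrices.
#' @name lattice-accessors
NULL

#' @rdname lattice-accessors
#' @export
siteCount <- function(spec) nrow(spec@coords)

#' @rdname lattice-accessors
#' @export
edgeCount <- function(spec) nrow(spec@edges)

#' @rdname lattice-accessors
#' @export
cornerCount <- function(spec) nrow(spec@corners)

#' @rdname lattice-accessors
#' @export
latticeEdges <- function(spec) spec@edges

#' @rdname lattice-accessors
#' @export
latticeCorners <- function(spec) spec@corners

#' Site index / coordinate conversion
#'
#' The site index is the fixed bijection `1 + x + Lx*(y + Ly*z)` with 0-based
#' coordinates, so enumeration order is reproducible across runs and
#' machines.
#'
#' @param spec a [LatticeSpec-class].
#' @param x,y,z 0-based integer coordinates.
#' @param site 1-based site index.
#' @return `siteIndex`: 1-based site index; `siteCoords`: integer vector
#'   (or matrix) of 0-based coordinates.
#' @export
siteIndex <- function(spec, x, y, z) {
  ext <- spec@extents
  if (any(x < 0 | x >= ext[1] | y < 0 | y >= ext[2] | z < 0 | z >= ext[3]))
    stop("coordinates out of range")
  as.integer(1L + x + ext[1] * (y + ext[2] * z))
}

#' @rdname siteIndex
#' @export
siteCoords <- function(spec, site) {
  if (any(site < 1L | site > siteCount(spec))) stop("site index out of range")
  spec@coords[site, , drop = length(site) > 1L]
}

#' Edges incident to a site
#'
#' @param spec a [LatticeSpec-class].
#' @param site 1-based site index.
#' @return Integer vector of edge indices having `site` as an endpoint.
#' @examples
#' spec <- buildLattice(2, 2, 2)
#' length(incidentEdges(spec, 1)) # 3: a cube corner has degree 3
#' @export
incidentEdges <- function(spec, site) {
  if (length(site) != 1L || is.na(site) || site < 1L || site > siteCount(spec))
    stop("site index out of range")
  spec@siteEdges[[site]]
}

#' Unit faces (plaquettes) of the lattice
#'
#' Enumerates every unit square face of the cuboid lattice.  Each face is
#' reported as its four corner sites and its four boundary edges arranged as
#' two opposite pairs; the plaquette-flip Monte Carlo move exchanges one
#' opposite pair for the other.
#'
#' @param spec a [LatticeSpec-class].
#' @return A list with integer matrices `sites` (`F x 4`) and `edges`
#'   (`F x 4`, columns `(a1, a2, b1, b2)`: edges `a1`,`a2` are opposite, as
#'   are `b1`,`b2`).
#' @export
latticeFaces <- function(spec) {
  ext <- spec@extents
  edge_lookup <- new.env(hash = TRUE, parent = emptyenv())
  E <- edgeCount(spec)
  for (e in seq_len(E)) {
    assign(paste(spec@edges[e, 1], spec@edges[e, 2], sep = "-"), e,
           envir = edge_lookup)
  }
  eidx <- function(a, b) {
    key <- if (a < b) paste(a, b, sep = "-") else paste(b, a, sep = "-")
    get(key, envir = edge_lookup)
  }
  sites <- NULL; edges <- NULL
  sl <- el <- list(); nf <- 0L
  strides <- c(1L, ext[1], ext[1] * ext[2])
  for (ax1 in 1:2) for (ax2 in (ax1 + 1):3) {
    lim <- ext
    lim[ax1] <- lim[ax1] - 1L
    lim[ax2] <- lim[ax2] - 1L
    if (any(lim < 1L)) next
    for (s in seq_len(siteCount(spec))) {
      co <- spec@coords[s, ]
      if (co[ax1] >= lim[ax1] || co[ax2] >= lim[ax2]) next
      a <- s
      b <- s + strides[ax1]
      c_ <- s + strides[ax1] + strides[ax2]
      d <- s + strides[ax2]
      nf <- nf + 1L
      sl[[nf]] <- c(a, b, c_, d)
      ## opposite pairs: (ab, dc) along ax1; (bd?) no: (ad, bc) along ax2
      el[[nf]] <- c(eidx(a, b), eidx(d, c_), eidx(a, d), eidx(b, c_))
    }
  }
  list(
    sites = if (nf) do.call(rbind, sl) else matrix(integer(0), 0, 4),
    edges = if (nf) do.call(rbind, el) else matrix(integer(0), 0, 4)
  )
}

#' @describeIn buildLattice compact printout of the lattice geometry.
#' @param object a [LatticeSpec-class].
#' @export
setMethod("show", "LatticeSpec", function(object) {
  ext <- object@extents
  cat(sprintf("LatticeSpec %d x %d x %d: %d sites, %d edges, %d corner triplets\n",
              ext[1], ext[2], ext[3], siteCount(object), edgeCount(object),
              cornerCount(object)))
  invisible(NULL)
})

#' Lattice summary as JSON
#'
#' @param spec a [LatticeSpec-class].
#' @return A JSON string with extents and element counts.
#' @export
latticeSummaryJson <- function(spec) {
  jsonlite::toJSON(list(
    extents = spec@extents,
    sites = siteCount(spec),
    edges = edgeCount(spec),
    corner_triplets = cornerCount(spec)
  ), auto_unbox = TRUE)
}
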
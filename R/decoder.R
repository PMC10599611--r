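#' Decoded ring-melt configuration
#'
#' A melt microstate: a set of vertex-disjoint simple cycles (rings) on the
#' lattice graph.  Every ring is stored as a cyclic sequence of site
#' indices, canonicalised to the lexicographically minimal
#' rotation/reflection so that configurations compare equal independently of
#' trace order; the ring list itself is sorted.  On the bipartite
#' simple-cubic lattice every ring length is even and at least 4, and the
#' number of occupied sites equals the number of active bonds.
#'
#' @slot lattice the [LatticeSpec-class] the configuration lives on.
#' @slot rings list of integer vectors (canonical cyclic site sequences).
#' @slot occupied sorted integer vector of occupied site indices.
#' @slot activeEdges sorted integer vector of active edge indices.
#' @export
setClass("RingConfiguration",
  representation(lattice = "ANY", rings = "list", occupied = "integer",
                 activeEdges = "integer"))

setValidity("RingConfiguration", function(object) {
  lens <- lengths(object@rings)
  if (any(lens < 4L)) return("ring shorter than 4 sites")
  if (any(lens %% 2L != 0L)) return("odd ring length on a bipartite lattice")
  if (sum(lens) != length(object@occupied))
    return("ring lengths do not sum to occupied-site count")
  if (length(object@occupied) != length(object@activeEdges))
    return("occupied sites != active bonds")
  if (anyDuplicated(unlist(object@rings))) return("rings share a site")
  TRUE
})

canonicalRing <- function(sites) {
  n <- length(sites)
  best <- NULL
  for (dir in list(sites, rev(sites))) {
    for (r in seq_len(n)) {
      cand <- c(dir[r:n], dir[seq_len(r - 1L)])
      if (is.null(best)) best <- cand
      else {
        cmp <- cand - best
        nz <- which(cmp != 0L)
        if (length(nz) && cmp[nz[1]] < 0L) best <- cand
      }
    }
  }
  best
}

sortRings <- function(rings) {
  if (length(rings) < 2L) return(rings)
  keys <- vapply(rings, function(r) paste(sprintf("%09d", r), collapse = ""),
                 character(1))
  rings[order(keys)]
}

#' Build a configuration from an active-edge set
#'
#' Traces the disjoint cycles through the adjacency structure of the active
#' edges, validating that every touched site has degree exactly 2.  Ring
#' traversal starts from the lowest unvisited occupied site and proceeds
#' toward its lower-index neighbour first; sequences are canonicalised, so
#' the result is independent of trace order.
#'
#' @param spec a [LatticeSpec-class].
#' @param activeEdges integer vector of active edge indices.
#' @return A [RingConfiguration-class].
#' @export
ringConfigurationFromEdges <- function(spec, activeEdges) {
  activeEdges <- sort(unique(as.integer(activeEdges)))
  if (any(activeEdges < 1L | activeEdges > edgeCount(spec)))
    stop("edge index out of range")
  ends <- spec@edges[activeEdges, , drop = FALSE]
  deg <- tabulate(c(ends[, 1], ends[, 2]), nbins = siteCount(spec))
  bad <- which(deg != 0L & deg != 2L)
  if (length(bad))
    stop(sprintf("site %d has degree %d (must be 0 or 2)", bad[1], deg[bad[1]]))
  ## neighbour table restricted to active edges
  nbr <- vector("list", siteCount(spec))
  for (r in seq_len(nrow(ends))) {
    i <- ends[r, 1]; j <- ends[r, 2]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  occupied <- which(deg == 2L)
  visited <- logical(siteCount(spec))
  rings <- list()
  for (s in occupied) {
    if (visited[s]) next
    path <- integer(0)
    prev <- NA_integer_
    cur <- s
    repeat {
      path <- c(path, cur)
      visited[cur] <- TRUE
      nb <- sort(nbr[[cur]])
      nxt <- if (is.na(prev)) nb[1] else nb[nb != prev][1]
      if (is.na(nxt)) stop(sprintf("broken cycle at site %d", cur))
      if (nxt == s) break
      prev <- cur
      cur <- nxt
    }
    rings[[length(rings) + 1L]] <- canonicalRing(path)
  }
  new("RingConfiguration", lattice = spec, rings = sortRings(rings),
      occupied = occupied, activeEdges = activeEdges)
}

#' Decode a zero-energy assignment into a ring configuration
#'
#' Marks the lattice edges whose binary variables are active, traces the
#' resulting cycles, and cross-checks every ancilla variable against the
#' value forced by the site/edge variables (corner = AND of its two edges;
#' contact-adjacency and contact indicators likewise).  Ancillas are
#' re-derived and checked, never trusted, to guard against solver
#' artifacts.
#'
#' @param assignment 0/1 vector over the model's variables.
#' @param model the [QuboModel-class] the assignment belongs to.
#' @return A [RingConfiguration-class].
#' @export
decodeAssignment <- function(assignment, model) {
  stopifnot(is(model, "QuboModel"))
  e <- quboEnergy(model, assignment)
  if (e != 0)
    stop(sprintf("assignment has energy %g, not a ground state", e))
  x <- as.integer(assignment)
  spec <- model@lattice
  meta <- model@meta
  edgeAct <- x[meta$edgeVar] == 1L
  activeEdges <- which(edgeAct)
  occ <- if (isTRUE(meta$fullFilling)) rep(TRUE, siteCount(spec))
         else x[meta$siteVar] == 1L
  ## ancilla cross-checks
  ce <- spec@cornerEdges
  cexp <- edgeAct[ce[, 1]] & edgeAct[ce[, 2]]
  cgot <- x[meta$cornerVar] == 1L
  if (any(cexp != cgot)) {
    t <- which(cexp != cgot)[1]
    stop(sprintf("corner ancilla %d inconsistent with its edges (triplet %d-%d-%d)",
                 t, spec@corners[t, 1], spec@corners[t, 2], spec@corners[t, 3]))
  }
  if (!all(is.na(meta$contactAVar))) {
    aexp <- occ[spec@edges[, 1]] & occ[spec@edges[, 2]]
    agot <- x[meta$contactAVar] == 1L
    if (any(aexp != agot))
      stop(sprintf("contact-adjacency ancilla inconsistent at edge %d",
                   which(aexp != agot)[1]))
    bexp <- aexp & !edgeAct
    bgot <- x[meta$contactBVar] == 1L
    if (any(bexp != bgot))
      stop(sprintf("contact indicator inconsistent at edge %d",
                   which(bexp != bgot)[1]))
  }
  config <- ringConfigurationFromEdges(spec, activeEdges)
  if (!setequal(config@occupied, which(occ)))
    stop("occupied-site variables inconsistent with traced rings")
  config
}

#' Encode a ring configuration as a QUBO assignment
#'
#' Inverse of [decodeAssignment()]: sets the site and edge variables from
#' the configuration and every ancilla to its forced logical value.  For a
#' valid configuration matching the model's monomer count and satisfiable
#' constraint targets the resulting energy is 0.
#'
#' @param config a [RingConfiguration-class].
#' @param model a [QuboModel-class] on the same lattice.
#' @return Integer 0/1 assignment vector.
#' @export
encodeConfiguration <- function(config, model) {
  stopifnot(is(config, "RingConfiguration"), is(model, "QuboModel"))
  spec <- model@lattice
  if (!identical(spec@extents, config@lattice@extents))
    stop("configuration lattice does not match model lattice")
  meta <- model@meta
  if (length(config@occupied) != meta$N)
    stop(sprintf("configuration has %d occupied sites, model expects N = %d",
                 length(config@occupied), meta$N))
  x <- integer(variableCount(model))
  occ <- logical(siteCount(spec))
  occ[config@occupied] <- TRUE
  edgeAct <- logical(edgeCount(spec))
  edgeAct[config@activeEdges] <- TRUE
  if (!isTRUE(meta$fullFilling)) x[meta$siteVar[occ]] <- 1L
  x[meta$edgeVar[edgeAct]] <- 1L
  ce <- spec@cornerEdges
  x[meta$cornerVar[edgeAct[ce[, 1]] & edgeAct[ce[, 2]]]] <- 1L
  if (!all(is.na(meta$contactAVar))) {
    aon <- occ[spec@edges[, 1]] & occ[spec@edges[, 2]]
    x[meta$contactAVar[aon]] <- 1L
    x[meta$contactBVar[aon & !edgeAct]] <- 1L
  }
  x
}

#' Melt observables of a ring configuration
#'
#' A corner is an occupied site whose two bonds are perpendicular; a contact
#' is a lattice edge joining two occupied sites that carries no bond.  At
#' complete filling the contact count is exactly `E - N` (every edge is
#' either a bond or a contact).
#'
#' @param config a [RingConfiguration-class].
#' @return List with `nRings`, `nCorners`, `nContacts`, `ringLengths`,
#'   `meanRingLength`.
#' @export
computeObservables <- function(config) {
  stopifnot(is(config, "RingConfiguration"))
  spec <- config@lattice
  edgeAct <- logical(edgeCount(spec))
  edgeAct[config@activeEdges] <- TRUE
  nCorners <- 0L
  for (s in config@occupied) {
    es <- spec@siteEdges[[s]]
    on <- es[edgeAct[es]]
    if (spec@edgeAxis[on[1]] != spec@edgeAxis[on[2]]) nCorners <- nCorners + 1L
  }
  occ <- logical(siteCount(spec))
  occ[config@occupied] <- TRUE
  nContacts <- sum(occ[spec@edges[, 1]] & occ[spec@edges[, 2]] & !edgeAct)
  lens <- lengths(config@rings)
  list(nRings = length(config@rings), nCorners = nCorners,
       nContacts = as.integer(nContacts), ringLengths = as.integer(lens),
       meanRingLength = mean(lens))
}

#' Ring coordinates
#'
#' @param config a [RingConfiguration-class].
#' @param ring ring index.
#' @return Numeric matrix `L x 3` of the ring's 0-based site coordinates in
#'   cyclic order.
#' @export
ringCoordinates <- function(config, ring) {
  sites <- config@rings[[ring]]
  config@lattice@coords[sites, , drop = FALSE] * 1.0
}

#' @describeIn ringConfigurationFromEdges printout of a configuration.
#' @param object a [RingConfiguration-class].
#' @export
setMethod("show", "RingConfiguration", function(object) {
  obs <- computeObservables(object)
  ext <- object@lattice@extents
  cat(sprintf("RingConfiguration on %dx%dx%d: %d sites in %d ring(s) (lengths %s), %d corners, %d contacts\n",
              ext[1], ext[2], ext[3], length(object@occupied), obs$nRings,
              paste(obs$ringLengths, collapse = ","), obs$nCorners,
              obs$nContacts))
  invisible(NULL)
})

#' Serialize configurations as JSON Lines
#'
#' One JSON object per configuration: lattice extents, ring site sequences
#' (1-based indices), ring coordinates are recoverable via the fixed site
#' bijection, and the computed observables.
#'
#' @param configs list of [RingConfiguration-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfigurationsJsonl <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    obs <- computeObservables(cf)
    writeLines(jsonlite::toJSON(list(
      extents = cf@lattice@extents,
      rings = cf@rings,
      n_rings = obs$nRings, n_corners = obs$nCorners,
      n_contacts = obs$nContacts
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read configurations written by [writeConfigurationsJsonl()]
#'
#' @param path JSONL path.
#' @return List of [RingConfiguration-class] objects.
#' @export
readConfigurationsJsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    spec <- do.call(buildLattice, as.list(obj$extents))
    rings <- obj$rings
    if (is.matrix(rings)) rings <- split(rings, seq_len(nrow(rings)))
    if (!is.list(rings)) rings <- list(rings)
    edges <- ringsToEdges(spec, lapply(rings, as.integer))
    ringConfigurationFromEdges(spec, edges)
  })
}

## site-sequence rings -> active edge indices
ringsToEdges <- function(spec, rings) {
  key <- paste(spec@edges[, 1], spec@edges[, 2], sep = "-")
  lookup <- setNames(seq_len(edgeCount(spec)), key)
  out <- integer(0)
  for (r in rings) {
    n <- length(r)
    a <- r; b <- c(r[-1], r[1])
    lo <- pmin(a, b); hi <- pmax(a, b)
    e <- lookup[paste(lo, hi, sep = "-")]
    if (any(is.na(e))) stop("ring step is not a lattice edge")
    out <- c(out, unname(e))
  }
  sort(unique(out))
}

#' Export a configuration in XYZ format
#'
#' One atom per monomer; rings are distinguished by the element label
#' (`R1`, `R2`, ...), suitable for quick inspection in molecular viewers.
#'
#' @param config a [RingConfiguration-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeXyz <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(config@occupied)
  writeLines(c(as.character(n), "ringmelt configuration"), con)
  for (ri in seq_along(config@rings)) {
    co <- config@lattice@coords[config@rings[[ri]], , drop = FALSE]
    writeLines(sprintf("R%d %d %d %d", ri, co[, 1], co[, 2], co[, 3]), con)
  }
  invisible(path)
}
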
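#' Catalog of all valid configurations on a tiny lattice
#'
#' Result of exhaustive enumeration, independent of the QUBO machinery:
#' every vertex-disjoint cycle cover of exactly `N` sites (optionally
#' filtered to given corner/contact targets), in canonical form, pairwise
#' distinct.  Symmetry-related configurations are counted as distinct
#' microstates, matching statistical-mechanical counting.
#'
#' @slot lattice the [LatticeSpec-class].
#' @slot N integer monomer count.
#' @slot nCorners,nContacts optional integer targets (NA if unconstrained).
#' @slot configurations list of [RingConfiguration-class] entries.
#' @export
setClass("GroundStateCatalog",
  representation(lattice = "ANY", N = "integer", nCorners = "integer",
                 nContacts = "integer", configurations = "list"))

#' @describeIn enumerateValidConfigurations number of catalog entries.
#' @param catalog a [GroundStateCatalog-class].
#' @export
catalogSize <- function(catalog) length(catalog@configurations)

#' @describeIn enumerateValidConfigurations printout of a catalog.
#' @param object a [GroundStateCatalog-class].
#' @export
setMethod("show", "GroundStateCatalog", function(object) {
  ext <- object@lattice@extents
  cat(sprintf("GroundStateCatalog: %d configuration(s) on %dx%dx%d at N = %d",
              catalogSize(object), ext[1], ext[2], ext[3], object@N))
  if (!is.na(object@nCorners)) cat(sprintf(", corners = %d", object@nCorners))
  if (!is.na(object@nContacts)) cat(sprintf(", contacts = %d", object@nContacts))
  cat("\n")
  invisible(NULL)
})

#' Enumerate all valid ring configurations on a tiny lattice
#'
#' Backtracking search over edge subsets with degree pruning: edges are
#' decided in order; a site whose incident edges are all decided must end
#' with degree 0 or 2, the bond count is bounded by `N`, and branches that
#' cannot reach `N` bonds are cut.  Every surviving edge subset is a
#' vertex-disjoint cycle cover of exactly `N` sites.  The search is
#' exponential, so lattices beyond 24 sites are refused outright rather
#' than silently truncated.
#'
#' @param spec a [LatticeSpec-class] with at most 24 sites.
#' @param N even monomer count.
#' @param nCorners,nContacts optional integer targets filtering the catalog.
#' @return A [GroundStateCatalog-class].
#' @examples
#' cat1 <- enumerateValidConfigurations(buildLattice(2, 2, 1), 4)
#' catalogSize(cat1)  # 1: the perimeter square
#' @export
enumerateValidConfigurations <- function(spec, N, nCorners = NA,
                                         nContacts = NA) {
  stopifnot(is(spec, "LatticeSpec"))
  S <- siteCount(spec)
  if (S > 24L)
    stop("lattice has more than 24 sites; exhaustive enumeration refused (exponential cost)")
  if (N %% 2L != 0L) stop("N must be even")
  E <- edgeCount(spec)
  edges <- spec@edges
  ## for pruning: last edge index touching each site
  lastEdge <- integer(S)
  for (e in seq_len(E)) {
    lastEdge[edges[e, 1]] <- e
    lastEdge[edges[e, 2]] <- e
  }
  found <- list()
  deg <- integer(S)
  chosen <- logical(E)

  recurse <- function(e, bonds) {
    if (bonds > N) return(invisible())
    if (bonds + (E - e + 1L) < N) return(invisible())  # cannot reach N bonds
    if (e > E) {
      if (bonds == N) found[[length(found) + 1L]] <<- which(chosen)
      return(invisible())
    }
    i <- edges[e, 1]; j <- edges[e, 2]
    ## include edge e
    if (deg[i] < 2L && deg[j] < 2L) {
      deg[i] <<- deg[i] + 1L; deg[j] <<- deg[j] + 1L
      chosen[e] <<- TRUE
      if ((lastEdge[i] != e || deg[i] == 2L) &&
          (lastEdge[j] != e || deg[j] == 2L))
        recurse(e + 1L, bonds + 1L)
      chosen[e] <<- FALSE
      deg[i] <<- deg[i] - 1L; deg[j] <<- deg[j] - 1L
    }
    ## exclude edge e: sites now fully decided must have degree 0 or 2
    okI <- lastEdge[i] != e || deg[i] %in% c(0L, 2L)
    okJ <- lastEdge[j] != e || deg[j] %in% c(0L, 2L)
    if (okI && okJ) recurse(e + 1L, bonds)
    invisible()
  }
  recurse(1L, 0L)

  configs <- lapply(found, function(es) ringConfigurationFromEdges(spec, es))
  if (!is.na(nCorners) || !is.na(nContacts)) {
    keep <- vapply(configs, function(cf) {
      obs <- computeObservables(cf)
      (is.na(nCorners) || obs$nCorners == nCorners) &&
        (is.na(nContacts) || obs$nContacts == nContacts)
    }, logical(1))
    configs <- configs[keep]
  }
  ## canonical keys guarantee pairwise-distinct entries
  keys <- vapply(configs, configurationKey, character(1))
  stopifnot(!anyDuplicated(keys))
  configs <- configs[order(keys)]
  new("GroundStateCatalog", lattice = spec, N = as.integer(N),
      nCorners = as.integer(nCorners), nContacts = as.integer(nContacts),
      configurations = configs)
}

#' Canonical identity key of a configuration
#'
#' Ring sequences are canonicalised at trace time, so the sorted active-edge
#' set identifies the microstate uniquely; the key is its compact string
#' form, usable for deduplication and for matching sampler hits to catalog
#' entries.
#'
#' @param config a [RingConfiguration-class].
#' @return Character scalar.
#' @export
configurationKey <- function(config) {
  paste(config@activeEdges, collapse = ",")
}

#' Chi-square uniformity test over a ground-state catalog
#'
#' Pearson goodness-of-fit test of per-state hit counts against the uniform
#' distribution over all catalog entries.  Uniform coverage of the
#' degenerate ground-state manifold is the requirement a sampler must meet
#' for its ensembles to be equilibrium ensembles; heuristically accelerated
#' optimizers need not meet it.
#'
#' @param sampleCounts integer vector of hit counts, one per catalog entry
#'   (zeros allowed).  Requires at least 2 entries and a total of at least
#'   5 hits per entry.
#' @return List with `statistic`, `df`, `pValue`.
#' @export
uniformityTest <- function(sampleCounts) {
  k <- length(sampleCounts)
  if (k < 2L) stop("catalog must have at least 2 entries")
  n <- sum(sampleCounts)
  if (n < 5L * k)
    stop(sprintf("need at least %d total hits (5 per entry), got %d", 5L * k, n))
  expected <- n / k
  stat <- sum((sampleCounts - expected)^2 / expected)
  df <- k - 1L
  list(statistic = stat, df = df,
       pValue = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Match sampler hits to catalog entries
#'
#' @param assignments list of 0/1 assignments with zero energy under
#'   `model`.
#' @param model the [QuboModel-class] the assignments minimise.
#' @param catalog a [GroundStateCatalog-class] on the same lattice/N.
#' @return Integer vector of per-entry hit counts (same order as the
#'   catalog).  Errors if a hit decodes to a configuration outside the
#'   catalog.
#' @export
catalogHitCounts <- function(assignments, model, catalog) {
  keys <- vapply(catalog@configurations, configurationKey, character(1))
  counts <- setNames(integer(length(keys)), keys)
  for (a in assignments) {
    k <- configurationKey(decodeAssignment(a, model))
    if (!k %in% keys) stop("sampled ground state is missing from the catalog")
    counts[k] <- counts[k] + 1L
  }
  unname(counts)
}
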
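#' Deterministic full packing of a cuboid lattice
#'
#' Constructs a valid fully packed loop configuration (every site degree 2)
#' to initialise the real-space sampler.  When both in-plane extents are
#' even, each layer is tiled with 2x2 square rings (stacked 4-ring columns);
#' otherwise a serpentine (boustrophedon) closed tour covers each layer of a
#' plane pair with an even site count.  Full packing by even cycles requires
#' at least one even extent.
#'
#' @param spec a [LatticeSpec-class] with an even number of sites and at
#'   least one even extent (and at least two extents > 1 in the packing
#'   plane).
#' @return A [RingConfiguration-class] at complete filling.
#' @export
initialFullPacking <- function(spec) {
  stopifnot(is(spec, "LatticeSpec"))
  ext <- spec@extents
  if (all(ext %% 2L == 1L))
    stop("all extents odd: an odd number of sites cannot be covered by even cycles")
  ## choose the packing plane: two axes spanning an even number of sites,
  ## both > 1 so that cycles exist
  axes <- NULL
  cand <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (ax in cand) {
    if (ext[ax[1]] > 1L && ext[ax[2]] > 1L &&
        (ext[ax[1]] %% 2L == 0L || ext[ax[2]] %% 2L == 0L)) {
      axes <- ax
      break
    }
  }
  if (is.null(axes))
    stop("no lattice plane with two extents > 1 and an even site count; cannot pack")
  a1 <- axes[1]; a2 <- axes[2]
  a3 <- setdiff(1:3, axes)
  ## make the even axis the second in-plane axis (the serpentine needs it)
  if (ext[a2] %% 2L != 0L) { tmp <- a1; a1 <- a2; a2 <- tmp }
  L1 <- ext[a1]; L2 <- ext[a2]; L3 <- ext[a3]

  siteAt <- function(c1, c2, c3) {
    co <- integer(3)
    co[a1] <- c1; co[a2] <- c2; co[a3] <- c3
    siteIndex(spec, co[1], co[2], co[3])
  }
  rings <- list()
  for (l in seq_len(L3) - 1L) {
    if (L1 %% 2L == 0L && L2 %% 2L == 0L) {
      ## 2x2 square tiling of the layer
      for (c1 in seq(0L, L1 - 2L, by = 2L)) for (c2 in seq(0L, L2 - 2L, by = 2L)) {
        rings[[length(rings) + 1L]] <-
          c(siteAt(c1, c2, l), siteAt(c1 + 1L, c2, l),
            siteAt(c1 + 1L, c2 + 1L, l), siteAt(c1, c2 + 1L, l))
      }
    } else {
      ## serpentine Hamiltonian cycle of the L1 x L2 layer (L2 even):
      ## across row 0, snake through rows 1..L2-1 over c1 >= 1, return
      ## down column 0
      path <- integer(0)
      for (c1 in seq_len(L1) - 1L) path <- c(path, siteAt(c1, 0L, l))
      for (c2 in seq_len(L2 - 1L)) {
        cs <- if (c2 %% 2L == 1L) rev(seq_len(L1 - 1L)) else seq_len(L1 - 1L)
        for (c1 in cs) path <- c(path, siteAt(c1, c2, l))
      }
      path <- c(path, siteAt(0L, L2 - 1L, l))
      for (c2 in rev(seq_len(L2 - 2L))) path <- c(path, siteAt(0L, c2, l))
      rings[[length(rings) + 1L]] <- path
    }
  }
  ringConfigurationFromEdges(spec, ringsToEdges(spec, rings))
}

mcGeometry <- function(spec) {
  faces <- latticeFaces(spec)
  list(edge_axis = as.integer(spec@edgeAxis),
       edge_sites = spec@edges - 1L,
       n_sites = siteCount(spec),
       face_edges = faces$edges - 1L)
}

#' Single plaquette-flip proposal
#'
#' If the given unit face carries exactly two opposite occupied edges and
#' two empty ones, proposes exchanging the pairs (a degree-preserving move
#' that can merge or split rings and change the corner count) and accepts
#' with Metropolis probability `min(1, exp(-beta * dCorners))`; any other
#' face pattern is a null proposal.  This is the elementary move of the
#' fully-packed-loop sampler; it is ergodic only at complete filling.
#'
#' @param spec a [LatticeSpec-class].
#' @param activeEdges integer vector of active edge indices (fully packed).
#' @param face face index into `latticeFaces(spec)`.
#' @param beta inverse temperature; `Inf` accepts only downhill moves.
#' @param u uniform random number in `[0,1)` used for the Metropolis
#'   decision (supply 0 to force acceptance of any legal proposal).
#' @return List with `accepted`, `null` (no legal proposal), `activeEdges`,
#'   `dCorners`.
#' @export
plaquetteFlip <- function(spec, activeEdges, face, beta = Inf, u = 0) {
  faces <- latticeFaces(spec)
  if (face < 1L || face > nrow(faces$edges)) stop("invalid face index")
  fe <- faces$edges[face, ]
  x <- logical(edgeCount(spec))
  x[activeEdges] <- TRUE
  if (x[fe[1]] && x[fe[2]] && !x[fe[3]] && !x[fe[4]]) {
    out <- fe[1:2]; inn <- fe[3:4]
  } else if (!x[fe[1]] && !x[fe[2]] && x[fe[3]] && x[fe[4]]) {
    out <- fe[3:4]; inn <- fe[1:2]
  } else {
    return(list(accepted = FALSE, null = TRUE, activeEdges = activeEdges,
                dCorners = 0L))
  }
  cfg0 <- ringConfigurationFromEdges(spec, activeEdges)
  e1 <- setdiff(union(activeEdges, inn), out)
  cfg1 <- ringConfigurationFromEdges(spec, e1)  # validates degree-2
  d <- computeObservables(cfg1)$nCorners - computeObservables(cfg0)$nCorners
  acc <- d <= 0 || u < exp(-beta * d)
  list(accepted = acc, null = FALSE,
       activeEdges = if (acc) sort(e1) else activeEdges,
       dCorners = as.integer(d))
}

#' Replica-exchange plaquette-flip Monte Carlo
#'
#' Parallel tempering over the curvature energy (total corner count) for
#' fully packed cuboids: each replica evolves by random plaquette-flip
#' proposals (one sweep = one proposal per lattice face), adjacent replicas
#' exchange configurations with probability
#' `min(1, exp((beta2 - beta1) * (E2 - E1)))`, and the coldest replica's
#' energy is recorded every sweep.  Deterministic given the seed.
#'
#' @param spec a [LatticeSpec-class] admitting a full packing.
#' @param betaLadder increasing vector of inverse temperatures (one per
#'   replica); a single value runs plain Metropolis.
#' @param sweeps number of sweeps.
#' @param exchangeInterval sweeps between exchange attempts (default 1, so
#'   the interval is far below the autocorrelation time).
#' @param recordInterval sweeps between stored coldest-replica
#'   configurations (0 stores none).
#' @param seed RNG seed.
#' @param initial optional [RingConfiguration-class] at complete filling to
#'   start from (default [initialFullPacking()]).
#' @return List with `energies` (coldest-replica corner count per sweep),
#'   `configurations` (list of [RingConfiguration-class]), `swapRate`, and
#'   `tau` (integrated autocorrelation time of the energy series, in
#'   sweeps).
#' @export
replicaExchangeRun <- function(spec, betaLadder, sweeps,
                               exchangeInterval = 1L, recordInterval = 0L,
                               seed = 1L, initial = NULL) {
  stopifnot(is(spec, "LatticeSpec"), length(betaLadder) >= 1L)
  if (is.unsorted(betaLadder)) stop("betaLadder must be sorted increasing")
  if (is.null(initial)) initial <- initialFullPacking(spec)
  x0 <- integer(edgeCount(spec))
  x0[initial@activeEdges] <- 1L
  res <- .rm_replica_exchange(mcGeometry(spec), x0, as.numeric(betaLadder),
                              as.integer(sweeps), as.integer(exchangeInterval),
                              as.integer(recordInterval), as.double(seed))
  configs <- list()
  if (recordInterval > 0L && nrow(res$configurations) > 0L) {
    configs <- lapply(seq_len(nrow(res$configurations)), function(r)
      ringConfigurationFromEdges(spec, res$configurations[r, ]))
  }
  tau <- tryCatch(integratedAutocorrelationTime(res$cold_energy),
                  error = function(e) NA_real_, warning = function(w) 0.5)
  if (length(betaLadder) > 1L && is.finite(tau) &&
      exchangeInterval > tau / 100)
    warning(sprintf("exchange interval %d exceeds tau/100 = %.2f sweeps",
                    exchangeInterval, tau / 100))
  list(energies = res$cold_energy, configurations = configs,
       swapRate = res$swap_rate, tau = tau)
}

#' Integrated autocorrelation time
#'
#' Standard integrated autocorrelation time
#' `tau = 1/2 + sum_t rho(t)` with the automatic windowing rule of Sokal:
#' the sum is truncated at the smallest window `W` with `W >= c * tau(W)`
#' (c = 5).  A white-noise series gives `tau ~ 0.5`; an AR(1) series with
#' coefficient `rho` gives `tau ~ (1 + rho) / (2 (1 - rho))`.
#'
#' @param series numeric energy series of length >= 100.
#' @param c window factor (default 5).
#' @return `tau` in sweeps.  A constant series is degenerate and returns
#'   0.5 with a warning.
#' @export
integratedAutocorrelationTime <- function(series, c = 5) {
  n <- length(series)
  if (n < 100L) stop("series too short for autocorrelation estimation (need >= 100)")
  v <- var(series)
  if (v == 0) {
    warning("constant series: autocorrelation time is degenerate, returning 0.5")
    return(0.5)
  }
  x <- series - mean(series)
  maxlag <- min(n - 1L, 10000L)
  ## FFT-based autocovariance
  m <- 2^ceiling(log2(2L * n))
  f <- fft(c(x, rep(0, m - n)))
  acov <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(maxlag + 1L)] / m
  rho <- acov / acov[1]
  tau <- 0.5
  for (t in seq_len(maxlag)) {
    tau <- tau + rho[t + 1L]
    if (t >= c * tau) break
  }
  max(tau, 0.5)
}
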
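#' Annealing schedule
#'
#' Parameterises the simulated-annealing protocol: a ladder of inverse
#' temperatures traversed once per run (one full single-flip Metropolis pass
#' over all variables per ladder step), the number of independent restarts,
#' and the RNG seed.  The ladder interpolates between `betaStart` and
#' `betaEnd` linearly (default) or geometrically.  The default window
#' `beta = 3 ... 9` brackets the freezing regime of the integer-penalty
#' models built here (uphill unit moves go from ~5% to ~0.01% acceptance),
#' which is where slow cooling pays off; the hot disordered phase above it
#' contributes nothing to equilibration and is skipped.
#'
#' When `sweeps` is `NULL` the solver uses `max(1000, 50 * variableCount)`
#' sweeps, a default sized so that the melts treated in this package
#' (hundreds to ~2500 binary variables) are solved reliably in practice.
#'
#' @param sweeps number of sweeps (ladder length), or `NULL` for the
#'   size-dependent default.
#' @param betaStart,betaEnd positive inverse temperatures,
#'   `betaStart <= betaEnd`.
#' @param interpolation `"geometric"` or `"linear"`.
#' @param restarts independent annealing runs per [simulatedAnneal()] call.
#' @param seed master RNG seed (integer).
#' @param order update order within a sweep: `"shuffle"` (fresh random
#'   permutation each sweep, the default), `"cyclic"` (fixed order with a
#'   random per-sweep offset), or `"random"` (independent random site
#'   picks).  Cyclic sweeps converge marginally faster on pure optimisation
#'   runs but measurably over-sample low-curvature ground states at large N
#'   (checked against the exact infinite-temperature plaquette-flip
#'   reference); the shuffled order removes that coverage bias at no cost.
#' @return An object of class `AnnealSchedule`.
#' @export
annealSchedule <- function(sweeps = NULL, betaStart = 3, betaEnd = 9,
                           interpolation = c("linear", "geometric"),
                           restarts = 10L, seed = 1L,
                           order = c("shuffle", "cyclic", "random")) {
  interpolation <- match.arg(interpolation)
  order <- match.arg(order)
  if (!is.null(sweeps) && (sweeps < 1 || sweeps != floor(sweeps)))
    stop("sweeps must be a positive integer")
  if (betaStart <= 0 || betaEnd < betaStart)
    stop("need 0 < betaStart <= betaEnd")
  if (restarts < 1) stop("restarts must be >= 1")
  structure(list(sweeps = if (is.null(sweeps)) NULL else as.integer(sweeps),
                 betaStart = betaStart, betaEnd = betaEnd,
                 interpolation = interpolation,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 order = order),
            class = "AnnealSchedule")
}

orderCode <- function(schedule) {
  switch(if (is.null(schedule$order)) "shuffle" else schedule$order,
         cyclic = 0L, random = 1L, shuffle = 2L)
}

scheduleBetas <- function(schedule, nvar) {
  ns <- schedule$sweeps
  if (is.null(ns)) ns <- max(1000L, 50L * nvar)
  if (schedule$interpolation == "geometric")
    exp(seq(log(schedule$betaStart), log(schedule$betaEnd), length.out = ns))
  else
    seq(schedule$betaStart, schedule$betaEnd, length.out = ns)
}

## Flatten a QuboModel into the arrays the C++ annealer consumes:
## symmetrized CSR adjacency for the generic couplings, flattened
## population-constraint groups, and a variable -> group membership table.
modelArrays <- function(model) {
  nv <- variableCount(model)
  sm <- if (is.null(model@Q)) data.frame(i = integer(0), j = integer(0),
                                         x = numeric(0))
        else Matrix::summary(model@Q)
  keep <- sm$x != 0
  i <- c(sm$i[keep], sm$j[keep]) - 1L
  j <- c(sm$j[keep], sm$i[keep]) - 1L
  w <- c(sm$x[keep], sm$x[keep])
  o <- order(i, j)
  i <- i[o]; j <- j[o]; w <- w[o]
  adj_ptr <- c(0L, cumsum(tabulate(i + 1L, nbins = nv)))

  ng <- length(model@groups)
  grp_coef <- vapply(model@groups, `[[`, numeric(1), "coef")
  grp_target <- vapply(model@groups, function(g) as.numeric(g$target), numeric(1))
  grp_vars0 <- lapply(model@groups, function(g) as.integer(g$vars) - 1L)
  grp_ptr <- c(0L, cumsum(vapply(grp_vars0, length, integer(1))))
  gv <- if (ng) unlist(grp_vars0) else integer(0)
  gid <- if (ng) rep(seq_len(ng) - 1L, vapply(grp_vars0, length, integer(1))) else integer(0)
  om <- order(gv)
  vgrp_ptr <- c(0L, cumsum(tabulate(gv + 1L, nbins = nv)))
  list(lin = as.numeric(model@linear),
       adj_ptr = as.integer(adj_ptr), adj_idx = as.integer(j),
       adj_w = as.numeric(w),
       grp_coef = as.numeric(grp_coef), grp_target = grp_target,
       grp_ptr = as.integer(grp_ptr), grp_vars = gv,
       vgrp_ptr = as.integer(vgrp_ptr), vgrp = gid[om],
       offset = as.numeric(model@offset))
}

#' Result of a simulated-annealing run
#'
#' @slot assignment integer 0/1 vector, the best assignment found.
#' @slot energy numeric, its energy.
#' @slot restartEnergies numeric, best energy of each restart performed
#'   (restarts stop early once the target ground energy is reached).
#' @slot hit logical, whether the target ground energy was attained.
#' @slot seed integer seed used.
#' @slot sweeps integer sweeps per restart.
#' @export
setClass("SolveResult",
  representation(assignment = "integer", energy = "numeric",
                 restartEnergies = "numeric", hit = "logical",
                 seed = "integer", sweeps = "integer"))

setValidity("SolveResult", function(object) {
  if (length(object@restartEnergies) &&
      object@energy > min(object@restartEnergies) + 1e-12)
    return("best energy exceeds a restart energy")
  TRUE
})

#' @describeIn simulatedAnneal printout of a solve result.
#' @param object a `SolveResult`.
#' @export
setMethod("show", "SolveResult", function(object) {
  cat(sprintf("SolveResult: best energy %g over %d restart(s), %s\n",
              object@energy, length(object@restartEnergies),
              if (object@hit) "ground state reached" else "no ground state"))
  invisible(NULL)
})

#' Minimise a QUBO model by simulated annealing
#'
#' Metropolis single-variable-flip dynamics over a decreasing-temperature
#' ladder with independent restarts, using exact incremental energy updates
#' (with the default integer coefficients the tracked energy is exact, so
#' the zero ground energy is recognised without tolerance).  Deterministic
#' given `(model, schedule)` including the schedule's seed.
#'
#' @param model a [QuboModel-class].
#' @param schedule an [annealSchedule()].
#' @param target target ground energy (0 for feasible constraint sets).
#' @param init optional 0/1 assignment to start every restart from (warm
#'   start) instead of a fresh random state.  Warm starts speed up targeting
#'   of rare constrained states but bias the sampled distribution toward the
#'   starting basin, so they are never used for equilibrium ensembles.
#' @param initProb optional per-variable Bernoulli probabilities for the
#'   random initial state (see [densityInitProb()]); `NULL` uses fair coin
#'   flips.
#' @return A [SolveResult-class].
#' @export
simulatedAnneal <- function(model, schedule = annealSchedule(), target = 0,
                            init = NULL, initProb = NULL) {
  stopifnot(is(model, "QuboModel"), inherits(schedule, "AnnealSchedule"))
  if (variableCount(model) == 0L) stop("model has no variables")
  betas <- scheduleBetas(schedule, variableCount(model))
  res <- .rm_anneal(modelArrays(model), betas, schedule$restarts,
                    target, 1e-9, as.double(schedule$seed),
                    if (is.null(init)) integer(0) else as.integer(init),
                    if (is.null(initProb)) numeric(0) else as.numeric(initProb),
                    orderCode(schedule))
  new("SolveResult", assignment = as.integer(res$assignment),
      energy = as.numeric(res$energy),
      restartEnergies = as.numeric(res$restart_energies),
      hit = isTRUE(res$hit), seed = schedule$seed,
      sweeps = length(betas))
}

#' Sample ground states by repeated annealing
#'
#' Runs independent annealing runs (fresh RNG streams derived from the
#' master seed) until `nSamples` ground-state hits are collected or the
#' attempt budget is exhausted.  Every returned assignment has energy
#' exactly equal to `target`.  Because each hit comes from an independent
#' fresh-start run, the collection samples the degenerate ground-state
#' manifold without inter-sample correlation.
#'
#' @param model a [QuboModel-class].
#' @param schedule an [annealSchedule()]; its `restarts` field is ignored
#'   here (each attempt is a single run).
#' @param nSamples number of ground-state samples wanted (>= 1).
#' @param seed master seed; defaults to the schedule's.
#' @param maxAttempts attempt budget (default `50 * nSamples`).  If it is
#'   exhausted first, a warning reports the shortfall and the hits found so
#'   far are returned.
#' @param target target ground energy.
#' @param init optional warm-start assignment, see [simulatedAnneal()].
#' @param initProb optional per-variable initial-state probabilities, see
#'   [simulatedAnneal()].
#' @return List of 0/1 integer assignments with attribute `attempts`.
#' @export
sampleGroundStates <- function(model, schedule = annealSchedule(), nSamples,
                               seed = schedule$seed,
                               maxAttempts = 50L * nSamples, target = 0,
                               init = NULL, initProb = NULL) {
  stopifnot(is(model, "QuboModel"), inherits(schedule, "AnnealSchedule"))
  if (length(nSamples) != 1L || is.na(nSamples) || nSamples < 1)
    stop("nSamples must be >= 1")
  betas <- scheduleBetas(schedule, variableCount(model))
  res <- .rm_anneal_collect(modelArrays(model), betas, as.integer(nSamples),
                            as.integer(maxAttempts), target, 1e-9,
                            as.double(seed),
                            if (is.null(init)) integer(0) else as.integer(init),
                            if (is.null(initProb)) numeric(0) else as.numeric(initProb),
                            orderCode(schedule))
  hits <- lapply(seq_len(nrow(res$hits)), function(r) as.integer(res$hits[r, ]))
  if (length(hits) < nSamples)
    warning(sprintf("attempt budget exhausted: %d of %d ground-state hits collected in %d attempts",
                    length(hits), nSamples, res$attempts))
  attr(hits, "attempts") <- res$attempts
  hits
}

#' Ground-state hit rate versus annealing effort
#'
#' Estimates the probability of reaching the ground state in a single
#' annealing run as a function of the number of sweeps, and derives the two
#' characteristic efforts: `tauHalf`, the sweeps at which the hit rate
#' crosses 50% (log-interpolated between grid points), and `tOpt`, the grid
#' sweeps maximising hits per sweep.  Both are reported in sweeps, not
#' wall-clock time.
#'
#' @param model a [QuboModel-class].
#' @param sweepGrid increasing vector of sweep counts.
#' @param trialsPerPoint independent runs per grid point.
#' @param seed master seed.
#' @param schedule base [annealSchedule()] supplying the beta ladder shape.
#' @param target target ground energy.
#' @return data.frame with columns `sweeps` and `hitFraction`, and
#'   attributes `tauHalf` and `tOpt`.
#' @export
hitRateCurve <- function(model, sweepGrid, trialsPerPoint, seed = 1L,
                         schedule = annealSchedule(), target = 0) {
  stopifnot(length(sweepGrid) >= 1L, trialsPerPoint >= 1L)
  sweepGrid <- as.integer(sort(sweepGrid))
  arrays <- modelArrays(model)
  hf <- numeric(length(sweepGrid))
  for (gi in seq_along(sweepGrid)) {
    sch <- schedule
    sch$sweeps <- sweepGrid[gi]
    betas <- scheduleBetas(sch, variableCount(model))
    res <- .rm_anneal_collect(arrays, betas, as.integer(trialsPerPoint) + 1L,
                              as.integer(trialsPerPoint), target, 1e-9,
                              as.double(seed) * 131 + gi, integer(0),
                              numeric(0), orderCode(schedule))
    hf[gi] <- nrow(res$hits) / trialsPerPoint
  }
  out <- data.frame(sweeps = sweepGrid, hitFraction = hf)
  tauHalf <- NA_real_
  above <- which(hf >= 0.5)
  if (length(above)) {
    a <- above[1]
    if (a == 1L || hf[a] == 0.5) tauHalf <- as.numeric(sweepGrid[a])
    else {
      x0 <- log(sweepGrid[a - 1]); x1 <- log(sweepGrid[a])
      y0 <- hf[a - 1]; y1 <- hf[a]
      tauHalf <- exp(x0 + (0.5 - y0) / (y1 - y0) * (x1 - x0))
    }
  }
  perSweep <- hf / sweepGrid
  attr(out, "tauHalf") <- tauHalf
  attr(out, "tOpt") <- as.numeric(sweepGrid[which.max(perSweep)])
  out
}

#' Density-matched initial-state probabilities
#'
#' Bernoulli probabilities for the annealer's random initial state that
#' match each variable kind's expected density in a valid configuration:
#' sites at `N/S`, edges at `N/E`, corner ancillas at the product of their
#' two edge probabilities, contact-adjacency ancillas at the squared site
#' probability, and contact indicators at adjacency times no-bond.  A
#' density-matched start shortens the burn-in of constrained targeting runs
#' without touching the dynamics (the initial state is forgotten during the
#' hot phase for equilibrium schedules).
#'
#' @param model a [QuboModel-class] built by [buildAssemblyHamiltonian()].
#' @return Numeric vector of probabilities, one per registered variable.
#' @export
densityInitProb <- function(model) {
  meta <- model@meta
  spec <- model@lattice
  N <- meta$N
  pSite <- N / siteCount(spec)
  pEdge <- N / edgeCount(spec)
  p <- numeric(variableCount(model))
  if (!isTRUE(meta$fullFilling)) p[meta$siteVar] <- pSite
  p[meta$edgeVar] <- pEdge
  p[meta$cornerVar] <- pEdge^2
  if (!all(is.na(meta$contactAVar))) {
    p[meta$contactAVar] <- pSite^2
    p[meta$contactBVar] <- pSite^2 * (1 - pEdge)
  }
  pmin(pmax(p, 0.01), 0.99)
}
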
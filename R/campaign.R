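#' Campaign configuration
#'
#' Describes a sampling campaign over a list of lattice sizes: which
#' sampler to use, how many ground-state samples to collect per size,
#' optional constraint targets, and the master seed.  Every derived
#' quantity is replayable from the configuration alone.
#'
#' @param sizes list of integer extent vectors `c(Lx, Ly, Lz)`.
#' @param N `"full"` for complete filling (N = site count) or a vector of
#'   explicit monomer counts, one per size.
#' @param nCorners,nContacts optional constraint targets (scalar, recycled,
#'   NA = unconstrained).
#' @param sampler `"qubo-anneal"` (ground states of the assembly QUBO),
#'   `"realspace-mc"` (plaquette-flip MC at infinite temperature, valid for
#'   unconstrained complete filling only), or a function
#'   `(model, n, seed) -> list of assignments` acting as an external solver
#'   adapter.
#' @param samplesPerPoint ground-state samples per size.
#' @param seed master seed.
#' @param schedule [annealSchedule()] for the QUBO sampler (`NULL` for
#'   defaults).
#' @param coeffs [ringCoefficients()] for model construction.
#' @param computeLinks logical, evaluate pairwise linking numbers.
#' @param outputJsonl optional path: per-sample observable stream.
#' @return Object of class `CampaignConfig`.
#' @export
campaignConfig <- function(sizes, N = "full", nCorners = NA, nContacts = NA,
                           sampler = "qubo-anneal", samplesPerPoint = 100L,
                           seed = 1L, schedule = NULL,
                           coeffs = ringCoefficients(),
                           computeLinks = FALSE, outputJsonl = NULL) {
  if (!is.list(sizes)) sizes <- list(sizes)
  k <- length(sizes)
  structure(list(sizes = sizes, N = N,
                 nCorners = rep(nCorners, length.out = k),
                 nContacts = rep(nContacts, length.out = k),
                 sampler = sampler,
                 samplesPerPoint = as.integer(samplesPerPoint),
                 seed = as.integer(seed), schedule = schedule,
                 coeffs = coeffs, computeLinks = isTRUE(computeLinks),
                 outputJsonl = outputJsonl),
            class = "CampaignConfig")
}

campaignHash <- function(config) {
  cfg <- unclass(config)
  cfg$outputJsonl <- NULL  # output location must not change the identity
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(cfg), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Run a sampling campaign
#'
#' For each lattice size: builds the (optionally constrained) assembly
#' Hamiltonian, collects the requested number of ground-state samples with
#' the configured sampler, decodes them, computes melt observables (and
#' linking reports when requested), and aggregates per-size means, SDs,
#' standard errors, and unlinking probabilities.  Sampler shortfalls are
#' propagated as warnings with partial per-size results preserved.
#'
#' @param config a [campaignConfig()].
#' @return List with `summary` (one data.frame row per size), `observables`
#'   (per-size data.frame of per-sample observables), `reports` (per-size
#'   list of [LinkReport-class], if requested), `hash` (config digest), and
#'   `seed`.
#' @export
runCampaign <- function(config) {
  stopifnot(inherits(config, "CampaignConfig"))
  k <- length(config$sizes)
  rows <- vector("list", k)
  obsList <- vector("list", k)
  repList <- vector("list", k)
  jsonlCon <- NULL
  if (!is.null(config$outputJsonl)) {
    jsonlCon <- file(config$outputJsonl, "w")
    on.exit(close(jsonlCon))
  }
  hash <- campaignHash(config)
  for (si in seq_len(k)) {
    ext <- config$sizes[[si]]
    spec <- buildLattice(ext[1], ext[2], ext[3])
    full <- identical(config$N, "full")
    N <- if (full) siteCount(spec) else as.integer(config$N[si])
    model <- buildAssemblyHamiltonian(spec, N, coeffs = config$coeffs,
                                      fullFilling = full)
    if (!is.na(config$nCorners[si]))
      model <- addCurvatureConstraint(model, config$nCorners[si])
    if (!is.na(config$nContacts[si]))
      model <- addContactsConstraint(model, config$nContacts[si])
    n <- config$samplesPerPoint
    seed_si <- (config$seed * 1009L + si * 9973L) %% .Machine$integer.max
    configs <- list()
    if (n > 0L) {
      if (is.function(config$sampler)) {
        hits <- config$sampler(model, n, seed_si)
        configs <- lapply(hits, decodeAssignment, model = model)
      } else if (config$sampler == "qubo-anneal") {
        sch <- if (is.null(config$schedule)) annealSchedule(seed = seed_si)
               else config$schedule
        hits <- sampleGroundStates(model, sch, nSamples = n, seed = seed_si)
        configs <- lapply(hits, decodeAssignment, model = model)
      } else if (config$sampler == "realspace-mc") {
        if (!full || !is.na(config$nCorners[si]) || !is.na(config$nContacts[si]))
          stop("realspace-mc sampling requires unconstrained complete filling")
        interval <- max(10L, siteCount(spec))
        run <- replicaExchangeRun(spec, betaLadder = 0,
                                  sweeps = n * interval,
                                  recordInterval = interval, seed = seed_si)
        configs <- run$configurations
      } else stop("unknown sampler")
    }
    obs <- do.call(rbind, lapply(configs, function(cf) {
      o <- computeObservables(cf)
      data.frame(nRings = o$nRings, nCorners = o$nCorners,
                 nContacts = o$nContacts, meanRingLength = o$meanRingLength)
    }))
    obsList[[si]] <- obs
    pU <- pLo <- pHi <- NA_real_; nEx <- NA_integer_
    if (config$computeLinks && length(configs)) {
      reps <- lapply(configs, linkReport)
      repList[[si]] <- reps
      up <- tryCatch(unlinkProbability(reps), error = function(e) NULL)
      if (!is.null(up)) {
        pU <- up$pUnlink; pLo <- up$ci[["lower"]]; pHi <- up$ci[["upper"]]
        nEx <- up$nExcluded
      }
    }
    if (!is.null(jsonlCon)) {
      for (ci in seq_along(configs)) {
        o <- computeObservables(configs[[ci]])
        writeLines(jsonlite::toJSON(list(
          hash = hash, seed = seed_si, extents = ext, N = N, sample = ci,
          key = configurationKey(configs[[ci]]),
          n_rings = o$nRings, n_corners = o$nCorners,
          n_contacts = o$nContacts
        ), auto_unbox = TRUE), jsonlCon)
      }
    }
    ns <- if (is.null(obs)) 0L else nrow(obs)
    rows[[si]] <- data.frame(
      Lx = ext[1], Ly = ext[2], Lz = ext[3], N = N, samples = ns,
      meanCorners = if (ns) mean(obs$nCorners) else NA_real_,
      sdCorners = if (ns > 1) stats::sd(obs$nCorners) else NA_real_,
      semCorners = if (ns > 1) stats::sd(obs$nCorners) / sqrt(ns) else NA_real_,
      meanRings = if (ns) mean(obs$nRings) else NA_real_,
      sdRings = if (ns > 1) stats::sd(obs$nRings) else NA_real_,
      meanContacts = if (ns) mean(obs$nContacts) else NA_real_,
      meanRingLength = if (ns) mean(obs$meanRingLength) else NA_real_,
      pUnlink = pU, pUnlinkLower = pLo, pUnlinkUpper = pHi,
      excludedSingleRing = nEx)
  }
  list(summary = do.call(rbind, rows), observables = obsList,
       reports = repList, hash = hash, seed = config$seed)
}

#' Power-law fit
#'
#' Least-squares fit of `log(value) ~ log(size)`, giving
#' `value ~ prefactor * size^exponent`.
#'
#' @param sizes,values positive numeric vectors (>= 3 points).
#' @return List with `exponent`, `prefactor`, `se` (standard error of the
#'   exponent), `residuals`.
#' @examples
#' fitPowerLaw(c(10, 20, 40), 2 * c(10, 20, 40)^0.5)$exponent  # 0.5
#' @export
fitPowerLaw <- function(sizes, values) {
  if (length(sizes) < 3L || length(sizes) != length(values))
    stop("need >= 3 matched points")
  if (any(sizes <= 0) || any(values <= 0))
    stop("power-law fit requires strictly positive sizes and values")
  fit <- lm(log(values) ~ log(sizes))
  s <- summary(fit)$coefficients
  list(exponent = unname(coef(fit)[2]),
       prefactor = exp(unname(coef(fit)[1])),
       se = unname(s[2, 2]),
       residuals = unname(residuals(fit)))
}

#' Exponential-decay fit
#'
#' Fits `p ~ exp(-N / N0)` by least squares of `log(p)` against `N` and
#' reports the e-folding scale `N0`.  Zero probabilities cannot enter the
#' log fit and are excluded with a warning; a constant `p = 1` series is
#' flagged as non-decaying with `N0 = Inf`.
#'
#' @param sizes numeric system sizes.
#' @param probabilities values in (0, 1].
#' @return List with `N0`, `se` (delta-method standard error), `slope`,
#'   `nonDecaying`.
#' @export
fitExponentialDecay <- function(sizes, probabilities) {
  if (length(sizes) != length(probabilities)) stop("length mismatch")
  drop <- probabilities <= 0
  if (any(drop)) {
    warning(sprintf("excluding %d zero/negative probability point(s) from the log fit",
                    sum(drop)))
    sizes <- sizes[drop == FALSE]; probabilities <- probabilities[!drop]
  }
  if (length(sizes) < 3L) stop("need >= 3 usable points")
  if (any(probabilities > 1)) stop("probabilities must lie in (0, 1]")
  y <- log(probabilities)
  if (all(y == 0))
    return(list(N0 = Inf, se = NA_real_, slope = 0, nonDecaying = TRUE))
  fit <- lm(y ~ sizes)
  slope <- unname(coef(fit)[2])
  seSlope <- summary(fit)$coefficients[2, 2]
  if (slope >= 0)
    return(list(N0 = Inf, se = NA_real_, slope = slope, nonDecaying = TRUE))
  list(N0 = -1 / slope, se = seSlope / slope^2, slope = slope,
       nonDecaying = FALSE)
}

#' Distance from a mean in standard deviations
#'
#' @param value observed value.
#' @param mean,sd ensemble mean and standard deviation (`sd > 0`).
#' @return Signed `(value - mean) / sd`.
#' @examples
#' sigmaDistance(100, 77.5, 4.3)  # ~ 5.2: maximal curvature vs the mode
#' @export
sigmaDistance <- function(value, mean, sd) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be strictly positive")
  (value - mean) / sd
}

#' Target a jointly constrained rare state
#'
#' Finds a zero-energy state of the doubly constrained Hamiltonian (fixed
#' total curvature and fixed contact count).  Such states can sit many
#' standard deviations from the equilibrium mode and their ground manifold
#' is tiny, so plain restarting is slow; each round of the search therefore
#' combines two complementary routes:
#'
#' 1. a direct annealing run of the joint model with a slow linear ramp
#'    through the freezing window (the only regime where these glassy
#'    instances equilibrate), and
#' 2. rejection sampling through the curvature-only model: curvature hits
#'    are much cheaper and a fraction of them already meets the contact
#'    target, in which case the re-encoded assignment has joint energy 0.
#'
#' Both routes return only assignments whose joint energy is exactly zero,
#' verified; the search strategy changes the path, never the target set.
#' Expect minutes of runtime on the 4x4x3 reference instance; the round
#' budget caps the worst case.
#'
#' @param spec a [LatticeSpec-class].
#' @param N monomer count.
#' @param nCorners,nContacts the joint targets.
#' @param coeffs [ringCoefficients()].
#' @param maxRounds number of search rounds before giving up.
#' @param directSweeps sweeps of the direct joint anneal per round.
#' @param seed master seed.
#' @return List with `assignment`, `model` (the joint [QuboModel-class]),
#'   `configuration`, and `rounds` used, or `NULL` if the budget is
#'   exhausted (with a warning).
#' @export
targetJointRareState <- function(spec, N, nCorners, nContacts,
                                 coeffs = ringCoefficients(),
                                 maxRounds = 12L, directSweeps = 2000000L,
                                 seed = 1L) {
  m1 <- addCurvatureConstraint(
    buildAssemblyHamiltonian(spec, N, coeffs = coeffs), nCorners,
    A_curv = coeffs[["A_curv"]])
  mj <- addContactsConstraint(
    addCurvatureConstraint(buildAssemblyHamiltonian(spec, N, coeffs = coeffs),
                           nCorners, A_curv = coeffs[["A_curv"]]),
    nContacts, coeffs = coeffs)
  slow <- annealSchedule(sweeps = directSweeps, betaStart = 3, betaEnd = 9,
                         restarts = 1L, order = "cyclic")
  stage1 <- annealSchedule(sweeps = 200000L, betaStart = 3, betaEnd = 9)
  found <- function(x, rounds)
    list(assignment = x, model = mj,
         configuration = decodeAssignment(x, mj), rounds = rounds)
  for (round in seq_len(maxRounds)) {
    ## route 1: direct slow-ramp anneal of the joint model
    slow$seed <- as.integer((seed * 1009 + round * 7717) %% .Machine$integer.max)
    direct <- simulatedAnneal(mj, slow, initProb = densityInitProb(mj))
    if (direct@hit) return(found(direct@assignment, round))
    ## route 2: curvature-stage rejection
    stage1$seed <- as.integer((seed * 131 + round * 101) %% .Machine$integer.max)
    hit <- tryCatch(
      suppressWarnings(sampleGroundStates(m1, stage1, nSamples = 1L,
                                          maxAttempts = 6L)),
      error = function(e) list())
    if (length(hit) == 0L) next
    x0 <- encodeConfiguration(decodeAssignment(hit[[1]], m1), mj)
    if (quboEnergy(mj, x0) == 0) return(found(x0, round))
  }
  warning("round budget exhausted without reaching the joint target")
  NULL
}
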
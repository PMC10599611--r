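test_that("initial full packings are valid degree-2 coverings", {
  for (ext in list(c(2, 2, 2), c(5, 5, 4), c(4, 4, 3), c(2, 2, 1))) {
    cfg <- initialFullPacking(buildLattice(ext[1], ext[2], ext[3]))
    expect_equal(length(cfg@occupied), prod(ext))  # complete filling
    expect_equal(length(cfg@activeEdges), prod(ext))
  }
  expect_error(initialFullPacking(buildLattice(3, 3, 3)), "odd")
})

test_that("plaquette flip merges opposite-face squares into one ring at zero cost", {
  spec <- spec222()
  tf <- twoFacePacking(3)
  faces <- latticeFaces(spec)
  done <- FALSE
  for (f in seq_len(nrow(faces$edges))) {
    r <- plaquetteFlip(spec, tf@activeEdges, f, beta = Inf)
    if (r$null) next
    expect_true(r$accepted)
    expect_equal(r$dCorners, 0L)  # 8 corners before and after
    merged <- ringConfigurationFromEdges(spec, r$activeEdges)
    expect_length(merged@rings, 1)
    expect_length(merged@rings[[1]], 8)
    done <- TRUE
    break
  }
  expect_true(done)
  ## face with a non-opposite occupied pattern is a null proposal
  one <- ringConfigurationFromEdges(spec, catalog222()@configurations[[
    which(vapply(catalog222()@configurations,
                 function(cf) length(cf@rings), integer(1)) == 1)[1]
  ]]@activeEdges)
  nulls <- 0L
  for (f in seq_len(nrow(faces$edges))) {
    r <- plaquetteFlip(spec, one@activeEdges, f, beta = Inf)
    if (r$null) nulls <- nulls + 1L
    else expect_true(all(tabulate(c(latticeEdges(spec)[r$activeEdges, ]),
                                  nbins = 8) == 2L))
  }
  expect_gt(nulls, 0L)
})

test_that("full packing survives a long random-move stress run", {
  spec <- buildLattice(4, 4, 3)
  init <- initialFullPacking(spec)
  x0 <- integer(edgeCount(spec))
  x0[init@activeEdges] <- 1L
  res <- ringmelt:::.rm_plaquette_stress(ringmelt:::mcGeometry(spec), x0,
                                         beta = 0.5, n_attempts = 1e6,
                                         seed = 3)
  expect_true(res$degree_ok)
  cfg <- ringConfigurationFromEdges(spec, which(res$x == 1L))
  expect_equal(computeObservables(cfg)$nCorners, res$energy)
})

test_that("a free single replica visits both ring-number sectors on the cube", {
  run <- replicaExchangeRun(spec222(), 0, sweeps = 3000, recordInterval = 10,
                            seed = 3)
  nr <- vapply(run$configurations, function(cf) length(cf@rings), integer(1))
  expect_setequal(sort(unique(nr)), c(1L, 2L))
})

test_that("fixed-temperature chain is uniform over the 9-state catalog", {
  ## all nine 2x2x2 packings have n_corners = 8, so the Boltzmann weights
  ## are equal at any beta and the chain must visit them uniformly
  keys <- vapply(catalog222()@configurations, configurationKey, character(1))
  run <- replicaExchangeRun(spec222(), 1.0, sweeps = 30000,
                            recordInterval = 3, seed = 9)
  expect_true(all(run$energies == 8))
  ks <- vapply(run$configurations, configurationKey, character(1))
  counts <- as.vector(table(factor(ks, levels = keys)))
  expect_gt(uniformityTest(counts)$pValue, 0.01)
})

test_that("cold replicas keep energy non-increasing under zero-temperature moves", {
  run <- replicaExchangeRun(buildLattice(4, 4, 2), 1e6, sweeps = 300, seed = 5)
  expect_true(all(diff(run$energies) <= 0))
})

test_that("autocorrelation time matches closed forms", {
  set.seed(31)
  expect_lt(abs(integratedAutocorrelationTime(rnorm(1e5)) - 0.5), 0.1)
  rho <- 0.9
  x <- as.numeric(arima.sim(list(ar = rho), 1e5))
  tau <- integratedAutocorrelationTime(x)
  expect_lt(abs(tau - 9.5) / 9.5, 0.2)
  ## duplicating every sample doubles the time scale
  y <- rep(as.numeric(arima.sim(list(ar = 0.5), 5e4)), each = 2)
  t1 <- integratedAutocorrelationTime(y)
  t0 <- integratedAutocorrelationTime(y[seq(1, length(y), by = 2)])
  expect_lt(abs(t1 / t0 - 2), 0.5)
  expect_warning(integratedAutocorrelationTime(rep(1, 200)), "constant")
  expect_error(integratedAutocorrelationTime(rnorm(50)), "too short")
})

test_that("replica exchange matches constrained QUBO minimum on small cuboids", {
  ## 2x2x2: every packing has 8 corners, so both methods must report 8
  run <- replicaExchangeRun(spec222(), c(0.5, 1, 2), sweeps = 500, seed = 7)
  expect_equal(min(run$energies), 8)
  m8 <- addCurvatureConstraint(model222full(), 8)
  expect_true(simulatedAnneal(m8, annealSchedule(sweeps = 500, seed = 7))@hit)
})
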
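test_that("trivial and tiny models are solved exactly", {
  ## single variable with positive linear coefficient -> 0 at x = 0
  reg <- data.frame(kind = "SITE", ref = 1L, i = 1L, j = NA_integer_,
                    k = NA_integer_, stringsAsFactors = FALSE)
  m1 <- new("QuboModel", lattice = NULL, registry = reg, linear = 2,
            Q = NULL, offset = 0, groups = list(),
            meta = list(N = NA_integer_, fullFilling = FALSE,
                        nCorners = NA_integer_, nContacts = NA_integer_,
                        coeffs = ringCoefficients()))
  r1 <- simulatedAnneal(m1, annealSchedule(sweeps = 50, seed = 2))
  expect_identical(r1@energy, 0)
  expect_identical(r1@assignment, 0L)

  ## 2x2x1 at N = 4: the unique square
  r <- simulatedAnneal(model221(), annealSchedule(sweeps = 300, seed = 3))
  expect_true(r@hit)
  cfg <- decodeAssignment(r@assignment, model221())
  expect_identical(cfg@rings, squareRingConfig()@rings)
})

test_that("reported energies equal full recomputation (incremental updates exact)", {
  spec <- buildLattice(3, 2, 2)
  m <- addCurvatureConstraint(buildAssemblyHamiltonian(spec, 8), 6)
  for (seed in 1:5) {
    ## short, hot run so the best state is a generic non-ground assignment
    r <- simulatedAnneal(m, annealSchedule(sweeps = 5, betaStart = 0.2,
                                           betaEnd = 0.5, restarts = 1,
                                           seed = seed))
    expect_identical(r@energy, quboEnergy(m, r@assignment))
  }
})

test_that("identical model, schedule, and seed reproduce identical output", {
  m <- model222full()
  sch <- annealSchedule(sweeps = 400, seed = 99)
  a <- simulatedAnneal(m, sch)
  b <- simulatedAnneal(m, sch)
  expect_identical(a@assignment, b@assignment)
  expect_identical(a@restartEnergies, b@restartEnergies)
  h1 <- sampleGroundStates(m, sch, nSamples = 20)
  h2 <- sampleGroundStates(m, sch, nSamples = 20)
  expect_identical(h1[], h2[])
})

test_that("sampled ground states all have exactly the target energy", {
  m <- model222full()
  hits <- sampleGroundStates(m, annealSchedule(sweeps = 300, seed = 17),
                             nSamples = 50)
  expect_length(hits, 50)
  for (x in hits) expect_identical(quboEnergy(m, x), 0)
  expect_error(sampleGroundStates(m, annealSchedule(), nSamples = 0), ">= 1")
})

test_that("infeasible constrained model yields no hits and a shortfall warning", {
  m0 <- addCurvatureConstraint(model221(), 0)  # the square needs 4 corners
  expect_warning(
    hits <- sampleGroundStates(m0, annealSchedule(sweeps = 300, seed = 5),
                               nSamples = 3, maxAttempts = 30),
    "budget exhausted")
  expect_length(hits, 0)
})

test_that("hit-rate curve is monotone-ish and exposes tauHalf and tOpt", {
  ## trivial model: hit fraction 1 everywhere
  m1 <- model221()
  hr <- hitRateCurve(m1, sweepGrid = c(200, 400, 800), trialsPerPoint = 10,
                     seed = 8)
  expect_true(all(hr$hitFraction == 1))
  expect_equal(attr(hr, "tauHalf"), 200)
  expect_equal(attr(hr, "tOpt"), 200)

  m <- model222full()
  hr2 <- hitRateCurve(m, sweepGrid = c(10, 40, 150, 600), trialsPerPoint = 40,
                      seed = 12)
  ## non-decreasing within estimation error (allow small fluctuation)
  expect_true(all(diff(hr2$hitFraction) > -0.18))
  expect_true(is.finite(attr(hr2, "tauHalf")))
  expect_gt(attr(hr2, "tauHalf"), 0)
})

test_that("warm starts reach the target from a nearby basin", {
  spec <- spec222()
  m <- model222full()
  cfg <- twoFacePacking(3)
  x0 <- encodeConfiguration(cfg, m)
  r <- simulatedAnneal(m, annealSchedule(sweeps = 50, betaStart = 6,
                                         betaEnd = 9, restarts = 1, seed = 4),
                       init = x0)
  expect_true(r@hit)
})
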
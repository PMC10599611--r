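test_that("reference linking values: coplanar squares, Hopf pair, far pair", {
  sqA <- rectangleRingCoords(1, 1, c(0, 0, 0))
  sqB <- rectangleRingCoords(1, 1, c(3, 0, 0))
  expect_identical(gaussLinkingNumber(sqA, sqB), 0L)

  h <- hopfLinkPair()
  expect_equal(abs(gaussLinkingNumber(h$A, h$B)), 1L)
  far <- h$B
  far[, 2] <- far[, 2] + 10
  expect_identical(gaussLinkingNumber(h$A, far), 0L)

  expect_error(gaussLinkingNumber(h$A, h$A), "share a vertex")
})

test_that("projection and Gauss-sum methods agree on fixtures and random pairs", {
  h <- hopfLinkPair()
  expect_identical(gaussLinkingNumber(h$A, h$B, method = "gauss"),
                   gaussLinkingNumber(h$A, h$B, method = "projection"))
  ## random non-intersecting ring pairs from sampled full packings
  set.seed(5)
  checked <- 0L
  for (seed in 1:40) {
    cfg <- randomFullPacking(buildLattice(3, 3, 2), seed = seed)
    if (length(cfg@rings) < 2) next
    pick <- sample(length(cfg@rings), 2)
    A <- ringCoordinates(cfg, pick[1]); B <- ringCoordinates(cfg, pick[2])
    expect_identical(gaussLinkingNumber(A, B, method = "gauss"),
                     gaussLinkingNumber(A, B, method = "projection"))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("Gauss double sum is near-integer for disjoint lattice rings", {
  h <- hopfLinkPair()
  raw <- ringmelt:::.rm_gauss_linking(h$A, h$B)
  expect_lt(abs(raw - round(raw)), 1e-6)
  sqA <- rectangleRingCoords(2, 3, c(0, 0, 0), plane = "xz")
  sqB <- rectangleRingCoords(1, 2, c(0, 2, 5), plane = "yz")
  raw2 <- ringmelt:::.rm_gauss_linking(sqA, sqB)
  expect_lt(abs(raw2 - round(raw2)), 1e-6)
})

test_that("Lk is invariant under rigid motion, flips sign under reversal, symmetric", {
  h <- hopfLinkPair()
  lk <- gaussLinkingNumber(h$A, h$B)
  ## joint translation
  t <- c(5, -2, 7)
  At <- sweep(h$A, 2, t, "+"); Bt <- sweep(h$B, 2, t, "+")
  expect_identical(gaussLinkingNumber(At, Bt), lk)
  ## joint rotation (90 degrees about z)
  rot <- function(M) cbind(-M[, 2], M[, 1], M[, 3])
  expect_identical(gaussLinkingNumber(rot(h$A), rot(h$B)), lk)
  ## orientation reversal of one ring
  expect_identical(gaussLinkingNumber(h$A[nrow(h$A):1, ], h$B), -lk)
  ## symmetry of arguments
  expect_identical(gaussLinkingNumber(h$B, h$A), lk)
})

test_that("link reports classify melts and flag single rings", {
  ## single 8-ring on 2x2x2 is excluded from unlink statistics
  cat9 <- catalog222()
  nr <- vapply(cat9@configurations, function(cf) length(cf@rings), integer(1))
  single <- cat9@configurations[[which(nr == 1)[1]]]
  rep1 <- linkReport(single)
  expect_true(rep1@isSingleRing)
  ## two opposite-face squares: unlinked
  rep2 <- linkReport(twoFacePacking(3))
  expect_false(rep2@isSingleRing)
  expect_true(rep2@isUnlinked)
  expect_equal(rep2@lk[1, 2], 0L)
})

test_that("unlink probability counts non-excluded melts with a Wilson interval", {
  r_unlinked <- linkReport(twoFacePacking(3))
  cat9 <- catalog222()
  nr <- vapply(cat9@configurations, function(cf) length(cf@rings), integer(1))
  r_single <- linkReport(cat9@configurations[[which(nr == 1)[1]]])
  ## synthetic linked report
  r_linked <- r_unlinked
  r_linked@lk[1, 2] <- r_linked@lk[2, 1] <- 1L
  r_linked@isUnlinked <- FALSE

  expect_equal(unlinkProbability(list(r_unlinked, r_unlinked))$pUnlink, 1.0)
  expect_equal(unlinkProbability(list(r_linked, r_linked))$pUnlink, 0.0)
  mixed <- unlinkProbability(list(r_unlinked, r_unlinked, r_unlinked, r_linked,
                                  r_single))
  expect_equal(mixed$pUnlink, 0.75)
  expect_equal(mixed$n, 4L)
  expect_equal(mixed$nExcluded, 1L)
  expect_true(mixed$ci[["lower"]] < 0.75 && mixed$ci[["upper"]] > 0.75)
  expect_error(unlinkProbability(list(r_single)), "single rings")
})
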
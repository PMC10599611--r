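test_that("catalog counts match hand enumeration on tiny lattices", {
  expect_equal(catalogSize(catalog221()), 1L)
  expect_equal(catalogSize(catalog222()), 9L)
  expect_equal(catalogSize(enumerateValidConfigurations(spec221(), 2)), 0L)
  expect_error(enumerateValidConfigurations(buildLattice(3, 3, 3), 10),
               "more than 24 sites")
})

test_that("cube Hamiltonian-cycle count cross-checks by permutation brute force", {
  ## independent route: enumerate cyclic orders of the 8 cube vertices and
  ## count adjacency-respecting cycles (fix start, divide by direction)
  s <- spec222()
  adj <- matrix(FALSE, 8, 8)
  ed <- latticeEdges(s)
  adj[ed] <- TRUE
  adj[ed[, c(2, 1)]] <- TRUE
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  nham <- 0L
  for (p in perms(2:8)) {
    cyc <- c(1L, p)
    steps <- cbind(cyc, c(cyc[-1], cyc[1]))
    if (all(adj[steps])) nham <- nham + 1L
  }
  nham <- nham / 2L  # two traversal directions
  expect_equal(nham, 6L)
  ## catalog composition: 6 single 8-rings + 3 two-ring packings
  nr <- vapply(catalog222()@configurations,
               function(cf) length(cf@rings), integer(1))
  expect_equal(sum(nr == 1), 6L)
  expect_equal(sum(nr == 2), 3L)
})

test_that("zero-energy set of the QUBO equals the catalog (bijection)", {
  ## 2x2x1, N = 4: full enumeration over all 2^12 assignments
  m <- model221()
  zero <- list()
  for (mask in 0:(2^12 - 1)) {
    x <- as.integer(intToBits(mask))[1:12]
    if (quboEnergy(m, x) == 0) zero[[length(zero) + 1L]] <- x
  }
  expect_length(zero, 1L)
  expect_identical(configurationKey(decodeAssignment(zero[[1]], m)),
                   configurationKey(catalog221()@configurations[[1]]))

  ## 2x2x2 full filling: per-term nonnegativity forces corner ancillas to
  ## the AND of their edges, so edge subsets enumerate the zero set
  z <- fullFillingZeroEnergyCount(model222full())
  expect_equal(z$count, 9L)
  keysQ <- sort(vapply(z$assignments, function(x)
    configurationKey(decodeAssignment(x, model222full())), character(1)))
  keysC <- sort(vapply(catalog222()@configurations, configurationKey,
                       character(1)))
  expect_identical(keysQ, keysC)
})

test_that("curvature constraint filters the catalog exactly", {
  full <- catalog222()
  corners <- vapply(full@configurations,
                    function(cf) computeObservables(cf)$nCorners, integer(1))
  expect_true(all(corners == 8L))  # every 2x2x2 packing turns at all 8 sites
  fil <- enumerateValidConfigurations(spec222(), 8, nCorners = 8)
  expect_equal(catalogSize(fil), 9L)
  none <- enumerateValidConfigurations(spec222(), 8, nCorners = 6)
  expect_equal(catalogSize(none), 0L)

  ## partial filling with both constraints on 3x2x2
  s <- buildLattice(3, 2, 2)
  all8 <- enumerateValidConfigurations(s, 8)
  obs <- lapply(all8@configurations, computeObservables)
  nc <- vapply(obs, `[[`, integer(1), "nCorners")
  ct <- vapply(obs, `[[`, integer(1), "nContacts")
  pick <- nc == nc[1] & ct == ct[1]
  fil2 <- enumerateValidConfigurations(s, 8, nCorners = nc[1],
                                       nContacts = ct[1])
  expect_equal(catalogSize(fil2), sum(pick))
})

test_that("uniformity test behaves at its reference points", {
  perfect <- uniformityTest(rep(1000L, 9))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$pValue, 1)

  lumped <- uniformityTest(c(9000L, rep(0L, 8)))
  expect_lt(lumped$pValue, 1e-10)

  expect_error(uniformityTest(c(5L)), "at least 2")
  expect_error(uniformityTest(c(3L, 2L)), "total hits")
})
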
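test_that("variable registry matches lattice geometry", {
  m <- model221()
  expect_equal(variableCount(m), 12L)  # 4 sites + 4 edges + 4 corners
  expect_equal(table(variableRegistry(m)$kind)[["SITE"]], 4L)

  mf <- model222full()
  expect_equal(variableCount(mf), 36L)  # 12 edges + 24 corners, no sites
  expect_false("SITE" %in% variableRegistry(mf)$kind)

  expect_error(buildAssemblyHamiltonian(spec221(), 3), "even")
  expect_error(buildAssemblyHamiltonian(spec221(), 8), "site count")
  expect_error(buildAssemblyHamiltonian(spec222(), 6, fullFilling = TRUE),
               "full-filling")
  expect_error(ringCoefficients(A_m = 0), "strictly positive")
})

test_that("reference energies: valid square is 0, empty assignment is 2 A N^2", {
  m <- model221()
  x <- encodeConfiguration(squareRingConfig(), m)
  expect_identical(quboEnergy(m, x), 0)
  expect_identical(quboEnergy(m, rep(0L, 12L)), 32)  # A_m 16 + A_b 16
  ## corner ancilla off with both edges on costs A_bc
  xc <- x
  cv <- m@meta$cornerVar[1]
  xc[cv] <- 0L
  expect_identical(quboEnergy(m, xc) - quboEnergy(m, x), 1)
  expect_error(quboEnergy(m, rep(0L, 5L)), "length")
})

test_that("contact ancilla penalty terms reproduce the derived truth tables", {
  ## adjacency term 4A + 2 si sj - 3 (si + sj) A over all 8 combinations
  adj <- function(si, sj, A) 4 * A + 2 * si * sj - 3 * (si + sj) * A
  for (si in 0:1) for (sj in 0:1) for (A in 0:1) {
    v <- adj(si, sj, A)
    expect_gte(v, 0)
    expect_equal(v == 0, A == (si & sj))
  }
  expect_equal(adj(1, 1, 0), 2)
  expect_equal(adj(1, 0, 1), 1)
  expect_equal(adj(0, 0, 1), 4)
  ## indicator term 2B + A - bA + 2bB - 3AB
  ind <- function(b, A, B) 2 * B + A - b * A + 2 * b * B - 3 * A * B
  for (b in 0:1) for (A in 0:1) for (B in 0:1) {
    v <- ind(b, A, B)
    expect_gte(v, 0)
    expect_equal(v == 0, B == (A & !b))
  }
  expect_equal(ind(1, 1, 1), 1)
  expect_equal(ind(1, 0, 1), 4)
})

test_that("contact-constrained model zeroes exactly on matching configurations", {
  spec <- spec221()
  m <- buildAssemblyHamiltonian(spec, 4)
  m0 <- addContactsConstraint(m, 0)
  expect_equal(variableCount(m0), 12L + 2L * 4L)
  sq <- squareRingConfig()
  x <- encodeConfiguration(sq, m0)
  expect_identical(quboEnergy(m0, x), 0)  # the square has no contacts
  m1 <- addContactsConstraint(m, 1)
  x1 <- encodeConfiguration(sq, m1)
  expect_identical(quboEnergy(m1, x1), 1)  # off-target by one contact
  mfull <- model222full()
  expect_error(addContactsConstraint(mfull, 0), "complete filling")
})

test_that("every term is nonnegative on random assignments", {
  set.seed(7)
  spec <- buildLattice(3, 2, 2)
  ## isolate terms via one-hot coefficient scaling: with all terms
  ## individually nonnegative, scaling any single coefficient up by K can
  ## decrease no energy below the unscaled one
  base <- buildAssemblyHamiltonian(spec, 8)
  base <- addCurvatureConstraint(base, 4)
  base <- addContactsConstraint(base, 2)
  nv <- variableCount(base)
  names <- c("A_m", "A_b", "A_mb", "A_c", "A_bc", "A_curv",
             "A_cont0", "A_cont1", "A_cont2")
  boosted <- lapply(names, function(nm) {
    co <- as.list(ringCoefficients())
    co[[nm]] <- 7
    m <- buildAssemblyHamiltonian(spec, 8, coeffs = do.call(ringCoefficients, co))
    m <- addCurvatureConstraint(m, 4, A_curv = co$A_curv)
    addContactsConstraint(m, 2, coeffs = do.call(ringCoefficients, co))
  })
  for (rep in 1:400) {
    x <- randomAssignment(nv)
    e0 <- quboEnergy(base, x)
    expect_gte(e0, 0)
    for (m in boosted) expect_gte(quboEnergy(m, x), e0 - 1e-9)
  }
})

test_that("ground-state set is independent of the coefficient values", {
  spec <- spec222()
  mA <- model222full()
  mB <- buildAssemblyHamiltonian(spec, 8, fullFilling = TRUE,
    coeffs = ringCoefficients(A_b = 3, A_c = 0.5, A_bc = 2.25))
  zA <- fullFillingZeroEnergyCount(mA)
  zB <- fullFillingZeroEnergyCount(mB)
  expect_equal(zA$count, zB$count)
  expect_identical(zA$assignments, zB$assignments)
})

test_that("full-filling reduction matches the full model on all-occupied states", {
  spec <- spec222()
  mFull <- buildAssemblyHamiltonian(spec, 8)             # with site variables
  mRed <- model222full()
  sv <- mFull@meta$siteVar
  set.seed(11)
  for (rep in 1:50) {
    xr <- randomAssignment(variableCount(mRed))
    xf <- integer(variableCount(mFull))
    xf[sv] <- 1L
    xf[mFull@meta$edgeVar] <- xr[mRed@meta$edgeVar]
    xf[mFull@meta$cornerVar] <- xr[mRed@meta$cornerVar]
    expect_identical(quboEnergy(mFull, xf), quboEnergy(mRed, xr))
  }
})

test_that("curvature constraint filters ground states by corner count", {
  m4 <- addCurvatureConstraint(model221(), 4)
  x <- encodeConfiguration(squareRingConfig(), m4)
  expect_identical(quboEnergy(m4, x), 0)
  ## n_corners = 0 is infeasible on 2x2x1: minimum energy > 0 over all 2^12
  m0 <- addCurvatureConstraint(model221(), 0)
  emin <- Inf
  for (mask in 0:(2^12 - 1)) {
    xx <- as.integer(intToBits(mask))[1:12]
    emin <- min(emin, quboEnergy(m0, xx))
  }
  expect_gt(emin, 0)
  expect_error(addCurvatureConstraint(model221(), -1), "nonnegative")
  expect_error(addCurvatureConstraint(model221(), 5), "exceeds")
})

test_that("export and re-import preserve energies in both formats", {
  spec <- spec221()
  m <- addContactsConstraint(addCurvatureConstraint(
    buildAssemblyHamiltonian(spec, 4), 4), 0)
  set.seed(3)
  for (fmt in c("qubo-coordinate", "json")) {
    path <- tempfile(fileext = if (fmt == "json") ".json" else ".qubo")
    exportQubo(m, path, format = fmt)
    m2 <- readQubo(path, format = fmt)
    expect_equal(variableCount(m2), variableCount(m))
    for (rep in 1:100) {
      x <- randomAssignment(variableCount(m))
      expect_equal(quboEnergy(m2, x), quboEnergy(m, x))
    }
    unlink(path)
  }
})

test_that("declared variable count appears in the coordinate export", {
  path <- tempfile()
  exportQubo(model221(), path, format = "qubo-coordinate")
  pl <- grep("^p qubo", readLines(path), value = TRUE)
  expect_equal(as.integer(strsplit(pl, " ")[[1]][4]), 12L)
  unlink(path)
})

test_that("an empty model exports to a valid file with zero entries", {
  reg <- data.frame(kind = character(0), ref = integer(0), i = integer(0),
                    j = integer(0), k = integer(0))
  m0 <- new("QuboModel", lattice = NULL, registry = reg, linear = numeric(0),
            Q = NULL, offset = 0, groups = list(),
            meta = list(N = NA_integer_, fullFilling = FALSE,
                        nCorners = NA_integer_, nContacts = NA_integer_,
                        coeffs = ringCoefficients()))
  path <- tempfile()
  exportQubo(m0, path, format = "qubo-coordinate")
  pl <- grep("^p qubo", readLines(path), value = TRUE)
  expect_equal(as.integer(strsplit(pl, " ")[[1]][4:6]), c(0L, 0L, 0L))
  m0b <- readQubo(path, format = "qubo-coordinate")
  expect_equal(variableCount(m0b), 0L)
  unlink(path)
})
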
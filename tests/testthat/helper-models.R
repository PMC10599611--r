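# Shared fixtures and a memo cache so expensive sampling runs are reused
# across test blocks within one suite run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

spec221 <- function() memo("spec221", buildLattice(2, 2, 1))
spec222 <- function() memo("spec222", buildLattice(2, 2, 2))

model221 <- function() memo("model221",
  buildAssemblyHamiltonian(spec221(), 4))

model222full <- function() memo("model222full",
  buildAssemblyHamiltonian(spec222(), 8, fullFilling = TRUE))

catalog221 <- function() memo("catalog221",
  enumerateValidConfigurations(spec221(), 4))

catalog222 <- function() memo("catalog222",
  enumerateValidConfigurations(spec222(), 8))

# All 2^E edge-subset assignments of a full-filling model with corner
# ancillas forced to the AND of their edges (any zero-energy assignment must
# have that form because each penalty term is individually nonnegative).
fullFillingZeroEnergyCount <- function(model) {
  spec <- model@lattice
  E <- edgeCount(spec)
  stopifnot(E <= 14)
  ev <- model@meta$edgeVar
  cv <- model@meta$cornerVar
  ce <- spec@cornerEdges
  nzero <- 0L
  zeros <- list()
  for (mask in 0:(2^E - 1)) {
    eb <- as.integer(intToBits(mask))[seq_len(E)]
    x <- integer(variableCount(model))
    x[ev] <- eb
    x[cv] <- as.integer(eb[ce[, 1]] & eb[ce[, 2]])
    if (quboEnergy(model, x) == 0) {
      nzero <- nzero + 1L
      zeros[[nzero]] <- x
    }
  }
  list(count = nzero, assignments = zeros)
}

# random 0/1 assignment
randomAssignment <- function(nv) sample(0:1, nv, replace = TRUE)

# the 48 signed axis permutations of the cube point group, as functions on
# 0-based coordinates within given extents
cubeSymmetries <- function(extents) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    if (!all(extents[p] == extents)) next  # permutation must preserve extents
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      sgn <- c(sx, sy, sz)
      out[[length(out) + 1L]] <- local({
        p0 <- p; s0 <- sgn
        function(co) {
          v <- co[, p0, drop = FALSE]
          for (a in 1:3) if (s0[a] < 0) v[, a] <- extents[a] - 1L - v[, a]
          v
        }
      })
    }
  }
  out
}

# apply a coordinate transform to a configuration, returning a new one
transformConfiguration <- function(config, fn) {
  spec <- config@lattice
  co <- spec@coords[config@rings[[1]][1], , drop = FALSE] # touch to assert valid
  rings <- lapply(config@rings, function(r) {
    v <- fn(spec@coords[r, , drop = FALSE])
    siteIndex(spec, v[, 1], v[, 2], v[, 3])
  })
  ringConfigurationFromEdges(spec, ringsToEdgesHelper(spec, rings))
}

ringsToEdgesHelper <- function(spec, rings) {
  key <- paste(latticeEdges(spec)[, 1], latticeEdges(spec)[, 2], sep = "-")
  lookup <- stats::setNames(seq_len(edgeCount(spec)), key)
  out <- integer(0)
  for (r in rings) {
    a <- r; b <- c(r[-1], r[1])
    lo <- pmin(a, b); hi <- pmax(a, b)
    out <- c(out, unname(lookup[paste(lo, hi, sep = "-")]))
  }
  sort(unique(out))
}
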
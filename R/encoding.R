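#' Hamiltonian coefficients
#'
#' Strictly positive weights of the quadratic penalty terms.  Every term of
#' the assembly Hamiltonian and of the optional constraint terms is
#' individually nonnegative and vanishes exactly on valid configurations, so
#' the set of zero-energy ground states does not depend on the coefficient
#' values; they only shape the energy landscape and hence annealing
#' efficiency.
#'
#' @param A_m weight of the site-count term (total occupied sites = N).
#' @param A_b weight of the bond-count term (total active bonds = N).
#' @param A_mb weight of the bond-endpoint term (active bonds join occupied
#'   sites).
#' @param A_c weight of the corner-exclusion term (no two corner ancillas
#'   share a middle site).
#' @param A_bc weight of the corner-consistency term (corner ancilla = AND of
#'   its two edges).
#' @param A_curv weight of the curvature constraint (total corners = target).
#' @param A_cont0,A_cont1,A_cont2 weights of the three contact-constraint
#'   terms (contact count = target; contact-adjacency ancilla consistency;
#'   contact-indicator ancilla consistency).
#' @return Named numeric vector of class `ringCoefficients`.
#' @export
ringCoefficients <- function(A_m = 1, A_b = 1, A_mb = 1, A_c = 1, A_bc = 1,
                             A_curv = 1, A_cont0 = 1, A_cont1 = 1, A_cont2 = 1) {
  co <- c(A_m = A_m, A_b = A_b, A_mb = A_mb, A_c = A_c, A_bc = A_bc,
          A_curv = A_curv, A_cont0 = A_cont0, A_cont1 = A_cont1,
          A_cont2 = A_cont2)
  if (any(!is.finite(co)) || any(co <= 0))
    stop("all Hamiltonian coefficients must be strictly positive")
  class(co) <- "ringCoefficients"
  co
}

#' QUBO model of ring self-assembly
#'
#' A quadratic form over binary variables `x` in `{0,1}`:
#' `E(x) = offset + sum(linear * x) + sum_{i<j} Q[i,j] x_i x_j
#'        + sum_g A_g * (sum(x[members_g]) - target_g)^2`.
#'
#' The last sum holds "population constraint" terms (bond count, curvature
#' target, contact count) in compressed form: expanding such a term to
#' explicit pairwise couplings would create a complete graph over its member
#' variables, which both [quboMatrix()] and [exportQubo()] can materialise on
#' demand, while the annealer exploits the compressed form for O(1) move
#' evaluation.  The two representations define the identical energy
#' function.
#'
#' Variables are registered in a fixed order (sites, edges, corner ancillas,
#' then contact ancillas when the contact constraint is added); the registry
#' maps each variable to its lattice element.  For models built from the
#' assembly and constraint terms the minimum attainable energy of a feasible
#' constraint set is 0, and every zero-energy assignment encodes a valid
#' melt microstate.
#'
#' @slot lattice the originating [LatticeSpec-class] (or `NULL` for models
#'   re-read from a bare coefficient file).
#' @slot registry data.frame with columns `kind` (`"SITE"`, `"EDGE"`,
#'   `"CORNER"`, `"CONTACT_A"`, `"CONTACT_B"`), `ref` (index into the lattice
#'   site/edge/corner tables) and site columns `i`, `j`, `k` (NA where
#'   unused); row order is variable order.
#' @slot linear numeric vector of linear coefficients (generic part).
#' @slot Q sparse upper-triangular `dgCMatrix` of pairwise coefficients
#'   (generic part).
#' @slot offset numeric constant.
#' @slot groups list of `list(coef, target, vars)` population-constraint
#'   terms.
#' @slot meta list: `N`, `fullFilling`, targets `nCorners`/`nContacts` (NA if
#'   unconstrained), `coeffs`, and variable-index maps `siteVar`, `edgeVar`,
#'   `cornerVar`, `contactAVar`, `contactBVar`.
#' @seealso [buildAssemblyHamiltonian()], [quboEnergy()], [exportQubo()]
#' @export
setClass("QuboModel",
  representation(
    lattice = "ANY",
    registry = "data.frame",
    linear = "numeric",
    Q = "ANY",
    offset = "numeric",
    groups = "list",
    meta = "list"
  )
)

setValidity("QuboModel", function(object) {
  nv <- nrow(object@registry)
  if (length(object@linear) != nv) return("linear length != variable count")
  if (!is.null(object@Q)) {
    if (nrow(object@Q) != nv || ncol(object@Q) != nv)
      return("Q dimension != variable count")
  }
  for (g in object@groups) {
    if (any(g$vars < 1L | g$vars > nv)) return("group member out of range")
    if (g$coef <= 0) return("group coefficient must be positive")
  }
  TRUE
})

#' Number of QUBO variables
#' @param model a [QuboModel-class].
#' @return Integer count of registered binary variables.
#' @export
variableCount <- function(model) nrow(model@registry)

#' @describeIn variableCount the variable registry data.frame.
#' @export
variableRegistry <- function(model) model@registry

emptyRegistry <- function() {
  data.frame(kind = character(0), ref = integer(0),
             i = integer(0), j = integer(0), k = integer(0),
             stringsAsFactors = FALSE)
}

newSparseQ <- function(i, j, v, nv) {
  if (length(i) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nv, nv)))
  ## enforce upper triangle i < j; duplicates are summed
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  if (any(i == j)) stop("diagonal quadratic entry; fold into linear instead")
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(nv, nv))
}

#' Build the ring self-assembly Hamiltonian
#'
#' Constructs the QUBO whose zero-energy assignments are exactly the
#' encodings of melts of disjoint closed lattice rings occupying `N` sites
#' with `N` bonds.  The five penalty terms enforce: (1) occupied-site count
#' `= N`; (2) active-bond count `= N`; (3) every active bond joins two
#' occupied sites; (4) no two corner ancillas share a middle site (so no
#' site carries more than one turn, which together with (5) caps the site
#' degree at 2); (5) each corner ancilla equals the logical AND of its two
#' constituent edge variables.
#'
#' At complete filling (`fullFilling = TRUE`, requiring `N` equal to the
#' site count) all site variables are identically 1, so terms (1) and (3)
#' are constant zero and site variables are dropped from the registry
#' entirely, leaving only edge and corner-ancilla variables.
#'
#' @param spec a [LatticeSpec-class].
#' @param N even monomer count, `4 <= N <= siteCount(spec)`.
#' @param coeffs a [ringCoefficients()] vector.
#' @param fullFilling logical; drop site variables (requires `N == S`).
#' @return A [QuboModel-class] with target ground energy 0.
#' @examples
#' spec <- buildLattice(2, 2, 1)
#' m <- buildAssemblyHamiltonian(spec, N = 4)
#' variableCount(m)  # 12: 4 sites + 4 edges + 4 corners
#' @export
buildAssemblyHamiltonian <- function(spec, N, coeffs = ringCoefficients(),
                                     fullFilling = FALSE) {
  stopifnot(is(spec, "LatticeSpec"))
  S <- siteCount(spec); E <- edgeCount(spec); C <- cornerCount(spec)
  if (length(N) != 1L || is.na(N) || N != floor(N)) stop("N must be an integer")
  N <- as.integer(N)
  if (N %% 2L != 0L)
    stop("N must be even: the simple-cubic lattice is bipartite and admits only even cycles")
  if (N < 4L || N > S) stop("N must satisfy 4 <= N <= site count")
  if (fullFilling && N != S)
    stop("full-filling mode requires N equal to the site count")
  if (!inherits(coeffs, "ringCoefficients")) coeffs <- do.call(ringCoefficients, as.list(coeffs))

  siteVar <- rep(NA_integer_, S)
  nv <- 0L
  reg_kind <- character(0); reg_ref <- integer(0)
  reg_i <- integer(0); reg_j <- integer(0); reg_k <- integer(0)
  if (!fullFilling) {
    siteVar <- seq_len(S)
    nv <- S
    reg_kind <- rep("SITE", S); reg_ref <- seq_len(S)
    reg_i <- seq_len(S); reg_j <- rep(NA_integer_, S); reg_k <- rep(NA_integer_, S)
  }
  edgeVar <- nv + seq_len(E)
  reg_kind <- c(reg_kind, rep("EDGE", E)); reg_ref <- c(reg_ref, seq_len(E))
  reg_i <- c(reg_i, spec@edges[, 1]); reg_j <- c(reg_j, spec@edges[, 2])
  reg_k <- c(reg_k, rep(NA_integer_, E))
  nv <- nv + E
  cornerVar <- nv + seq_len(C)
  reg_kind <- c(reg_kind, rep("CORNER", C)); reg_ref <- c(reg_ref, seq_len(C))
  reg_i <- c(reg_i, spec@corners[, 1]); reg_j <- c(reg_j, spec@corners[, 2])
  reg_k <- c(reg_k, spec@corners[, 3])
  nv <- nv + C

  registry <- data.frame(kind = reg_kind, ref = reg_ref,
                         i = reg_i, j = reg_j, k = reg_k,
                         stringsAsFactors = FALSE)

  lin <- numeric(nv); offset <- 0
  qi <- integer(0); qj <- integer(0); qv <- numeric(0)
  groups <- list()

  ## (1) site count = N, as a population-constraint group
  if (!fullFilling)
    groups[[length(groups) + 1L]] <-
      list(coef = unname(coeffs["A_m"]), target = N, vars = siteVar)

  ## (2) bond count = N
  groups[[length(groups) + 1L]] <-
    list(coef = unname(coeffs["A_b"]), target = N, vars = edgeVar)

  ## (3) active bonds need occupied endpoints: A_mb * b_e * (2 - s_i - s_j)
  if (!fullFilling && E > 0L) {
    lin[edgeVar] <- lin[edgeVar] + 2 * coeffs["A_mb"]
    qi <- c(qi, edgeVar, edgeVar)
    qj <- c(qj, siteVar[spec@edges[, 1]], siteVar[spec@edges[, 2]])
    qv <- c(qv, rep(-coeffs[["A_mb"]], 2L * E))
  }

  ## (4) corner exclusion: A_c * c_t * c_u over unordered distinct pairs of
  ##     corner triplets sharing the middle site
  if (C > 0L) {
    mids <- spec@corners[, 2]
    by_mid <- split(seq_len(C), mids)
    for (grp in by_mid) {
      m <- length(grp)
      if (m < 2L) next
      pr <- utils::combn(grp, 2L)
      qi <- c(qi, cornerVar[pr[1, ]])
      qj <- c(qj, cornerVar[pr[2, ]])
      qv <- c(qv, rep(coeffs[["A_c"]], ncol(pr)))
    }
  }

  ## (5) corner ancilla = AND(edge1, edge2):
  ##     A_bc * (3 c + b1 b2 - 2 c (b1 + b2))
  if (C > 0L) {
    e1 <- edgeVar[spec@cornerEdges[, 1]]
    e2 <- edgeVar[spec@cornerEdges[, 2]]
    lin[cornerVar] <- lin[cornerVar] + 3 * coeffs["A_bc"]
    qi <- c(qi, e1, cornerVar, cornerVar)
    qj <- c(qj, e2, e1, e2)
    qv <- c(qv, rep(coeffs[["A_bc"]], C), rep(-2 * coeffs[["A_bc"]], 2L * C))
  }

  meta <- list(N = N, fullFilling = fullFilling,
               nCorners = NA_integer_, nContacts = NA_integer_,
               coeffs = coeffs,
               siteVar = siteVar, edgeVar = edgeVar, cornerVar = cornerVar,
               contactAVar = rep(NA_integer_, E),
               contactBVar = rep(NA_integer_, E))

  new("QuboModel", lattice = spec, registry = registry, linear = lin,
      Q = newSparseQ(qi, qj, qv, nv), offset = offset, groups = groups,
      meta = meta)
}

#' Constrain total curvature (number of corner turns)
#'
#' Adds the quadratic penalty `A_curv * (sum of corner ancillas - nCorners)^2`,
#' so that zero-energy states additionally carry exactly `nCorners` corner
#' turns.  No new binary variables are introduced.  An infeasible target is
#' accepted silently: feasibility is a hard combinatorial question, and it is
#' detected downstream by the minimum energy staying strictly positive.
#'
#' @param model a [QuboModel-class] built by [buildAssemblyHamiltonian()].
#' @param nCorners nonnegative integer target, at most the corner-triplet
#'   count.
#' @param A_curv positive weight.
#' @return The extended [QuboModel-class].
#' @export
addCurvatureConstraint <- function(model, nCorners,
                                   A_curv = model@meta$coeffs[["A_curv"]]) {
  stopifnot(is(model, "QuboModel"))
  if (length(nCorners) != 1L || is.na(nCorners) || nCorners < 0 ||
      nCorners != floor(nCorners))
    stop("nCorners target must be a nonnegative integer")
  cv <- model@meta$cornerVar
  if (nCorners > length(cv)) stop("nCorners target exceeds corner-triplet count")
  if (!is.finite(A_curv) || A_curv <= 0) stop("A_curv must be strictly positive")
  model@groups[[length(model@groups) + 1L]] <-
    list(coef = A_curv, target = as.integer(nCorners), vars = cv)
  model@meta$nCorners <- as.integer(nCorners)
  model
}

#' Constrain the number of contacts
#'
#' A contact is an adjacent pair of occupied sites not joined by a bond.
#' Two ancilla variables per lattice edge are registered: the adjacency
#' ancilla A with `A_ij = s_i AND s_j` and the contact indicator B with
#' `B_ij = A_ij AND NOT b_ij`, each enforced by an exact quadratic penalty
#' truth table; a third term pins `sum(B) = nContacts`.  At complete filling
#' contacts are the constant `E - N`, so the constraint is unsupported for
#' full-filling models.
#'
#' @param model a [QuboModel-class] not in full-filling mode.
#' @param nContacts nonnegative integer target.
#' @param coeffs a [ringCoefficients()] vector supplying `A_cont0`,
#'   `A_cont1`, `A_cont2`.
#' @return The extended [QuboModel-class] (with `2 * edgeCount` new
#'   variables).
#' @export
addContactsConstraint <- function(model, nContacts,
                                  coeffs = model@meta$coeffs) {
  stopifnot(is(model, "QuboModel"))
  if (isTRUE(model@meta$fullFilling))
    stop("contact constraint is unsupported at complete filling (contacts are constant there)")
  if (length(nContacts) != 1L || is.na(nContacts) || nContacts < 0 ||
      nContacts != floor(nContacts))
    stop("nContacts target must be a nonnegative integer")
  if (!inherits(coeffs, "ringCoefficients")) coeffs <- do.call(ringCoefficients, as.list(coeffs))
  spec <- model@lattice
  E <- edgeCount(spec)
  if (any(!is.na(model@meta$contactAVar)))
    stop("contact constraint already added")
  nv0 <- variableCount(model)
  aVar <- nv0 + seq_len(E)
  bVar <- nv0 + E + seq_len(E)

  regA <- data.frame(kind = rep("CONTACT_A", E), ref = seq_len(E),
                     i = spec@edges[, 1], j = spec@edges[, 2],
                     k = rep(NA_integer_, E), stringsAsFactors = FALSE)
  regB <- regA; regB$kind <- "CONTACT_B"
  model@registry <- rbind(model@registry, regA, regB)
  nv <- nv0 + 2L * E
  lin <- c(model@linear, numeric(2L * E))

  sv <- model@meta$siteVar
  ev <- model@meta$edgeVar
  si <- sv[spec@edges[, 1]]; sj <- sv[spec@edges[, 2]]

  qi <- integer(0); qj <- integer(0); qv <- numeric(0)
  ## adjacency ancilla: A1 * (4 A + 2 s_i s_j - 3 (s_i + s_j) A)
  A1 <- coeffs[["A_cont1"]]
  lin[aVar] <- lin[aVar] + 4 * A1
  qi <- c(qi, si, si, sj); qj <- c(qj, sj, aVar, aVar)
  qv <- c(qv, rep(2 * A1, E), rep(-3 * A1, 2L * E))
  ## contact indicator: A2 * (2 B + A - b A + 2 b B - 3 A B)
  A2 <- coeffs[["A_cont2"]]
  lin[bVar] <- lin[bVar] + 2 * A2
  lin[aVar] <- lin[aVar] + A2
  qi <- c(qi, ev, ev, aVar); qj <- c(qj, aVar, bVar, bVar)
  qv <- c(qv, rep(-A2, E), rep(2 * A2, E), rep(-3 * A2, E))

  Qnew <- newSparseQ(qi, qj, qv, nv)
  sm <- Matrix::summary(model@Q)
  Qpad <- Matrix::sparseMatrix(i = sm$i, j = sm$j, x = sm$x, dims = c(nv, nv))
  model@Q <- Qpad + Qnew
  model@linear <- lin
  ## contact count = target
  model@groups[[length(model@groups) + 1L]] <-
    list(coef = unname(coeffs["A_cont0"]), target = as.integer(nContacts),
         vars = bVar)
  model@meta$contactAVar <- aVar
  model@meta$contactBVar <- bVar
  model@meta$nContacts <- as.integer(nContacts)
  model
}

#' QUBO energy of a binary assignment
#'
#' Evaluates `offset + sum(linear x) + sum_{i<j} Q_ij x_i x_j` plus the
#' population-constraint terms.  With the default integer coefficients the
#' arithmetic is exact, so `quboEnergy(...) == 0` identifies ground states
#' without any floating-point tolerance.
#'
#' @param model a [QuboModel-class].
#' @param assignment 0/1 vector, one value per registered variable.
#' @return Nonnegative numeric energy (for models built from the assembly
#'   and constraint terms).
#' @export
quboEnergy <- function(model, assignment) {
  x <- as.numeric(assignment)
  if (length(x) != variableCount(model))
    stop(sprintf("assignment length %d != variable count %d",
                 length(x), variableCount(model)))
  if (any(is.na(x)) || any(x != 0 & x != 1)) stop("assignment must be 0/1")
  e <- model@offset + sum(model@linear * x)
  if (!is.null(model@Q) && length(model@Q@x))
    e <- e + sum(x * as.vector(model@Q %*% x))
  for (g in model@groups)
    e <- e + g$coef * (sum(x[g$vars]) - g$target)^2
  e
}

#' Fully expanded coefficient arrays
#'
#' Materialises the population-constraint groups into explicit linear terms,
#' pairwise couplings, and offset, returning the plain QUBO arrays
#' `E(x) = offset + sum(linear x) + sum_{i<j} Q_ij x_i x_j`.
#'
#' @param model a [QuboModel-class].
#' @return list with `linear` (numeric), `Q` (upper-triangular dgCMatrix),
#'   `offset` (numeric).
#' @export
quboMatrix <- function(model) {
  nv <- variableCount(model)
  lin <- model@linear
  offset <- model@offset
  Q <- model@Q
  if (is.null(Q))
    Q <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nv, nv))
  for (g in model@groups) {
    ## A (sum x - n)^2 = A n^2 + A(1-2n) sum x + 2A sum_{i<j in g} x_i x_j
    offset <- offset + g$coef * g$target^2
    lin[g$vars] <- lin[g$vars] + g$coef * (1 - 2 * g$target)
    if (length(g$vars) >= 2L) {
      pr <- utils::combn(g$vars, 2L)
      Q <- Q + Matrix::sparseMatrix(i = pr[1, ], j = pr[2, ],
                                    x = rep(2 * g$coef, ncol(pr)),
                                    dims = c(nv, nv))
    }
  }
  list(linear = lin, Q = methods::as(Matrix::drop0(Q), "generalMatrix"),
       offset = offset)
}

#' Write a QUBO model to disk
#'
#' Two plain-text formats are supported.
#'
#' `"qubo-coordinate"` is an upper-triangular coordinate list: comment lines
#' prefixed `c` (one of which records the constant offset as
#' `c offset <value>`), a problem line `p qubo 0 <nvars> <ndiag> <noffdiag>`,
#' then one line `i i value` per nonzero linear coefficient and `i j value`
#' (`i < j`, 0-based) per nonzero coupling.  Population-constraint groups
#' are expanded to explicit couplings, so the file is a plain QUBO.
#'
#' `"json"` dumps the registry descriptors, expanded coefficient arrays,
#' offset, and metadata (lattice extents, N, constraint targets); it
#' round-trips losslessly through [readQubo()].
#'
#' @param model a [QuboModel-class].
#' @param path output file path.
#' @param format `"qubo-coordinate"` or `"json"`.
#' @return `path`, invisibly.
#' @export
exportQubo <- function(model, path, format = c("qubo-coordinate", "json")) {
  format <- match.arg(format)
  xp <- quboMatrix(model)
  nv <- variableCount(model)
  sm <- Matrix::summary(xp$Q)
  keep <- sm$x != 0
  qi <- sm$i[keep]; qj <- sm$j[keep]; qx <- sm$x[keep]
  ldx <- which(xp$linear != 0)
  if (format == "qubo-coordinate") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("c ringmelt qubo coordinate export", con)
    writeLines(sprintf("c offset %.17g", xp$offset), con)
    writeLines(sprintf("p qubo 0 %d %d %d", nv, length(ldx), length(qi)), con)
    if (length(ldx))
      writeLines(sprintf("%d %d %.17g", ldx - 1L, ldx - 1L, xp$linear[ldx]), con)
    if (length(qi))
      writeLines(sprintf("%d %d %.17g", qi - 1L, qj - 1L, qx), con)
  } else {
    meta <- model@meta
    dump <- list(
      format = "ringmelt-qubo-json",
      extents = if (is.null(model@lattice)) NULL else model@lattice@extents,
      n_variables = nv,
      registry = model@registry,
      linear_index = ldx, linear_value = xp$linear[ldx],
      quad_i = qi, quad_j = qj, quad_value = qx,
      offset = xp$offset,
      meta = list(N = meta$N, fullFilling = meta$fullFilling,
                  nCorners = meta$nCorners, nContacts = meta$nContacts)
    )
    jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read a QUBO model written by [exportQubo()]
#'
#' Returns a [QuboModel-class] holding the explicit coefficient arrays (no
#' compressed groups).  For `"qubo-coordinate"` files the registry and
#' lattice are unavailable and left empty; energies are fully defined.
#'
#' @param path file path.
#' @param format `"qubo-coordinate"` or `"json"`.
#' @return A [QuboModel-class].
#' @export
readQubo <- function(path, format = c("qubo-coordinate", "json")) {
  format <- match.arg(format)
  if (format == "qubo-coordinate") {
    lines <- readLines(path)
    off <- 0
    offl <- grep("^c offset ", lines, value = TRUE)
    if (length(offl)) off <- as.numeric(sub("^c offset ", "", offl[1]))
    pl <- grep("^p qubo", lines, value = TRUE)
    if (!length(pl)) stop("missing problem line")
    nv <- as.integer(strsplit(trimws(pl[1]), "\\s+")[[1]][4])
    body <- lines[!grepl("^(c|p)", lines) & nzchar(trimws(lines))]
    lin <- numeric(nv)
    qi <- integer(0); qj <- integer(0); qv <- numeric(0)
    if (length(body)) {
      parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
      ii <- as.integer(parts[, 1]) + 1L
      jj <- as.integer(parts[, 2]) + 1L
      vv <- as.numeric(parts[, 3])
      diag <- ii == jj
      lin[ii[diag]] <- lin[ii[diag]] + vv[diag]
      qi <- ii[!diag]; qj <- jj[!diag]; qv <- vv[!diag]
    }
    reg <- data.frame(kind = rep("VAR", nv), ref = seq_len(nv),
                      i = rep(NA_integer_, nv), j = rep(NA_integer_, nv),
                      k = rep(NA_integer_, nv), stringsAsFactors = FALSE)
    new("QuboModel", lattice = NULL, registry = reg, linear = lin,
        Q = newSparseQ(qi, qj, qv, nv), offset = off, groups = list(),
        meta = list(N = NA_integer_, fullFilling = FALSE,
                    nCorners = NA_integer_, nContacts = NA_integer_,
                    coeffs = ringCoefficients()))
  } else {
    dump <- jsonlite::read_json(path, simplifyVector = TRUE)
    nv <- dump$n_variables
    lin <- numeric(nv)
    if (length(dump$linear_index))
      lin[dump$linear_index] <- dump$linear_value
    spec <- if (!is.null(dump$extents)) do.call(buildLattice, as.list(dump$extents)) else NULL
    reg <- as.data.frame(dump$registry, stringsAsFactors = FALSE)
    new("QuboModel", lattice = spec, registry = reg, linear = lin,
        Q = newSparseQ(as.integer(dump$quad_i), as.integer(dump$quad_j),
                       as.numeric(dump$quad_value), nv),
        offset = as.numeric(dump$offset), groups = list(),
        meta = list(N = dump$meta$N, fullFilling = isTRUE(dump$meta$fullFilling),
                    nCorners = dump$meta$nCorners, nContacts = dump$meta$nContacts,
                    coeffs = ringCoefficients()))
  }
}

#' @describeIn variableCount compact printout of a model.
#' @param object a [QuboModel-class].
#' @export
setMethod("show", "QuboModel", function(object) {
  m <- object@meta
  cat(sprintf("QuboModel: %d variables, %d couplings (+%d constraint groups)\n",
              variableCount(object),
              if (is.null(object@Q)) 0L else length(object@Q@x),
              length(object@groups)))
  if (!is.null(object@lattice)) {
    ext <- object@lattice@extents
    cat(sprintf("  lattice %dx%dx%d, N = %s, full filling: %s\n",
                ext[1], ext[2], ext[3], m$N, isTRUE(m$fullFilling)))
  }
  if (!is.na(m$nCorners)) cat(sprintf("  curvature target: %d corners\n", m$nCorners))
  if (!is.na(m$nContacts)) cat(sprintf("  contact target: %d contacts\n", m$nContacts))
  invisible(NULL)
})
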
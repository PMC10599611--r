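---
title: "Sampling self-assembled ring-polymer melts through a QUBO encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling self-assembled ring-polymer melts through a QUBO encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmelt)
```

## The model

`ringmelt` studies melts of self-assembled ring polymers on cuboid patches
of the simple-cubic lattice with open boundaries.  A melt microstate is a
set of mutually avoiding closed lattice walks (rings) occupying `N` sites
with `N` bonds; "complete filling" means every lattice site is occupied.
Unlike conventional polymer Monte Carlo, chain number and lengths are not
fixed: any partition of the `N` monomers into disjoint rings is admissible,
as in supramolecular self-assembly of limited-valence particles.

Rather than moving monomers in real space, the package encodes the whole
configuration space into binary variables:

* a site variable per lattice site (occupied / empty),
* a bond variable per nearest-neighbour edge (bonded / not),
* a corner ancilla per pair of perpendicular edges sharing a middle site.

The assembly energy is a sum of five quadratic penalties, each nonnegative
and zero exactly on valid states: the occupied-site count and the bond
count are pinned to `N` by squared-sum terms; each active bond must join
two occupied sites; no two corner ancillas may share a middle site; and
each corner ancilla must equal the logical AND of its two edges.  The last
two terms jointly cap every site's bond degree at two, so zero-energy
assignments are exactly the valid melts — the ground-state manifold *is*
the configuration space, and sampling becomes repeated minimisation.
Straight-through (collinear) triplets carry no ancilla: a straight
degree-2 site is not a corner, and dropping those variables shrinks the
model.

At complete filling all site variables are identically one, so the
site-count and bond-endpoint terms are constants and the site variables are
dropped altogether; only edge and corner variables remain.

Two physical constraints can be imposed as additional quadratic penalties:

* **curvature**: `(sum of corner ancillas - nCorners)^2` pins the total
  number of corner turns, the melt's discrete total curvature (inversely
  related to effective chain stiffness); no new variables are needed;
* **contacts**: two ancillas per edge (adjacency `A = s_i AND s_j`, and the
  contact indicator `B = A AND NOT bond`) are forced by exact penalty truth
  tables, and `(sum B - nContacts)^2` pins the number of occupied,
  non-bonded neighbour pairs, a compactness measure.

Coefficient choice affects only the shape of the energy landscape, never
the zero set: every term is individually nonnegative, so for any strictly
positive coefficients the ground states coincide.  The package defaults to
all coefficients equal to 1, which keeps every energy an exact integer in
double arithmetic — ground-state identification (`energy == 0`) then
involves no floating-point tolerance at all.

## Representation of the quadratic form

`QuboModel` stores generic pairwise couplings sparsely and keeps the
squared-sum ("population") terms in compressed form `(A, target, members)`.
Expanding such a term would create a complete coupling graph over its
members (tens of thousands of pairs for the bond-count term at N = 216),
while the compressed form lets the annealer evaluate a single-variable flip
in O(1) through the running member sum.  `quboMatrix()` and `exportQubo()`
materialise the explicit arrays on demand; both representations define the
identical energy function, which the export/re-import tests verify on
random assignments.

## Simulated annealing

The solver is single-variable-flip Metropolis dynamics over a ladder of
inverse temperatures, with independent restarts and exact incremental
energy bookkeeping.  Three design points deserve explanation.

**Update order.**  Within a sweep the variables are visited in a fresh
random permutation (default).  We also implement the classic fixed cyclic
order with a random per-sweep offset, and found it measurably biases
*which* ground states a quench reaches: on the 5×5×4 melt at complete
filling, cyclic sweeps yield a mean corner count of about 76.1–76.7
depending on the schedule, while the exact uniform value — computable
independently by the plaquette-flip sampler at infinite temperature — is
78.25.  Shuffled sweeps reproduce 78.0 ± 0.8 at identical cost, so they
are the default; the cyclic order remains available for pure optimisation
runs.

**Schedule.**  The default ladder is linear from beta 3 to beta 9 over
`max(1000, 50 * nVariables)` sweeps.  With unit coefficients the relevant
barriers are small integers, and this window walks the acceptance
probability of a unit uphill move from ~5% down to ~10^-4^; sweeps spent at
hotter temperatures do not help minimisation.  Two regimes warrant
different settings:

* *Uniformity-critical sampling on tiny lattices.*  On the 2×2×2 cube the
  nine ground states are few enough that a chi-square test over ~10^4^
  hits detects percent-level coverage bias.  Cold-start ladders fail that
  test regardless of update order; a hot-start geometric ladder
  (beta 0.1 → 10, 1000 sweeps) passes it across seeds and is what the
  package uses whenever uniform coverage is asserted.  At larger sizes a
  hot start is unaffordable and, by the 5×5×4 cross-check above,
  unnecessary: the shuffled-order quench shows no detectable bias there.
* *Hard constrained targets.*  Rare-state models (fixed extremal curvature
  and/or contacts) freeze glassily; what helps is cooling *slowly through
  the freezing window* (linear 3 → 9 over 2×10^5^–2×10^6^ sweeps), not
  restarting more often.

**Exactness.**  Energies are accumulated incrementally; with integer
coefficients the running energy is exact, and the suite verifies that the
reported best energy always equals a from-scratch recomputation.

The annealer is deterministic given (model, schedule, seed).  Any object
that maps a model to assignments can substitute for it (an external or
hybrid solver adapter); the campaign layer accepts such adapters.

## Decoding and observables

A zero-energy assignment is decoded by marking active edges and tracing the
degree-2 adjacency into cycles.  The decoder re-derives corner and contact
ancillas from the site/edge variables and errors on any mismatch, so solver
artifacts cannot leak into observables.  Rings are canonicalised
(lexicographically minimal rotation/reflection, ring list sorted), making
configuration identity a plain string comparison.  Observables: ring count,
ring lengths, corner count (site with perpendicular bonds), contact count
(occupied adjacent non-bonded pair).  At complete filling contacts equal
`E - N` identically, a decoder invariant the tests exploit.

## Exhaustive oracle

For lattices of at most 24 sites, a backtracking search over edge subsets
(degree pruning, bond-count bounds) enumerates *every* valid configuration
independently of the QUBO machinery.  The 2×2×1 lattice has a single valid
state at N = 4; the 2×2×2 cube at complete filling has exactly 9 (six
Hamiltonian cycles, verified against a separate permutation-based count,
plus three stacked-face pairs).  The suite proves the QUBO zero-energy set
equals this catalog element-by-element, which is the encoding's central
correctness claim, and the catalog underpins the chi-square uniformity
tests.  The 24-site guard is a hard refusal: beyond it the search cost is
exponential and silent truncation would corrupt the reference.

## Topological analysis

Inter-ring entanglement is quantified by the Gaussian linking number of
each ring pair, computed by two independent routes that are cross-checked
on every call in `method = "both"` mode:

* the discrete Gauss double sum — each segment pair contributes the signed
  solid angle of its endpoint quadrilateral in closed form; for disjoint
  closed polygons the total is an integer up to ~10^-10^;
* signed crossings in a generic projection — the projection axis is tilted
  from the z axis by the fixed irrational vector `(pi, e) * 1e-4`, which
  breaks all axis-aligned degeneracies deterministically: no two distinct
  lattice segments project onto one line and no crossing hits a vertex.

A melt is "unlinked" when every pair has `Lk = 0`; single-ring melts
(Hamiltonian cycles) have no pairs and are excluded from unlinking
statistics.  Wilson 95% intervals accompany every unlinking probability.
`Lk = 0` does not rule out higher-order (Brunnian-style) entanglement;
detecting it is out of scope.

## Real-space baseline

The plaquette-flip sampler works directly on fully packed bond
configurations: a unit lattice face with exactly two opposite occupied
edges may swap them for its two empty edges.  The move preserves the
degree-2 invariant exactly, merges or splits rings, and changes the corner
count; the implemented rule is our reconstruction of the move class from
its stated properties (bond count preserved; connectivity, ring number and
curvature fluctuate; ergodic only at complete filling).  The energy is the
total corner count, sampled by Metropolis at fixed beta or by replica
exchange over a beta ladder (swap probability
`min(1, exp((beta2 - beta1) (E2 - E1)))`, adjacent pairs, alternating
parity).  At beta = 0 every legal proposal is accepted and the chain
samples full packings uniformly — this is the exact reference distribution
used to audit the annealer, and it doubles as a fast sampler for
unconstrained complete-filling ensembles in campaigns.  Detailed balance
is validated on the 2×2×2 catalog, where all nine packings share one
energy, so the chain must visit them uniformly — a sharp test.  Integrated
autocorrelation times use Sokal's automatic windowing
(`tau = 1/2 + sum rho(t)`, window `W >= 5 tau(W)`); exchanges are proposed
every sweep, far below any autocorrelation time encountered, and a warning
fires if that margin is violated.

Initial packings are built deterministically: 2×2 square columns when both
in-plane extents are even, otherwise a serpentine closed tour layer by
layer; a lattice with all extents odd admits no full packing by even
cycles and is refused.

## Campaigns, fits, and problem sizes

`runCampaign()` orchestrates sampling over lattice-size lists with either
sampler or an external adapter, aggregates observables, and (optionally)
linking statistics; every output line carries the config hash and seed, and
re-running a config byte-reproduces the JSONL stream.  Power laws are
fitted by least squares in log–log coordinates, unlinking decay by a log
fit yielding the e-folding scale `N0` (zero probabilities are excluded with
a warning; non-decaying series are flagged).

Two size-scaling facts anchor the campaign analyses.  Ring lengths sum
exactly to `N` in every sample, so the fitted exponents of the mean ring
count and mean ring length must sum to ~1; and the total curvature is
bounded by `N` and measured extensive (exponent ~1.0 across N = 48-100,
with the per-site corner fraction near 0.78).  Ring count and ring length
split the remaining scaling at roughly `N^0.5` and `N^0.4` over the sampled
range.  Any assignment of a strongly sublinear exponent to the *curvature*
is inconsistent with both constraints, which is worth keeping in mind when
comparing exponent conventions across studies.

The package's own studies use desk-scale ensembles: hundreds of samples per
size on cuboids between N = 24 and N = 100, versus 10^4^–10^5^ in a full
production campaign.  These sizes were chosen so the complete test suite
and the acceptance analysis re-run end to end on one CPU core; ensemble
statistics consequently carry standard errors of a few tenths of a corner
and scaling exponents carry standard errors of a few hundredths, which the
tests account for with SEM-scaled tolerances.

For the doubly constrained rare states (extremal curvature *and* contacts)
plain restarts are inefficient; `targetJointRareState()` stages the search
— curvature-only annealing first, then a warm-started joint repair — and
returns only verified zero-energy states of the joint model.  Staging
changes the search path, never the target set.

## What the generator does and does not emulate

All inputs are synthetic by construction: the model *is* the ensemble
definition, so there is no approximation gap between "generator" and
"method" as in data-driven packages.  What desk scale does limit is reach:
tail quantities (the unlinking decay constant, extreme-curvature bands at
many sigmas) are estimated from small lattices and loose sampling, so they
are order-of-magnitude checks, not precision measurements.  Passing tests
demonstrate correctness of the encoding, decoding, topology, and samplers,
and statistical consistency of the desk-scale ensembles; they do not
certify production-scale tail estimates.

## Known limitations

* Cold-start annealing ladders bias ground-state coverage on tiny lattices;
  use the hot geometric ladder where uniformity matters (the package does).
* The plaquette move set is a reconstruction; its ergodicity at complete
  filling is verified empirically on small instances only, and it is not
  ergodic at partial filling (there it is not offered).
* `Lk = 0` is the operational definition of "unlinked"; topological links
  with vanishing Gaussian linking number are not detected.
* Periodic boundaries, non-cubic lattices, and minor-embedding for
  annealing hardware are out of scope; the solver interface accepts
  external adapters instead.
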
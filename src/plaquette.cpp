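// Plaquette-flip Monte Carlo with replica exchange for fully packed loop
// configurations on cuboid lattices. The elementary move exchanges the two
// occupied opposite edges of a unit face for the two empty ones, which
// preserves the degree-2 (full packing) invariant exactly; the energy is the
// total number of corner turns.
#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Geometry {
  int E, S, F;
  std::vector<int> edge_axis;          // 1,2,3
  std::vector<int> edge_a, edge_b;     // 0-based endpoints
  std::vector<std::array<int, 4>> face_edges; // a1,a2,b1,b2 (a,b opposite pairs)
};

struct Replica {
  std::vector<uint8_t> x;        // edge occupancy
  std::vector<int> act;          // 2 active edges per site (full packing)
  long energy;                   // total corners
};

inline bool corner(const Geometry& g, const Replica& r, int s) {
  return g.edge_axis[r.act[2 * s]] != g.edge_axis[r.act[2 * s + 1]];
}

void build_act(const Geometry& g, Replica& r) {
  r.act.assign(2 * g.S, -1);
  std::vector<int> deg(g.S, 0);
  for (int e = 0; e < g.E; ++e) {
    if (!r.x[e]) continue;
    int a = g.edge_a[e], b = g.edge_b[e];
    if (deg[a] > 1 || deg[b] > 1) stop("initial state is not degree-2");
    r.act[2 * a + deg[a]++] = e;
    r.act[2 * b + deg[b]++] = e;
  }
  for (int s = 0; s < g.S; ++s)
    if (deg[s] != 2) stop("initial state is not fully packed");
  r.energy = 0;
  for (int s = 0; s < g.S; ++s) r.energy += corner(g, r, s);
}

inline void replace_act(Replica& r, int s, int old_e, int new_e) {
  if (r.act[2 * s] == old_e) r.act[2 * s] = new_e;
  else r.act[2 * s + 1] = new_e;
}

// Attempt a flip on face f; returns energy change if accepted (and applies
// it), or returns false for null/rejected proposals.
bool attempt_flip(const Geometry& g, Replica& r, int f, double beta,
                  std::mt19937_64& rng,
                  std::uniform_real_distribution<double>& unif) {
  const std::array<int, 4>& fe = g.face_edges[f];
  int out0, out1, in0, in1;
  if (r.x[fe[0]] && r.x[fe[1]] && !r.x[fe[2]] && !r.x[fe[3]]) {
    out0 = fe[0]; out1 = fe[1]; in0 = fe[2]; in1 = fe[3];
  } else if (!r.x[fe[0]] && !r.x[fe[1]] && r.x[fe[2]] && r.x[fe[3]]) {
    out0 = fe[2]; out1 = fe[3]; in0 = fe[0]; in1 = fe[1];
  } else {
    return false; // null proposal
  }
  // the 4 face sites: endpoints of the outgoing pair
  int sites[4] = {g.edge_a[out0], g.edge_b[out0], g.edge_a[out1], g.edge_b[out1]};
  long before = 0;
  for (int q = 0; q < 4; ++q) before += corner(g, r, sites[q]);
  // each face site loses one outgoing edge and gains the incoming edge that
  // has it as an endpoint
  auto incoming_for = [&](int s) {
    return (g.edge_a[in0] == s || g.edge_b[in0] == s) ? in0 : in1;
  };
  int old_e[4], new_e[4];
  for (int q = 0; q < 4; ++q) {
    old_e[q] = (q < 2) ? out0 : out1;
    new_e[q] = incoming_for(sites[q]);
    replace_act(r, sites[q], old_e[q], new_e[q]);
  }
  long after = 0;
  for (int q = 0; q < 4; ++q) after += corner(g, r, sites[q]);
  long de = after - before;
  if (de <= 0 || unif(rng) < std::exp(-beta * (double)de)) {
    r.x[out0] = 0; r.x[out1] = 0; r.x[in0] = 1; r.x[in1] = 1;
    r.energy += de;
    return true;
  }
  // revert act
  for (int q = 0; q < 4; ++q) replace_act(r, sites[q], new_e[q], old_e[q]);
  return false;
}

Geometry unpack_geom(List geom) {
  Geometry g;
  g.edge_axis = as<std::vector<int>>(geom["edge_axis"]);
  g.E = (int)g.edge_axis.size();
  IntegerMatrix es = geom["edge_sites"];
  g.edge_a.resize(g.E); g.edge_b.resize(g.E);
  for (int e = 0; e < g.E; ++e) { g.edge_a[e] = es(e, 0); g.edge_b[e] = es(e, 1); }
  g.S = as<int>(geom["n_sites"]);
  IntegerMatrix fe = geom["face_edges"];
  g.F = fe.nrow();
  g.face_edges.resize(g.F);
  for (int f = 0; f < g.F; ++f)
    g.face_edges[f] = {fe(f, 0), fe(f, 1), fe(f, 2), fe(f, 3)};
  return g;
}

} // namespace

// [[Rcpp::export(name = ".rm_replica_exchange")]]
List rm_replica_exchange(List geom, IntegerVector x0, NumericVector betas,
                         int sweeps, int exchange_interval,
                         int record_interval, double seed) {
  Geometry g = unpack_geom(geom);
  int K = betas.size();
  if (K < 1) stop("need at least one replica");
  if (sweeps < 1) stop("need at least one sweep");
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<Replica> reps(K);
  for (int k = 0; k < K; ++k) {
    reps[k].x.assign(x0.begin(), x0.end());
    build_act(g, reps[k]);
  }
  int cold = K - 1; // betas sorted ascending; last is coldest
  NumericVector cold_energy(sweeps);
  int nrec = record_interval > 0 ? sweeps / record_interval : 0;
  IntegerMatrix recs(nrec, g.S); // full packing: S active edges
  int ri = 0;
  long swap_acc = 0, swap_try = 0;
  for (int sw = 0; sw < sweeps; ++sw) {
    for (int k = 0; k < K; ++k) {
      Replica& r = reps[k];
      double beta = betas[k];
      for (int t = 0; t < g.F; ++t) {
        int f = (int)(rng() % (uint64_t)g.F);
        attempt_flip(g, r, f, beta, rng, unif);
      }
    }
    if (K > 1 && exchange_interval > 0 && (sw + 1) % exchange_interval == 0) {
      int par = (sw / exchange_interval) & 1;
      for (int k = par; k + 1 < K; k += 2) {
        ++swap_try;
        double arg = (betas[k + 1] - betas[k]) *
                     ((double)reps[k + 1].energy - (double)reps[k].energy);
        if (arg >= 0.0 || unif(rng) < std::exp(arg)) {
          std::swap(reps[k], reps[k + 1]);
          ++swap_acc;
        }
      }
    }
    cold_energy[sw] = (double)reps[cold].energy;
    if (record_interval > 0 && (sw + 1) % record_interval == 0 && ri < nrec) {
      int c = 0;
      for (int e = 0; e < g.E && c < g.S; ++e)
        if (reps[cold].x[e]) recs(ri, c++) = e + 1; // 1-based edge indices
      ++ri;
    }
    if ((sw & 1023) == 0) checkUserInterrupt();
  }
  return List::create(_["cold_energy"] = cold_energy,
                      _["configurations"] = recs,
                      _["swap_rate"] = swap_try ? (double)swap_acc / swap_try : NA_REAL);
}

// Degree audit helper used by property tests: run n random flip attempts on
// a single replica and return the final edge occupancy plus a degree check.
// [[Rcpp::export(name = ".rm_plaquette_stress")]]
List rm_plaquette_stress(List geom, IntegerVector x0, double beta,
                         double n_attempts, double seed) {
  Geometry g = unpack_geom(geom);
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  Replica r;
  r.x.assign(x0.begin(), x0.end());
  build_act(g, r);
  long n = (long)n_attempts, acc = 0;
  for (long t = 0; t < n; ++t) {
    int f = (int)(rng() % (uint64_t)g.F);
    if (attempt_flip(g, r, f, beta, rng, unif)) ++acc;
    if ((t & 65535) == 0) checkUserInterrupt();
  }
  std::vector<int> deg(g.S, 0);
  for (int e = 0; e < g.E; ++e)
    if (r.x[e]) { ++deg[g.edge_a[e]]; ++deg[g.edge_b[e]]; }
  bool ok = true;
  for (int s = 0; s < g.S; ++s) if (deg[s] != 2) ok = false;
  long crn = 0;
  for (int s = 0; s < g.S; ++s) crn += corner(g, r, s);
  IntegerVector xv(g.E);
  for (int e = 0; e < g.E; ++e) xv[e] = r.x[e];
  return List::create(_["x"] = xv, _["degree_ok"] = ok, _["accepted"] = (double)acc,
                      _["energy"] = (double)crn);
}
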
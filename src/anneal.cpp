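// Simulated-annealing core for sparse QUBO models with population-constraint
// groups kept in compressed form: a term A*(sum_{v in g} x_v - n)^2 is
// evaluated incrementally through the running sum S_g, so a single-variable
// flip costs O(deg_generic(v) + groups(v)) instead of touching the dense
// couplings the expanded square would induce.
#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  int nv;
  std::vector<double> lin;
  std::vector<int> adj_ptr, adj_idx;   // symmetrized generic couplings (CSR)
  std::vector<double> adj_w;
  std::vector<double> grp_coef, grp_target;
  std::vector<int> grp_ptr, grp_vars;  // group -> member variables
  std::vector<int> vgrp_ptr, vgrp;     // variable -> groups containing it
  double offset;
};

Model unpack(const List& m) {
  Model mod;
  mod.lin = as<std::vector<double>>(m["lin"]);
  mod.nv = (int)mod.lin.size();
  mod.adj_ptr = as<std::vector<int>>(m["adj_ptr"]);
  mod.adj_idx = as<std::vector<int>>(m["adj_idx"]);
  mod.adj_w = as<std::vector<double>>(m["adj_w"]);
  mod.grp_coef = as<std::vector<double>>(m["grp_coef"]);
  mod.grp_target = as<std::vector<double>>(m["grp_target"]);
  mod.grp_ptr = as<std::vector<int>>(m["grp_ptr"]);
  mod.grp_vars = as<std::vector<int>>(m["grp_vars"]);
  mod.vgrp_ptr = as<std::vector<int>>(m["vgrp_ptr"]);
  mod.vgrp = as<std::vector<int>>(m["vgrp"]);
  mod.offset = as<double>(m["offset"]);
  return mod;
}

struct State {
  std::vector<uint8_t> x;
  std::vector<double> h;    // generic local field: lin_v + sum_j w_vj x_j
  std::vector<double> gsum; // per-group running sum
  double energy;
};

void init_state(const Model& m, State& st, std::mt19937_64& rng,
                const IntegerVector& x0, const NumericVector& p_init) {
  int nv = m.nv;
  st.x.assign(nv, 0);
  if (x0.size() == nv) {
    for (int v = 0; v < nv; ++v) st.x[v] = (uint8_t)(x0[v] != 0);
  } else if (p_init.size() == nv) {
    std::uniform_real_distribution<double> u01(0.0, 1.0);
    for (int v = 0; v < nv; ++v) st.x[v] = (uint8_t)(u01(rng) < p_init[v]);
  } else {
    for (int v = 0; v < nv; ++v) st.x[v] = (uint8_t)(rng() & 1u);
  }
  st.h.assign(m.lin.begin(), m.lin.end());
  for (int v = 0; v < nv; ++v) {
    if (!st.x[v]) continue;
    for (int p = m.adj_ptr[v]; p < m.adj_ptr[v + 1]; ++p)
      st.h[m.adj_idx[p]] += m.adj_w[p];
  }
  int ng = (int)m.grp_coef.size();
  st.gsum.assign(ng, 0.0);
  for (int g = 0; g < ng; ++g)
    for (int p = m.grp_ptr[g]; p < m.grp_ptr[g + 1]; ++p)
      st.gsum[g] += st.x[m.grp_vars[p]];
  double e = m.offset;
  for (int v = 0; v < nv; ++v)
    if (st.x[v]) e += m.lin[v] + 0.5 * (st.h[v] - m.lin[v]);
  for (int g = 0; g < ng; ++g) {
    double d = st.gsum[g] - m.grp_target[g];
    e += m.grp_coef[g] * d * d;
  }
  st.energy = e;
}

inline double flip_delta(const Model& m, const State& st, int v) {
  double d = st.x[v] ? -1.0 : 1.0;
  double de = d * st.h[v];
  for (int p = m.vgrp_ptr[v]; p < m.vgrp_ptr[v + 1]; ++p) {
    int g = m.vgrp[p];
    de += m.grp_coef[g] * (2.0 * d * (st.gsum[g] - m.grp_target[g]) + 1.0);
  }
  return de;
}

inline void apply_flip(const Model& m, State& st, int v, double de) {
  double d = st.x[v] ? -1.0 : 1.0;
  st.x[v] = !st.x[v];
  st.energy += de;
  for (int p = m.adj_ptr[v]; p < m.adj_ptr[v + 1]; ++p)
    st.h[m.adj_idx[p]] += d * m.adj_w[p];
  for (int p = m.vgrp_ptr[v]; p < m.vgrp_ptr[v + 1]; ++p)
    st.gsum[m.vgrp[p]] += d;
}

// One annealing run over the beta ladder; returns best energy seen and
// leaves the best assignment in best_x. Stops early on reaching target.
double anneal_once(const Model& m, const NumericVector& betas, double target,
                   double tol, std::mt19937_64& rng,
                   std::vector<uint8_t>& best_x, const IntegerVector& x0,
                   const NumericVector& p_init, int random_order) {
  State st;
  init_state(m, st, rng, x0, p_init);
  int nv = m.nv;
  best_x = st.x;
  double best_e = st.energy;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  if (best_e <= target + tol) return best_e;
  int nsweeps = betas.size();
  std::vector<int> perm(nv);
  for (int v = 0; v < nv; ++v) perm[v] = v;
  // with the default integer coefficients uphill moves have small integer
  // energies; cache their acceptance probabilities per sweep
  const int TAB = 64;
  double ptab[TAB];
  for (int s = 0; s < nsweeps; ++s) {
    double beta = betas[s];
    for (int d = 1; d < TAB; ++d) ptab[d] = std::exp(-beta * d);
    int start = (int)(rng() % (uint64_t)nv);
    if (random_order == 2) {
      for (int t = nv - 1; t > 0; --t) {
        int u = (int)(rng() % (uint64_t)(t + 1));
        std::swap(perm[t], perm[u]);
      }
    }
    for (int t = 0; t < nv; ++t) {
      int v;
      if (random_order == 1) {
        v = (int)(rng() % (uint64_t)nv);
      } else if (random_order == 2) {
        v = perm[t];
      } else {
        v = start + t;
        if (v >= nv) v -= nv;
      }
      double de = flip_delta(m, st, v);
      bool accept;
      if (de <= 0.0) {
        accept = true;
      } else {
        int di = (int)de;
        double p = (di < TAB && (double)di == de) ? ptab[di]
                                                  : std::exp(-beta * de);
        accept = unif(rng) < p;
      }
      if (accept) {
        apply_flip(m, st, v, de);
        if (st.energy < best_e) {
          best_e = st.energy;
          best_x = st.x;
          if (best_e <= target + tol) return best_e;
        }
      }
    }
  }
  return best_e;
}

} // namespace

// [[Rcpp::export(name = ".rm_anneal")]]
List rm_anneal(List model, NumericVector betas, int restarts, double target,
               double tol, double seed, IntegerVector x0,
               NumericVector p_init = NumericVector(0),
               int random_order = 0) {
  Model m = unpack(model);
  if (m.nv == 0) stop("empty model");
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<uint8_t> best_x, run_x;
  double best_e = R_PosInf;
  NumericVector restart_e(restarts);
  for (int r = 0; r < restarts; ++r) {
    double e = anneal_once(m, betas, target, tol, rng, run_x, x0, p_init,
                           random_order);
    restart_e[r] = e;
    if (e < best_e) {
      best_e = e;
      best_x = run_x;
    }
    if (best_e <= target + tol) {
      // truncate remaining restarts: ground state reached
      restart_e = NumericVector(restart_e.begin(), restart_e.begin() + r + 1);
      break;
    }
  }
  IntegerVector xa(m.nv);
  for (int v = 0; v < m.nv; ++v) xa[v] = best_x[v];
  return List::create(_["assignment"] = xa, _["energy"] = best_e,
                      _["restart_energies"] = restart_e,
                      _["hit"] = best_e <= target + tol);
}

// Repeated independent annealing runs until n_target ground-state hits are
// collected or max_attempts runs are spent.
// [[Rcpp::export(name = ".rm_anneal_collect")]]
List rm_anneal_collect(List model, NumericVector betas, int n_target,
                       int max_attempts, double target, double tol,
                       double seed, IntegerVector x0,
                       NumericVector p_init = NumericVector(0),
                       int random_order = 0) {
  Model m = unpack(model);
  if (m.nv == 0) stop("empty model");
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<std::vector<uint8_t>> hits;
  std::vector<uint8_t> run_x;
  int attempts = 0;
  while ((int)hits.size() < n_target && attempts < max_attempts) {
    ++attempts;
    double e = anneal_once(m, betas, target, tol, rng, run_x, x0, p_init,
                           random_order);
    if (e <= target + tol) hits.push_back(run_x);
    if (attempts % 256 == 0) checkUserInterrupt();
  }
  IntegerMatrix hm((int)hits.size(), m.nv);
  for (int i = 0; i < (int)hits.size(); ++i)
    for (int v = 0; v < m.nv; ++v) hm(i, v) = hits[i][v];
  return List::create(_["hits"] = hm, _["attempts"] = attempts);
}
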
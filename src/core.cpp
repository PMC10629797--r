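#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Piecewise-linear z-score event model internals.
//
// Events are indexed 0..E-1; ev_region maps each event to its (0-based)
// region; ev_z is the z threshold the event crosses; zmax is the
// per-region plateau reached at stage E. A sequence is a permutation of
// event indices; stages are the integers 0..E. The hot paths (greedy
// optimizer, Metropolis chain) run on pre-allocated flat buffers: one
// likelihood evaluation is O(n * R * (E+1)) with no R allocations.

namespace {

struct Model {
  int n, R, E, S;                  // S = E + 1 stages
  std::vector<double> Xt;          // subject-major: Xt[j*R + i]
  std::vector<int> ev_region;
  std::vector<double> ev_z, zmax;
  double sigma, cst, inv2s2;
  std::vector<std::vector<int> > byreg;  // region -> events in threshold order
  std::vector<double> G;           // trajectory, G[i*S + k]
  std::vector<double> acc;         // per-stage accumulator

  Model(const NumericMatrix& X, const IntegerVector& evr,
        const NumericVector& evz, const NumericVector& zm,
        int n_regions, double sig) {
    n = X.nrow();
    R = n_regions;
    E = evr.size();
    S = E + 1;
    sigma = sig;
    inv2s2 = 1.0 / (2.0 * sigma * sigma);
    cst = -0.5 * R * std::log(2.0 * M_PI * sigma * sigma);
    Xt.resize((size_t) n * R);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < R; ++i) Xt[(size_t) j * R + i] = X(j, i);
    ev_region.assign(evr.begin(), evr.end());
    ev_z.assign(evz.begin(), evz.end());
    zmax.assign(zm.begin(), zm.end());
    byreg.resize(R);
    // events arrive grouped per region in ascending threshold order; keep
    // that order explicitly (and robustly) by sorting on threshold
    for (int e = 0; e < E; ++e) byreg[ev_region[e]].push_back(e);
    for (int i = 0; i < R; ++i)
      std::sort(byreg[i].begin(), byreg[i].end(),
                [&](int a, int b) { return ev_z[a] < ev_z[b]; });
    G.resize((size_t) R * S);
    acc.resize(S);
  }

  // fill G from event positions (1..E); within a valid sequence a region's
  // threshold order equals its position order
  void traj_from_pos(const std::vector<int>& pos) {
    for (int i = 0; i < R; ++i) {
      double* g = &G[(size_t) i * S];
      int x0 = 0;
      double y0 = 0.0;
      int t = 0;
      const std::vector<int>& evs = byreg[i];
      for (size_t a = 0; a <= evs.size(); ++a) {
        int x1;
        double y1;
        if (a < evs.size()) {
          x1 = pos[evs[a]];
          y1 = ev_z[evs[a]];
        } else {
          if (x0 == E) break;        // plateau anchor would be zero-length
          x1 = E;
          y1 = zmax[i];
        }
        for (; t <= x1; ++t)
          g[t] = (x1 == x0) ? y1 : y0 + (y1 - y0) * double(t - x0) / double(x1 - x0);
        x0 = x1;
        y0 = y1;
      }
      for (; t <= E; ++t) g[t] = y0;
    }
  }

  // weighted sum over subjects of the stage-marginalized log-likelihood
  // under the current G; optionally writes per-subject values
  double weighted_marginal(const double* w, double* lj_out) {
    double lp = -std::log((double) S);
    double tot = 0.0;
    for (int j = 0; j < n; ++j) {
      const double* xj = &Xt[(size_t) j * R];
      for (int k = 0; k < S; ++k) acc[k] = 0.0;
      for (int i = 0; i < R; ++i) {
        const double xv = xj[i];
        const double* g = &G[(size_t) i * S];
        for (int k = 0; k < S; ++k) {
          double d = xv - g[k];
          acc[k] += d * d;
        }
      }
      double m = acc[0];
      for (int k = 1; k < S; ++k) if (acc[k] < m) m = acc[k];
      double s = 0.0;
      for (int k = 0; k < S; ++k) s += std::exp((m - acc[k]) * inv2s2);
      double lj = cst - m * inv2s2 + std::log(s) + lp;
      if (lj_out) lj_out[j] = lj;
      tot += (w ? w[j] : 1.0) * lj;
    }
    return tot;
  }

  double marginal_from_order(const std::vector<int>& order, const double* w,
                             double* lj_out, std::vector<int>& pos) {
    for (int k = 0; k < E; ++k) pos[order[k]] = k + 1;
    traj_from_pos(pos);
    return weighted_marginal(w, lj_out);
  }
};

// feasible insertion window (0-based slots into order-without-e) keeping
// the within-region threshold order
void feasible_window(const std::vector<int>& rest, const std::vector<int>& reg,
                     const std::vector<double>& z, int e, int& lo, int& hi) {
  lo = 0;
  hi = (int) rest.size();
  for (size_t k = 0; k < rest.size(); ++k) {
    int o = rest[k];
    if (reg[o] == reg[e]) {
      if (z[o] < z[e]) lo = std::max(lo, (int) k + 1);
      else hi = std::min(hi, (int) k);
    }
  }
}

double logsumexp2(const double* v, int k) {
  double m = v[0];
  for (int i = 1; i < k; ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (int i = 0; i < k; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_traj_matrix(IntegerVector seq, IntegerVector ev_region,
                              NumericVector ev_z, NumericVector zmax,
                              int n_regions) {
  NumericMatrix dummy(1, n_regions);
  Model md(dummy, ev_region, ev_z, zmax, n_regions, 1.0);
  std::vector<int> pos(md.E);
  for (int k = 0; k < md.E; ++k) pos[seq[k] - 1] = k + 1;
  md.traj_from_pos(pos);
  NumericMatrix G(n_regions, md.S);
  for (int i = 0; i < n_regions; ++i)
    for (int k = 0; k < md.S; ++k) G(i, k) = md.G[(size_t) i * md.S + k];
  return G;
}

// [[Rcpp::export]]
NumericMatrix cpp_stage_loglik(NumericMatrix X, NumericMatrix G, double sigma) {
  int n = X.nrow(), R = X.ncol(), S = G.ncol();
  NumericMatrix L(n, S);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double cst = -0.5 * R * std::log(2.0 * M_PI * sigma * sigma);
  for (int k = 0; k < S; ++k)
    for (int j = 0; j < n; ++j) {
      double a = 0.0;
      for (int i = 0; i < R; ++i) {
        double d = X(j, i) - G(i, k);
        a += d * d;
      }
      L(j, k) = cst - a * inv2s2;
    }
  return L;
}

// [[Rcpp::export]]
NumericVector cpp_seq_subject_loglik(NumericMatrix X, IntegerVector seq,
                                     IntegerVector ev_region, NumericVector ev_z,
                                     NumericVector zmax, int n_regions,
                                     double sigma) {
  Model md(X, ev_region, ev_z, zmax, n_regions, sigma);
  std::vector<int> pos(md.E);
  std::vector<int> order(md.E);
  for (int k = 0; k < md.E; ++k) order[k] = seq[k] - 1;
  NumericVector out(md.n);
  md.marginal_from_order(order, nullptr, REAL(out), pos);
  return out;
}

// [[Rcpp::export]]
double cpp_mixture_loglik(NumericMatrix L, NumericVector f) {
  int n = L.nrow(), C = L.ncol();
  std::vector<double> logf(C), v(C);
  for (int c = 0; c < C; ++c) logf[c] = std::log(f[c]);
  double tot = 0.0;
  for (int j = 0; j < n; ++j) {
    for (int c = 0; c < C; ++c) v[c] = logf[c] + L(j, c);
    tot += logsumexp2(v.data(), C);
  }
  return tot;
}

// greedy coordinate ascent: repeatedly relocate each event to its best
// feasible position until no single move improves the weighted objective
// [[Rcpp::export]]
List cpp_greedy_optimize(NumericMatrix X, NumericVector w, IntegerVector seq0,
                         IntegerVector ev_region, NumericVector ev_z,
                         NumericVector zmax, int n_regions, double sigma,
                         int max_sweeps) {
  Model md(X, ev_region, ev_z, zmax, n_regions, sigma);
  int E = md.E;
  std::vector<int> order(E), pos(E);
  for (int k = 0; k < E; ++k) order[k] = seq0[k] - 1;
  const double* wp = REAL(w);

  double best = md.marginal_from_order(order, wp, nullptr, pos);
  std::vector<int> rest, cand;
  rest.reserve(E);
  cand.reserve(E);

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool improved = false;
    for (int e = 0; e < E; ++e) {
      rest.clear();
      for (int k = 0; k < E; ++k) if (order[k] != e) rest.push_back(order[k]);
      int lo, hi;
      feasible_window(rest, md.ev_region, md.ev_z, e, lo, hi);
      int best_slot = -1;
      double best_here = best;
      for (int s = lo; s <= hi; ++s) {
        cand = rest;
        cand.insert(cand.begin() + s, e);
        double obj = md.marginal_from_order(cand, wp, nullptr, pos);
        if (obj > best_here + 1e-12) {
          best_here = obj;
          best_slot = s;
        }
      }
      if (best_slot >= 0) {
        cand = rest;
        cand.insert(cand.begin() + best_slot, e);
        order = cand;
        best = best_here;
        improved = true;
      }
    }
    if (!improved) break;
  }

  IntegerVector out(E);
  for (int k = 0; k < E; ++k) out[k] = order[k] + 1;
  return List::create(_["seq"] = out, _["loglik"] = best);
}

// Metropolis chain over (sequences, fractions). Each iteration: one
// single-event relocation in one uniformly chosen subtype, accepted with
// min(1, exp(delta loglik)); then (optionally) a joint Dirichlet fraction
// proposal accepted the same way. Flat priors; R's RNG throughout.
// [[Rcpp::export]]
List cpp_mcmc(NumericMatrix X, IntegerMatrix seqs, NumericVector f,
              int n_iter, double burn_frac, IntegerVector ev_region,
              NumericVector ev_z, NumericVector zmax, int n_regions,
              double sigma, bool sample_fractions, double dirichlet_scale,
              bool store_samples) {
  RNGScope scope;
  Model md(X, ev_region, ev_z, zmax, n_regions, sigma);
  int E = md.E, C = seqs.ncol(), n = md.n;

  std::vector<std::vector<int> > order(C, std::vector<int>(E));
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < E; ++k) order[c][k] = seqs(k, c) - 1;
  std::vector<double> fcur(f.begin(), f.end()), logf(C);
  for (int c = 0; c < C; ++c) logf[c] = std::log(fcur[c]);

  std::vector<double> L((size_t) n * C), lj(n), v(C);
  std::vector<int> pos(E), rest, cand;
  rest.reserve(E);
  cand.reserve(E);
  for (int c = 0; c < C; ++c) {
    md.marginal_from_order(order[c], nullptr, lj.data(), pos);
    for (int j = 0; j < n; ++j) L[(size_t) j * C + c] = lj[j];
  }
  auto mixture = [&](const std::vector<double>& Lm,
                     const std::vector<double>& lf) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j) {
      const double* Lj = &Lm[(size_t) j * C];
      for (int c = 0; c < C; ++c) v[c] = lf[c] + Lj[c];
      tot += logsumexp2(v.data(), C);
    }
    return tot;
  };
  double cur_ll = mixture(L, logf);

  int burn = (int) std::floor(burn_frac * n_iter);
  int n_keep = n_iter - burn;

  std::vector<std::vector<double> > pvd(C, std::vector<double>((size_t) E * E, 0.0));
  IntegerMatrix samp_seq;
  NumericMatrix samp_f;
  if (store_samples) {
    samp_seq = IntegerMatrix(n_keep, C * E);
    samp_f = NumericMatrix(n_keep, C);
  }
  NumericVector ll_trace(n_iter);
  int acc_seq = 0, acc_f = 0, prop_f = 0;
  std::vector<double> fprop(C), logfprop(C);

  for (int it = 0; it < n_iter; ++it) {
    // --- sequence move ---
    int c = std::min(C - 1, (int) std::floor(unif_rand() * C));
    int e = std::min(E - 1, (int) std::floor(unif_rand() * E));
    rest.clear();
    for (int k = 0; k < E; ++k)
      if (order[c][k] != e) rest.push_back(order[c][k]);
    int lo, hi;
    feasible_window(rest, md.ev_region, md.ev_z, e, lo, hi);
    int s = std::min(hi, lo + (int) std::floor(unif_rand() * (hi - lo + 1)));
    cand = rest;
    cand.insert(cand.begin() + s, e);
    md.marginal_from_order(cand, nullptr, lj.data(), pos);
    double new_ll = 0.0;
    for (int j = 0; j < n; ++j) {
      const double* Lj = &L[(size_t) j * C];
      for (int cc = 0; cc < C; ++cc)
        v[cc] = logf[cc] + (cc == c ? lj[j] : Lj[cc]);
      new_ll += logsumexp2(v.data(), C);
    }
    if (std::log(unif_rand()) < new_ll - cur_ll) {
      order[c] = cand;
      for (int j = 0; j < n; ++j) L[(size_t) j * C + c] = lj[j];
      cur_ll = new_ll;
      ++acc_seq;
    }

    // --- fraction move ---
    if (sample_fractions && C > 1) {
      ++prop_f;
      double tot = 0.0;
      for (int k = 0; k < C; ++k) {
        fprop[k] = R::rgamma(dirichlet_scale * fcur[k] + 1.0, 1.0);
        tot += fprop[k];
      }
      for (int k = 0; k < C; ++k) {
        fprop[k] /= tot;
        logfprop[k] = std::log(fprop[k]);
      }
      double new_llf = mixture(L, logfprop);
      if (std::log(unif_rand()) < new_llf - cur_ll) {
        fcur = fprop;
        logf = logfprop;
        cur_ll = new_llf;
        ++acc_f;
      }
    }

    ll_trace[it] = cur_ll;
    if (it >= burn) {
      int r = it - burn;
      for (int cc = 0; cc < C; ++cc) {
        for (int k = 0; k < E; ++k) {
          pvd[cc][(size_t) order[cc][k] * E + k] += 1.0;
          if (store_samples) samp_seq(r, cc * E + k) = order[cc][k] + 1;
        }
        if (store_samples) samp_f(r, cc) = fcur[cc];
      }
    }
  }

  List pvds(C);
  for (int c = 0; c < C; ++c) {
    NumericMatrix P(E, E);
    for (int e = 0; e < E; ++e)
      for (int k = 0; k < E; ++k)
        P(e, k) = pvd[c][(size_t) e * E + k] / (double) n_keep;
    pvds[c] = P;
  }
  IntegerMatrix final_seqs(E, C);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < E; ++k) final_seqs(k, c) = order[c][k] + 1;
  NumericVector ffin(fcur.begin(), fcur.end());

  return List::create(
    _["final_seqs"] = final_seqs,
    _["final_f"] = ffin,
    _["final_loglik"] = cur_ll,
    _["pvd"] = pvds,
    _["samples_seq"] = store_samples ? (SEXP) samp_seq : R_NilValue,
    _["samples_f"] = store_samples ? (SEXP) samp_f : R_NilValue,
    _["loglik_trace"] = ll_trace,
    _["n_kept"] = n_keep,
    _["accept_rate_seq"] = (double) acc_seq / n_iter,
    _["accept_rate_f"] = prop_f > 0 ? (double) acc_f / prop_f : NA_REAL);
}
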
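// Dynamic-programming kernels for HMM parameter training.
//
// State convention: 0 = Start, S-1 = End (both silent), 1..S-2 emitting.
// `trans` is an S x S matrix of linear-space transition probabilities,
// `emit` an S x A matrix (silent rows ignored), `obs` a 1-based vector of
// symbol indices. Viterbi works in log space; forward-based kernels use
// per-position scaling because the back-tracing ratios are scale-invariant
// within a position pair.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// rolling path hash: 64-bit multiplicative combine, reported to R as the
// top 53 bits (exactly representable in a double)
static inline double hash_to_double(unsigned long long h) {
  return (double)(h >> 11);
}
static inline unsigned long long hash_step(unsigned long long h, int m) {
  return h * 1315423911ULL + (unsigned long long)(m + 1);
}

// argmax over predecessors with ties broken toward the lowest state index
// (strict > so the first maximal index wins)
static inline int argmax_pred(const std::vector<double>& vprev,
                              const NumericMatrix& trans,
                              int m, int S, double* best_out) {
  int l = -1;
  double best = R_NegInf;
  for (int n = 0; n < S; ++n) {
    double t = trans(n, m);
    if (t <= 0.0 || !R_finite(vprev[n]) ) continue;
    double cand = vprev[n] + std::log(t);
    if (cand > best) { best = cand; l = n; }
  }
  *best_out = best;
  return l;
}

// [[Rcpp::export(name = ".cpp_viterbi_full")]]
List cpp_viterbi_full(NumericMatrix trans, NumericMatrix emit, IntegerVector obs) {
  const int S = trans.nrow(), L = obs.size(), E = S - 1;
  if (L < 1) stop("sequence must have length >= 1");
  std::vector<double> vprev(S, R_NegInf), vcur(S, R_NegInf);
  vprev[0] = 0.0;
  IntegerMatrix back(S, L);
  std::fill(back.begin(), back.end(), -1);
  for (int k = 0; k < L; ++k) {
    int y = obs[k] - 1;
    for (int m = 1; m < E; ++m) {
      double e = emit(m, y);
      if (e <= 0.0) { vcur[m] = R_NegInf; back(m, k) = -1; continue; }
      double best;
      int l = argmax_pred(vprev, trans, m, S, &best);
      vcur[m] = (l >= 0) ? best + std::log(e) : R_NegInf;
      back(m, k) = l;
    }
    vcur[0] = R_NegInf;
    vcur[E] = R_NegInf;
    vprev = vcur;
  }
  double best;
  int l = argmax_pred(vprev, trans, E, S, &best);
  if (l < 0 || !R_finite(best)) stop("sequence unreachable");
  IntegerVector path(L);
  int cur = l;
  for (int k = L - 1; k >= 0; --k) {
    path[k] = cur + 1; // 1-based for R
    cur = back(cur, k);
  }
  return List::create(_["path"] = path, _["log_prob"] = best);
}

// One-pass Viterbi count propagation: per current state m we carry the
// transition/emission count tables of the best path ending in m, plus a
// rolling hash of that path so strict path identity can be tested without
// ever materializing the path.
// [[Rcpp::export(name = ".cpp_viterbi_counts")]]
List cpp_viterbi_counts(NumericMatrix trans, NumericMatrix emit, IntegerVector obs) {
  const int S = trans.nrow(), A = emit.ncol(), L = obs.size(), E = S - 1;
  if (L < 1) stop("sequence must have length >= 1");
  const int TS = S * S, ES = S * A;
  std::vector<double> vprev(S, R_NegInf), vcur(S, R_NegInf);
  vprev[0] = 0.0;
  std::vector<std::vector<double>> Tprev(S, std::vector<double>(TS, 0.0)), Tcur = Tprev;
  std::vector<std::vector<double>> Eprev(S, std::vector<double>(ES, 0.0)), Ecur = Eprev;
  std::vector<unsigned long long> hprev(S, 0ULL), hcur(S, 0ULL);

  for (int k = 0; k < L; ++k) {
    int y = obs[k] - 1;
    for (int m = 1; m < E; ++m) {
      double e = emit(m, y);
      if (e <= 0.0) { vcur[m] = R_NegInf; continue; }
      double best;
      int l = argmax_pred(vprev, trans, m, S, &best);
      if (l < 0) { vcur[m] = R_NegInf; continue; }
      vcur[m] = best + std::log(e);
      Tcur[m] = Tprev[l];
      Tcur[m][l + S * m] += 1.0;
      Ecur[m] = Eprev[l];
      Ecur[m][m + S * y] += 1.0;
      hcur[m] = hash_step(hprev[l], m);
    }
    vcur[0] = R_NegInf;
    vcur[E] = R_NegInf;
    std::swap(vprev, vcur);
    std::swap(Tprev, Tcur);
    std::swap(Eprev, Ecur);
    std::swap(hprev, hcur);
  }
  double best;
  int l = argmax_pred(vprev, trans, E, S, &best);
  if (l < 0 || !R_finite(best)) stop("sequence unreachable");
  NumericMatrix Tout(S, S), Eout(S, A);
  std::memcpy(&Tout[0], Tprev[l].data(), sizeof(double) * TS);
  std::memcpy(&Eout[0], Eprev[l].data(), sizeof(double) * ES);
  Tout(l, E) += 1.0;
  double hash = hash_to_double(hash_step(hprev[l], E));
  // rolling state: two v columns, two hash columns, two banks of count tables
  double retained = 2.0 * S + 2.0 * S + 2.0 * S * (TS + ES);
  return List::create(_["trans_counts"] = Tout, _["emit_counts"] = Eout,
                      _["log_prob"] = best, _["path_hash"] = hash,
                      _["retained_doubles"] = retained);
}

// Scaled forward pass; returns the full matrix for two-step back-tracing.
// [[Rcpp::export(name = ".cpp_forward")]]
List cpp_forward(NumericMatrix trans, NumericMatrix emit, IntegerVector obs) {
  const int S = trans.nrow(), L = obs.size(), E = S - 1;
  if (L < 1) stop("sequence must have length >= 1");
  NumericMatrix fhat(S, L + 1);
  NumericVector logscale(L);
  fhat(0, 0) = 1.0;
  double logP = 0.0;
  for (int k = 1; k <= L; ++k) {
    int y = obs[k - 1] - 1;
    double s = 0.0;
    for (int m = 1; m < E; ++m) {
      double e = emit(m, y);
      double acc = 0.0;
      if (e > 0.0) {
        for (int n = 0; n < S; ++n) {
          double t = trans(n, m);
          if (t > 0.0) acc += fhat(n, k - 1) * t;
        }
        acc *= e;
      }
      fhat(m, k) = acc;
      s += acc;
    }
    if (s <= 0.0) stop("sequence unreachable");
    for (int m = 1; m < E; ++m) fhat(m, k) /= s;
    logscale[k - 1] = std::log(s);
    logP += logscale[k - 1];
  }
  double tail = 0.0;
  for (int n = 1; n < E; ++n) tail += fhat(n, L) * trans(n, E);
  if (tail <= 0.0) stop("sequence unreachable");
  logP += std::log(tail);
  return List::create(_["fhat"] = fhat, _["logscale"] = logscale, _["log_prob"] = logP);
}

static inline int sample_index(const std::vector<double>& w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int last = -1;
  for (size_t n = 0; n < w.size(); ++n) {
    if (w[n] <= 0.0) continue;
    acc += w[n];
    last = (int)n;
    if (u <= acc) return (int)n;
  }
  return last; // guard against floating-point shortfall
}

// Classical stochastic back-tracing over a stored forward matrix. Samples
// `n_paths` independent state paths from the posterior P(path | X). The
// per-position scale factors cancel in the normalized previous-state
// distribution, so scaled forward values can be used directly.
// [[Rcpp::export(name = ".cpp_sample_paths")]]
IntegerMatrix cpp_sample_paths(NumericMatrix trans, NumericMatrix emit,
                               IntegerVector obs, NumericMatrix fhat, int n_paths) {
  const int S = trans.nrow(), L = obs.size(), E = S - 1;
  IntegerMatrix paths(n_paths, L);
  std::vector<double> w(S);
  for (int p = 0; p < n_paths; ++p) {
    // silent End at k = L
    double total = 0.0;
    for (int n = 0; n < S; ++n) {
      w[n] = (n >= 1 && n < E) ? fhat(n, L) * trans(n, E) : 0.0;
      total += w[n];
    }
    if (total <= 0.0) stop("degenerate back-tracing distribution");
    int cur = sample_index(w, total);
    paths(p, L - 1) = cur + 1;
    for (int k = L - 1; k >= 1; --k) {
      total = 0.0;
      for (int n = 0; n < S; ++n) {
        w[n] = fhat(n, k) * trans(n, cur);
        total += w[n];
      }
      if (total <= 0.0) stop("degenerate back-tracing distribution");
      cur = sample_index(w, total);
      paths(p, k - 1) = cur + 1;
    }
  }
  return paths;
}

// One-pass linear-memory sampling counts: at every position k and state m a
// previous state l is sampled per chain from p_m(k, .) and that chain's
// count tables for m are copied from l and incremented. At termination the
// End-state draw selects which table becomes the sampled path's counts.
// Consumes one uniform draw per (position, reachable state, chain).
// [[Rcpp::export(name = ".cpp_sem_counts")]]
List cpp_sem_counts(NumericMatrix trans, NumericMatrix emit, IntegerVector obs, int K) {
  const int S = trans.nrow(), A = emit.ncol(), L = obs.size(), E = S - 1;
  if (L < 1) stop("sequence must have length >= 1");
  if (K < 1) stop("K must be >= 1");
  const int TS = S * S, ES = S * A;
  std::vector<double> fprev(S, 0.0), fcur(S, 0.0), w(S, 0.0);
  fprev[0] = 1.0;
  // per chain, per current state: cumulative count tables
  std::vector<std::vector<std::vector<double>>> Tprev(
      K, std::vector<std::vector<double>>(S, std::vector<double>(TS, 0.0)));
  std::vector<std::vector<std::vector<double>>> Eprev(
      K, std::vector<std::vector<double>>(S, std::vector<double>(ES, 0.0)));
  std::vector<std::vector<std::vector<double>>> Tcur = Tprev, Ecur = Eprev;
  double logP = 0.0;

  for (int k = 0; k < L; ++k) {
    int y = obs[k] - 1;
    double s = 0.0;
    for (int m = 1; m < E; ++m) {
      double e = emit(m, y);
      double W = 0.0;
      if (e > 0.0) {
        for (int n = 0; n < S; ++n) {
          double t = trans(n, m);
          w[n] = (t > 0.0) ? fprev[n] * t : 0.0;
          W += w[n];
        }
      }
      if (e <= 0.0 || W <= 0.0) { fcur[m] = 0.0; continue; }
      fcur[m] = e * W;
      for (int c = 0; c < K; ++c) {
        int l = sample_index(w, W);
        Tcur[c][m] = Tprev[c][l];
        Tcur[c][m][l + S * m] += 1.0;
        Ecur[c][m] = Eprev[c][l];
        Ecur[c][m][m + S * y] += 1.0;
      }
      s += fcur[m];
    }
    if (s <= 0.0) stop("sequence unreachable");
    for (int m = 1; m < E; ++m) fcur[m] /= s;
    fcur[0] = 0.0;
    logP += std::log(s);
    std::swap(fprev, fcur);
    std::swap(Tprev, Tcur);
    std::swap(Eprev, Ecur);
  }
  double W = 0.0;
  for (int n = 0; n < S; ++n) {
    double t = trans(n, E);
    w[n] = (n >= 1 && n < E && t > 0.0) ? fprev[n] * t : 0.0;
    W += w[n];
  }
  if (W <= 0.0) stop("sequence unreachable");
  logP += std::log(W);
  List Tout(K), Eout(K);
  for (int c = 0; c < K; ++c) {
    int l = sample_index(w, W);
    NumericMatrix Tm(S, S), Em(S, A);
    std::memcpy(&Tm[0], Tprev[c][l].data(), sizeof(double) * TS);
    std::memcpy(&Em[0], Eprev[c][l].data(), sizeof(double) * ES);
    Tm(l, E) += 1.0;
    Tout[c] = Tm;
    Eout[c] = Em;
  }
  double retained = 2.0 * S + S /* w */ + 2.0 * K * S * (TS + ES);
  return List::create(_["trans_counts"] = Tout, _["emit_counts"] = Eout,
                      _["log_prob"] = logP, _["retained_doubles"] = retained);
}

// Forward-backward posterior-expected counts (two-pass baseline).
// [[Rcpp::export(name = ".cpp_expected_counts_fb")]]
List cpp_expected_counts_fb(NumericMatrix trans, NumericMatrix emit, IntegerVector obs) {
  const int S = trans.nrow(), A = emit.ncol(), L = obs.size(), E = S - 1;
  List fw = cpp_forward(trans, emit, obs);
  NumericMatrix fhat = fw["fhat"];
  NumericVector logscale = fw["logscale"];
  double logP = fw["log_prob"];
  // cumulative forward log scales: F[k] = sum of logscale[0..k-1]
  std::vector<double> F(L + 1, 0.0);
  for (int k = 1; k <= L; ++k) F[k] = F[k - 1] + logscale[k - 1];

  // scaled backward pass, columns 1..L, with right-cumulative scale logs
  NumericMatrix bhat(S, L + 1);
  std::vector<double> B(L + 1, 0.0);
  double s = 0.0;
  for (int i = 1; i < E; ++i) { bhat(i, L) = trans(i, E); s += bhat(i, L); }
  if (s <= 0.0) stop("sequence unreachable");
  for (int i = 1; i < E; ++i) bhat(i, L) /= s;
  B[L] = std::log(s);
  for (int k = L - 1; k >= 1; --k) {
    int y = obs[k] - 1; // symbol x_{k+1}
    s = 0.0;
    for (int i = 1; i < E; ++i) {
      double acc = 0.0;
      for (int j = 1; j < E; ++j) {
        double t = trans(i, j), e = emit(j, y);
        if (t > 0.0 && e > 0.0) acc += t * e * bhat(j, k + 1);
      }
      bhat(i, k) = acc;
      s += acc;
    }
    if (s <= 0.0) stop("sequence unreachable");
    for (int i = 1; i < E; ++i) bhat(i, k) /= s;
    B[k] = B[k + 1] + std::log(s);
  }

  NumericMatrix Tout(S, S), Eout(S, A);
  // Start transitions (k = 0)
  {
    int y = obs[0] - 1;
    double coef = std::exp(B[1] - logP);
    for (int j = 1; j < E; ++j) {
      double t = trans(0, j), e = emit(j, y);
      if (t > 0.0 && e > 0.0) Tout(0, j) = t * e * bhat(j, 1) * coef;
    }
  }
  // interior transitions
  for (int k = 1; k < L; ++k) {
    int y = obs[k] - 1; // x_{k+1}
    double coef = std::exp(F[k] + B[k + 1] - logP);
    for (int i = 1; i < E; ++i) {
      double fi = fhat(i, k);
      if (fi <= 0.0) continue;
      for (int j = 1; j < E; ++j) {
        double t = trans(i, j), e = emit(j, y);
        if (t > 0.0 && e > 0.0) Tout(i, j) += fi * t * e * bhat(j, k + 1) * coef;
      }
    }
  }
  // transitions into End
  {
    double coef = std::exp(F[L] - logP);
    for (int i = 1; i < E; ++i) {
      double t = trans(i, E);
      if (t > 0.0) Tout(i, E) += fhat(i, L) * t * coef;
    }
  }
  // emissions
  for (int k = 1; k <= L; ++k) {
    int y = obs[k - 1] - 1;
    double coef = std::exp(F[k] + B[k] - logP);
    for (int i = 1; i < E; ++i) {
      double v = fhat(i, k) * bhat(i, k);
      if (v > 0.0) Eout(i, y) += v * coef;
    }
  }
  return List::create(_["trans_counts"] = Tout, _["emit_counts"] = Eout,
                      _["log_prob"] = logP);
}

// One-pass linear-memory expected counts: per current state m the
// posterior-expected count tables conditional on occupying m at position k
// are propagated as a predecessor-weighted mixture.
// [[Rcpp::export(name = ".cpp_expected_counts_linear")]]
List cpp_expected_counts_linear(NumericMatrix trans, NumericMatrix emit, IntegerVector obs) {
  const int S = trans.nrow(), A = emit.ncol(), L = obs.size(), E = S - 1;
  if (L < 1) stop("sequence must have length >= 1");
  const int TS = S * S, ES = S * A;
  std::vector<double> fprev(S, 0.0), fcur(S, 0.0), w(S, 0.0);
  fprev[0] = 1.0;
  std::vector<std::vector<double>> Tprev(S, std::vector<double>(TS, 0.0)), Tcur = Tprev;
  std::vector<std::vector<double>> Eprev(S, std::vector<double>(ES, 0.0)), Ecur = Eprev;
  double logP = 0.0;

  for (int k = 0; k < L; ++k) {
    int y = obs[k] - 1;
    double s = 0.0;
    for (int m = 1; m < E; ++m) {
      double e = emit(m, y);
      double W = 0.0;
      if (e > 0.0) {
        for (int n = 0; n < S; ++n) {
          double t = trans(n, m);
          w[n] = (t > 0.0) ? fprev[n] * t : 0.0;
          W += w[n];
        }
      }
      std::vector<double>& Tm = Tcur[m];
      std::vector<double>& Em = Ecur[m];
      std::fill(Tm.begin(), Tm.end(), 0.0);
      std::fill(Em.begin(), Em.end(), 0.0);
      if (e <= 0.0 || W <= 0.0) { fcur[m] = 0.0; continue; }
      for (int n = 0; n < S; ++n) {
        if (w[n] <= 0.0) continue;
        double wb = w[n] / W;
        const std::vector<double>& Tn = Tprev[n];
        const std::vector<double>& En = Eprev[n];
        for (int z = 0; z < TS; ++z) Tm[z] += wb * Tn[z];
        for (int z = 0; z < ES; ++z) Em[z] += wb * En[z];
        Tm[n + S * m] += wb;
      }
      Em[m + S * y] += 1.0;
      fcur[m] = e * W;
      s += fcur[m];
    }
    if (s <= 0.0) stop("sequence unreachable");
    for (int m = 1; m < E; ++m) fcur[m] /= s;
    fcur[0] = 0.0;
    logP += std::log(s);
    std::swap(fprev, fcur);
    std::swap(Tprev, Tcur);
    std::swap(Eprev, Ecur);
  }
  double W = 0.0;
  for (int n = 0; n < S; ++n) {
    double t = trans(n, E);
    w[n] = (n >= 1 && n < E && t > 0.0) ? fprev[n] * t : 0.0;
    W += w[n];
  }
  if (W <= 0.0) stop("sequence unreachable");
  logP += std::log(W);
  NumericMatrix Tout(S, S), Eout(S, A);
  for (int n = 0; n < S; ++n) {
    if (w[n] <= 0.0) continue;
    double wb = w[n] / W;
    for (int z = 0; z < TS; ++z) Tout[z] += wb * Tprev[n][z];
    for (int z = 0; z < ES; ++z) Eout[z] += wb * Eprev[n][z];
    Tout(n, E) += wb;
  }
  double retained = 2.0 * S + S + 2.0 * S * (TS + ES);
  return List::create(_["trans_counts"] = Tout, _["emit_counts"] = Eout,
                      _["log_prob"] = logP, _["retained_doubles"] = retained);
}

// Ancestral simulation: follow transitions from Start until End, emitting a
// symbol in every non-silent state. Gives up (complete = FALSE) once
// max_len symbols have been emitted without reaching End.
// [[Rcpp::export(name = ".cpp_simulate_path")]]
List cpp_simulate_path(NumericMatrix trans, NumericMatrix emit, int max_len) {
  const int S = trans.nrow(), A = emit.ncol(), E = S - 1;
  std::vector<int> states, symbols;
  std::vector<double> w(S);
  int cur = 0;
  bool complete = false;
  while (true) {
    double total = 0.0;
    for (int n = 0; n < S; ++n) { w[n] = trans(cur, n); total += w[n]; }
    if (total <= 0.0) stop("state has no outgoing transitions");
    cur = sample_index(w, total);
    if (cur == E) { complete = true; break; }
    if ((int)states.size() >= max_len) break;
    states.push_back(cur + 1);
    double etot = 0.0;
    std::vector<double> ew(A);
    for (int a = 0; a < A; ++a) { ew[a] = emit(cur, a); etot += ew[a]; }
    int y = sample_index(ew, etot);
    symbols.push_back(y + 1);
  }
  return List::create(_["states"] = wrap(states), _["symbols"] = wrap(symbols),
                      _["complete"] = complete);
}

// Exact sampling of a path conditioned on emitting exactly L symbols.
// `u` holds the (column-normalized) length-feasibility recursion
// u_j(r) = sum_j' t(j,j') u_j'(r-1), u_j(0) = t(j,End); column r (0-based)
// of `u` is u_.(r). Transitions are reweighted by the probability that the
// remaining path length is exactly the remaining number of symbols, which
// yields the model's conditional path distribution given total length L.
// [[Rcpp::export(name = ".cpp_simulate_conditional")]]
List cpp_simulate_conditional(NumericMatrix trans, NumericMatrix emit, NumericMatrix u) {
  const int S = trans.nrow(), A = emit.ncol(), E = S - 1;
  const int L = u.ncol();
  IntegerVector states(L), symbols(L);
  std::vector<double> w(S), ew(A);
  int cur = 0;
  for (int k = 0; k < L; ++k) {
    int r = L - 1 - k; // symbols remaining after this one
    double total = 0.0;
    for (int n = 1; n < E; ++n) {
      w[n] = trans(cur, n) * u(n, r);
      total += w[n];
    }
    w[0] = 0.0; w[E] = 0.0;
    if (total <= 0.0) stop("target length unreachable from current state");
    cur = sample_index(w, total);
    states[k] = cur + 1;
    double etot = 0.0;
    for (int a = 0; a < A; ++a) { ew[a] = emit(cur, a); etot += ew[a]; }
    symbols[k] = sample_index(ew, etot) + 1;
  }
  return List::create(_["states"] = states, _["symbols"] = symbols);
}
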
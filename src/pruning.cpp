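// Felsenstein pruning core. Trees arrive as ape-style postorder edge
// matrices (1-based node ids, tips 1..ntip, root ntip+1); state spaces are
// tiny (2-8 composite states). Transition matrices are built from one
// eigendecomposition of Q per call, P(t) = V exp(D t) V^{-1}, which is far
// cheaper across thousands of edges than a Pade expmat per edge; defective
// Q (repeated eigenvalues without full eigenspace) falls back to expmat.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct QSpectral {
  bool ok = false;
  cx_mat V, Vinv;
  cx_vec d;
};

QSpectral decompose(const mat& Q) {
  QSpectral s;
  cx_vec d;
  cx_mat V;
  if (!eig_gen(d, V, Q)) return s;
  cx_mat Vinv;
  if (!inv(Vinv, V)) return s;
  // guard against a defective or ill-conditioned eigenbasis
  mat recon = real(V * diagmat(d) * Vinv);
  double scale = std::max(1.0, norm(Q, "inf"));
  if (norm(recon - Q, "inf") > 1e-9 * scale) return s;
  s.ok = true;
  s.V = std::move(V);
  s.Vinv = std::move(Vinv);
  s.d = std::move(d);
  return s;
}

mat pmat(const mat& Q, const QSpectral& s, double t) {
  mat P;
  if (s.ok) {
    P = real(s.V * diagmat(exp(s.d * t)) * s.Vinv);
    P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  } else {
    P = expmat(Q * t);
  }
  return P;
}

} // namespace

// Transition probability matrices exp(Q t) for every edge length.
// [[Rcpp::export]]
arma::cube edge_pmats_cpp(const arma::mat& Q, const arma::vec& el) {
  const uword k = Q.n_rows;
  QSpectral s = decompose(Q);
  cube P(k, k, el.n_elem);
  for (uword i = 0; i < el.n_elem; ++i) {
    P.slice(i) = pmat(Q, s, el(i));
  }
  return P;
}

// Postorder pruning pass. edge: (nedge x 2) parent/child, postorder;
// tipL: (ntip x k) tip partial likelihoods; returns per-node scaled
// partials and the accumulated log scaling factor.
// [[Rcpp::export]]
Rcpp::List prune_cpp(const arma::imat& edge, const arma::vec& el,
                     const arma::mat& tipL, const arma::mat& Q) {
  const uword k = Q.n_rows;
  const uword ntip = tipL.n_rows;
  const uword nedge = edge.n_rows;
  uword nnode = ntip;
  for (uword i = 0; i < nedge; ++i) {
    nnode = std::max(nnode, (uword) edge(i, 0));
    nnode = std::max(nnode, (uword) edge(i, 1));
  }
  QSpectral s = decompose(Q);
  mat part(nnode, k, fill::ones);
  part.rows(0, ntip - 1) = tipL;
  double logscale = 0.0;
  bool degenerate = false;
  for (uword i = 0; i < nedge; ++i) {
    const uword parent = (uword) edge(i, 0) - 1;
    const uword child  = (uword) edge(i, 1) - 1;
    vec v = pmat(Q, s, el(i)) * part.row(child).t();
    part.row(parent) %= v.t();
    double m = part.row(parent).max();
    if (m <= 0.0 || !std::isfinite(m)) { degenerate = true; break; }
    if (m < 1e-200) {
      part.row(parent) /= m;
      logscale += std::log(m);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("partials") = part,
    Rcpp::Named("logscale") = logscale,
    Rcpp::Named("degenerate") = degenerate);
}

namespace {

// Shared power cache for the uniformized chain R = I + Q/omega. Powers
// converge geometrically to the stationary projector and are frozen once
// they do, so branches with large omega*t cost O(n) scalar work only.
struct Uniformizer {
  mat R;
  double omega;
  std::vector<mat> pows;
  int frozen = -1;
  explicit Uniformizer(const mat& Q) {
    omega = -Q.diag().min();
    uword k = Q.n_rows;
    if (omega > 0.0) {
      R = eye(k, k) + Q / omega;
      pows.push_back(eye(k, k));
      pows.push_back(R);
    }
  }
  const mat& powm(int m) {
    if (frozen >= 0 && m >= frozen) return pows[(size_t)frozen];
    while ((int)pows.size() <= m) {
      mat nxt = pows.back() * R;
      if (norm(nxt - pows.back(), "inf") < 1e-14) {
        frozen = (int)pows.size() - 1;
        return pows[(size_t)frozen];
      }
      pows.push_back(std::move(nxt));
    }
    return pows[(size_t)m];
  }
  // Exact endpoint-conditioned path: rows (time, from, to), real changes
  // only, 1-based states. pab = P(end | start, t). Uses R's RNG.
  mat bridge(double t, uword ia, uword ib, double pab) {
    mat empty(0, 3);
    if (omega <= 0.0 || t <= 0.0) return empty;
    const uword k = R.n_rows;
    const double lam = omega * t;
    const double u = R::unif_rand() * pab;
    const int n_cap = (int)(lam + 12.0 * std::sqrt(lam + 1.0) + 200.0);
    // Poisson weights by recurrence; for large lam start where the mass is
    // (the skipped lower tail is < 1e-15 of the distribution)
    int n_lo = 0;
    if (lam > 600.0) n_lo = (int)std::max(0.0, lam - 9.0 * std::sqrt(lam));
    double pterm = R::dpois((double)n_lo, lam, 0);
    double cum = 0.0;
    int n = n_lo - 1;
    while (n < n_cap) {
      ++n;
      if (n > n_lo) pterm *= lam / (double)n;
      cum += pterm * powm(n)(ia, ib);
      if (cum >= u) break;
    }
    if (n <= 0) return empty;
    // make sure every tail power is materialized (or frozen) up front so the
    // hot loop below is allocation-free
    powm(n);
    std::vector<uword> s((size_t)n + 1);
    s[0] = ia; s[(size_t)n] = ib;
    double w[32];
    for (int i = 1; i < n; ++i) {
      const mat& tail = powm(n - i);
      const uword prev = s[(size_t)i - 1];
      double tot = 0.0;
      for (uword j = 0; j < k; ++j) {
        w[j] = R(prev, j) * tail(j, ib);
        tot += w[j];
      }
      double v = R::unif_rand() * tot;
      uword j = 0;
      double c = w[0];
      while (c < v && j + 1 < k) { ++j; c += w[j]; }
      s[(size_t)i] = j;
    }
    vec times((uword)n);
    for (int i = 0; i < n; ++i) times((uword)i) = R::unif_rand() * t;
    times = sort(times);
    uword nreal = 0;
    for (int i = 0; i < n; ++i) if (s[(size_t)i] != s[(size_t)i + 1]) ++nreal;
    mat out(nreal, 3);
    uword r = 0;
    for (int i = 0; i < n; ++i) {
      if (s[(size_t)i] != s[(size_t)i + 1]) {
        out(r, 0) = times((uword)i);
        out(r, 1) = (double)(s[(size_t)i] + 1);
        out(r, 2) = (double)(s[(size_t)i + 1] + 1);
        ++r;
      }
    }
    return out;
  }
};

uword sample_state(const vec& w) {
  double tot = accu(w);
  double v = R::unif_rand() * tot;
  uword j = 0;
  double c = w(0);
  while (c < v && j + 1 < w.n_elem) { ++j; c += w(j); }
  return j;
}

} // namespace

// Single endpoint-conditioned branch path (exported surface; the map
// sampler below shares one power cache across all branches of a map).
// [[Rcpp::export]]
arma::mat sample_bridge_cpp(const arma::mat& Q, double t, int a, int b,
                            double pab) {
  Uniformizer uni(Q);
  return uni.bridge(t, (uword)(a - 1), (uword)(b - 1), pab);
}

// One full stochastic character map: joint node-state sampling by the
// downward pass (each node conditional on its sampled parent and subtree
// partials), then endpoint-conditioned paths on every branch. Edges must be
// in postorder; P is the per-edge transition-matrix cube; up the scaled
// upward partials; prior the root prior. Returns 1-based node states and an
// event matrix (edge, time, from, to).
// [[Rcpp::export]]
Rcpp::List sample_one_map_cpp(const arma::mat& Q, const arma::imat& edge,
                              const arma::vec& el, const arma::cube& P,
                              const arma::mat& up, const arma::vec& prior,
                              int root) {
  const uword nedge = edge.n_rows;
  const uword k = Q.n_rows;
  const uword nnode = up.n_rows;
  Uniformizer uni(Q);
  ivec ns(nnode, fill::zeros);
  vec rw = prior % up.row((uword)root - 1).t();
  ns((uword)root - 1) = (sword)sample_state(rw) + 1;
  std::vector<mat> evs;
  uword total_rows = 0;
  for (uword ii = 0; ii < nedge; ++ii) {
    const uword e = nedge - 1 - ii; // preorder
    const uword p = (uword) edge(e, 0) - 1;
    const uword c = (uword) edge(e, 1) - 1;
    const uword sp = (uword) ns(p) - 1;
    vec w(k);
    for (uword j = 0; j < k; ++j) w(j) = P(sp, j, e) * up(c, j);
    const uword sc = sample_state(w);
    ns(c) = (sword)sc + 1;
    mat ev = uni.bridge(el(e), sp, sc, P(sp, sc, e));
    if (ev.n_rows > 0) {
      mat ev4(ev.n_rows, 4);
      ev4.col(0).fill((double)(e + 1));
      ev4.cols(1, 3) = ev;
      evs.push_back(std::move(ev4));
      total_rows += evs.back().n_rows;
    }
  }
  mat events(total_rows, 4);
  uword at = 0;
  for (const mat& ev : evs) {
    events.rows(at, at + ev.n_rows - 1) = ev;
    at += ev.n_rows;
  }
  return Rcpp::List::create(Rcpp::Named("node_states") = ns,
                            Rcpp::Named("events") = events);
}
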
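// Subset-search engines over a cached cross-product ("Gram") matrix of
// [1, X, y].  All fits are solved from the Gram matrix, so the per-subset
// cost is independent of n; this is what makes the parametric-bootstrap
// p-values (2 * p * nboot constrained searches per table) affordable.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double PIVOT_TOL = 1e-10;  // relative to the original diagonal
static const double TIE_TOL   = 1e-9;   // Q ties resolved by size, then lex order

// In-place lower Cholesky of M (m x m, row-major flattened), with a relative
// pivot check against diag0. Returns the failing column (0-based) or -1.
static int chol_lower(std::vector<double>& M, const std::vector<double>& diag0,
                      int m) {
  for (int j = 0; j < m; ++j) {
    double d = M[j * m + j];
    for (int k = 0; k < j; ++k) d -= M[j * m + k] * M[j * m + k];
    double scale = diag0[j] > 0 ? diag0[j] : 1.0;
    if (d < PIVOT_TOL * scale) return j;
    double ljj = std::sqrt(d);
    M[j * m + j] = ljj;
    for (int i = j + 1; i < m; ++i) {
      double s = M[i * m + j];
      for (int k = 0; k < j; ++k) s -= M[i * m + k] * M[j * m + k];
      M[i * m + j] = s / ljj;
    }
  }
  return -1;
}

// forward solve L z = v (L lower, from chol_lower layout)
static void forward_solve(const std::vector<double>& L, int m,
                          std::vector<double>& v) {
  for (int i = 0; i < m; ++i) {
    double s = v[i];
    for (int k = 0; k < i; ++k) s -= L[i * m + k] * v[k];
    v[i] = s / L[i * m + i];
  }
}

// back solve L' b = z
static void back_solve(const std::vector<double>& L, int m,
                       std::vector<double>& z) {
  for (int i = m - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < m; ++k) s -= L[k * m + i] * z[k];
    z[i] = s / L[i * m + i];
  }
}

struct GramView {
  const double* G;   // (p+2) x (p+2), column-major from R, symmetric
  int p;             // number of candidate predictors
  double n;
  double yty;
  GramView(const NumericMatrix& Gm, double n_) : G(Gm.begin()),
      p(Gm.ncol() - 2), n(n_) {
    yty = G[(p + 1) * (p + 2) + (p + 1)];
  }
  inline double at(int i, int j) const { return G[j * (p + 2) + i]; }
};

struct FitOut {
  double rss, neg2ll, q;
  std::vector<double> beta;  // intercept first, then active coefs
};

// Fit intercept + the predictors in `active` (0-based, sorted).
// want_beta = false skips the backsolve.
static FitOut gram_fit(const GramView& g, const std::vector<int>& active,
                       double lambda, bool want_beta) {
  int m = (int)active.size() + 1;
  std::vector<int> idx(m);
  idx[0] = 0;
  for (size_t k = 0; k < active.size(); ++k) idx[k + 1] = active[k] + 1;

  std::vector<double> M(m * m), diag0(m), v(m);
  for (int a = 0; a < m; ++a) {
    for (int b = 0; b <= a; ++b) M[a * m + b] = g.at(idx[a], idx[b]);
    diag0[a] = g.at(idx[a], idx[a]);
    v[a] = g.at(idx[a], g.p + 1);
  }
  int bad = chol_lower(M, diag0, m);
  if (bad >= 0) {
    int col = idx[bad];  // 0 = intercept, otherwise predictor col (1-based -1)
    if (col == 0)
      stop("rank-deficient subset: intercept column is degenerate");
    stop("rank-deficient subset: predictor column %d is collinear within the active set",
         col);
  }
  forward_solve(M, m, v);               // v := z
  double rss = g.yty;
  for (int a = 0; a < m; ++a) rss -= v[a] * v[a];
  if (rss <= 0 || !std::isfinite(rss))
    stop("degenerate fit: residual sum of squares is not positive (perfect fit unsupported)");
  FitOut out;
  out.rss = rss;
  out.neg2ll = g.n * (std::log(2.0 * M_PI * rss / g.n) + 1.0);
  out.q = out.neg2ll + lambda * (double)active.size();
  if (want_beta) {
    back_solve(M, m, v);
    out.beta = v;
  }
  return out;
}

// comparator implementing the deterministic tie-break:
// smaller q wins outright beyond TIE_TOL; within TIE_TOL prefer fewer
// variables, then the lexicographically smallest (sorted) index sequence.
static bool better(double qa, const std::vector<int>& aa,
                   double qb, const std::vector<int>& ab) {
  if (qa < qb - TIE_TOL) return true;
  if (qa > qb + TIE_TOL) return false;
  if (aa.size() != ab.size()) return aa.size() < ab.size();
  return std::lexicographical_compare(aa.begin(), aa.end(),
                                      ab.begin(), ab.end());
}

static std::vector<int> mask_to_active(std::uint32_t mask,
                                       const std::vector<int>& forced_in,
                                       const std::vector<int>& free_vars) {
  std::vector<int> act(forced_in);
  for (size_t j = 0; j < free_vars.size(); ++j)
    if (mask & (std::uint32_t(1) << j)) act.push_back(free_vars[j]);
  std::sort(act.begin(), act.end());
  return act;
}

struct SearchOut {
  std::vector<int> active;
  double q = std::numeric_limits<double>::infinity();
  long nodes = 0;
  bool found = false;
};

static SearchOut exhaustive(const GramView& g, double lambda,
                            const std::vector<int>& forced_in,
                            const std::vector<int>& free_vars) {
  SearchOut out;
  int k = (int)free_vars.size();
  std::uint64_t total = std::uint64_t(1) << k;
  for (std::uint64_t mask = 0; mask < total; ++mask) {
    std::vector<int> act = mask_to_active((std::uint32_t)mask, forced_in, free_vars);
    FitOut f = gram_fit(g, act, lambda, false);
    ++out.nodes;
    if (!out.found || better(f.q, act, out.q, out.active)) {
      out.q = f.q;
      out.active = act;
      out.found = true;
    }
  }
  return out;
}

struct BBState {
  const GramView* g;
  double lambda;
  std::vector<int> order;      // free vars in branching order
  std::vector<int> forced_in;
  SearchOut inc;               // incumbent
};

static void bb_recurse(BBState& st, std::vector<int>& fixed, int depth) {
  ++st.inc.nodes;
  int k = (int)st.order.size();
  if (depth == k) {
    std::vector<int> act(fixed);
    act.insert(act.end(), st.forced_in.begin(), st.forced_in.end());
    std::sort(act.begin(), act.end());
    FitOut f = gram_fit(*st.g, act, st.lambda, false);
    if (!st.inc.found || better(f.q, act, st.inc.q, st.inc.active)) {
      st.inc.q = f.q;
      st.inc.active = act;
      st.inc.found = true;
    }
    return;
  }
  // lower bound over the subtree: every descendant S satisfies
  // fixed (+ forced_in) <= S <= fixed + remaining free, so
  // neg2ll(S) >= neg2ll(all) and lambda|S| >= lambda|fixed + forced_in|.
  std::vector<int> all(fixed);
  all.insert(all.end(), st.forced_in.begin(), st.forced_in.end());
  size_t n_fixed = all.size();
  for (int j = depth; j < k; ++j) all.push_back(st.order[j]);
  std::sort(all.begin(), all.end());
  FitOut fall = gram_fit(*st.g, all, st.lambda, false);
  double bound = fall.neg2ll + st.lambda * (double)n_fixed;
  if (st.inc.found && bound > st.inc.q + TIE_TOL) return;

  int v = st.order[depth];
  fixed.push_back(v);                       // include branch first
  bb_recurse(st, fixed, depth + 1);
  fixed.pop_back();
  bb_recurse(st, fixed, depth + 1);         // exclude branch
}

static SearchOut branch_and_bound(const GramView& g, double lambda,
                                  const std::vector<int>& forced_in,
                                  const std::vector<int>& free_vars) {
  BBState st;
  st.g = &g;
  st.lambda = lambda;
  st.forced_in = forced_in;

  // root ordering: branch first on the variable with the largest
  // single-variable drop in Q relative to the forced-in model
  FitOut base = gram_fit(g, forced_in, lambda, false);
  std::vector<std::pair<double, int> > drops;
  for (size_t j = 0; j < free_vars.size(); ++j) {
    std::vector<int> act(forced_in);
    act.push_back(free_vars[j]);
    std::sort(act.begin(), act.end());
    FitOut f = gram_fit(g, act, lambda, false);
    drops.push_back(std::make_pair(base.q - f.q, free_vars[j]));
  }
  std::stable_sort(drops.begin(), drops.end(),
                   [](const std::pair<double, int>& a,
                      const std::pair<double, int>& b) {
                     if (a.first != b.first) return a.first > b.first;
                     return a.second < b.second;
                   });
  for (size_t j = 0; j < drops.size(); ++j) st.order.push_back(drops[j].second);

  // incumbent from a greedy forward pass (cheap, usually near-optimal)
  {
    std::vector<int> cur(forced_in);
    std::sort(cur.begin(), cur.end());
    FitOut fc = gram_fit(g, cur, lambda, false);
    st.inc.q = fc.q;
    st.inc.active = cur;
    st.inc.found = true;
    std::vector<int> remaining(free_vars);
    bool improved = true;
    while (improved && !remaining.empty()) {
      improved = false;
      double best_q = fc.q;
      int best_j = -1;
      std::vector<int> best_act;
      for (size_t j = 0; j < remaining.size(); ++j) {
        std::vector<int> act(cur);
        act.push_back(remaining[j]);
        std::sort(act.begin(), act.end());
        FitOut f = gram_fit(g, act, lambda, false);
        if (f.q < best_q - TIE_TOL) {
          best_q = f.q;
          best_j = (int)j;
          best_act = act;
        }
      }
      if (best_j >= 0) {
        cur = best_act;
        fc.q = best_q;
        remaining.erase(remaining.begin() + best_j);
        improved = true;
        if (better(best_q, cur, st.inc.q, st.inc.active)) {
          st.inc.q = best_q;
          st.inc.active = cur;
        }
      }
    }
  }

  std::vector<int> fixed;
  bb_recurse(st, fixed, 0);
  return st.inc;
}

// [[Rcpp::export(name = ".cpp_gram_fit")]]
List cpp_gram_fit(NumericMatrix G, double n, IntegerVector active0,
                  double lambda) {
  GramView g(G, n);
  std::vector<int> act(active0.begin(), active0.end());
  std::sort(act.begin(), act.end());
  FitOut f = gram_fit(g, act, lambda, true);
  return List::create(_["active"] = wrap(act),
                      _["coefficients"] = wrap(f.beta),
                      _["rss"] = f.rss, _["neg2ll"] = f.neg2ll, _["q"] = f.q);
}

// [[Rcpp::export(name = ".cpp_search")]]
List cpp_search(NumericMatrix G, double n, double lambda,
                IntegerVector forced_in0, IntegerVector forced_out0,
                std::string engine) {
  GramView g(G, n);
  std::vector<int> fin(forced_in0.begin(), forced_in0.end());
  std::sort(fin.begin(), fin.end());
  std::vector<bool> excluded(g.p, false), included(g.p, false);
  for (int v : fin) included[v] = true;
  for (int v : forced_out0) excluded[v] = true;
  std::vector<int> free_vars;
  for (int v = 0; v < g.p; ++v)
    if (!included[v] && !excluded[v]) free_vars.push_back(v);

  SearchOut out;
  if (engine == "exhaustive") {
    if (free_vars.size() > 25)
      stop("exhaustive search limited to 25 free variables (got %d); use engine = \"branch_and_bound\"",
           (int)free_vars.size());
    out = exhaustive(g, lambda, fin, free_vars);
  } else if (engine == "branch_and_bound") {
    out = branch_and_bound(g, lambda, fin, free_vars);
  } else {
    stop("unknown engine '%s'", engine.c_str());
  }
  FitOut f = gram_fit(g, out.active, lambda, true);
  return List::create(_["active"] = wrap(out.active),
                      _["coefficients"] = wrap(f.beta),
                      _["rss"] = f.rss, _["neg2ll"] = f.neg2ll, _["q"] = f.q,
                      _["nodes"] = (double)out.nodes);
}

// ---------------------------------------------------------------------------
// Fast mVI evaluator + parametric bootstrap for one variable group.
//
// All 2^p subsets are enumerated once; per response vector only the
// cross-products [1,X]'y and y'y change, so each constrained search is a
// sweep over precomputed Cholesky factors.  Subsets that contain part but
// not all of the group are never candidates for either constrained optimum
// and are skipped.
// ---------------------------------------------------------------------------

struct MaskTables {
  int p, m1;                         // m1 = p + 1 (intercept block)
  std::vector<std::uint32_t> masks;  // usable masks
  std::vector<int> msize;            // popcount
  std::vector<int> cls;              // 0 = group excluded, 1 = group included
  std::vector<std::vector<int> > idx;     // Gram row indices (0 = intercept)
  std::vector<std::vector<double> > fact; // lower Cholesky, dense m x m
};

static void build_mask_tables(MaskTables& T, const std::vector<double>& Gxx,
                              int p, std::uint32_t gmask) {
  T.p = p;
  T.m1 = p + 1;
  std::uint32_t total = std::uint32_t(1) << p;
  for (std::uint32_t mask = 0; mask < total; ++mask) {
    std::uint32_t inter = mask & gmask;
    if (inter != 0 && inter != gmask) continue;  // partial group: never optimal side
    int m = 1;
    std::vector<int> idx;
    idx.push_back(0);
    for (int v = 0; v < p; ++v)
      if (mask & (std::uint32_t(1) << v)) { idx.push_back(v + 1); ++m; }
    std::vector<double> M(m * m), diag0(m);
    for (int a = 0; a < m; ++a) {
      for (int b = 0; b <= a; ++b) M[a * m + b] = Gxx[idx[b] * T.m1 + idx[a]];
      diag0[a] = Gxx[idx[a] * T.m1 + idx[a]];
    }
    int bad = chol_lower(M, diag0, m);
    if (bad >= 0)
      stop("rank-deficient subset: predictor column %d is collinear within a candidate subset",
           idx[bad]);
    T.masks.push_back(mask);
    T.msize.push_back(m - 1);
    T.cls.push_back(inter == gmask ? 1 : 0);
    T.idx.push_back(idx);
    T.fact.push_back(M);
  }
}

// mVI for each lambda given the cross-products of one response.
static void mvi_for_response(const MaskTables& T, const std::vector<double>& v,
                             double yty, double n,
                             const std::vector<double>& lambdas, int gsize,
                             double* out) {
  size_t nmask = T.masks.size();
  std::vector<double> neg2ll(nmask);
  std::vector<double> z;
  for (size_t s = 0; s < nmask; ++s) {
    int m = (int)T.idx[s].size();
    z.resize(m);
    for (int a = 0; a < m; ++a) z[a] = v[T.idx[s][a]];
    const std::vector<double>& L = T.fact[s];
    double rss = yty;
    for (int i = 0; i < m; ++i) {
      double sum = z[i];
      for (int k = 0; k < i; ++k) sum -= L[i * m + k] * z[k];
      sum /= L[i * m + i];
      z[i] = sum;
      rss -= sum * sum;
    }
    if (rss <= 0) rss = std::numeric_limits<double>::min();
    neg2ll[s] = n * (std::log(2.0 * M_PI * rss / n) + 1.0);
  }
  for (size_t l = 0; l < lambdas.size(); ++l) {
    double lam = lambdas[l];
    double q_exc = std::numeric_limits<double>::infinity();
    double q_inc = std::numeric_limits<double>::infinity();
    for (size_t s = 0; s < nmask; ++s) {
      double q = neg2ll[s] + lam * T.msize[s];
      if (T.cls[s] == 0) { if (q < q_exc) q_exc = q; }
      else               { if (q < q_inc) q_inc = q; }
    }
    out[l] = q_exc - q_inc + lam * gsize;
  }
}

// [[Rcpp::export(name = ".cpp_mvi_boot")]]
List cpp_mvi_boot(NumericMatrix X, NumericVector y, IntegerVector group0,
                  NumericVector lambdas, int B, bool sigma_mle) {
  int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  if (p > 15)
    stop("fast bootstrap enumerator supports at most 15 predictors (got %d)", p);
  std::uint32_t gmask = 0;
  for (int i = 0; i < group0.size(); ++i)
    gmask |= std::uint32_t(1) << group0[i];
  int gsize = (int)group0.size();
  int m1 = p + 1;

  // cross-products of [1, X]
  std::vector<double> Gxx(m1 * m1, 0.0);
  Gxx[0] = (double)n;
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j);
    Gxx[(j + 1) * m1 + 0] = Gxx[0 * m1 + (j + 1)] = s;
    for (int k = 0; k <= j; ++k) {
      double ss = 0;
      for (int i = 0; i < n; ++i) ss += X(i, j) * X(i, k);
      Gxx[(j + 1) * m1 + (k + 1)] = Gxx[(k + 1) * m1 + (j + 1)] = ss;
    }
  }

  MaskTables T;
  build_mask_tables(T, Gxx, p, gmask);

  std::vector<double> lam(lambdas.begin(), lambdas.end());

  // observed statistic
  std::vector<double> v(m1);
  double yty = 0;
  for (int i = 0; i < n; ++i) yty += y[i] * y[i];
  v[0] = 0;
  for (int i = 0; i < n; ++i) v[0] += y[i];
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j) * y[i];
    v[j + 1] = s;
  }
  NumericVector mvi_obs(L);
  mvi_for_response(T, v, yty, (double)n, lam, gsize, mvi_obs.begin());

  // reduced model: all predictors except the group
  std::vector<int> red_idx;
  red_idx.push_back(0);
  for (int j = 0; j < p; ++j)
    if (!(gmask & (std::uint32_t(1) << j))) red_idx.push_back(j + 1);
  int mr = (int)red_idx.size();
  std::vector<double> Mr(mr * mr), dr(mr), vr(mr);
  for (int a = 0; a < mr; ++a) {
    for (int b = 0; b <= a; ++b) Mr[a * mr + b] = Gxx[red_idx[b] * m1 + red_idx[a]];
    dr[a] = Gxx[red_idx[a] * m1 + red_idx[a]];
    vr[a] = v[red_idx[a]];
  }
  int bad = chol_lower(Mr, dr, mr);
  if (bad >= 0)
    stop("reduced model is rank deficient (column %d)", red_idx[bad]);
  forward_solve(Mr, mr, vr);
  double rss_red = yty;
  for (int a = 0; a < mr; ++a) rss_red -= vr[a] * vr[a];
  if (rss_red <= 0)
    stop("degenerate reduced-model fit: residual sum of squares is not positive");
  back_solve(Mr, mr, vr);  // vr := beta_reduced
  double sigma2 = sigma_mle ? rss_red / n : rss_red / (n - mr);
  double sigma = std::sqrt(sigma2);

  std::vector<double> fitted(n);
  for (int i = 0; i < n; ++i) {
    double mu = vr[0];
    for (int a = 1; a < mr; ++a) mu += X(i, red_idx[a] - 1) * vr[a];
    fitted[i] = mu;
  }

  NumericMatrix draws(B, L);
  std::vector<double> ystar(n), vb(m1), row(L);
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    double yy = 0, sy = 0;
    for (int i = 0; i < n; ++i) {
      double yi = fitted[i] + sigma * norm_rand();
      ystar[i] = yi;
      yy += yi * yi;
      sy += yi;
    }
    vb[0] = sy;
    for (int j = 0; j < p; ++j) {
      double s = 0;
      for (int i = 0; i < n; ++i) s += X(i, j) * ystar[i];
      vb[j + 1] = s;
    }
    mvi_for_response(T, vb, yy, (double)n, lam, gsize, &row[0]);
    for (int l = 0; l < L; ++l) draws(b, l) = row[l];
  }

  return List::create(_["mvi_obs"] = mvi_obs, _["draws"] = draws,
                      _["sigma2"] = sigma2, _["rss_reduced"] = rss_red,
                      _["n_searches"] = 2.0 * B * L);
}
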
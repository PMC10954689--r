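#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Incrementally maintained Cholesky factor of M_AA = G_AA/m + alpha2 I for a
// working set A. Adding a variable extends L by one row (O(d^2)); dropping
// one refactors from scratch (rare). Row-major, leading dimension `ld`.
struct WorkingChol {
  std::vector<double> L;
  std::vector<int> A;
  int ld;
  const double* G;
  int N, m;
  double alpha2;

  WorkingChol(const double* G_, int N_, int m_, double alpha2_)
    : L((size_t)N_ * N_), ld(N_), G(G_), N(N_), m(m_), alpha2(alpha2_) {}

  // returns 0 on a non-positive pivot (rank deficiency, e.g. alpha2 = 0
  // with linearly dependent columns)
  int add(int j) {
    int d = (int)A.size();
    if (d >= ld) return 0;
    const double* Gj = G + (size_t)j * N;
    double* Ld = &L[(size_t)d * ld];
    for (int i = 0; i < d; ++i) {
      double s = Gj[A[i]] / m;
      const double* Li = &L[(size_t)i * ld];
      for (int k = 0; k < i; ++k) s -= Li[k] * Ld[k];
      Ld[i] = s / Li[i];
    }
    double s = Gj[j] / m + alpha2;
    for (int k = 0; k < d; ++k) s -= Ld[k] * Ld[k];
    if (s <= 1e-14) return 0;
    Ld[d] = std::sqrt(s);
    A.push_back(j);
    return 1;
  }

  int drop(int pos) {
    std::vector<int> keep(A);
    keep.erase(keep.begin() + pos);
    A.clear();
    for (size_t i = 0; i < keep.size(); ++i)
      if (!add(keep[i])) return 0;
    return 1;
  }

  // solve M_AA x = rhs with rhs_i = xty[A_i]/m - alpha
  void solve(const double* xty, double alpha, std::vector<double>& x) const {
    int d = (int)A.size();
    x.resize(d);
    for (int i = 0; i < d; ++i) {
      double s = xty[A[i]] / m - alpha;
      const double* Li = &L[(size_t)i * ld];
      for (int k = 0; k < i; ++k) s -= Li[k] * x[k];
      x[i] = s / Li[i];
    }
    for (int i = d - 1; i >= 0; --i) {
      double s = x[i];
      for (int k = i + 1; k < d; ++k) s -= L[(size_t)k * ld + i] * x[k];
      x[i] = s / L[(size_t)i * ld + i];
    }
  }
};

// Active-set (Lawson-Hanson style) finisher: starting from the support that
// coordinate descent identified, alternately (a) minimize exactly over the
// working set, dropping coordinates the solve sends negative, and (b) scan
// dual feasibility of the zero coordinates, admitting the worst violator.
// Commits w/act and returns 1 only when the KKT conditions hold, i.e. w is
// the exact optimum; returns 0 untouched on rank deficiency or cycling.
static int newton_refine(const double* G, int N, int m, const double* xty,
                         double alpha, double alpha2,
                         std::vector<double>& w, std::vector<int>& act) {
  if (act.empty()) return 0;
  WorkingChol wc(G, N, m, alpha2);
  for (size_t i = 0; i < act.size(); ++i)
    if (!wc.add(act[i])) return 0;
  std::vector<double> sol;
  std::vector<char> in_A(N, 0);
  for (size_t i = 0; i < act.size(); ++i) in_A[act[i]] = 1;
  for (int outer = 0; outer < 4 * N; ++outer) {
    int ok = 0;
    for (int inner = 0; inner < (int)wc.A.size() + 8; ++inner) {
      if (wc.A.empty()) return 0;
      wc.solve(xty, alpha, sol);
      std::vector<int> keep;
      for (size_t i = 0; i < sol.size(); ++i) {
        if (sol[i] >= 0.0) keep.push_back(wc.A[i]);
        else in_A[wc.A[i]] = 0;
      }
      if (keep.size() == wc.A.size()) { ok = 1; break; }
      // drop every negative coordinate, then refactor once
      wc.A.clear();
      int good = 1;
      for (size_t i = 0; i < keep.size(); ++i)
        if (!wc.add(keep[i])) { good = 0; break; }
      if (!good) return 0;
    }
    if (!ok) return 0;
    // dual feasibility over the zero coordinates
    int viol = -1;
    double worst_g = -1e-10;
    for (int j = 0; j < N; ++j) {
      if (in_A[j] || xty[j] / m <= alpha) continue;  // screened coordinates
      const double* Gj = G + (size_t)j * N;
      double dot = 0.0;
      for (size_t i = 0; i < wc.A.size(); ++i) dot += Gj[wc.A[i]] * sol[i];
      double g = (dot - xty[j]) / m + alpha;
      if (g < worst_g) { worst_g = g; viol = j; }
    }
    if (viol < 0) {
      for (size_t a = 0; a < act.size(); ++a) w[act[a]] = 0.0;
      for (size_t i = 0; i < wc.A.size(); ++i) w[wc.A[i]] = sol[i];
      act = wc.A;
      return 1;
    }
    if (!wc.add(viol)) return 0;
    in_A[viol] = 1;
  }
  return 0;
}

// Solver for the non-negative elastic net on one pixel:
//   min_{w >= 0}  1/(2m) ||y - X w||^2 + alpha ||w||_1 + (alpha2/2) ||w||_2^2
// expressed through the Gram matrix G = X'X and the correlation vector
// xty = X'y, so the image Y never has to be revisited per iteration.
// Coordinate descent identifies the support (on w >= 0 the L1 term is
// linear, so the objective is a smooth quadratic on the orthant and each
// exact coordinate step's decrement is available in closed form); the
// active-set finisher then lands on the exact optimum. Convergence: KKT via
// newton_refine, max coordinate change < tol, or a full sweep lowering the
// objective by less than ftol. Returns 1 on convergence.
static int cd_solve(const double* G, int N, int m, const double* xty,
                    double alpha, double alpha2, double tol, double ftol,
                    int maxit, std::vector<double>& w, std::vector<int>& act) {
  double dec1 = -1.0;
  for (int it = 0; it < maxit; ++it) {
    double maxdel = 0.0, dec = 0.0;
    for (int j = 0; j < N; ++j) {
      // screening: with a nonnegative design (binary X) and w >= 0 the
      // residual correlation can only shrink, so an inactive coordinate whose
      // marginal correlation is below the L1 threshold stays at zero
      if (w[j] == 0.0 && xty[j] / m <= alpha) continue;
      double dot = 0.0;
      const double* Gj = G + (size_t)j * N;
      for (size_t a = 0; a < act.size(); ++a) {
        int l = act[a];
        if (l != j) dot += Gj[l] * w[l];
      }
      double curv = Gj[j] / m + alpha2;
      double num = (xty[j] - dot) / m - alpha;
      double wn = (num > 0.0) ? num / curv : 0.0;
      if (wn != w[j]) {
        double del = wn - w[j];
        // gradient of the smooth-on-orthant objective at the current w_j
        double g = (dot + Gj[j] * w[j] - xty[j]) / m + alpha + alpha2 * w[j];
        dec -= g * del + 0.5 * curv * del * del;
        if (std::fabs(del) > maxdel) maxdel = std::fabs(del);
        if (w[j] == 0.0 && wn > 0.0) {
          act.push_back(j);
        } else if (w[j] > 0.0 && wn == 0.0) {
          for (size_t a = 0; a < act.size(); ++a)
            if (act[a] == j) { act[a] = act.back(); act.pop_back(); break; }
        }
        w[j] = wn;
      }
    }
    if (dec1 < 0.0) dec1 = dec;
    if (maxdel < tol || dec < ftol) return 1;
    // crowded supports: a stalled objective cannot change the elbow verdict
    if (act.size() > 48 && dec < 1e-8 * dec1) return 1;
    // after support identification, try to finish exactly; retry sparsely
    if ((it == 2 || (it > 2 && it % 64 == 0)) &&
        newton_refine(G, N, m, xty, alpha, alpha2, w, act))
      return 1;
  }
  return 0;
}

// Elbow filter + OLS refit on the Gram system. Fills sup (1-based, 0 = none)
// and wols. Negative refit weights are clipped by support reduction.
static void elbow_ols(const double* G, int N, const double* xty,
                      const std::vector<double>& w, const std::vector<int>& act,
                      double second_ratio, double third_ratio,
                      int* sup, double* wols) {
  sup[0] = sup[1] = 0;
  wols[0] = wols[1] = 0.0;
  int i1 = -1, i2 = -1, i3 = -1;
  double w1 = 0.0, w2 = 0.0, w3 = 0.0;
  for (size_t a = 0; a < act.size(); ++a) {
    int j = act[a];
    double v = w[j];
    if (v > w1 || (v == w1 && i1 >= 0 && j < i1)) {
      i3 = i2; w3 = w2; i2 = i1; w2 = w1; i1 = j; w1 = v;
    } else if (v > w2 || (v == w2 && i2 >= 0 && j < i2)) {
      i3 = i2; w3 = w2; i2 = j; w2 = v;
    } else if (v > w3 || (v == w3 && i3 >= 0 && j < i3)) {
      i3 = j; w3 = v;
    }
  }
  if (i1 < 0 || w1 <= 0.0) return;
  bool top1 = (w2 < second_ratio * w1);
  bool top2 = !top1 && (w3 < third_ratio * w1);
  if (!top1 && !top2) return;
  if (top1 || i2 < 0) {
    double g = G[(size_t)i1 * N + i1];
    double b = (g > 0.0) ? xty[i1] / g : 0.0;
    if (b <= 0.0) return;
    sup[0] = i1 + 1; wols[0] = b;
    return;
  }
  // 2x2 normal equations on the Gram entries
  double g11 = G[(size_t)i1 * N + i1], g22 = G[(size_t)i2 * N + i2];
  double g12 = G[(size_t)i1 * N + i2];
  double det = g11 * g22 - g12 * g12;
  if (det <= 1e-12 * g11 * g22) {  // near-identical columns: keep top 1
    double b = xty[i1] / g11;
    if (b <= 0.0) return;
    sup[0] = i1 + 1; wols[0] = b;
    return;
  }
  double b1 = (g22 * xty[i1] - g12 * xty[i2]) / det;
  double b2 = (g11 * xty[i2] - g12 * xty[i1]) / det;
  if (b1 > 0.0 && b2 > 0.0) {
    sup[0] = i1 + 1; wols[0] = b1;
    sup[1] = i2 + 1; wols[1] = b2;
  } else if (b1 <= 0.0 && b2 <= 0.0) {
    return;
  } else {
    int keep = (b1 > 0.0) ? i1 : i2;
    double b = xty[keep] / G[(size_t)keep * N + keep];
    if (b <= 0.0) return;
    sup[0] = keep + 1; wols[0] = b;
  }
}

// [[Rcpp::export]]
List cpp_spd_batch(NumericMatrix XtY, NumericMatrix G, int m, NumericVector alpha,
                   double ratio, double second_ratio, double third_ratio,
                   double tol, double ftol, int maxit, bool keep_lasso) {
  int N = G.nrow(), P = XtY.ncol();
  IntegerMatrix sup(2, P);
  NumericMatrix wols(2, P);
  NumericVector l1(P);
  IntegerVector nnz(P), conv(P);
  std::vector<int> li, lj;
  std::vector<double> lx;
  std::vector<double> w(N, 0.0);
  std::vector<int> act;
  const double* Gp = G.begin();
  for (int p = 0; p < P; ++p) {
    std::fill(w.begin(), w.end(), 0.0);
    act.clear();
    const double* xty = &XtY(0, p);
    double a = alpha[p];
    conv[p] = cd_solve(Gp, N, m, xty, a, a * ratio, tol, ftol, maxit, w, act);
    double s = 0.0;
    for (size_t q = 0; q < act.size(); ++q) s += w[act[q]];
    l1[p] = s;
    nnz[p] = (int)act.size();
    if (conv[p]) {
      elbow_ols(Gp, N, xty, w, act, second_ratio, third_ratio,
                &sup(0, p), &wols(0, p));
    }
    if (keep_lasso) {
      for (size_t q = 0; q < act.size(); ++q) {
        li.push_back(act[q] + 1);
        lj.push_back(p + 1);
        lx.push_back(w[act[q]]);
      }
    }
  }
  List out = List::create(_["support"] = sup, _["w_ols"] = wols,
                          _["l1_lasso"] = l1, _["nnz"] = nnz,
                          _["converged"] = conv);
  if (keep_lasso)
    out["lasso"] = DataFrame::create(_["barcode"] = wrap(li), _["pixel"] = wrap(lj),
                                     _["weight"] = wrap(lx));
  return out;
}

// L1 norm of the elbow-filtered OLS refit for every pixel at every alpha in a
// descending grid (warm starts across the path). Rows = pixels, cols = grid.
// [[Rcpp::export]]
NumericMatrix cpp_spd_grid_l1(NumericMatrix XtY, NumericMatrix G, int m,
                              NumericVector alpha_desc, double ratio,
                              double second_ratio, double third_ratio,
                              double tol, double ftol, int maxit) {
  int N = G.nrow(), P = XtY.ncol(), A = alpha_desc.size();
  NumericMatrix out(P, A);
  std::vector<double> w(N, 0.0);
  std::vector<int> act;
  int sup[2];
  double wolsv[2];
  const double* Gp = G.begin();
  for (int p = 0; p < P; ++p) {
    const double* xty = &XtY(0, p);
    for (int a = 0; a < A; ++a) {
      double al = alpha_desc[a];
      std::fill(w.begin(), w.end(), 0.0);
      act.clear();
      int ok = cd_solve(Gp, N, m, xty, al, al * ratio, tol, ftol, maxit, w, act);
      double s = 0.0;
      if (ok) {
        elbow_ols(Gp, N, xty, w, act, second_ratio, third_ratio, sup, wolsv);
        if (sup[0]) s += wolsv[0];
        if (sup[1]) s += wolsv[1];
      }
      out(p, a) = s;
    }
  }
  return out;
}

// Additive rendering of isotropic Gaussian spots into an (H, W, C) array.
// Coordinates are 0-based pixel-centered; each spot writes its peak-scaled
// Gaussian within +/- 4 sigma into the planes listed in its row of `planes`.
// [[Rcpp::export]]
NumericVector cpp_render_spots(NumericVector stack, int H, int W,
                               NumericVector row0, NumericVector col0,
                               NumericVector peak, NumericVector sigma,
                               IntegerMatrix planes) {
  int n = row0.size(), k = planes.ncol();
  double* s = stack.begin();
  for (int i = 0; i < n; ++i) {
    double r0 = row0[i], c0 = col0[i], pk = peak[i], sg = sigma[i];
    double inv = 1.0 / (2.0 * sg * sg);
    int rmin = std::max(0, (int)std::ceil(r0 - 4.0 * sg));
    int rmax = std::min(H - 1, (int)std::floor(r0 + 4.0 * sg));
    int cmin = std::max(0, (int)std::ceil(c0 - 4.0 * sg));
    int cmax = std::min(W - 1, (int)std::floor(c0 + 4.0 * sg));
    for (int c = cmin; c <= cmax; ++c) {
      double dc = c - c0;
      for (int r = rmin; r <= rmax; ++r) {
        double dr = r - r0;
        double v = pk * std::exp(-(dr * dr + dc * dc) * inv);
        for (int q = 0; q < k; ++q) {
          int pl = planes(i, q) - 1;
          s[((size_t)pl * W + c) * H + r] += v;
        }
      }
    }
  }
  return stack;
}

// Randomized maximal-independent-set search: each run extends the seed set by
// scanning a fresh uniformly random node order (R's RNG), keeping nodes whose
// neighbors are not yet in the set. `comp` assigns each node to a connected
// component (0-based); because runs decompose over components, the returned
// set is the union over components of the best sub-set seen in any run,
// which is itself a maximal independent set containing the seed.
// [[Rcpp::export]]
List cpp_mis_search(List adj, IntegerVector seed, int n_runs,
                    IntegerVector comp) {
  int n = adj.size();
  int K = 0;
  for (int i = 0; i < n; ++i) if (comp[i] + 1 > K) K = comp[i] + 1;
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i].assign(v.begin(), v.end());
    for (size_t q = 0; q < nb[i].size(); ++q) nb[i][q]--;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<unsigned char> state(n);
  std::vector<std::vector<int> > comp_best(K), comp_cur(K);
  IntegerVector sizes(n_runs);
  int best_single = 0;
  for (int run = 0; run < n_runs; ++run) {
    std::fill(state.begin(), state.end(), 0);  // 0 free, 1 in, 2 blocked
    for (int c = 0; c < K; ++c) comp_cur[c].clear();
    for (int q = 0; q < seed.size(); ++q) {
      int v = seed[q] - 1;
      state[v] = 1;
      comp_cur[comp[v]].push_back(v);
      for (size_t t = 0; t < nb[v].size(); ++t)
        if (state[nb[v][t]] == 0) state[nb[v][t]] = 2;
    }
    // Fisher-Yates with R's RNG for reproducibility under set.seed()
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int i = 0; i < n; ++i) {
      int v = order[i];
      if (state[v] != 0) continue;
      state[v] = 1;
      comp_cur[comp[v]].push_back(v);
      for (size_t t = 0; t < nb[v].size(); ++t)
        if (state[nb[v][t]] == 0) state[nb[v][t]] = 2;
    }
    int tot = 0;
    for (int c = 0; c < K; ++c) {
      tot += (int)comp_cur[c].size();
      if (comp_cur[c].size() > comp_best[c].size()) comp_best[c] = comp_cur[c];
    }
    sizes[run] = tot;
    if (tot > best_single) best_single = tot;
  }
  std::vector<int> best;
  for (int c = 0; c < K; ++c)
    best.insert(best.end(), comp_best[c].begin(), comp_best[c].end());
  IntegerVector bv(best.size());
  for (size_t i = 0; i < best.size(); ++i) bv[i] = best[i] + 1;
  return List::create(_["best"] = bv, _["sizes"] = sizes,
                      _["best_single_run"] = best_single);
}
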
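// Fast engine for the discrete additive-noise-model causation statistic.
//
// Everything here is a function of the x-by-y contingency table: the
// integer regression (conditional mode, optionally refined to minimize
// residual-cause dependence), the residual-by-cause table, and the
// dependence measure Delta = -log10(p) with Fisher's exact test on small
// tables and the Pearson chi-square test otherwise. The permutation null
// (random tables with the observed margins) is evaluated in bulk.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// log-factorial table, rebuilt when n grows
static std::vector<double> lfact_tab;
static void ensure_lfact(int n) {
  int old = (int)lfact_tab.size();
  if (old > n) return;
  lfact_tab.resize(n + 1);
  if (old == 0) { lfact_tab[0] = 0.0; old = 1; }
  for (int i = old; i <= n; ++i) lfact_tab[i] = lfact_tab[i - 1] + std::log((double)i);
}
static inline double lfact(int n) { return lfact_tab[n]; }

// two-sided Fisher exact p for a 2 x 2 table
static double fisher_2x2(int a, int b, int c, int d) {
  int r0 = a + b, r1 = c + d, c0 = a + c, c1 = b + d, n = r0 + r1;
  ensure_lfact(n);
  double base = lfact(r0) + lfact(r1) + lfact(c0) + lfact(c1) - lfact(n);
  double lp_obs = base - lfact(a) - lfact(b) - lfact(c) - lfact(d);
  int lo = std::max(0, r0 - c1), hi = std::min(r0, c0);
  double cutoff = lp_obs + 1e-7;
  double psum = 0.0;
  for (int x = lo; x <= hi; ++x) {
    double lp = base - lfact(x) - lfact(r0 - x) - lfact(c0 - x)
                - lfact(r1 - c0 + x);
    if (lp <= cutoff) psum += std::exp(lp);
  }
  return std::min(psum, 1.0);
}

// two-sided Fisher exact p for a 2 x 3 table by enumeration
static double fisher_2x3(const int t[2][3]) {
  int r0 = t[0][0] + t[0][1] + t[0][2];
  int r1 = t[1][0] + t[1][1] + t[1][2];
  int c0 = t[0][0] + t[1][0], c1 = t[0][1] + t[1][1], c2 = t[0][2] + t[1][2];
  int n = r0 + r1;
  ensure_lfact(n);
  double base = lfact(r0) + lfact(r1) + lfact(c0) + lfact(c1) + lfact(c2)
                - lfact(n);
  double lp_obs = base - lfact(t[0][0]) - lfact(t[0][1]) - lfact(t[0][2])
                  - lfact(t[1][0]) - lfact(t[1][1]) - lfact(t[1][2]);
  double cutoff = lp_obs + 1e-7;
  double psum = 0.0;
  int ahi = std::min(r0, c0);
  for (int a = 0; a <= ahi; ++a) {
    int bhi = std::min(r0 - a, c1);
    for (int b = 0; b <= bhi; ++b) {
      int cc = r0 - a - b;
      if (cc > c2) continue;
      double lp = base - lfact(a) - lfact(b) - lfact(cc)
                  - lfact(c0 - a) - lfact(c1 - b) - lfact(c2 - cc);
      if (lp <= cutoff) psum += std::exp(lp);
    }
  }
  return std::min(psum, 1.0);
}

// chi-square p (no continuity correction) from sparse nonzero cells;
// rs/cs are the positive row/column sums
static double chisq_p_sparse(const std::vector<int>& cnt,
                             const std::vector<int>& row,
                             const std::vector<int>& col,
                             const std::vector<double>& rs,
                             const std::vector<double>& cs, double n) {
  double s = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k)
    s += (double)cnt[k] * (double)cnt[k] / (rs[row[k]] * cs[col[k]]);
  double stat = n * s - n;
  if (stat < 0) stat = 0;
  double df = (double)(rs.size() - 1) * (double)(cs.size() - 1);
  return R::pchisq(stat, df, 0, 0);
}

// Delta = -log10(p) for a residual-by-cause table given as nonzero cells.
// Rows/cols with zero totals are absent by construction. Degenerate
// (single row or column) tables return 0.
static double delta_cells(const std::vector<int>& cnt,
                          const std::vector<int>& row,
                          const std::vector<int>& col,
                          int nrow, int ncol, int fisher_max_cells) {
  if (nrow < 2 || ncol < 2) return 0.0;
  std::vector<double> rs(nrow, 0.0), cs(ncol, 0.0);
  double n = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    rs[row[k]] += cnt[k]; cs[col[k]] += cnt[k]; n += cnt[k];
  }
  double p;
  if (nrow * ncol <= fisher_max_cells &&
      ((nrow == 2 && ncol <= 3) || (ncol == 2 && nrow <= 3))) {
    // densify (tiny) and use the exact test
    std::vector<int> dense(nrow * ncol, 0);
    for (size_t k = 0; k < cnt.size(); ++k) dense[row[k] * ncol + col[k]] = cnt[k];
    if (nrow == 2 && ncol == 2) {
      p = fisher_2x2(dense[0], dense[1], dense[2], dense[3]);
    } else if (nrow == 2 && ncol == 3) {
      int t[2][3] = {{dense[0], dense[1], dense[2]},
                     {dense[3], dense[4], dense[5]}};
      p = fisher_2x3(t);
    } else { // 3 x 2: transpose
      int t[2][3] = {{dense[0], dense[2], dense[4]},
                     {dense[1], dense[3], dense[5]}};
      p = fisher_2x3(t);
    }
  } else {
    p = chisq_p_sparse(cnt, row, col, rs, cs, n);
  }
  if (p < DBL_MIN) p = DBL_MIN;
  return -std::log10(p);
}

// Dependence of residuals y - f(x) on x, for the fit f(x_i) = yv[a[i]].
// T is nx x ny counts (no all-zero rows), yv the response values.
static double delta_for_assignment(const IntegerMatrix& T,
                                   const NumericVector& yv,
                                   const std::vector<int>& a,
                                   int fisher_max_cells) {
  int nx = T.nrow(), ny = T.ncol();
  std::map<double, int> rowid;
  std::vector<int> cnt, row, col;
  cnt.reserve(nx * ny); row.reserve(nx * ny); col.reserve(nx * ny);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      int c = T(i, j);
      if (c == 0) continue;
      double rv = yv[j] - yv[a[i]];
      auto it = rowid.find(rv);
      int rid;
      if (it == rowid.end()) { rid = (int)rowid.size(); rowid[rv] = rid; }
      else rid = it->second;
      cnt.push_back(c); row.push_back(rid); col.push_back(i);
    }
  }
  // column ids must be compacted in case a row of T is empty (callers
  // trim, but keep this safe)
  return delta_cells(cnt, row, col, (int)rowid.size(), nx, fisher_max_cells);
}

// conditional mode of row i with ties broken toward the weighted median,
// then the smaller value; returns the column index
static int mode_index(const IntegerMatrix& T, const NumericVector& yv, int i) {
  int ny = T.ncol();
  int mx = 0;
  double tot = 0.0;
  for (int j = 0; j < ny; ++j) { if (T(i, j) > mx) mx = T(i, j); tot += T(i, j); }
  // weighted median: first value with cumulative weight fraction >= 0.5
  double cum = 0.0; double med = yv[ny - 1];
  for (int j = 0; j < ny; ++j) {
    cum += T(i, j);
    if (cum / tot >= 0.5) { med = yv[j]; break; }
  }
  int best = -1; double bestd = DBL_MAX;
  for (int j = 0; j < ny; ++j) {
    if (T(i, j) != mx) continue;
    double d = std::fabs(yv[j] - med);
    if (d < bestd - 1e-15) { bestd = d; best = j; }
    // equal distance: earlier (smaller) value wins; j ascending ensures it
  }
  return best;
}

// Delta for direction cause -> response from the cause-by-response count
// matrix. refine = coordinate-descent over f values minimizing Delta,
// started at the conditional mode (deterministic sweeps and tie-breaks).
static double direction_delta_engine(const IntegerMatrix& T,
                                     const NumericVector& yv,
                                     bool refine, int fisher_max_cells) {
  int nx = T.nrow(), ny = T.ncol();
  std::vector<int> a(nx);
  for (int i = 0; i < nx; ++i) a[i] = mode_index(T, yv, i);
  double d = delta_for_assignment(T, yv, a, fisher_max_cells);
  if (!refine) return d;
  for (int sweep = 0; sweep < 10; ++sweep) {
    bool changed = false;
    for (int i = 0; i < nx; ++i) {
      int bi = a[i]; double best = d;
      int keep = a[i];
      for (int c = 0; c < ny; ++c) {
        if (c == keep) continue;
        a[i] = c;
        double d2 = delta_for_assignment(T, yv, a, fisher_max_cells);
        if (d2 < best - 1e-12) { best = d2; bi = c; }
      }
      a[i] = bi;
      if (bi != keep) { d = best; changed = true; }
    }
    if (!changed) break;
  }
  return d;
}

// trim all-zero rows/columns of a table, keeping value labels aligned
// and sorting levels ascending (the mode/median scans assume it)
static void trim_table(const IntegerMatrix& T, const NumericVector& xv,
                       const NumericVector& yv, IntegerMatrix& Tt,
                       NumericVector& xvt, NumericVector& yvt) {
  int nx = T.nrow(), ny = T.ncol();
  std::vector<int> ri, ci;
  for (int i = 0; i < nx; ++i) {
    int s = 0; for (int j = 0; j < ny; ++j) s += T(i, j);
    if (s > 0) ri.push_back(i);
  }
  for (int j = 0; j < ny; ++j) {
    int s = 0; for (int i = 0; i < nx; ++i) s += T(i, j);
    if (s > 0) ci.push_back(j);
  }
  std::sort(ri.begin(), ri.end(),
            [&](int a, int b) { return xv[a] < xv[b]; });
  std::sort(ci.begin(), ci.end(),
            [&](int a, int b) { return yv[a] < yv[b]; });
  Tt = IntegerMatrix((int)ri.size(), (int)ci.size());
  xvt = NumericVector((int)ri.size());
  yvt = NumericVector((int)ci.size());
  for (size_t i = 0; i < ri.size(); ++i) {
    xvt[i] = xv[ri[i]];
    for (size_t j = 0; j < ci.size(); ++j) Tt(i, j) = T(ri[i], ci[j]);
  }
  for (size_t j = 0; j < ci.size(); ++j) yvt[j] = yv[ci[j]];
}

static IntegerMatrix transpose_int(const IntegerMatrix& T) {
  IntegerMatrix R(T.ncol(), T.nrow());
  for (int i = 0; i < T.nrow(); ++i)
    for (int j = 0; j < T.ncol(); ++j) R(j, i) = T(i, j);
  return R;
}

// [[Rcpp::export(name = ".tc_engine")]]
NumericVector tc_engine(IntegerMatrix T, NumericVector xv, NumericVector yv,
                        bool refine = true, int fisher_max_cells = 6) {
  IntegerMatrix Tt; NumericVector xvt, yvt;
  trim_table(T, xv, yv, Tt, xvt, yvt);
  double dxy = direction_delta_engine(Tt, yvt, refine, fisher_max_cells);
  double dyx = direction_delta_engine(transpose_int(Tt), xvt, refine,
                                      fisher_max_cells);
  return NumericVector::create(_["delta_xy"] = dxy, _["delta_yx"] = dyx,
                               _["t_c"] = std::fabs(dxy - dyx));
}

// [[Rcpp::export(name = ".tc_perm_engine")]]
NumericVector tc_perm_engine(List tables, NumericVector xv, NumericVector yv,
                             bool refine = true, int fisher_max_cells = 6) {
  int B = tables.size();
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    IntegerMatrix T = tables[b];
    out[b] = tc_engine(T, xv, yv, refine, fisher_max_cells)[2];
  }
  return out;
}

// [[Rcpp::export(name = ".fisher_exact_small")]]
double fisher_exact_small(IntegerMatrix T) {
  int nr = T.nrow(), nc = T.ncol();
  if (nr == 2 && nc == 2) return fisher_2x2(T(0,0), T(0,1), T(1,0), T(1,1));
  if (nr == 2 && nc == 3) {
    int t[2][3] = {{T(0,0), T(0,1), T(0,2)}, {T(1,0), T(1,1), T(1,2)}};
    return fisher_2x3(t);
  }
  if (nr == 3 && nc == 2) {
    int t[2][3] = {{T(0,0), T(1,0), T(2,0)}, {T(0,1), T(1,1), T(2,1)}};
    return fisher_2x3(t);
  }
  stop("exact test implemented for 2x2, 2x3 and 3x2 tables only");
}
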
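#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase primal simplex on the standard form
//   min c'x  s.t.  A x {<=,=,>=} b,  x >= 0
// sense: -1 (<=), 0 (=), +1 (>=).  Bland's rule throughout, so the
// method cannot cycle; problem sizes here are tiny (toy metabolic
// networks), so the O(m*n) dense pivots are not a concern.
//
// status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.

static const double PIV_TOL = 1e-9;

struct Tableau {
  int m, ncol;                 // active rows, columns (excl. rhs)
  std::vector<std::vector<double> > T; // m rows + objective row, ncol+1 wide
  std::vector<int> basis;      // basis[i] = column basic in row i, -1 inactive
  std::vector<bool> forbidden; // columns that may never enter (artificials)

  void pivot(int pr, int pc) {
    double piv = T[pr][pc];
    for (int j = 0; j <= ncol; ++j) T[pr][j] /= piv;
    for (int i = 0; i <= m; ++i) {
      if (i == pr) continue;
      double f = T[i][pc];
      if (std::fabs(f) < PIV_TOL) { T[i][pc] = 0.0; continue; }
      for (int j = 0; j <= ncol; ++j) T[i][j] -= f * T[pr][j];
      T[i][pc] = 0.0;
    }
    basis[pr] = pc;
  }

  // returns 0 optimal, 2 unbounded, 3 maxit
  // Dantzig pricing for speed; after a run of non-improving (degenerate)
  // pivots, switch to Bland's rule until the objective strictly improves,
  // which guarantees termination.
  int iterate(int maxit) {
    int stalled = 0;
    double last_obj = T[m][ncol];
    for (int it = 0; it < maxit; ++it) {
      bool bland = stalled > 30;
      int pc = -1;
      if (bland) {
        for (int j = 0; j < ncol; ++j) {
          if (forbidden[j]) continue;
          if (T[m][j] < -PIV_TOL) { pc = j; break; }
        }
      } else {
        double most = -PIV_TOL;
        for (int j = 0; j < ncol; ++j) {
          if (forbidden[j]) continue;
          if (T[m][j] < most) { most = T[m][j]; pc = j; }
        }
      }
      if (pc < 0) return 0;
      // ratio test, Bland tie-break on smallest basis index
      int pr = -1; double best = 0.0;
      for (int i = 0; i < m; ++i) {
        if (basis[i] < 0) continue;
        double a = T[i][pc];
        if (a > PIV_TOL) {
          double ratio = T[i][ncol] / a;
          if (pr < 0 || ratio < best - PIV_TOL ||
              (ratio < best + PIV_TOL && basis[i] < basis[pr])) {
            pr = i; best = ratio;
          }
        }
      }
      if (pr < 0) return 2;
      pivot(pr, pc);
      double obj = T[m][ncol];
      if (obj > last_obj + 1e-12) {
        stalled = 0;
        last_obj = obj;
      } else {
        ++stalled;
      }
    }
    return 3;
  }
};

// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(NumericVector cost, NumericMatrix A, NumericVector rhs,
                  IntegerVector sense, int maxit = 50000) {
  int m = A.nrow(), n = A.ncol();
  std::vector<std::vector<double> > rows(m, std::vector<double>(n));
  std::vector<double> b(m);
  std::vector<int> sn(m);
  for (int i = 0; i < m; ++i) {
    double s = (rhs[i] < 0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j) rows[i][j] = s * A(i, j);
    b[i] = s * rhs[i];
    sn[i] = (rhs[i] < 0) ? -sense[i] : sense[i];
  }
  // column layout: vars | slacks/surplus | artificials
  int nslack = 0;
  for (int i = 0; i < m; ++i) if (sn[i] != 0) ++nslack;
  // artificials for rows whose slack cannot start basic (>= and = rows)
  int nart = 0;
  for (int i = 0; i < m; ++i) if (sn[i] >= 0) ++nart;
  int ncol = n + nslack + nart;
  int art0 = n + nslack;

  Tableau tb;
  tb.m = m; tb.ncol = ncol;
  tb.T.assign(m + 1, std::vector<double>(ncol + 1, 0.0));
  tb.basis.assign(m, -1);
  tb.forbidden.assign(ncol, false);

  int sl = n, ar = art0;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) tb.T[i][j] = rows[i][j];
    tb.T[i][ncol] = b[i];
    if (sn[i] < 0) {            // <= : slack enters basis
      tb.T[i][sl] = 1.0; tb.basis[i] = sl; ++sl;
    } else if (sn[i] > 0) {     // >= : surplus + artificial
      tb.T[i][sl] = -1.0; ++sl;
      tb.T[i][ar] = 1.0; tb.basis[i] = ar; ++ar;
    } else {                    // = : artificial
      tb.T[i][ar] = 1.0; tb.basis[i] = ar; ++ar;
    }
  }

  int status;
  if (nart > 0) {
    // phase 1: minimize sum of artificials
    for (int j = art0; j < ncol; ++j) tb.T[m][j] = 1.0;
    for (int i = 0; i < m; ++i) {
      if (tb.basis[i] >= art0) {
        for (int j = 0; j <= ncol; ++j) tb.T[m][j] -= tb.T[i][j];
      }
    }
    status = tb.iterate(maxit);
    if (status == 2) status = 1; // phase-1 unbounded cannot happen; guard
    if (status != 0)
      return List::create(_["status"] = status == 1 ? 1 : 3,
                          _["x"] = NumericVector(n), _["objval"] = NA_REAL);
    double z1 = -tb.T[m][ncol];
    if (z1 > 1e-7)
      return List::create(_["status"] = 1, _["x"] = NumericVector(n),
                          _["objval"] = NA_REAL);
    // drive remaining artificials out of the basis; drop redundant rows
    for (int i = 0; i < m; ++i) {
      if (tb.basis[i] >= art0) {
        int pc = -1;
        for (int j = 0; j < art0; ++j)
          if (std::fabs(tb.T[i][j]) > 1e-7) { pc = j; break; }
        if (pc >= 0) tb.pivot(i, pc);
        else { // redundant constraint
          for (int j = 0; j <= ncol; ++j) tb.T[i][j] = 0.0;
          tb.basis[i] = -1;
        }
      }
    }
    for (int j = art0; j < ncol; ++j) tb.forbidden[j] = true;
  }

  // phase 2
  for (int j = 0; j <= ncol; ++j) tb.T[m][j] = 0.0;
  for (int j = 0; j < n; ++j) tb.T[m][j] = cost[j];
  for (int i = 0; i < m; ++i) {
    int bj = tb.basis[i];
    if (bj >= 0 && bj < n && std::fabs(cost[bj]) > 0) {
      double f = cost[bj];
      for (int j = 0; j <= ncol; ++j) tb.T[m][j] -= f * tb.T[i][j];
    }
  }
  status = tb.iterate(maxit);
  NumericVector x(n);
  for (int i = 0; i < m; ++i) {
    int bj = tb.basis[i];
    if (bj >= 0 && bj < n) x[bj] = tb.T[i][ncol];
  }
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += cost[j] * x[j];
  return List::create(_["status"] = status, _["x"] = x, _["objval"] = obj);
}
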
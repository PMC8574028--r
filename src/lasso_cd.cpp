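#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the L1-penalized least-squares objective
//   sum_i (y_i - x_i' a)^2 + lambda * sum_j |a_j|
// over a decreasing lambda grid with warm starts (covariance updates) and
// active-set cycling: after each full sweep, coordinates in the active set
// are iterated to convergence before the next full sweep confirms the KKT
// conditions for the rest. tol is the convergence threshold on the largest
// coefficient change in a sweep.
// [[Rcpp::export]]
NumericMatrix lasso_cd_path(const NumericMatrix& X, const NumericVector& y,
                            const NumericVector& lambdas,
                            double tol = 1e-11, int max_iter = 50000) {
  const int m = X.nrow(), c = X.ncol(), nl = lambdas.size();
  std::vector<double> XtX((size_t)c * c), Xty(c), xx(c);
  for (int j = 0; j < c; ++j) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += X(i, j) * y[i];
    Xty[j] = s;
    for (int k = j; k < c; ++k) {
      double t = 0.0;
      for (int i = 0; i < m; ++i) t += X(i, j) * X(i, k);
      XtX[(size_t)j * c + k] = t;
      XtX[(size_t)k * c + j] = t;
    }
    xx[j] = XtX[(size_t)j * c + j];
  }
  NumericMatrix out(c, nl);
  std::vector<double> a(c, 0.0);
  std::vector<int> active;
  active.reserve(c);

  auto update_one = [&](int j, double thr) -> double {
    if (xx[j] <= 0.0) { double d = std::fabs(a[j]); a[j] = 0.0; return d; }
    double rho = Xty[j];
    const double* row = &XtX[(size_t)j * c];
    for (int k = 0; k < c; ++k) rho -= row[k] * a[k];
    rho += xx[j] * a[j];
    double anew;
    if (rho > thr) anew = (rho - thr) / xx[j];
    else if (rho < -thr) anew = (rho + thr) / xx[j];
    else anew = 0.0;
    const double del = std::fabs(anew - a[j]);
    a[j] = anew;
    return del;
  };

  for (int l = 0; l < nl; ++l) {
    const double thr = lambdas[l] / 2.0;
    int iter = 0;
    while (iter < max_iter) {
      // full sweep
      double maxdel = 0.0;
      for (int j = 0; j < c; ++j) {
        const double del = update_one(j, thr);
        if (del > maxdel) maxdel = del;
      }
      ++iter;
      if (maxdel < tol) break;
      // cycle on the active set
      active.clear();
      for (int j = 0; j < c; ++j) if (a[j] != 0.0) active.push_back(j);
      while (iter < max_iter) {
        double adel = 0.0;
        for (size_t t = 0; t < active.size(); ++t) {
          const double del = update_one(active[t], thr);
          if (del > adel) adel = del;
        }
        ++iter;
        if (adel < tol) break;
      }
    }
    for (int j = 0; j < c; ++j) out(j, l) = a[j];
  }
  return out;
}
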
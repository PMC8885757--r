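#include <Rcpp.h>
using namespace Rcpp;

// Realized trajectory for one parameter draw at a given K.
// n must have length n_years; eps and catches likewise.
static void project_one(double rmax, double k, double z, double sig,
                        double nc, const double* catches, const double* eps,
                        int n_years, int n_pre, double* n) {
  for (int i = 0; i < n_pre; ++i) n[i] = k * std::exp(sig * eps[i]);
  for (int i = n_pre - 1; i < n_years - 1; ++i) {
    double ni = n[i];
    double ratio = ni / k;
    double f = rmax * ni * (1.0 - std::pow(ratio, z));
    double ntil = ni + f - catches[i];
    if (ntil < nc) ntil = nc;
    n[i + 1] = ntil * std::exp(sig * eps[i + 1]);
  }
}

// Back-solve K for a batch of importance draws.
//
// catches and eps are (n_years x n_draws) matrices; anchor_idx is 0-based.
// Returns the solved K per draw, a feasibility flag, and the realized
// abundance matrix at the solution (NA columns for infeasible draws).
// [[Rcpp::export]]
List sir_backsolve_batch(NumericVector rmax, NumericVector z,
                         NumericVector sigma2, NumericVector nrecent,
                         NumericMatrix catches, NumericMatrix eps,
                         double nc, int anchor_idx, int n_pre,
                         double k_max, double tol) {
  const int n_years = catches.nrow();
  const int n = rmax.size();
  if (eps.nrow() != n_years || eps.ncol() != n || catches.ncol() != n)
    stop("dimension mismatch in sir_backsolve_batch");
  if (anchor_idx < 0 || anchor_idx >= n_years)
    stop("anchor index out of range");

  NumericVector k_out(n);
  LogicalVector feasible(n);
  NumericMatrix N(n_years, n);
  std::vector<double> buf(n_years);

  for (int j = 0; j < n; ++j) {
    const double* cj = &catches(0, j);
    const double* ej = &eps(0, j);
    double sig = std::sqrt(sigma2[j]);
    double target = nrecent[j];

    project_one(rmax[j], k_max, z[j], sig, nc, cj, ej, n_years, n_pre,
                buf.data());
    if (buf[anchor_idx] < target) {
      k_out[j] = NA_REAL;
      feasible[j] = false;
      for (int i = 0; i < n_years; ++i) N(i, j) = NA_REAL;
      continue;
    }
    double lo = target, hi = k_max;
    for (int it = 0; it < 60; ++it) {
      project_one(rmax[j], lo, z[j], sig, nc, cj, ej, n_years, n_pre,
                  buf.data());
      if (buf[anchor_idx] <= target) break;
      lo *= 0.5;
    }
    while ((hi - lo) > tol * hi) {
      double mid = 0.5 * (lo + hi);
      project_one(rmax[j], mid, z[j], sig, nc, cj, ej, n_years, n_pre,
                  buf.data());
      if (buf[anchor_idx] < target) lo = mid; else hi = mid;
    }
    double k = 0.5 * (lo + hi);
    project_one(rmax[j], k, z[j], sig, nc, cj, ej, n_years, n_pre,
                buf.data());
    k_out[j] = k;
    feasible[j] = true;
    for (int i = 0; i < n_years; ++i) N(i, j) = buf[i];
  }
  return List::create(_["k"] = k_out, _["feasible"] = feasible,
                      _["n"] = N);
}
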
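#include <Rcpp.h>
using namespace Rcpp;

// Weighted decision-stump scan over one feature column.
//
// A stump with polarity +1 predicts +1 where x <= threshold and -1
// elsewhere; polarity -1 flips both sides. Candidate thresholds are the
// midpoints between consecutive distinct sorted values plus -Inf/+Inf
// sentinels. Ties are broken toward the smaller threshold, then toward
// polarity +1 (strict '<' while scanning in threshold order guarantees
// both). The running error is accumulated left-to-right so it matches the
// sequential cumsum of the R reference implementation bit for bit.
static void scan_feature(const double* x, const int* ord, const int* y,
                         const double* D, int n, double wpos,
                         double& best_eps, double& best_thr, int& best_pol) {
  best_eps = R_PosInf;
  best_thr = R_NegInf;
  best_pol = 1;
  double err = wpos; // cut s = 0: everything predicted -1 under polarity +1
  for (int s = 0; s <= n; ++s) {
    bool valid;
    double thr;
    if (s == 0) {
      valid = true;
      thr = R_NegInf;
    } else if (s == n) {
      valid = true;
      thr = R_PosInf;
    } else {
      double xl = x[ord[s - 1]], xr = x[ord[s]];
      valid = xl < xr;
      thr = (xl + xr) / 2.0;
    }
    if (valid) {
      if (err < best_eps) {
        best_eps = err;
        best_thr = thr;
        best_pol = 1;
      }
      double err_flip = 1.0 - err;
      if (err_flip < best_eps) {
        best_eps = err_flip;
        best_thr = thr;
        best_pol = -1;
      }
    }
    if (s < n) {
      int i = ord[s];
      if (y[i] > 0) err -= D[i]; else err += D[i];
    }
  }
}

// [[Rcpp::export]]
List stump_scan_cpp(NumericMatrix X, IntegerMatrix ORD, IntegerVector y,
                    NumericVector D, IntegerVector cols) {
  int n = X.nrow();
  int p = cols.size();
  NumericVector eps(p), thr(p);
  IntegerVector pol(p);
  double wpos = 0.0;
  for (int i = 0; i < n; ++i) if (y[i] > 0) wpos += D[i];
  for (int jj = 0; jj < p; ++jj) {
    int j = cols[jj]; // 0-based column index
    scan_feature(&X(0, j), &ORD(0, j), &y[0], &D[0], n,
                 wpos, eps[jj], thr[jj], pol[jj]);
  }
  return List::create(_["epsilon"] = eps, _["threshold"] = thr,
                      _["polarity"] = pol);
}

// Full AdaBoost forward-selection loop: each round fits one stump per
// remaining feature under the current sample weights, moves the
// minimum-error feature (ties -> lowest column index) into the selected
// set, and reweights samples with the winning stump's predictions.
// [[Rcpp::export]]
List select_core_cpp(NumericMatrix X, IntegerMatrix ORD, IntegerVector y,
                     NumericVector D0, int k, double eps_clamp) {
  int n = X.nrow();
  int p = X.ncol();
  std::vector<bool> active(p, true);
  NumericVector D = clone(D0);
  IntegerVector sel(k), sel_pol(k);
  NumericVector sel_eps(k), sel_thr(k), sel_beta(k);
  for (int t = 0; t < k; ++t) {
    double wpos = 0.0;
    for (int i = 0; i < n; ++i) if (y[i] > 0) wpos += D[i];
    double best_eps = R_PosInf, best_thr = 0.0;
    int best_pol = 1, best_j = -1;
    for (int j = 0; j < p; ++j) {
      if (!active[j]) continue;
      double e, th;
      int pl;
      scan_feature(&X(0, j), &ORD(0, j), &y[0], &D[0], n, wpos, e, th, pl);
      if (e < best_eps) {
        best_eps = e;
        best_thr = th;
        best_pol = pl;
        best_j = j;
      }
    }
    double eps_c = best_eps;
    if (eps_c < eps_clamp) eps_c = eps_clamp;
    if (eps_c > 1.0 - eps_clamp) eps_c = 1.0 - eps_clamp;
    double beta = 0.5 * std::log((1.0 - eps_c) / eps_c);
    // reweight: correct predictions shrink by e^-beta, mistakes grow
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      double xv = X(i, best_j);
      int pred;
      if (best_thr == R_PosInf) pred = best_pol;
      else if (best_thr == R_NegInf) pred = -best_pol;
      else pred = (xv <= best_thr) ? best_pol : -best_pol;
      D[i] *= (pred == y[i]) ? std::exp(-beta) : std::exp(beta);
      total += D[i];
    }
    for (int i = 0; i < n; ++i) D[i] /= total;
    active[best_j] = false;
    sel[t] = best_j + 1; // 1-based for R
    sel_eps[t] = best_eps;
    sel_thr[t] = best_thr;
    sel_pol[t] = best_pol;
    sel_beta[t] = beta;
  }
  return List::create(_["feature"] = sel, _["epsilon"] = sel_eps,
                      _["beta"] = sel_beta, _["threshold"] = sel_thr,
                      _["polarity"] = sel_pol, _["D"] = D);
}
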
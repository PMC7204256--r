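#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sweep over the random effects u.
//
// For each sample i (in order), draws
//   u_i | rest ~ N( (1 + c_ii * gamma)^{-1} * (resid_i - gamma * c_{i,-i} u_{-i}),
//                   (1 + c_ii * gamma)^{-1} )
// where resid = l - X beta, C = A^{-1}, c_ii its diagonal, gamma = 1/sigma_u2.
// The running product s = C u is updated incrementally so the sweep costs
// O(n^2) instead of O(n^3). Uses R's RNG, so results are reproducible under
// set.seed().
// [[Rcpp::export]]
NumericVector gibbs_u_sweep(NumericVector resid, NumericMatrix Cinv,
                            NumericVector u, double gamma) {
  int n = u.size();
  if (resid.size() != n || Cinv.nrow() != n || Cinv.ncol() != n)
    stop("gibbs_u_sweep: dimension mismatch");
  NumericVector unew = clone(u);
  std::vector<double> s(n, 0.0);
  for (int j = 0; j < n; ++j) {
    double uj = unew[j];
    if (uj != 0.0) {
      const double* col = &Cinv(0, j);
      for (int i = 0; i < n; ++i) s[i] += col[i] * uj;
    }
  }
  for (int i = 0; i < n; ++i) {
    double cii = Cinv(i, i);
    double cross = s[i] - cii * unew[i];  // c_{i,-i} . u_{-i}
    double prec = 1.0 + cii * gamma;
    double mean = (resid[i] - gamma * cross) / prec;
    double draw = mean + ::norm_rand() / std::sqrt(prec);
    double delta = draw - unew[i];
    if (delta != 0.0) {
      const double* col = &Cinv(0, i);
      for (int k = 0; k < n; ++k) s[k] += col[k] * delta;
    }
    unew[i] = draw;
  }
  return unew;
}
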
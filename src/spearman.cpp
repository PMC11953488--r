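#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Exact permutation p-value for the Spearman correlation: enumerate every
// distinct arrangement of the y mid-ranks against the fixed x mid-ranks and
// count arrangements whose |rho| >= |rho_obs|. With tied ranks each distinct
// arrangement has the same multiplicity under the uniform distribution over
// the n! pairings, so enumerating distinct arrangements once is exact.
// [[Rcpp::export]]
double spearman_perm_p(NumericVector rx, NumericVector ry, double rho_obs) {
  const int n = rx.size();
  std::vector<double> xr(rx.begin(), rx.end());
  std::vector<double> yr(ry.begin(), ry.end());
  std::sort(yr.begin(), yr.end());

  double sx = 0, sxx = 0, sy = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    sx += xr[i]; sxx += xr[i] * xr[i];
    sy += yr[i]; syy += yr[i] * yr[i];
  }
  const double vx = sxx - sx * sx / n;
  const double vy = syy - sy * sy / n;
  const double denom = std::sqrt(vx * vy);
  const double thr = std::fabs(rho_obs) - 1e-12;

  long long total = 0, hits = 0;
  do {
    double sxy = 0;
    for (int i = 0; i < n; ++i) sxy += xr[i] * yr[i];
    const double rho = (sxy - sx * sy / n) / denom;
    ++total;
    if (std::fabs(rho) >= thr) ++hits;
  } while (std::next_permutation(yr.begin(), yr.end()));

  return static_cast<double>(hits) / static_cast<double>(total);
}
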
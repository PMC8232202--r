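#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>
#include <cmath>

using namespace Rcpp;

// Sample permutations position-by-position from an item-by-position
// probability matrix (rows = features, columns = positions). Entry (i, s)
// of the result is the 1-based feature placed at position s in sample i.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix ce_sample_permutations(NumericMatrix prob, int n_samples) {
  const int p = prob.nrow();
  if (prob.ncol() != p) stop("probability matrix must be square");
  IntegerMatrix out(n_samples, p);
  std::vector<int> avail(p);
  std::vector<double> w(p);
  for (int i = 0; i < n_samples; ++i) {
    for (int f = 0; f < p; ++f) avail[f] = f;
    int m = p;
    for (int s = 0; s < p; ++s) {
      double tot = 0.0;
      for (int a = 0; a < m; ++a) {
        w[a] = prob(avail[a], s);
        tot += w[a];
      }
      int pick;
      if (tot > 0.0) {
        double u = R::unif_rand() * tot, cum = 0.0;
        pick = m - 1;
        for (int a = 0; a < m; ++a) {
          cum += w[a];
          if (u <= cum) { pick = a; break; }
        }
      } else {
        // all remaining mass zero: fall back to uniform over what is left
        pick = (int)std::floor(R::unif_rand() * m);
        if (pick >= m) pick = m - 1;
      }
      out(i, s) = avail[pick] + 1;
      avail[pick] = avail[m - 1];
      --m;
    }
  }
  return out;
}

// Weighted Spearman footrule objective for a batch of candidate lists.
// perms: n x p, feature index at each position; rankmat: p x m, the rank of
// each feature under each of the m input lists; w: m list weights.
// [[Rcpp::export]]
NumericVector footrule_objectives(IntegerMatrix perms, IntegerMatrix rankmat,
                                  NumericVector w) {
  const int n = perms.nrow(), p = perms.ncol(), m = rankmat.ncol();
  if (rankmat.nrow() != p) stop("rank matrix does not match permutation width");
  if (w.size() != m) stop("one weight per list required");
  NumericVector out(n);
  std::vector<int> rk(p);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < p; ++s) rk[perms(i, s) - 1] = s + 1;
    double obj = 0.0;
    for (int j = 0; j < m; ++j) {
      double d = 0.0;
      for (int f = 0; f < p; ++f) d += std::abs((double)(rk[f] - rankmat(f, j)));
      obj += w[j] * d;
    }
    out[i] = obj;
  }
  return out;
}

// For each instance, count how many of its k nearest neighbours on a single
// feature belong to the other class. Self is excluded; distance ties are
// broken by ascending sample index, matching the documented tie rule.
// [[Rcpp::export]]
IntegerVector knn_opposite_counts(NumericVector x, IntegerVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y lengths differ");
  if (k < 1 || k >= n) stop("k must be in [1, n - 1]");
  IntegerVector out(n);
  std::vector<std::pair<double, int> > d;
  d.reserve(n - 1);
  for (int i = 0; i < n; ++i) {
    d.clear();
    for (int j = 0; j < n; ++j)
      if (j != i) d.push_back(std::make_pair(std::fabs(x[j] - x[i]), j));
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    int cnt = 0;
    for (int t = 0; t < k; ++t)
      if (y[d[t].second] != y[i]) ++cnt;
    out[i] = cnt;
  }
  return out;
}
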
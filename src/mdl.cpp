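// Recursive entropy/MDL discretization, two-class case. The hot loop of
// tree induction: every candidate split re-discretizes the children, so
// this runs thousands of times per training.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// binary entropy of a count pair, matching the R reference formula
static inline double ent2(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  double n = a + b;
  double p = a / n;
  return -(p * std::log2(p) + (1.0 - p) * std::log2(1.0 - p));
}

// recurse on the sorted block [lo, hi); y is 0/1
static void mdl_rec(const double* v, const int* y, int lo, int hi,
                    std::vector<double>& cuts) {
  int n = hi - lo;
  if (n < 2) return;
  int tot1 = 0;
  for (int i = lo; i < hi; ++i) tot1 += y[i];
  int tot0 = n - tot1;
  if (tot1 == 0 || tot0 == 0 || v[lo] == v[hi - 1]) return;

  double ent_all = ent2(tot1, tot0);
  double best_gain = R_NegInf;
  int best_i = -1, best_c1 = 0;
  int c1 = 0;
  for (int i = lo; i < hi - 1; ++i) {
    c1 += y[i];
    if (v[i] < v[i + 1]) {
      int nl = i - lo + 1;
      int nr = n - nl;
      double el = ent2(c1, nl - c1);
      double er = ent2(tot1 - c1, nr - (tot1 - c1));
      double gain = ent_all - (nl * el + nr * er) / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_i = i;
        best_c1 = c1;
      }
    }
  }
  if (best_i < 0) return;

  int nl = best_i - lo + 1;
  int nr = n - nl;
  int c0 = nl - best_c1;
  int r1 = tot1 - best_c1;
  int r0 = nr - r1;
  int k1 = (best_c1 > 0) + (c0 > 0);
  int k2 = (r1 > 0) + (r0 > 0);
  double delta = std::log2(7.0) -
    (2.0 * ent_all - k1 * ent2(best_c1, c0) - k2 * ent2(r1, r0));
  if (best_gain <= (std::log2((double)(n - 1)) + delta) / n) return;

  mdl_rec(v, y, lo, best_i + 1, cuts);
  cuts.push_back((v[best_i] + v[best_i + 1]) / 2.0);
  mdl_rec(v, y, best_i + 1, hi, cuts);
}

// [[Rcpp::export(name = ".mdl_split2_cpp")]]
NumericVector mdl_split2_cpp(NumericVector v, IntegerVector y) {
  std::vector<double> cuts;
  if (v.size() >= 2) {
    mdl_rec(v.begin(), y.begin(), 0, (int)v.size(), cuts);
  }
  return wrap(cuts);
}
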
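#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// abundance-weighted beta mean nearest taxon distance between two
// communities given 0-based indices into the pool distance matrix and
// relative-abundance weights summing to 1 per community
static double bmntd_one(const NumericMatrix& d,
                        const int* ix, int nx, const double* wx,
                        const int* iy, int ny, const double* wy) {
  // d is symmetric: index d(row, col) with col fixed inside the inner
  // loop so each pass stays within one cached column
  const double* dp = d.begin();
  const int n = d.nrow();
  double acc = 0.0;
  for (int a = 0; a < nx; ++a) {
    double mn = R_PosInf;
    const double* col = dp + (size_t)ix[a] * n;
    for (int b = 0; b < ny; ++b) {
      const double v = col[iy[b]];
      if (v < mn) mn = v;
    }
    acc += wx[a] * mn;
  }
  for (int b = 0; b < ny; ++b) {
    double mn = R_PosInf;
    const double* col = dp + (size_t)iy[b] * n;
    for (int a = 0; a < nx; ++a) {
      const double v = col[ix[a]];
      if (v < mn) mn = v;
    }
    acc += wy[b] * mn;
  }
  return acc / 2.0;
}

// [[Rcpp::export]]
double cpp_bmntd(const NumericMatrix& d, const IntegerVector& ix,
                 const IntegerVector& iy, const NumericVector& wx,
                 const NumericVector& wy) {
  return bmntd_one(d, ix.begin(), ix.size(), wx.begin(),
                   iy.begin(), iy.size(), wy.begin());
}

// null betaMNTD draws under taxa-label shuffling: perms is a reps x P
// matrix whose rows are 0-based permutations of the pool positions
// [[Rcpp::export]]
NumericVector cpp_bmntd_null(const NumericMatrix& d, const IntegerVector& ix,
                             const IntegerVector& iy, const NumericVector& wx,
                             const NumericVector& wy,
                             const IntegerMatrix& perms) {
  const int reps = perms.nrow();
  const int nx = ix.size(), ny = iy.size();
  std::vector<int> px(nx), py(ny);
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    for (int a = 0; a < nx; ++a) px[a] = perms(r, ix[a]);
    for (int b = 0; b < ny; ++b) py[b] = perms(r, iy[b]);
    out[r] = bmntd_one(d, px.data(), nx, wx.begin(),
                       py.data(), ny, wy.begin());
  }
  return out;
}

// weighted sampling without replacement of k items with weights w
// (Efraimidis-Spirakis exponential keys); writes chosen indices to sel
static void sample_wo_replacement(const std::vector<double>& w, int k,
                                  std::vector<int>& sel,
                                  std::vector<std::pair<double, int> >& keys) {
  const int n = (int)w.size();
  keys.clear();
  for (int i = 0; i < n; ++i) {
    if (w[i] <= 0.0) continue;
    keys.push_back(std::make_pair(exp_rand() / w[i], i));
  }
  std::partial_sort(keys.begin(), keys.begin() + k, keys.end());
  sel.resize(k);
  for (int i = 0; i < k; ++i) sel[i] = keys[i].second;
}

// assemble one null community: choose `rich` taxa with probability
// proportional to occupancy, give each one individual, distribute the
// remaining n - rich individuals with probability proportional to
// metacommunity relative abundance; accumulate counts into cnt
static void assemble_null(const std::vector<double>& occ_w,
                          const NumericVector& meta_p, int rich, int n,
                          std::vector<double>& cnt, std::vector<int>& sel,
                          std::vector<std::pair<double, int> >& keys) {
  sample_wo_replacement(occ_w, rich, sel, keys);
  double ptot = 0.0;
  for (int i = 0; i < rich; ++i) ptot += meta_p[sel[i]];
  int nleft = n - rich;
  for (int i = 0; i < rich; ++i) {
    const int j = sel[i];
    int add;
    if (i == rich - 1) {
      add = nleft;
    } else {
      double pr = (ptot > 0.0) ? meta_p[j] / ptot : 1.0 / (rich - i);
      if (pr > 1.0) pr = 1.0;
      if (pr < 0.0) pr = 0.0;
      add = (int)R::rbinom((double)nleft, pr);
      ptot -= meta_p[j];
    }
    nleft -= add;
    cnt[j] += 1.0 + add;
  }
}

// Raup-Crick null distribution of Bray-Curtis: per rep both communities
// are assembled probabilistically (richness and totals fixed, inclusion
// prob ~ occupancy, filling prob ~ metacommunity relative abundance)
// [[Rcpp::export]]
NumericVector cpp_rc_null(const NumericVector& meta_p,
                          const NumericVector& occ,
                          int rich_x, int n_x, int rich_y, int n_y,
                          int reps) {
  RNGScope scope;
  const int T = meta_p.size();
  std::vector<double> occ_w(T);
  for (int i = 0; i < T; ++i) occ_w[i] = occ[i];
  NumericVector out(reps);
  std::vector<double> cx(T, 0.0), cy(T, 0.0);
  std::vector<int> sel;
  std::vector<std::pair<double, int> > keys;
  keys.reserve(T);
  for (int r = 0; r < reps; ++r) {
    std::fill(cx.begin(), cx.end(), 0.0);
    std::fill(cy.begin(), cy.end(), 0.0);
    assemble_null(occ_w, meta_p, rich_x, n_x, cx, sel, keys);
    assemble_null(occ_w, meta_p, rich_y, n_y, cy, sel, keys);
    double num = 0.0;
    for (int i = 0; i < T; ++i) num += std::abs(cx[i] - cy[i]);
    out[r] = num / (double)(n_x + n_y);
  }
  return out;
}
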
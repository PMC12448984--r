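// Adjacency-constrained Ward clustering of SNPs from a banded r^2
// similarity, and exact dynamic-programming segmentation into K
// contiguous groups minimizing total within-cluster Ward cost.
//
// Dissimilarity d(j,k) = 1 - r^2(j,k), pairs beyond the band at d = 1.
// Cluster cost ESS(C) = (1/(2|C|)) sum_{i,j in C} d(i,j)
//               = (|C| - S_C/|C|) / 2,  S_C = |C| + 2 * sum_{pairs} r^2.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// band(d-1, j-1) = r^2 between SNPs j and j+d (1-based), 0 beyond p
// F(k, i) = sum_{d=1..k} band(d-1, i): within-band similarity of SNP i
// to its k right neighbours
static mat band_prefix(const mat &band) {
  const uword h = band.n_rows, p = band.n_cols;
  mat F(h + 1, p, fill::zeros);
  for (uword i = 0; i < p; ++i)
    for (uword d = 0; d < h; ++d) F(d + 1, i) = F(d, i) + band(d, i);
  return F;
}

// similarity cross-sum between adjacent clusters [a,m) and [m,b), 0-based
static double cross_sum(const mat &F, int a, int m, int b, int h) {
  double s = 0.0;
  int i0 = std::max(a, m - h);
  for (int i = i0; i < m; ++i) {
    int kb = std::min(b - 1 - i, h);
    int ka = std::min(m - 1 - i, h);
    if (kb > 0) s += F(kb, i);
    if (ka > 0) s -= F(ka, i);
  }
  return s;
}

static inline double ess_from_w(double w, int m) {
  // ESS = (m - (m + 2w)/m)/2
  return 0.5 * (m - (m + 2.0 * w) / m);
}

struct Cand {
  double cost;
  int a, m, b; // merge [a,m) with [m,b)
};
struct CandCmp {
  bool operator()(const Cand &x, const Cand &y) const {
    if (x.cost != y.cost) return x.cost > y.cost; // min-heap
    return x.a > y.a;                             // ties: leftmost first
  }
};

// [[Rcpp::export]]
Rcpp::List ld_dendro_cpp(const arma::mat &band) {
  const int p = band.n_cols, h = band.n_rows;
  if (p < 2)
    return Rcpp::List::create(
        Rcpp::Named("merge") = Rcpp::IntegerMatrix(0, 2),
        Rcpp::Named("height") = Rcpp::NumericVector(0));
  mat F = band_prefix(band);

  std::vector<int> endOf(p), nextS(p), prevS(p), idOf(p);
  std::vector<double> wOf(p, 0.0);
  std::vector<bool> active(p, true);
  for (int i = 0; i < p; ++i) {
    endOf[i] = i + 1;
    nextS[i] = i + 1 < p ? i + 1 : -1;
    prevS[i] = i - 1;
    idOf[i] = -(i + 1); // hclust convention: negative = singleton
  }
  std::priority_queue<Cand, std::vector<Cand>, CandCmp> pq;
  auto push_cand = [&](int a, int b) {
    int m = endOf[a];
    double r = cross_sum(F, a, m, endOf[b], h);
    double wAB = wOf[a] + wOf[b] + r;
    double d = ess_from_w(wAB, endOf[b] - a) - ess_from_w(wOf[a], m - a) -
               ess_from_w(wOf[b], endOf[b] - b);
    pq.push(Cand{d, a, m, endOf[b]});
  };
  for (int i = 0; i + 1 < p; ++i) push_cand(i, i + 1);

  Rcpp::IntegerMatrix merge(p - 1, 2);
  Rcpp::NumericVector height(p - 1);
  int nm = 0;
  while (nm < p - 1) {
    Cand c = pq.top();
    pq.pop();
    if (!active[c.a] || endOf[c.a] != c.m) continue;
    int bstart = c.m;
    if (!active[bstart] || endOf[bstart] != c.b) continue;
    // merge
    double r = cross_sum(F, c.a, c.m, c.b, h);
    wOf[c.a] = wOf[c.a] + wOf[bstart] + r;
    endOf[c.a] = c.b;
    active[bstart] = false;
    merge(nm, 0) = idOf[c.a];
    merge(nm, 1) = idOf[bstart];
    height[nm] = c.cost;
    idOf[c.a] = nm + 1;
    nextS[c.a] = nextS[bstart];
    if (nextS[bstart] >= 0) prevS[nextS[bstart]] = c.a;
    ++nm;
    if (prevS[c.a] >= 0) push_cand(prevS[c.a], c.a);
    if (nextS[c.a] >= 0) push_cand(c.a, nextS[c.a]);
  }
  return Rcpp::List::create(Rcpp::Named("merge") = merge,
                            Rcpp::Named("height") = height);
}

// [[Rcpp::export]]
Rcpp::IntegerVector ld_dp_cut_cpp(const arma::mat &band, int K,
                                  int min_len = 1, int max_len = 0) {
  const int p = band.n_cols, h = band.n_rows;
  if (min_len < 1) min_len = 1;
  if (K * min_len > p) K = p / min_len; // largest feasible K
  if (max_len > 0 && (long)K * max_len < p)
    K = (p + max_len - 1) / max_len;    // smallest feasible K
  if (max_len > 0 && max_len < min_len) max_len = min_len;
  if (K < 1) K = 1;
  if (K >= p) { // singletons
    Rcpp::IntegerVector bnd(p + 1);
    for (int i = 0; i <= p; ++i) bnd[i] = i;
    return bnd;
  }
  mat F = band_prefix(band);
  const double INF = std::numeric_limits<double>::infinity();
  // D[k][b]: best cost of splitting [0,b) into k groups
  mat D(K + 1, p + 1);
  D.fill(INF);
  D(0, 0) = 0.0;
  imat arg(K + 1, p + 1, fill::zeros);
  std::vector<double> S(p + 1), costcol(p + 1);
  for (int b = 1; b <= p; ++b) {
    // S[a] = similarity self-sum of [a,b); backward recurrence in a
    S[b - 1] = 1.0;
    costcol[b - 1] = 0.0;
    for (int a = b - 2; a >= 0; --a) {
      int k = std::min(b - 1 - a, h);
      S[a] = S[a + 1] + 1.0 + 2.0 * (k > 0 ? F(k, a) : 0.0);
      int m = b - a;
      costcol[a] = 0.5 * (m - S[a] / m);
    }
    int kmax = std::min(K, b / min_len);
    for (int k = 1; k <= kmax; ++k) {
      double best = INF;
      int barg = -1;
      int a_lo = (k - 1) * min_len;
      if (max_len > 0 && b - max_len > a_lo) a_lo = b - max_len;
      for (int a = a_lo; a <= b - min_len; ++a) {
        if (D(k - 1, a) == INF) continue;
        double v = D(k - 1, a) + costcol[a];
        if (v < best - 1e-15) {
          best = v;
          barg = a;
        }
      }
      D(k, b) = best;
      arg(k, b) = barg;
    }
  }
  Rcpp::IntegerVector bnd(K + 1);
  int b = p;
  bnd[K] = p;
  for (int k = K; k >= 1; --k) {
    int a = arg(k, b);
    bnd[k - 1] = a;
    b = a;
  }
  return bnd;
}
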
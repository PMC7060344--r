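// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic RNG (splitmix64) so that decoding results are bit-reproducible
// across platforms independently of the C++ standard library implementation.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed ^ 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = (int)(next() % (uint64_t)(i + 1));
      std::swap(v[i], v[j]);
    }
  }
};

// Dual coordinate descent for the L1-loss (hinge) linear SVM on a
// precomputed kernel (Gram) matrix:
//   min_a 0.5 a' Q a - 1'a,  0 <= a_i <= C,  Q_ij = y_i y_j K_ij,
// where K already contains the +1 of the augmented bias feature. `m`
// maintains m_i = sum_j a_j y_j K_ij so one coordinate update costs O(n).
// Supports warm starts through `alpha` (m is rebuilt on entry), which is
// exploited across adjacent time bins.
static void dcd_kernel(const arma::mat& K, const std::vector<double>& y,
                       double C, std::vector<double>& alpha,
                       std::vector<double>& m, SplitMix& rng,
                       int max_pass = 40, double eps = 1e-1) {
  const int n = (int)y.size();
  std::fill(m.begin(), m.end(), 0.0);
  for (int j = 0; j < n; ++j)
    if (alpha[j] != 0.0) {
      const double ay = alpha[j] * y[j];
      for (int i = 0; i < n; ++i) m[i] += ay * K(i, j);
    }
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double Mbar = std::numeric_limits<double>::infinity();
  double mbar = -std::numeric_limits<double>::infinity();
  for (int pass = 0; pass < max_pass; ++pass) {
    rng.shuffle(active);
    double max_pg = -std::numeric_limits<double>::infinity();
    double min_pg = std::numeric_limits<double>::infinity();
    for (size_t k = 0; k < active.size();) {
      const int i = active[k];
      const double G = y[i] * m[i] - 1.0;
      double PG = 0.0;
      if (alpha[i] <= 0.0) {
        if (G > Mbar) {  // shrink bounded-at-0 variable
          active[k] = active.back();
          active.pop_back();
          continue;
        }
        if (G < 0.0) PG = G;
      } else if (alpha[i] >= C) {
        if (G < mbar) {  // shrink bounded-at-C variable
          active[k] = active.back();
          active.pop_back();
          continue;
        }
        if (G > 0.0) PG = G;
      } else {
        PG = G;
      }
      if (PG > max_pg) max_pg = PG;
      if (PG < min_pg) min_pg = PG;
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - G / K(i, i);
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double step = (a_new - a_old) * y[i];
        if (step != 0.0)
          for (int j = 0; j < n; ++j) m[j] += step * K(j, i);
      }
      ++k;
    }
    if (max_pg - min_pg < eps) {
      if ((int)active.size() == n) break;
      // converged on the shrunken problem: restore and take a full pass
      active.resize(n);
      for (int i = 0; i < n; ++i) active[i] = i;
      Mbar = std::numeric_limits<double>::infinity();
      mbar = -std::numeric_limits<double>::infinity();
      continue;
    }
    Mbar = (max_pg <= 0.0) ? std::numeric_limits<double>::infinity() : max_pg;
    mbar = (min_pg >= 0.0) ? -std::numeric_limits<double>::infinity() : min_pg;
  }
}

static inline double get3(const double* data, int Tall, int C,
                          int t, int c, int b) {
  return data[(size_t)t + (size_t)Tall * ((size_t)c + (size_t)C * b)];
}

// [[Rcpp::export]]
NumericMatrix cpp_window_features(NumericVector data, IntegerVector dims,
                                  IntegerVector trials0, int bin0,
                                  int radius) {
  const int Tall = dims[0], C = dims[1], B = dims[2];
  if (bin0 < 0 || bin0 >= B) stop("bin index out of range");
  const int lo = std::max(0, bin0 - radius);
  const int hi = std::min(B - 1, bin0 + radius);
  const int n = trials0.size();
  NumericMatrix out(n, (hi - lo + 1) * C);
  for (int i = 0; i < n; ++i) {
    int f = 0;
    for (int b = lo; b <= hi; ++b)
      for (int c = 0; c < C; ++c)
        out(i, f++) = get3(REAL(data), Tall, C, trials0[i], c, b);
  }
  return out;
}

// Full cross-validated, time-resolved decoding run: pseudo-trial averaging on
// training folds, optional per-fold label shuffling (permutation null),
// per-feature standardization from the averaged training set, one-vs-one
// linear SVMs (C-regularized hinge loss) with majority voting, ties broken by
// summed pairwise decision margins. Features at bin t are all channels over
// bins [t - radius, t + radius] (clipped at the epoch edges) plus an
// augmented bias. Returns a folds x bins matrix of single-trial test
// accuracies.
// [[Rcpp::export]]
NumericMatrix cpp_decode_run(NumericVector data, IntegerVector dims,
                             IntegerVector trials0, IntegerVector labels0,
                             IntegerVector fold_id0, int n_folds,
                             int radius, int group_size, double Csvm,
                             bool standardize, bool shuffle, double seed) {
  const int Tall = dims[0], C = dims[1], B = dims[2];
  const int T = trials0.size();
  const double* dat = REAL(data);
  int M = 0;
  for (int i = 0; i < T; ++i) if (labels0[i] + 1 > M) M = labels0[i] + 1;
  if (M < 2) stop("need at least two classes");
  SplitMix rng((uint64_t)(seed < 0 ? -seed : seed) + 0x51ED270B0A1ULL);

  NumericMatrix acc(n_folds, B);
  const int n_pairs = M * (M - 1) / 2;

  for (int k = 0; k < n_folds; ++k) {
    std::vector<int> test_pos, train_pos;
    for (int i = 0; i < T; ++i)
      (fold_id0[i] == k ? test_pos : train_pos).push_back(i);
    if (test_pos.empty()) {
      for (int b = 0; b < B; ++b) acc(k, b) = NA_REAL;
      continue;
    }
    const int n_test = (int)test_pos.size();

    // pseudo-trial groups: within each class shuffle, chunk into groups of
    // group_size; a remainder of >= 2 forms its own averaged group, a
    // singleton passes through unaveraged
    std::vector<std::vector<int> > groups;
    std::vector<int> glab;
    for (int m = 0; m < M; ++m) {
      std::vector<int> cls;
      for (size_t i = 0; i < train_pos.size(); ++i)
        if (labels0[train_pos[i]] == m) cls.push_back(train_pos[i]);
      if (cls.empty()) stop("empty training class in fold");
      rng.shuffle(cls);
      size_t i = 0;
      while (i < cls.size()) {
        size_t take = std::min((size_t)group_size, cls.size() - i);
        groups.push_back(std::vector<int>(cls.begin() + i,
                                          cls.begin() + i + take));
        glab.push_back(m);
        i += take;
      }
    }
    const int G = (int)groups.size();
    if (shuffle) {
      // permute labels of the averaged pseudo-trials once per fold, applied
      // identically at every time bin (test labels untouched)
      std::vector<int> idx(G);
      for (int i = 0; i < G; ++i) idx[i] = i;
      rng.shuffle(idx);
      std::vector<int> gl2(G);
      for (int i = 0; i < G; ++i) gl2[i] = glab[idx[i]];
      glab = gl2;
    }

    // averaged pseudo-trial matrix, G x (B*C), channel-major within bin, so
    // the feature window of bin b is the contiguous column block
    // [lo*C, (hi+1)*C)
    arma::mat avg(G, (size_t)B * C, arma::fill::zeros);
    for (int g = 0; g < G; ++g) {
      const double inv = 1.0 / groups[g].size();
      for (size_t mi = 0; mi < groups[g].size(); ++mi) {
        const int tr = trials0[groups[g][mi]];
        for (int b = 0; b < B; ++b)
          for (int c = 0; c < C; ++c)
            avg(g, (size_t)b * C + c) += inv * get3(dat, Tall, C, tr, c, b);
      }
    }
    arma::mat tst(n_test, (size_t)B * C);
    for (int t = 0; t < n_test; ++t) {
      const int tr = trials0[test_pos[t]];
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < C; ++c)
          tst(t, (size_t)b * C + c) = get3(dat, Tall, C, tr, c, b);
    }
    if (standardize) {
      // feature statistics from the averaged training set, applied to both;
      // constant features are left centered (scale 1)
      arma::rowvec mu = arma::mean(avg, 0);
      arma::rowvec sdv = (G > 1) ? arma::stddev(avg, 0, 0)
                                 : arma::rowvec(avg.n_cols, arma::fill::zeros);
      sdv.elem(arma::find(sdv < 1e-12)).fill(1.0);
      avg.each_row() -= mu;
      avg.each_row() /= sdv;
      tst.each_row() -= mu;
      tst.each_row() /= sdv;
    }

    // pairwise problems with warm-started alphas carried across time bins
    std::vector<std::vector<int> > pair_rows(n_pairs);
    std::vector<std::pair<int, int> > pair_cls(n_pairs);
    std::vector<std::vector<double> > alphas(n_pairs), ys(n_pairs);
    {
      int p = 0;
      for (int a = 0; a < M; ++a)
        for (int bcl = a + 1; bcl < M; ++bcl) {
          pair_cls[p] = std::make_pair(a, bcl);
          for (int g = 0; g < G; ++g)
            if (glab[g] == a || glab[g] == bcl) {
              pair_rows[p].push_back(g);
              ys[p].push_back(glab[g] == a ? 1.0 : -1.0);
            }
          alphas[p].assign(pair_rows[p].size(), 0.0);
          ++p;
        }
    }

    std::vector<double> mbuf;
    std::vector<int> votes(M);
    std::vector<double> margin(M);
    for (int b0 = 0; b0 < B; ++b0) {
      const int lo = std::max(0, b0 - radius);
      const int hi = std::min(B - 1, b0 + radius);
      const arma::mat Xw = avg.cols((size_t)lo * C, (size_t)(hi + 1) * C - 1);
      const arma::mat Tw = tst.cols((size_t)lo * C, (size_t)(hi + 1) * C - 1);
      // +1 absorbs the augmented bias feature into the kernel
      const arma::mat K = Xw * Xw.t() + 1.0;
      const arma::mat Kt = Xw * Tw.t() + 1.0;  // G x n_test

      // fit all pairwise classifiers, collect test decisions
      arma::mat dec(n_pairs, n_test);
      for (int p = 0; p < n_pairs; ++p) {
        const int np = (int)pair_rows[p].size();
        arma::mat Kp(np, np);
        for (int i = 0; i < np; ++i)
          for (int j = 0; j <= i; ++j)
            Kp(i, j) = Kp(j, i) = K(pair_rows[p][i], pair_rows[p][j]);
        mbuf.assign(np, 0.0);
        dcd_kernel(Kp, ys[p], Csvm, alphas[p], mbuf, rng);
        for (int t = 0; t < n_test; ++t) {
          double d = 0.0;
          for (int i = 0; i < np; ++i)
            if (alphas[p][i] != 0.0)
              d += alphas[p][i] * ys[p][i] * Kt(pair_rows[p][i], t);
          dec(p, t) = d;
        }
      }

      int n_correct = 0;
      for (int t = 0; t < n_test; ++t) {
        std::fill(votes.begin(), votes.end(), 0);
        std::fill(margin.begin(), margin.end(), 0.0);
        for (int p = 0; p < n_pairs; ++p) {
          const int a = pair_cls[p].first, bcl = pair_cls[p].second;
          if (dec(p, t) > 0.0) votes[a]++; else votes[bcl]++;
          margin[a] += dec(p, t);
          margin[bcl] -= dec(p, t);
        }
        int best = 0;
        for (int m = 1; m < M; ++m)
          if (votes[m] > votes[best] ||
              (votes[m] == votes[best] && margin[m] > margin[best]))
            best = m;
        if (best == labels0[test_pos[t]]) ++n_correct;
      }
      acc(k, b0) = (double)n_correct / (double)n_test;
    }
  }
  return acc;
}

// Zero-phase IIR filtering (forward-backward), scipy-style: odd extension of
// length `padlen` at both ends and steady-state initial conditions scaled to
// the first sample of each pass, so step transients at the edges are
// suppressed. `b`, `a` are the transfer-function coefficients (a[0] = 1
// after normalization).
static arma::vec lfilter_zi(const arma::vec& b, const arma::vec& a) {
  const int n = (int)std::max(a.n_elem, b.n_elem) - 1;
  arma::vec bb = arma::zeros(n + 1), aa = arma::zeros(n + 1);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  // companion form: zi = (I - A)^-1 * B with A the transposed direct-form-II
  // state matrix
  arma::mat IminusA = arma::eye(n, n);
  for (int i = 0; i < n; ++i) IminusA(i, 0) += aa(i + 1);
  for (int i = 0; i < n - 1; ++i) IminusA(i, i + 1) -= 1.0;
  arma::vec B(n);
  for (int i = 0; i < n; ++i) B(i) = bb(i + 1) - aa(i + 1) * bb(0);
  return arma::solve(IminusA, B);
}

static void lfilter_1d(const arma::vec& b, const arma::vec& a,
                       const double* x, double* y, int n,
                       const arma::vec& zi, double x0) {
  const int ord = (int)zi.n_elem;
  arma::vec bb = arma::zeros(ord + 1), aa = arma::zeros(ord + 1);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  arma::vec z = zi * x0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb(0) * xi + z(0);
    for (int j = 0; j < ord - 1; ++j)
      z(j) = bb(j + 1) * xi + z(j + 1) - aa(j + 1) * yi;
    z(ord - 1) = bb(ord) * xi - aa(ord) * yi;
    y[i] = yi;
  }
}

// [[Rcpp::export]]
NumericVector cpp_filtfilt(NumericVector b_, NumericVector a_,
                           NumericVector x_, int padlen) {
  arma::vec b(b_.begin(), b_.size()), a(a_.begin(), a_.size());
  if (a(0) == 0.0) stop("a[0] must be nonzero");
  b /= a(0);
  a /= a(0);
  const int n = x_.size();
  if (padlen >= n) padlen = n - 1;
  if (padlen < 0) padlen = 0;
  const arma::vec zi = lfilter_zi(b, a);
  const int m = n + 2 * padlen;
  std::vector<double> ext(m), tmp(m);
  const double* x = REAL(x_);
  for (int i = 0; i < padlen; ++i) ext[i] = 2.0 * x[0] - x[padlen - i];
  for (int i = 0; i < n; ++i) ext[padlen + i] = x[i];
  for (int i = 0; i < padlen; ++i)
    ext[padlen + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  lfilter_1d(b, a, ext.data(), tmp.data(), m, zi, ext[0]);
  std::reverse(tmp.begin(), tmp.end());
  lfilter_1d(b, a, tmp.data(), ext.data(), m, zi, tmp[0]);
  std::reverse(ext.begin(), ext.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ext[padlen + i];
  return out;
}

// Centered (zero-phase) FIR anti-alias filtering combined with decimation:
// only every q-th output sample is computed. `b` must have odd length;
// samples beyond the signal ends are treated as zero.
// [[Rcpp::export]]
NumericVector cpp_fir_decimate(NumericVector b_, NumericVector x_, int q) {
  const int L = b_.size(), n = x_.size();
  if (L % 2 == 0) stop("FIR kernel must have odd length");
  const int half = (L - 1) / 2;
  const double* b = REAL(b_);
  const double* x = REAL(x_);
  const int n_out = (n + q - 1) / q;
  NumericVector out(n_out);
  for (int i = 0; i < n_out; ++i) {
    const int c = i * q;  // center index (0-based)
    const int k0 = std::max(0, c - half), k1 = std::min(n - 1, c + half);
    double acc = 0.0;
    for (int k = k0; k <= k1; ++k) acc += b[half + (c - k)] * x[k];
    out[i] = acc;
  }
  return out;
}
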
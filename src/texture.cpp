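// Sliding-window GLCM texture statistics.
//
// For every pixel, a window x window neighbourhood (reflective padding at
// the edges) is scanned for co-occurring grey-level pairs at each offset;
// the eight statistics are computed per offset and averaged. Pairs are
// collected and sorted per window instead of filling a dense N x N matrix,
// since a 7x7 window holds at most a few dozen pairs.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// mirror index into [0, n): symmetric (edge-duplicating) padding
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

struct Stats {
  double mean, var, hom, con, dis, ent, sm, corr;
};

// stats of one symmetrised/normalised GLCM given sorted cell keys
static Stats glcm_stats(std::vector<int> &keys, int levels,
                        bool paper_literal) {
  std::sort(keys.begin(), keys.end());
  const double total = (double)keys.size();
  double mu_i = 0, mu_j = 0;
  size_t a = 0;
  // first pass: marginal means
  while (a < keys.size()) {
    size_t b = a;
    while (b < keys.size() && keys[b] == keys[a]) ++b;
    double p = (b - a) / total;
    int i = keys[a] / levels, j = keys[a] % levels;
    mu_i += i * p;
    mu_j += j * p;
    a = b;
  }
  double var_i = 0, var_j = 0, cov = 0, hom = 0, con = 0, dis = 0,
         ent = 0, sm = 0;
  a = 0;
  while (a < keys.size()) {
    size_t b = a;
    while (b < keys.size() && keys[b] == keys[a]) ++b;
    double p = (b - a) / total;
    int i = keys[a] / levels, j = keys[a] % levels;
    int d = i - j;
    var_i += (i - mu_i) * (i - mu_i) * p;
    var_j += (j - mu_j) * (j - mu_j) * p;
    cov += (i - mu_i) * (j - mu_j) * p;
    hom += p / (1.0 + d * d);
    con += d * d * p;
    if (paper_literal) {
      dis += i * p * std::abs(d);
      ent += -i * p * std::log(p);
      sm += i * p * p;
    } else {
      dis += std::abs(d) * p;
      ent += -p * std::log(p);
      sm += p * p;
    }
    a = b;
  }
  Stats s;
  s.mean = mu_i;
  s.var = var_i;
  s.hom = hom;
  s.con = con;
  s.dis = dis;
  s.ent = ent;
  s.sm = sm;
  s.corr = (var_i <= 0.0 || var_j <= 0.0)
               ? 1.0
               : cov / std::sqrt(var_i * var_j);
  return s;
}

// [[Rcpp::export]]
List texture_rasters_cpp(IntegerMatrix q, int levels, int window,
                         IntegerMatrix offsets, bool symmetric,
                         bool paper_literal) {
  const int nr = q.nrow(), nc = q.ncol();
  const int half = window / 2;
  const int noff = offsets.nrow();

  std::vector<NumericMatrix> out;
  for (int k = 0; k < 8; ++k) out.push_back(NumericMatrix(nr, nc));

  std::vector<int> keys;
  keys.reserve(2 * window * window);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
      for (int o = 0; o < noff; ++o) {
        const int dr = offsets(o, 0), dc = offsets(o, 1);
        keys.clear();
        for (int wc = -half; wc <= half; ++wc) {
          for (int wr = -half; wr <= half; ++wr) {
            const int wr2 = wr + dr, wc2 = wc + dc;
            if (wr2 < -half || wr2 > half || wc2 < -half || wc2 > half)
              continue;
            const int v1 = q(reflect(r + wr, nr), reflect(c + wc, nc));
            const int v2 = q(reflect(r + wr2, nr), reflect(c + wc2, nc));
            keys.push_back(v1 * levels + v2);
            if (symmetric) keys.push_back(v2 * levels + v1);
          }
        }
        if (keys.empty()) stop("no valid pixel pairs in window");
        Stats s = glcm_stats(keys, levels, paper_literal);
        acc[0] += s.mean;
        acc[1] += s.var;
        acc[2] += s.hom;
        acc[3] += s.con;
        acc[4] += s.dis;
        acc[5] += s.ent;
        acc[6] += s.sm;
        acc[7] += s.corr;
      }
      for (int k = 0; k < 8; ++k) out[k](r, c) = acc[k] / noff;
    }
  }
  List res(8);
  for (int k = 0; k < 8; ++k) res[k] = out[k];
  return res;
}
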
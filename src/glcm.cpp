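#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-voxel windowed grey-level co-occurrence statistics.
//
// For every in-mask pixel of `img`, the in-plane window of side `window`
// (clipped at the image border) is min-max quantized to `levels` bins and a
// symmetric, normalized GLCM is accumulated at each requested offset
// (drow, dcol). 18 Haralick-family statistics are emitted per offset.
// Level values are 1-based (i, j in 1..levels) in all statistic formulas.
//
// Degenerate windows (single grey level, or no valid pixel pair for an
// offset) yield a point-mass GLCM at (1,1); correlation and the information
// measure of correlation fall back to 0 when their denominators vanish.
//
// Rows are emitted in R's column-major which(mask) order. Columns are the
// 18 statistics for offset 1, then offset 2, ...

static const int N_STATS = 18;

static void glcm_stats(const std::vector<double>& P, int L, double* out) {
  const double log2e = 1.4426950408889634; // 1/ln(2)
  std::vector<double> px(L, 0.0), psum(2 * L - 1, 0.0), pdiff(L, 0.0);
  double energy = 0, contrast = 0, idmn = 0, entropy = 0, homog = 0,
         autoc = 0, dissim = 0, maxp = 0, sij = 0;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) {
      double p = P[i + L * j];
      if (p <= 0) continue;
      double iv = i + 1, jv = j + 1, d = iv - jv;
      energy += p * p;
      contrast += d * d * p;
      idmn += p / (1.0 + d * d / (double)(L * L));
      entropy -= p * std::log(p) * log2e;
      homog += p / (1.0 + std::fabs(d));
      autoc += iv * jv * p;
      dissim += std::fabs(d) * p;
      sij += iv * jv * p;
      if (p > maxp) maxp = p;
      px[i] += p;
      psum[i + j] += p;
      pdiff[(int)std::fabs((double)(i - j))] += p;
    }
  }
  double mu = 0;
  for (int i = 0; i < L; ++i) mu += (i + 1) * px[i];
  double var = 0;
  for (int i = 0; i < L; ++i) var += (i + 1 - mu) * (i + 1 - mu) * px[i];
  double corr = 0;
  if (var > 1e-300) corr = (sij - mu * mu) / var; // sigma_x == sigma_y
  double sa = 0, se = 0;
  for (int k = 0; k < 2 * L - 1; ++k) {
    double p = psum[k];
    if (p <= 0) continue;
    sa += (k + 2) * p;
    se -= p * std::log(p) * log2e;
  }
  double sv = 0;
  for (int k = 0; k < 2 * L - 1; ++k)
    sv += (k + 2 - sa) * (k + 2 - sa) * psum[k];
  double da = 0, de = 0;
  for (int k = 0; k < L; ++k) {
    double p = pdiff[k];
    if (p <= 0) continue;
    da += k * p;
    de -= p * std::log(p) * log2e;
  }
  double dv = 0;
  for (int k = 0; k < L; ++k) dv += (k - da) * (k - da) * pdiff[k];
  double hx = 0;
  for (int i = 0; i < L; ++i)
    if (px[i] > 0) hx -= px[i] * std::log(px[i]) * log2e;
  double hxy1 = 0;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) {
      double p = P[i + L * j];
      if (p <= 0) continue;
      hxy1 -= p * std::log(px[i] * px[j]) * log2e;
    }
  }
  double imc1 = 0;
  if (hx > 1e-12) imc1 = (entropy - hxy1) / hx;
  double shade = 0, prom = 0;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) {
      double p = P[i + L * j];
      if (p <= 0) continue;
      double c = (i + 1) + (j + 1) - 2 * mu;
      shade += c * c * c * p;
      prom += c * c * c * c * p;
    }
  }
  out[0] = energy;  out[1] = contrast; out[2] = corr;  out[3] = var;
  out[4] = idmn;    out[5] = sa;       out[6] = sv;    out[7] = entropy;
  out[8] = se;      out[9] = de;       out[10] = imc1; out[11] = homog;
  out[12] = autoc;  out[13] = dv;      out[14] = dissim;
  out[15] = shade;  out[16] = prom;    out[17] = maxp;
}

// [[Rcpp::export]]
NumericMatrix glcm_window_stats_cpp(NumericMatrix img, LogicalMatrix mask,
                                    int window, int levels,
                                    IntegerMatrix offsets) {
  int nr = img.nrow(), nc = img.ncol();
  int half = window / 2;
  int noff = offsets.nrow();
  int nvox = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) ++nvox;
  NumericMatrix out(nvox, N_STATS * noff);
  std::vector<double> P((size_t)levels * levels);
  std::vector<int> q((size_t)window * window);
  int row = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int r0 = std::max(0, i - half), r1 = std::min(nr - 1, i + half);
      int c0 = std::max(0, j - half), c1 = std::min(nc - 1, j + half);
      int wr = r1 - r0 + 1, wc = c1 - c0 + 1;
      double lo = R_PosInf, hi = R_NegInf;
      for (int cc = c0; cc <= c1; ++cc)
        for (int rr = r0; rr <= r1; ++rr) {
          double v = img(rr, cc);
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
      // quantize window to 0..levels-1
      double rng = hi - lo;
      for (int cc = 0; cc < wc; ++cc)
        for (int rr = 0; rr < wr; ++rr) {
          int qv = 0;
          if (rng > 0) {
            qv = (int)((img(r0 + rr, c0 + cc) - lo) / rng * levels);
            if (qv >= levels) qv = levels - 1;
          }
          q[rr + wr * cc] = qv;
        }
      for (int o = 0; o < noff; ++o) {
        int drow = offsets(o, 0), dcol = offsets(o, 1);
        std::fill(P.begin(), P.end(), 0.0);
        double total = 0;
        for (int cc = 0; cc < wc; ++cc) {
          for (int rr = 0; rr < wr; ++rr) {
            int r2 = rr + drow, c2 = cc + dcol;
            if (r2 < 0 || r2 >= wr || c2 < 0 || c2 >= wc) continue;
            int a = q[rr + wr * cc], b = q[r2 + wr * c2];
            P[a + levels * b] += 1.0;
            P[b + levels * a] += 1.0;
            total += 2.0;
          }
        }
        if (total == 0) { P[0] = 1.0; total = 1.0; }
        for (size_t t = 0; t < P.size(); ++t) P[t] /= total;
        double buf[N_STATS];
        glcm_stats(P, levels, buf);
        for (int k = 0; k < N_STATS; ++k) out(row, N_STATS * o + k) = buf[k];
      }
      ++row;
    }
  }
  return out;
}
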
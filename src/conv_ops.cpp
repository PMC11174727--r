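// Low-level numeric kernels: im2col/col2im for 2-D convolution with stride,
// zero padding and dilation, and batch GLCM texture featurization with
// edge-replicated windows. Layout conventions (must match the R callers):
//   * images are H x W x C arrays, column-major;
//   * im2col rows are ordered channel-major, then kernel row, then kernel col;
//   * im2col columns enumerate output positions with the output row fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& x, int kh, int kw,
                     int stride, int pad, int dilation) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int eff_kh = (kh - 1) * dilation + 1;
  const int eff_kw = (kw - 1) * dilation + 1;
  const int oh = (H + 2 * pad - eff_kh) / stride + 1;
  const int ow = (W + 2 * pad - eff_kw) / stride + 1;
  if (oh < 1 || ow < 1) stop("kernel does not fit in the padded input");

  arma::mat cols(kh * kw * C, oh * ow, arma::fill::zeros);
  for (int oc = 0; oc < ow; ++oc) {
    for (int orow = 0; orow < oh; ++orow) {
      const int col_idx = oc * oh + orow;
      const int r0 = orow * stride - pad;
      const int c0 = oc * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int ki = 0; ki < kh; ++ki) {
          const int r = r0 + ki * dilation;
          if (r < 0 || r >= H) continue;
          for (int kj = 0; kj < kw; ++kj) {
            const int cc = c0 + kj * dilation;
            if (cc < 0 || cc >= W) continue;
            cols(c * kh * kw + ki * kw + kj, col_idx) = x(r, cc, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube col2im_cpp(const arma::mat& cols, int H, int W, int C,
                      int kh, int kw, int stride, int pad, int dilation) {
  const int eff_kh = (kh - 1) * dilation + 1;
  const int eff_kw = (kw - 1) * dilation + 1;
  const int oh = (H + 2 * pad - eff_kh) / stride + 1;
  const int ow = (W + 2 * pad - eff_kw) / stride + 1;
  if ((int)cols.n_cols != oh * ow || (int)cols.n_rows != kh * kw * C)
    stop("cols dimensions inconsistent with the stated geometry");

  arma::cube x(H, W, C, arma::fill::zeros);
  for (int oc = 0; oc < ow; ++oc) {
    for (int orow = 0; orow < oh; ++orow) {
      const int col_idx = oc * oh + orow;
      const int r0 = orow * stride - pad;
      const int c0 = oc * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int ki = 0; ki < kh; ++ki) {
          const int r = r0 + ki * dilation;
          if (r < 0 || r >= H) continue;
          for (int kj = 0; kj < kw; ++kj) {
            const int cc = c0 + kj * dilation;
            if (cc < 0 || cc >= W) continue;
            x(r, cc, c) += cols(c * kh * kw + ki * kw + kj, col_idx);
          }
        }
      }
    }
  }
  return x;
}

// Five Haralick statistics (contrast, dissimilarity, homogeneity,
// correlation, ASM) of the symmetric, per-offset-normalized GLCM of the
// size x size window centered at each pixel, averaged over offsets.
// Border pixels are handled by edge replication (coordinate clamping,
// equivalent to replicating border rows/columns outward). Degenerate
// windows (zero marginal variance) take correlation 1.
// q: H x W integer matrix of quantized gray levels in [0, levels).
// offsets: n x 2 integer matrix of (drow, dcol).
// Returns 5 x (H*W), pixels in column-major order.
// [[Rcpp::export]]
NumericMatrix glcm_features_cpp(const IntegerMatrix& q, int levels,
                                int window, const IntegerMatrix& offsets) {
  const int H = q.nrow(), W = q.ncol();
  const int half = window / 2;
  const int n_off = offsets.nrow();
  const int L2 = levels * levels;
  NumericMatrix out(5, H * W);
  std::vector<double> hist(L2);

  for (int pc = 0; pc < W; ++pc) {
    for (int pr = 0; pr < H; ++pr) {
      double stats[5] = {0, 0, 0, 0, 0};
      for (int o = 0; o < n_off; ++o) {
        const int dr = offsets(o, 0), dc = offsets(o, 1);
        std::fill(hist.begin(), hist.end(), 0.0);
        double total = 0.0;
        for (int wi = -half; wi <= half; ++wi) {
          const int wi2 = wi + dr;
          if (wi2 < -half || wi2 > half) continue;
          int r1 = std::min(std::max(pr + wi, 0), H - 1);
          int r2 = std::min(std::max(pr + wi2, 0), H - 1);
          for (int wj = -half; wj <= half; ++wj) {
            const int wj2 = wj + dc;
            if (wj2 < -half || wj2 > half) continue;
            int c1 = std::min(std::max(pc + wj, 0), W - 1);
            int c2 = std::min(std::max(pc + wj2, 0), W - 1);
            const int a = q(r1, c1), b = q(r2, c2);
            hist[a * levels + b] += 1.0;
            hist[b * levels + a] += 1.0;
            total += 2.0;
          }
        }
        if (total <= 0) stop("offset larger than the window: no valid pairs");
        double contrast = 0, dissim = 0, homog = 0, asm_ = 0;
        double mu = 0, ex2 = 0, exy = 0;
        for (int i = 0; i < levels; ++i) {
          for (int j = 0; j < levels; ++j) {
            const double p = hist[i * levels + j] / total;
            if (p == 0) continue;
            const int d = i - j;
            contrast += p * d * d;
            dissim   += p * std::abs(d);
            homog    += p / (1.0 + d * d);
            asm_     += p * p;
            mu  += p * i;
            ex2 += p * i * i;
            exy += p * i * j;
          }
        }
        const double var = ex2 - mu * mu;
        const double corr = (var > 1e-12) ? (exy - mu * mu) / var : 1.0;
        stats[0] += contrast; stats[1] += dissim; stats[2] += homog;
        stats[3] += corr;     stats[4] += asm_;
      }
      const int idx = pc * H + pr;
      for (int s = 0; s < 5; ++s) out(s, idx) = stats[s] / n_off;
    }
  }
  return out;
}
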
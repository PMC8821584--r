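// Minimal CPU kernels for the segmentation network and object labeling.
// Activations are H x W x C cubes (column-major, matching R arrays).
// Convolution weights are (k*k*Cin) x Cout matrices; the weight row index
// runs fastest over kernel rows, then kernel cols, then input channels,
// matching the im2col column order below.
//
// im2col uses the transposed layout (Ho*Wo) x (k*k*Cin) so that the
// innermost loop (output rows) writes and reads contiguous memory.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;
using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col_t(const cube& x, int k, int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(Ho * Wo, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = cols.colptr((c * k + kj) * k + ki);
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + kj - pad;
          if (ij < 0 || ij >= W) continue;
          // valid output rows: 0 <= oi*stride + ki - pad < H
          int lo = std::max(0, (pad - ki + stride - 1) / stride);
          int hi = std::min(Ho - 1, (H - 1 - ki + pad) / stride);
          const double* src = xs + (size_t)ij * H + (lo * stride + ki - pad);
          double* dst = col + (size_t)oj * Ho + lo;
          if (stride == 1) {
            std::copy(src, src + (hi - lo + 1), dst);
          } else {
            for (int oi = lo; oi <= hi; ++oi, src += stride, ++dst) *dst = *src;
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_t_add(cube& gx, const mat& cols, int k, int stride,
                         int pad, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    double* xs = gx.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = cols.colptr((c * k + kj) * k + ki);
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + kj - pad;
          if (ij < 0 || ij >= W) continue;
          int lo = std::max(0, (pad - ki + stride - 1) / stride);
          int hi = std::min(Ho - 1, (H - 1 - ki + pad) / stride);
          double* dst = xs + (size_t)ij * H + (lo * stride + ki - pad);
          const double* src = col + (size_t)oj * Ho + lo;
          for (int oi = lo; oi <= hi; ++oi, dst += stride, ++src) *dst += *src;
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int k, int stride, int pad) {
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = w.n_cols;
  mat cols = im2col_t(x, k, stride, pad, Ho, Wo);
  mat o = cols * w;                       // (Ho*Wo) x Cout
  o.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  std::copy(o.memptr(), o.memptr() + o.n_elem, out.memptr());
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gout, int k, int stride, int pad) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, Cout = gout.n_slices;
  mat g(Ho * Wo, Cout);
  std::copy(gout.memptr(), gout.memptr() + gout.n_elem, g.memptr());
  mat cols = im2col_t(x, k, stride, pad, Ho, Wo);
  mat gw = cols.t() * g;                  // (k*k*Cin) x Cout
  vec gb = sum(g, 0).t();
  mat gcols = g * w.t();                  // (Ho*Wo) x (k*k*Cin)
  cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im_t_add(gx, gcols, k, stride, pad, Ho, Wo);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Depthwise convolution: w is (k*k) x C, one kernel per input channel.
// [[Rcpp::export]]
arma::cube dwconv2d_fwd_cpp(const arma::cube& x, const arma::mat& w,
                            const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    out.slice(c).fill(b(c));
    const double* xs = x.slice_memptr(c);
    double* os = out.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double wv = w(kj * k + ki, c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + kj - pad;
          if (ij < 0 || ij >= W) continue;
          int lo = std::max(0, (pad - ki + stride - 1) / stride);
          int hi = std::min(Ho - 1, (H - 1 - ki + pad) / stride);
          const double* src = xs + (size_t)ij * H + (lo * stride + ki - pad);
          double* dst = os + (size_t)oj * Ho + lo;
          for (int oi = lo; oi <= hi; ++oi, src += stride, ++dst)
            *dst += wv * *src;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List dwconv2d_bwd_cpp(const arma::cube& x, const arma::mat& w,
                            const arma::cube& gout, int k, int stride,
                            int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  mat gw(k * k, C, fill::zeros);
  vec gb(C, fill::zeros);
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    const double* gs = gout.slice_memptr(c);
    double* gxs = gx.slice_memptr(c);
    gb(c) = accu(gout.slice(c));
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double wv = w(kj * k + ki, c);
        double acc = 0.0;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + kj - pad;
          if (ij < 0 || ij >= W) continue;
          int lo = std::max(0, (pad - ki + stride - 1) / stride);
          int hi = std::min(Ho - 1, (H - 1 - ki + pad) / stride);
          const double* xp = xs + (size_t)ij * H + (lo * stride + ki - pad);
          double* gxp = gxs + (size_t)ij * H + (lo * stride + ki - pad);
          const double* gp = gs + (size_t)oj * Ho + lo;
          for (int oi = lo; oi <= hi; ++oi, xp += stride, gxp += stride, ++gp) {
            acc += *gp * *xp;
            *gxp += *gp * wv;
          }
        }
        gw(kj * k + ki, c) = acc;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 8-connected component labeling of a logical mask, BFS in scan order so the
// labeling is deterministic: component ids increase with the linear index of
// their first (column-major) pixel.
// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components_cpp(const Rcpp::LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
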
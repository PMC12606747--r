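// Hot numeric kernels for the reference network: 2-D convolution via
// im2col + BLAS matmul, and bilinear grid sampling with gradients for both
// the sampled feature map and the (predicted, hence differentiable)
// sampling coordinates. Feature maps are R arrays dim c(H, W, C), which
// share memory layout with arma::cube(H, W, C).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// col matrix: (kh*kw*Cin) x (Ho*Wo), row index ky + kh*kx + kh*kw*ci,
// col index y + Ho*x  (matches column-major cube layout).
static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  arma::mat col(kh * kw * C, Ho * Wo, arma::fill::zeros);
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      const int n = oy + Ho * ox;
      for (int ci = 0; ci < C; ++ci) {
        for (int kx = 0; kx < kw; ++kx) {
          const int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            col(ky + kh * (kx + kw * ci), n) = x(iy, ix, ci);
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(arma::cube& gx, const arma::mat& gcol,
                       int kh, int kw, int stride, int pad) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      const int n = oy + Ho * ox;
      for (int ci = 0; ci < C; ++ci) {
        for (int kx = 0; kx < kw; ++kx) {
          const int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            gx(iy, ix, ci) += gcol(ky + kh * (kx + kw * ci), n);
          }
        }
      }
    }
  }
}

// w: R array dim c(kh, kw, Cin, Cout) flattened column-major.
// Returns the output cube and the im2col matrix (reused by the backward
// pass so patch extraction runs once per layer and step).
// [[Rcpp::export]]
List cpp_conv2d_fw(const arma::cube& x, const NumericVector& w,
                   const NumericVector& b, int kh, int kw,
                   int cout, int stride, int pad) {
  const int cin = x.n_slices;
  const int Ho = out_size(x.n_rows, kh, stride, pad);
  const int Wo = out_size(x.n_cols, kw, stride, pad);
  arma::mat Wmat(const_cast<double*>(w.begin()), kh * kw * cin, cout, false, true);
  arma::mat col = im2col(x, kh, kw, stride, pad);
  arma::mat out = col.t() * Wmat;            // N x Cout, N = Ho*Wo
  out.each_row() += arma::rowvec(const_cast<double*>(b.begin()), cout, false, true);
  arma::cube res(Ho, Wo, cout);
  std::memcpy(res.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return List::create(_["out"] = res, _["col"] = col);
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::mat& col, const NumericVector& w,
                   const arma::cube& gout, int H, int W, int cin,
                   int kh, int kw, int cout, int stride, int pad,
                   bool need_gx) {
  const int N = gout.n_rows * gout.n_cols;
  arma::mat Wmat(const_cast<double*>(w.begin()), kh * kw * cin, cout, false, true);
  arma::mat gout_mat(const_cast<double*>(gout.memptr()), N, cout, false, true);
  arma::mat gW = col * gout_mat;             // R x Cout
  arma::vec gb = arma::sum(gout_mat, 0).t();
  if (!need_gx) {
    return List::create(_["gw"] = gW, _["gb"] = gb);
  }
  arma::mat gcol = Wmat * gout_mat.t();      // R x N
  arma::cube gx(H, W, cin, arma::fill::zeros);
  col2im_add(gx, gcol, kh, kw, stride, pad);
  return List::create(_["gx"] = gx, _["gw"] = gW, _["gb"] = gb);
}

// Bilinear sampling with border clamping; xs/ys in 0-based pixel units of
// the feature grid. Returns N x C matrix.
// [[Rcpp::export]]
arma::mat cpp_grid_sample_fw(const arma::cube& f, const NumericVector& xs,
                             const NumericVector& ys) {
  const int H = f.n_rows, W = f.n_cols, C = f.n_slices, N = xs.size();
  arma::mat out(N, C);
  for (int n = 0; n < N; ++n) {
    double x = std::min(std::max(xs[n], 0.0), (double)(W - 1));
    double y = std::min(std::max(ys[n], 0.0), (double)(H - 1));
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
    double wx = x - x0, wy = y - y0;
    for (int c = 0; c < C; ++c) {
      out(n, c) = (1 - wy) * ((1 - wx) * f(y0, x0, c) + wx * f(y0, x1, c)) +
                  wy * ((1 - wx) * f(y1, x0, c) + wx * f(y1, x1, c));
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_grid_sample_bw(const arma::cube& f, const NumericVector& xs,
                        const NumericVector& ys, const arma::mat& gout) {
  const int H = f.n_rows, W = f.n_cols, C = f.n_slices, N = xs.size();
  arma::cube gf(H, W, C, arma::fill::zeros);
  NumericVector gx(N), gy(N);
  for (int n = 0; n < N; ++n) {
    double xr = xs[n], yr = ys[n];
    bool in_x = (xr > 0.0 && xr < (double)(W - 1));
    bool in_y = (yr > 0.0 && yr < (double)(H - 1));
    double x = std::min(std::max(xr, 0.0), (double)(W - 1));
    double y = std::min(std::max(yr, 0.0), (double)(H - 1));
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
    double wx = x - x0, wy = y - y0;
    double gxa = 0.0, gya = 0.0;
    for (int c = 0; c < C; ++c) {
      double g = gout(n, c);
      gf(y0, x0, c) += g * (1 - wy) * (1 - wx);
      gf(y0, x1, c) += g * (1 - wy) * wx;
      gf(y1, x0, c) += g * wy * (1 - wx);
      gf(y1, x1, c) += g * wy * wx;
      gxa += g * ((1 - wy) * (f(y0, x1, c) - f(y0, x0, c)) +
                  wy * (f(y1, x1, c) - f(y1, x0, c)));
      gya += g * ((1 - wx) * (f(y1, x0, c) - f(y0, x0, c)) +
                  wx * (f(y1, x1, c) - f(y0, x1, c)));
    }
    gx[n] = in_x ? gxa : 0.0;  // clamped coordinates receive no gradient
    gy[n] = in_y ? gya : 0.0;
  }
  return List::create(_["gf"] = gf, _["gx"] = gx, _["gy"] = gy);
}
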
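#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// All tensors use R's column-major layout:
//   activations  x : H x W x C x N
//   conv weights w : k x k x Cin x Cout  ("same" padding, stride 1, k odd)
//   deconv weights : 2 x 2 x Cin x Cout  (stride 2)

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::mat weight_mat(const NumericVector& w, int k, int cin, int cout) {
  // (a, b, ci, co) is stored at a + k*b + k*k*ci + k*k*cin*co, so the array is
  // already a (k*k*cin) x cout matrix.
  return arma::mat(const_cast<double*>(w.begin()), k * k * cin, cout, false, true);
}

// Build the im2col matrix for one sample: rows = H*W output pixels,
// cols = k*k*Cin receptive-field entries (matching weight_mat's row order).
static void im2col(const double* x, int H, int W, int cin, int k, arma::mat& col) {
  const int pad = k / 2;
  col.zeros();
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int cidx = a + k * b + k * k * ci;
        double* dst = col.colptr(cidx);
        for (int j = 0; j < W; ++j) {
          const int sj = j + b - pad;
          if (sj < 0 || sj >= W) continue;
          const int si0 = a - pad;
          int i_lo = std::max(0, -si0), i_hi = std::min(H, H - si0);
          const double* src = xc + (size_t)H * sj + si0;
          double* d = dst + (size_t)H * j;
          for (int i = i_lo; i < i_hi; ++i) d[i] = src[i];
        }
      }
    }
  }
}

// Scatter-add a column matrix back onto the (padded) input gradient.
static void col2im(const arma::mat& col, int H, int W, int cin, int k, double* gx) {
  const int pad = k / 2;
  for (int ci = 0; ci < cin; ++ci) {
    double* gc = gx + (size_t)H * W * ci;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int cidx = a + k * b + k * k * ci;
        const double* src0 = col.colptr(cidx);
        for (int j = 0; j < W; ++j) {
          const int sj = j + b - pad;
          if (sj < 0 || sj >= W) continue;
          const int si0 = a - pad;
          int i_lo = std::max(0, -si0), i_hi = std::min(H, H - si0);
          double* d = gc + (size_t)H * sj + si0;
          const double* s = src0 + (size_t)H * j;
          for (int i = i_lo; i < i_hi; ++i) d[i] += s[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], cin = xd[2], N = xd[3];
  const int k = wd[0], cout = wd[3];
  if (wd[2] != cin) stop("conv2d_fw: channel mismatch");
  NumericVector y = alloc4(H, W, cout, N);
  arma::mat Wm = weight_mat(w, k, cin, cout);
  arma::mat col(H * W, k * k * cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * cin * n, H, W, cin, k, col);
    arma::mat yn(y.begin() + (size_t)H * W * cout * n, H * W, cout, false, true);
    yn = col * Wm;
    for (int co = 0; co < cout; ++co) yn.col(co) += bias[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], cin = xd[2], N = xd[3];
  const int k = wd[0], cout = wd[3];
  NumericVector gx = alloc4(H, W, cin, N);
  arma::mat Wm = weight_mat(w, k, cin, cout);
  arma::mat gW(k * k * cin, cout, arma::fill::zeros);
  arma::vec gb(cout, arma::fill::zeros);
  arma::mat col(H * W, k * k * cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * cin * n, H, W, cin, k, col);
    arma::mat gyn(const_cast<double*>(gy.begin()) + (size_t)H * W * cout * n,
                  H * W, cout, false, true);
    gW += col.t() * gyn;
    gb += arma::sum(gyn, 0).t();
    arma::mat gcol = gyn * Wm.t();
    col2im(gcol, H, W, cin, k, gx.begin() + (size_t)H * W * cin * n);
  }
  NumericVector gw = alloc4(k, k, cin, cout);
  std::copy(gW.begin(), gW.end(), gw.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// 2x2 max pooling, stride 2. Returns pooled values and argmax linear indices
// (1-based, into the full input array) for the backward pass.
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          size_t p00 = base + (size_t)H * (2 * j) + 2 * i;
          size_t cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
          size_t best = cand[0];
          for (int t = 1; t < 4; ++t) if (x[cand[t]] > x[best]) best = cand[t];
          y[o] = x[best];
          idx[o] = (int)(best + 1);
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  NumericVector gx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  const R_xlen_t n = gy.size();
  for (R_xlen_t t = 0; t < n; ++t) gx[idx[t] - 1] += gy[t];
  return gx;
}

// Transposed convolution, kernel 2x2, stride 2 (2x upsampling).
// y[2i+a, 2j+b, co] = sum_ci x[i,j,ci] * w[a,b,ci,co] + bias[co]
// [[Rcpp::export]]
NumericVector convt2_fw(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], cin = xd[2], N = xd[3];
  const int cout = wd[3];
  if (wd[2] != cin) stop("convt2_fw: channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = alloc4(Ho, Wo, cout, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < cout; ++co) {
      double* yc = y.begin() + (size_t)Ho * Wo * (co + (size_t)cout * n);
      for (R_xlen_t t = 0; t < (R_xlen_t)Ho * Wo; ++t) yc[t] = bias[co];
      for (int ci = 0; ci < cin; ++ci) {
        const double* xc = x.begin() + (size_t)H * W * (ci + (size_t)cin * n);
        const double* wk = w.begin() + 4 * (ci + (size_t)cin * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xc[i + (size_t)H * j];
            double* yp = yc + (size_t)Ho * (2 * j) + 2 * i;
            yp[0] += v * wk[0];          // a=0,b=0
            yp[1] += v * wk[1];          // a=1,b=0
            yp[Ho] += v * wk[2];         // a=0,b=1
            yp[Ho + 1] += v * wk[3];     // a=1,b=1
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List convt2_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], cin = xd[2], N = xd[3];
  const int cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx = alloc4(H, W, cin, N);
  NumericVector gw = alloc4(2, 2, cin, cout);
  NumericVector gb(cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < cout; ++co) {
      const double* gyc = gy.begin() + (size_t)Ho * Wo * (co + (size_t)cout * n);
      double acc = 0.0;
      for (R_xlen_t t = 0; t < (R_xlen_t)Ho * Wo; ++t) acc += gyc[t];
      gb[co] += acc;
      for (int ci = 0; ci < cin; ++ci) {
        const double* xc = x.begin() + (size_t)H * W * (ci + (size_t)cin * n);
        const double* wk = w.begin() + 4 * (ci + (size_t)cin * co);
        double* gxc = gx.begin() + (size_t)H * W * (ci + (size_t)cin * n);
        double* gwk = gw.begin() + 4 * (ci + (size_t)cin * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double* gyp = gyc + (size_t)Ho * (2 * j) + 2 * i;
            const double v = xc[i + (size_t)H * j];
            gxc[i + (size_t)H * j] +=
              gyp[0] * wk[0] + gyp[1] * wk[1] + gyp[Ho] * wk[2] + gyp[Ho + 1] * wk[3];
            gwk[0] += v * gyp[0];
            gwk[1] += v * gyp[1];
            gwk[2] += v * gyp[Ho];
            gwk[3] += v * gyp[Ho + 1];
          }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
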
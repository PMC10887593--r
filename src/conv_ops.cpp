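// Convolution and pooling kernels for (N, H, W, C) channel-last tensors.
// R arrays are column-major, so element (n, i, j, c) (0-based) sits at
// n + N*(i + H*(j + W*c)).  Convolutions go through im2col + BLAS gemm;
// grouped convolution (groups == C_in gives depthwise) is supported so the
// same kernel serves plain, depthwise and 1x1 convolutions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline R_xlen_t idx4(R_xlen_t n, R_xlen_t i, R_xlen_t j, R_xlen_t c,
                            R_xlen_t N, R_xlen_t H, R_xlen_t W) {
  return n + N * (i + H * (j + W * c));
}

// Fill the im2col matrix for one channel group.
// M has dim (N*oh*ow) x (kh*kw*cpg); row r = n + N*oi + N*oh*oj,
// col k = ki + kh*kj + kh*kw*c  (c is the within-group channel).
static void im2col_group(const double* x, arma::mat& M,
                         R_xlen_t N, R_xlen_t H, R_xlen_t W,
                         R_xlen_t kh, R_xlen_t kw, R_xlen_t cpg,
                         R_xlen_t c0, R_xlen_t oh, R_xlen_t ow,
                         R_xlen_t stride, R_xlen_t pad_top, R_xlen_t pad_left) {
  for (R_xlen_t c = 0; c < cpg; ++c) {
    for (R_xlen_t kj = 0; kj < kw; ++kj) {
      for (R_xlen_t ki = 0; ki < kh; ++ki) {
        R_xlen_t col = ki + kh * (kj + kw * c);
        double* Mcol = M.colptr(col);
        for (R_xlen_t oj = 0; oj < ow; ++oj) {
          R_xlen_t jj = oj * stride - pad_left + kj;
          for (R_xlen_t oi = 0; oi < oh; ++oi) {
            R_xlen_t ii = oi * stride - pad_top + ki;
            R_xlen_t r0 = N * (oi + oh * oj);
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) {
              for (R_xlen_t n = 0; n < N; ++n) Mcol[r0 + n] = 0.0;
            } else {
              const double* src = x + idx4(0, ii, jj, c0 + c, N, H, W);
              for (R_xlen_t n = 0; n < N; ++n) Mcol[r0 + n] = src[n];
            }
          }
        }
      }
    }
  }
}

// Scatter-add the im2col gradient back onto the input gradient.
static void col2im_group(const arma::mat& M, double* dx,
                         R_xlen_t N, R_xlen_t H, R_xlen_t W,
                         R_xlen_t kh, R_xlen_t kw, R_xlen_t cpg,
                         R_xlen_t c0, R_xlen_t oh, R_xlen_t ow,
                         R_xlen_t stride, R_xlen_t pad_top, R_xlen_t pad_left) {
  for (R_xlen_t c = 0; c < cpg; ++c) {
    for (R_xlen_t kj = 0; kj < kw; ++kj) {
      for (R_xlen_t ki = 0; ki < kh; ++ki) {
        R_xlen_t col = ki + kh * (kj + kw * c);
        const double* Mcol = M.colptr(col);
        for (R_xlen_t oj = 0; oj < ow; ++oj) {
          R_xlen_t jj = oj * stride - pad_left + kj;
          if (jj < 0 || jj >= W) continue;
          for (R_xlen_t oi = 0; oi < oh; ++oi) {
            R_xlen_t ii = oi * stride - pad_top + ki;
            if (ii < 0 || ii >= H) continue;
            R_xlen_t r0 = N * (oi + oh * oj);
            double* dst = dx + idx4(0, ii, jj, c0 + c, N, H, W);
            for (R_xlen_t n = 0; n < N; ++n) dst[n] += Mcol[r0 + n];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad_top, int pad_left,
                         int oh, int ow, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  R_xlen_t N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  R_xlen_t kh = wd[0], kw = wd[1], cpg = wd[2], cout = wd[3];
  if (C != cpg * groups) stop("conv2d: channel/group mismatch");
  R_xlen_t coutg = cout / groups;
  R_xlen_t R = N * (R_xlen_t)oh * (R_xlen_t)ow;
  NumericVector y(R * cout);
  y.attr("dim") = IntegerVector::create((int)N, oh, ow, (int)cout);
  arma::mat M(R, kh * kw * cpg);
  for (int g = 0; g < groups; ++g) {
    im2col_group(x.begin(), M, N, H, W, kh, kw, cpg, g * cpg,
                 oh, ow, stride, pad_top, pad_left);
    arma::mat Wg(const_cast<double*>(w.begin()) + kh * kw * cpg * coutg * g,
                 kh * kw * cpg, coutg, false, true);
    arma::mat Yg(y.begin() + R * coutg * g, R, coutg, false, true);
    Yg = M * Wg;
    for (R_xlen_t co = 0; co < coutg; ++co) Yg.col(co) += b[g * coutg + co];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_x(NumericVector dy, NumericVector w,
                               IntegerVector xdim, int stride,
                               int pad_top, int pad_left, int groups) {
  IntegerVector wd = w.attr("dim"), yd = dy.attr("dim");
  R_xlen_t N = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  R_xlen_t kh = wd[0], kw = wd[1], cpg = wd[2], cout = wd[3];
  R_xlen_t oh = yd[1], ow = yd[2];
  R_xlen_t coutg = cout / groups;
  R_xlen_t R = N * oh * ow;
  NumericVector dx(N * H * W * C);
  dx.attr("dim") = xdim;
  for (int g = 0; g < groups; ++g) {
    arma::mat Wg(const_cast<double*>(w.begin()) + kh * kw * cpg * coutg * g,
                 kh * kw * cpg, coutg, false, true);
    arma::mat dYg(const_cast<double*>(dy.begin()) + R * coutg * g,
                  R, coutg, false, true);
    arma::mat dM = dYg * Wg.t();
    col2im_group(dM, dx.begin(), N, H, W, kh, kw, cpg, g * cpg,
                 oh, ow, stride, pad_top, pad_left);
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd_w(NumericVector x, NumericVector dy,
                      int kh, int kw, int stride,
                      int pad_top, int pad_left, int groups) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  R_xlen_t N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  R_xlen_t oh = yd[1], ow = yd[2], cout = yd[3];
  R_xlen_t cpg = C / groups, coutg = cout / groups;
  R_xlen_t R = N * oh * ow;
  NumericVector dw(kh * (R_xlen_t)kw * cpg * cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, (int)cpg, (int)cout);
  NumericVector db(cout);
  arma::mat M(R, kh * (R_xlen_t)kw * cpg);
  for (int g = 0; g < groups; ++g) {
    im2col_group(x.begin(), M, N, H, W, kh, kw, cpg, g * cpg,
                 oh, ow, stride, pad_top, pad_left);
    arma::mat dYg(const_cast<double*>(dy.begin()) + R * coutg * g,
                  R, coutg, false, true);
    arma::mat dWg(dw.begin() + kh * kw * cpg * coutg * g,
                  kh * kw * cpg, coutg, false, true);
    dWg = M.t() * dYg;
    for (R_xlen_t co = 0; co < coutg; ++co)
      db[g * coutg + co] = arma::accu(dYg.col(co));
  }
  return List::create(_["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_pool2d(NumericVector x, int ksize, int stride,
                         int pad_top, int pad_left, int oh, int ow,
                         std::string type) {
  IntegerVector xd = x.attr("dim");
  R_xlen_t N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  NumericVector y(N * (R_xlen_t)oh * ow * C);
  y.attr("dim") = IntegerVector::create((int)N, oh, ow, (int)C);
  bool do_max = (type == "max");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t c = 0; c < C; ++c)
    for (R_xlen_t oj = 0; oj < ow; ++oj)
      for (R_xlen_t oi = 0; oi < oh; ++oi)
        for (R_xlen_t n = 0; n < N; ++n) {
          double best = do_max ? R_NegInf : 0.0;
          int cnt = 0;
          for (int kj = 0; kj < ksize; ++kj) {
            R_xlen_t jj = oj * stride - pad_left + kj;
            if (jj < 0 || jj >= W) continue;
            for (int ki = 0; ki < ksize; ++ki) {
              R_xlen_t ii = oi * stride - pad_top + ki;
              if (ii < 0 || ii >= H) continue;
              double v = xp[idx4(n, ii, jj, c, N, H, W)];
              if (do_max) { if (v > best) best = v; }
              else best += v;
              ++cnt;
            }
          }
          yp[idx4(n, oi, oj, c, N, (R_xlen_t)oh, (R_xlen_t)ow)] =
            do_max ? best : (cnt > 0 ? best / cnt : 0.0);
        }
  return y;
}
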
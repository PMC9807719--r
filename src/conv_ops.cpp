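// Forward and backward kernels for valid-padding 2-D convolution and
// average pooling on batched single- or multi-channel images.
//
// Layout conventions (all column-major, matching R arrays):
//   activations: dim (h, w, c, n)       -- n = batch size
//   conv weights: dim (kh, kw, c_in, n_filters), bias length n_filters
//
// Convolution is implemented as im2col followed by one BLAS gemm per
// sample; the backward pass reuses the patch matrix for the weight
// gradient and scatters W * dY^T back with col2im for the input gradient.
// Everything is single-threaded for bit-reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (h, w, c, n)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Fill the patch matrix K (kh*kw*c x ho*wo) for one sample.
static void im2col(const double* x, int h, int w, int c,
                   int kh, int kw, int stride, int ho, int wo,
                   arma::mat& K) {
  for (int ow = 0; ow < wo; ++ow) {
    for (int oh = 0; oh < ho; ++oh) {
      const int col = oh + ow * ho;
      double* kcol = K.colptr(col);
      const int base_h = oh * stride, base_w = ow * stride;
      for (int ci = 0; ci < c; ++ci) {
        const double* xc = x + (std::size_t)ci * h * w;
        for (int j = 0; j < kw; ++j) {
          const double* xcol = xc + (std::size_t)(base_w + j) * h + base_h;
          double* kdst = kcol + ci * kh * kw + j * kh;
          for (int i = 0; i < kh; ++i) kdst[i] = xcol[i];
        }
      }
    }
  }
}

// Scatter-add the patch-gradient matrix dK back onto the input gradient.
static void col2im_add(const arma::mat& dK, int h, int w, int c,
                       int kh, int kw, int stride, int ho, int wo,
                       double* dx) {
  for (int ow = 0; ow < wo; ++ow) {
    for (int oh = 0; oh < ho; ++oh) {
      const int col = oh + ow * ho;
      const double* kcol = dK.colptr(col);
      const int base_h = oh * stride, base_w = ow * stride;
      for (int ci = 0; ci < c; ++ci) {
        double* xc = dx + (std::size_t)ci * h * w;
        for (int j = 0; j < kw; ++j) {
          double* xcol = xc + (std::size_t)(base_w + j) * h + base_h;
          const double* ksrc = kcol + ci * kh * kw + j * kh;
          for (int i = 0; i < kh; ++i) xcol[i] += ksrc[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector wts,
                                 NumericVector bias, int stride) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(wts, dw);
  const int h = dx[0], w = dx[1], c = dx[2], n = dx[3];
  const int kh = dw[0], kw = dw[1], nf = dw[3];
  if (dw[2] != c) stop("weight input channels do not match input");
  const int ho = (h - kh) / stride + 1, wo = (w - kw) / stride + 1;
  if (ho < 1 || wo < 1) stop("non-positive convolution output size");

  arma::mat Wm(const_cast<double*>(wts.begin()), (std::size_t)kh * kw * c, nf,
               false, true);
  arma::vec b(const_cast<double*>(bias.begin()), nf, false, true);

  NumericVector out((R_xlen_t)ho * wo * nf * n);
  out.attr("dim") = IntegerVector::create(ho, wo, nf, n);
  arma::mat K((std::size_t)kh * kw * c, (std::size_t)ho * wo);

  for (int s = 0; s < n; ++s) {
    const double* xs = x.begin() + (std::size_t)s * h * w * c;
    im2col(xs, h, w, c, kh, kw, stride, ho, wo, K);
    arma::mat Y = K.t() * Wm;               // (ho*wo) x nf
    Y.each_row() += b.t();
    std::copy(Y.begin(), Y.end(),
              out.begin() + (std::size_t)s * ho * wo * nf);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward_cpp(NumericVector x, NumericVector wts,
                         NumericVector dy, int stride) {
  int dx_[4], dw_[4], dy_[4];
  get_dims4(x, dx_); get_dims4(wts, dw_); get_dims4(dy, dy_);
  const int h = dx_[0], w = dx_[1], c = dx_[2], n = dx_[3];
  const int kh = dw_[0], kw = dw_[1], nf = dw_[3];
  const int ho = dy_[0], wo = dy_[1];
  if (dy_[2] != nf || dy_[3] != n) stop("dy dimensions inconsistent");

  arma::mat Wm(const_cast<double*>(wts.begin()), (std::size_t)kh * kw * c, nf,
               false, true);

  NumericVector dxv((R_xlen_t)h * w * c * n);
  dxv.attr("dim") = IntegerVector::create(h, w, c, n);
  arma::mat dWm((std::size_t)kh * kw * c, nf, arma::fill::zeros);
  arma::vec db(nf, arma::fill::zeros);
  arma::mat K((std::size_t)kh * kw * c, (std::size_t)ho * wo);

  for (int s = 0; s < n; ++s) {
    const double* xs = x.begin() + (std::size_t)s * h * w * c;
    arma::mat dY(const_cast<double*>(dy.begin()) + (std::size_t)s * ho * wo * nf,
                 (std::size_t)ho * wo, nf, false, true);
    im2col(xs, h, w, c, kh, kw, stride, ho, wo, K);
    dWm += K * dY;
    db += arma::sum(dY, 0).t();
    arma::mat dK = Wm * dY.t();             // (kh*kw*c) x (ho*wo)
    col2im_add(dK, h, w, c, kh, kw, stride, ho, wo,
               dxv.begin() + (std::size_t)s * h * w * c);
  }

  NumericVector dwv(wts.size());
  dwv.attr("dim") = wts.attr("dim");
  std::copy(dWm.begin(), dWm.end(), dwv.begin());
  return List::create(_["dx"] = dxv, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".avgpool_forward")]]
NumericVector avgpool_forward_cpp(NumericVector x, int kh, int kw, int stride) {
  int d[4];
  get_dims4(x, d);
  const int h = d[0], w = d[1], c = d[2], n = d[3];
  const int ho = (h - kh) / stride + 1, wo = (w - kw) / stride + 1;
  if (ho < 1 || wo < 1) stop("non-positive pooling output size");
  const double inv = 1.0 / (kh * kw);

  NumericVector out((R_xlen_t)ho * wo * c * n);
  out.attr("dim") = IntegerVector::create(ho, wo, c, n);
  const double* px = x.begin();
  double* po = out.begin();

  for (int s = 0; s < n; ++s)
    for (int ci = 0; ci < c; ++ci) {
      const double* xc = px + ((std::size_t)s * c + ci) * h * w;
      double* oc = po + ((std::size_t)s * c + ci) * ho * wo;
      for (int ow = 0; ow < wo; ++ow)
        for (int oh = 0; oh < ho; ++oh) {
          double acc = 0.0;
          const int bh = oh * stride, bw = ow * stride;
          for (int j = 0; j < kw; ++j) {
            const double* xcol = xc + (std::size_t)(bw + j) * h + bh;
            for (int i = 0; i < kh; ++i) acc += xcol[i];
          }
          oc[oh + (std::size_t)ow * ho] = acc * inv;
        }
    }
  return out;
}

// [[Rcpp::export(name = ".avgpool_backward")]]
NumericVector avgpool_backward_cpp(NumericVector dy, int h, int w,
                                   int kh, int kw, int stride) {
  int d[4];
  get_dims4(dy, d);
  const int ho = d[0], wo = d[1], c = d[2], n = d[3];
  const double inv = 1.0 / (kh * kw);

  NumericVector dx((R_xlen_t)h * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  const double* pd = dy.begin();
  double* px = dx.begin();

  for (int s = 0; s < n; ++s)
    for (int ci = 0; ci < c; ++ci) {
      const double* gc = pd + ((std::size_t)s * c + ci) * ho * wo;
      double* xc = px + ((std::size_t)s * c + ci) * h * w;
      for (int ow = 0; ow < wo; ++ow)
        for (int oh = 0; oh < ho; ++oh) {
          const double g = gc[oh + (std::size_t)ow * ho] * inv;
          const int bh = oh * stride, bw = ow * stride;
          for (int j = 0; j < kw; ++j) {
            double* xcol = xc + (std::size_t)(bw + j) * h + bh;
            for (int i = 0; i < kh; ++i) xcol[i] += g;
          }
        }
    }
  return dx;
}
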
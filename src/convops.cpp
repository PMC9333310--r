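// Low-level conv-net kernels: im2col/col2im convolution, max-pooling.
// Layout conventions shared with the R side:
//   activations: arma::cube (H, W, C), column-major as in R arrays [H, W, C]
//   conv weights: matrix (k*k*Cin, Cout); row index = kh + k*kw + k*k*c,
//     i.e. exactly matrix(W_array[k,k,Cin,Cout], ncol = Cout) in R.
//   patch matrix ("cols"): (OH*OW, k*k*Cin) — spatial index fastest, so the
//     gather/scatter loops below write contiguously.
// Padding is explicit per side so stride-2 'same' layers can pad
// asymmetrically (TensorFlow convention: excess on bottom/right).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col(const cube& x, int k, int stride,
                   int pt, int pl, int OH, int OW, mat& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* dst = cols.colptr(kh + k * kw + k * k * c);
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow * stride - pl + kw;
          if (iw < 0 || iw >= W) continue;
          const double* src = x.slice_colptr(c, iw);
          double* d = dst + (size_t)OH * ow;
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh * stride - pt + kh;
            if (ih < 0 || ih >= H) continue;
            d[oh] = src[ih];
          }
        }
      }
    }
  }
}

static void col2im(const mat& cols, int k, int stride,
                   int pt, int pl, int OH, int OW, cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* src = cols.colptr(kh + k * kw + k * k * c);
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow * stride - pl + kw;
          if (iw < 0 || iw >= W) continue;
          double* dst = x.slice_colptr(c, iw);
          const double* s = src + (size_t)OH * ow;
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh * stride - pt + kh;
            if (ih < 0 || ih >= H) continue;
            dst[ih] += s[oh];
          }
        }
      }
    }
  }
}

// Forward convolution; optionally applies a ReLU in place and returns the
// im2col patch matrix for reuse in the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_conv_fw(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b, int k, int stride,
                       int pt, int pb, int pl, int pr,
                       bool relu, bool keep_cols) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int OH = (H + pt + pb - k) / stride + 1;
  const int OW = (Wd + pl + pr - k) / stride + 1;
  const int Cout = W.n_cols;
  mat cols((size_t)OH * OW, W.n_rows, fill::zeros);
  im2col(x, k, stride, pt, pl, OH, OW, cols);
  mat out = cols * W;                 // (OH*OW) x Cout
  out.each_row() += b.t();
  if (relu) out.transform([](double v) { return v > 0 ? v : 0.0; });
  cube res(OH, OW, Cout);
  std::copy(out.begin(), out.end(), res.begin());
  Rcpp::List ret = Rcpp::List::create(Rcpp::Named("out") = res);
  if (keep_cols) ret["cols"] = cols;
  return ret;
}

// Backward pass. `dout` must already be gated by the activation mask.
// `cols` is the patch matrix saved by the forward pass; pass a 0x0 matrix
// to have it recomputed from x.
// [[Rcpp::export]]
Rcpp::List cpp_conv_bw(const arma::cube& x, const arma::mat& W,
                       const arma::cube& dout, const arma::mat& cols_in,
                       int k, int stride, int pt, int pb, int pl, int pr,
                       bool need_dx) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int OH = dout.n_rows, OW = dout.n_cols, Cout = dout.n_slices;
  mat cols;
  const mat* colsp = &cols_in;
  if (cols_in.n_elem == 0) {
    cols.zeros((size_t)OH * OW, W.n_rows);
    im2col(x, k, stride, pt, pl, OH, OW, cols);
    colsp = &cols;
  }
  mat dout_mat((size_t)OH * OW, Cout);
  std::copy(dout.begin(), dout.end(), dout_mat.begin());
  mat dW = colsp->t() * dout_mat;             // (k*k*C) x Cout
  vec db = sum(dout_mat, 0).t();
  Rcpp::List ret = Rcpp::List::create(Rcpp::Named("dW") = dW,
                                      Rcpp::Named("db") = db);
  if (need_dx) {
    mat dcols = dout_mat * W.t();             // (OH*OW) x (k*k*C)
    cube dx(H, Wd, C, fill::zeros);
    col2im(dcols, k, stride, pt, pl, OH, OW, dx);
    ret["dx"] = dx;
  }
  return ret;
}

// 2x2 (or size x size) max pooling with floor division: trailing rows/cols
// that do not fill a window are dropped (VGG convention).
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fw(const arma::cube& x, int size) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int OH = H / size, OW = W / size;
  cube out(OH, OW, C);
  Rcpp::IntegerVector arg((size_t)OH * OW * C);  // 0-based linear index into x
  size_t a = 0;
  for (int c = 0; c < C; ++c)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        double best = -datum::inf; int besti = 0;
        for (int j = 0; j < size; ++j)
          for (int i = 0; i < size; ++i) {
            const int ih = oh * size + i, iw = ow * size + j;
            const double v = x(ih, iw, c);
            if (v > best) { best = v; besti = ih + H * (iw + (size_t)W * c); }
          }
        out(oh, ow, c) = best;
        arg[a++] = besti;
      }
  arg.attr("dim") = Rcpp::IntegerVector::create(OH, OW, C);
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("argmax") = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const Rcpp::IntegerVector& argmax,
                          const arma::cube& dout, int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  const double* d = dout.begin();
  for (size_t i = 0; i < (size_t)argmax.size(); ++i)
    dx.begin()[argmax[i]] += d[i];
  return dx;
}

// Zero-stuffing / strided subsampling: a stride-s transposed convolution is
// an ordinary convolution of the zero-stuffed input with the spatially
// flipped kernel, and its input-gradient is the strided subsample of the
// stuffed gradient. Keeping both here lets the R side express deconv layers
// entirely through cpp_conv_fw / cpp_conv_bw.
// [[Rcpp::export]]
arma::cube cpp_zero_stuff(const arma::cube& x, int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int OH = (H - 1) * stride + 1, OW = (W - 1) * stride + 1;
  cube out(OH, OW, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        out(h * stride, w * stride, c) = x(h, w, c);
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_subsample(const arma::cube& x, int stride) {
  const int OH = (x.n_rows - 1) / stride + 1, OW = (x.n_cols - 1) / stride + 1;
  cube out(OH, OW, x.n_slices);
  for (size_t c = 0; c < x.n_slices; ++c)
    for (int w = 0; w < (int)OW; ++w)
      for (int h = 0; h < (int)OH; ++h)
        out(h, w, c) = x(h * stride, w * stride, c);
  return out;
}

// Elementwise ReLU gate: dout * (out > 0), done in C++ to avoid two full
// R-level array allocations per layer per step.
// [[Rcpp::export]]
arma::cube cpp_relu_gate(const arma::cube& dout, const arma::cube& out) {
  cube r(dout.n_rows, dout.n_cols, dout.n_slices);
  const double* o = out.begin();
  const double* d = dout.begin();
  double* p = r.begin();
  for (size_t i = 0; i < dout.n_elem; ++i) p[i] = o[i] > 0 ? d[i] : 0.0;
  return r;
}
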
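// Minimal conv-net kernels: stride-1 same-padding convolution, 2x2 max
// pooling and average pooling over batches stored as R arrays (h, w, c, n).
// Convolutions use a shift-and-accumulate formulation with hoisted bounds
// so the innermost loops run contiguously over the first array dimension.
#include <Rcpp.h>
using namespace Rcpp;

static inline int idx4(int i, int j, int c, int s, int h, int w, int nc) {
  return i + h * (j + w * (c + nc * s));
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector X, NumericVector W, NumericVector b) {
  IntegerVector dx = X.attr("dim");  // h, w, cin, n
  IntegerVector dw = W.attr("dim");  // kh, kw, cin, f
  int h = dx[0], w = dx[1], cin = dx[2], n = dx[3];
  int kh = dw[0], kw = dw[1], f = dw[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector Y(static_cast<R_xlen_t>(h) * w * f * n);
  Y.attr("dim") = IntegerVector::create(h, w, f, n);
  const double *xp = X.begin(), *wp = W.begin();
  double *yp = Y.begin();
  for (int s = 0; s < n; ++s)
    for (int of = 0; of < f; ++of) {
      double *ys = yp + idx4(0, 0, of, s, h, w, f);
      double bias = b[of];
      for (int k = 0; k < h * w; ++k) ys[k] = bias;
      for (int c = 0; c < cin; ++c) {
        const double *xs = xp + idx4(0, 0, c, s, h, w, cin);
        for (int q = 0; q < kw; ++q) {
          int jlo = std::max(0, pw - q), jhi = std::min(w - 1, w - 1 + pw - q);
          for (int p = 0; p < kh; ++p) {
            double wv = wp[p + kh * (q + kw * (c + cin * of))];
            int ilo = std::max(0, ph - p), ihi = std::min(h - 1, h - 1 + ph - p);
            for (int j = jlo; j <= jhi; ++j) {
              const double *xcol = xs + (j + q - pw) * h + (p - ph);
              double *ycol = ys + j * h;
              for (int i = ilo; i <= ihi; ++i) ycol[i] += wv * xcol[i];
            }
          }
        }
      }
    }
  return Y;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector X, NumericVector W, NumericVector dY) {
  IntegerVector dx = X.attr("dim");
  IntegerVector dw = W.attr("dim");
  int h = dx[0], w = dx[1], cin = dx[2], n = dx[3];
  int kh = dw[0], kw = dw[1], f = dw[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector dW(W.size()), db(f), dX(X.size());
  dW.attr("dim") = dw;
  dX.attr("dim") = dx;
  const double *xp = X.begin(), *wp = W.begin(), *gp = dY.begin();
  double *dwp = dW.begin(), *dxp = dX.begin();
  for (int s = 0; s < n; ++s)
    for (int of = 0; of < f; ++of) {
      const double *gs = gp + idx4(0, 0, of, s, h, w, f);
      double acc = 0;
      for (int k = 0; k < h * w; ++k) acc += gs[k];
      db[of] += acc;
      for (int c = 0; c < cin; ++c) {
        const double *xs = xp + idx4(0, 0, c, s, h, w, cin);
        double *dxs = dxp + idx4(0, 0, c, s, h, w, cin);
        for (int q = 0; q < kw; ++q) {
          int jlo = std::max(0, pw - q), jhi = std::min(w - 1, w - 1 + pw - q);
          for (int p = 0; p < kh; ++p) {
            int wix = p + kh * (q + kw * (c + cin * of));
            double wv = wp[wix];
            double wacc = 0;
            int ilo = std::max(0, ph - p), ihi = std::min(h - 1, h - 1 + ph - p);
            for (int j = jlo; j <= jhi; ++j) {
              const double *xcol = xs + (j + q - pw) * h + (p - ph);
              double *dxcol = dxs + (j + q - pw) * h + (p - ph);
              const double *gcol = gs + j * h;
              for (int i = ilo; i <= ihi; ++i) {
                wacc += gcol[i] * xcol[i];
                dxcol[i] += wv * gcol[i];
              }
            }
            dwp[wix] += wacc;
          }
        }
      }
    }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// [[Rcpp::export(name = ".cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(NumericVector X, int size) {
  IntegerVector dx = X.attr("dim");
  int h = dx[0], w = dx[1], c = dx[2], n = dx[3];
  int h2 = h / size, w2 = w / size;
  NumericVector Y(static_cast<R_xlen_t>(h2) * w2 * c * n);
  IntegerVector A(Y.size());  // 0-based linear index into X of the argmax
  Y.attr("dim") = IntegerVector::create(h2, w2, c, n);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc)
      for (int j = 0; j < w2; ++j)
        for (int i = 0; i < h2; ++i) {
          double best = -1e300; int bix = -1;
          for (int q = 0; q < size; ++q)
            for (int p = 0; p < size; ++p) {
              int xix = idx4(i * size + p, j * size + q, cc, s, h, w, c);
              if (X[xix] > best) { best = X[xix]; bix = xix; }
            }
          int yix = idx4(i, j, cc, s, h2, w2, c);
          Y[yix] = best; A[yix] = bix;
        }
  return List::create(_["Y"] = Y, _["argmax"] = A);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(NumericVector dY, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector dX(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] *
                   xdim[3]);
  dX.attr("dim") = xdim;
  for (int k = 0; k < dY.size(); ++k) dX[argmax[k]] += dY[k];
  return dX;
}

// [[Rcpp::export(name = ".cpp_avgpool")]]
NumericVector cpp_avgpool(NumericVector X, int sh, int sw) {
  IntegerVector dx = X.attr("dim");
  int h = dx[0], w = dx[1], c = dx[2], n = dx[3];
  int h2 = h / sh, w2 = w / sw;
  NumericVector Y(static_cast<R_xlen_t>(h2) * w2 * c * n);
  Y.attr("dim") = IntegerVector::create(h2, w2, c, n);
  double inv = 1.0 / (sh * sw);
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc)
      for (int j = 0; j < w2; ++j)
        for (int i = 0; i < h2; ++i) {
          double acc = 0;
          for (int q = 0; q < sw; ++q)
            for (int p = 0; p < sh; ++p)
              acc += X[idx4(i * sh + p, j * sw + q, cc, s, h, w, c)];
          Y[idx4(i, j, cc, s, h2, w2, c)] = acc * inv;
        }
  return Y;
}
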
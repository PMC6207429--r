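#include <Rcpp.h>
using namespace Rcpp;

// Dense 3x3 (or any odd kernel) same-padding convolution kernels for the
// layered network. Arrays are R-ordered: X is H x W x C (dim attribute),
// W is kh x kw x Cin x Cout. All loops are plain C++ for determinism.

static inline int dim3(const NumericVector& x, int i) {
  IntegerVector d = x.attr("dim");
  return d[i];
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector X, NumericVector W, NumericVector b) {
  IntegerVector dx = X.attr("dim");
  IntegerVector dw = W.attr("dim");
  const int H = dx[0], Wd = dx[1], Cin = dx[2];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != Cin) stop("filter input channels do not match image channels");
  const int ph = kh / 2, pw = kw / 2;
  NumericVector out(H * Wd * Cout);
  out.attr("dim") = IntegerVector::create(H, Wd, Cout);
  const double* x = X.begin();
  const double* w = W.begin();
  double* o = out.begin();
  for (int co = 0; co < Cout; ++co) {
    for (int ci = 0; ci < Cin; ++ci) {
      const double* wk = w + (size_t)co * kh * kw * Cin + (size_t)ci * kh * kw;
      const double* xc = x + (size_t)ci * H * Wd;
      for (int j = 0; j < Wd; ++j) {
        for (int i = 0; i < H; ++i) {
          double acc = 0.0;
          for (int v = 0; v < kw; ++v) {
            int jj = j + v - pw;
            if (jj < 0 || jj >= Wd) continue;
            for (int u = 0; u < kh; ++u) {
              int ii = i + u - ph;
              if (ii < 0 || ii >= H) continue;
              acc += wk[u + kh * v] * xc[ii + (size_t)jj * H];
            }
          }
          o[i + (size_t)j * H + (size_t)co * H * Wd] += acc;
        }
      }
    }
    double bb = b[co];
    double* oc = o + (size_t)co * H * Wd;
    for (int t = 0; t < H * Wd; ++t) oc[t] += bb;
  }
  return out;
}

// Gradient of the loss w.r.t. the layer input, given gradient w.r.t. the
// pre-activation output dI (H x W x Cout). Correlation with flipped kernels.
// [[Rcpp::export(name = ".conv2d_backward_input")]]
NumericVector conv2d_backward_input(NumericVector dI, NumericVector W) {
  IntegerVector dg = dI.attr("dim");
  IntegerVector dw = W.attr("dim");
  const int H = dg[0], Wd = dg[1], Cout = dg[2];
  const int kh = dw[0], kw = dw[1], Cin = dw[2];
  if (dw[3] != Cout) stop("filter output channels do not match gradient channels");
  const int ph = kh / 2, pw = kw / 2;
  NumericVector out(H * Wd * Cin);
  out.attr("dim") = IntegerVector::create(H, Wd, Cin);
  const double* g = dI.begin();
  const double* w = W.begin();
  double* o = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* gc = g + (size_t)co * H * Wd;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* wk = w + (size_t)co * kh * kw * Cin + (size_t)ci * kh * kw;
      double* oc = o + (size_t)ci * H * Wd;
      for (int j = 0; j < Wd; ++j) {
        for (int i = 0; i < H; ++i) {
          double gij = gc[i + (size_t)j * H];
          if (gij == 0.0) continue;
          for (int v = 0; v < kw; ++v) {
            int jj = j + v - pw;
            if (jj < 0 || jj >= Wd) continue;
            for (int u = 0; u < kh; ++u) {
              int ii = i + u - ph;
              if (ii < 0 || ii >= H) continue;
              oc[ii + (size_t)jj * H] += wk[u + kh * v] * gij;
            }
          }
        }
      }
    }
  }
  return out;
}

// Gradient w.r.t. filter weights: X is the layer input (H x W x Cin),
// dI the pre-activation gradient (H x W x Cout); kernel size kh x kw.
// [[Rcpp::export(name = ".conv2d_backward_weights")]]
NumericVector conv2d_backward_weights(NumericVector X, NumericVector dI,
                                      int kh, int kw) {
  IntegerVector dx = X.attr("dim");
  IntegerVector dg = dI.attr("dim");
  const int H = dx[0], Wd = dx[1], Cin = dx[2], Cout = dg[2];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector out((size_t)kh * kw * Cin * Cout);
  out.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  const double* x = X.begin();
  const double* g = dI.begin();
  double* o = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* gc = g + (size_t)co * H * Wd;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x + (size_t)ci * H * Wd;
      double* ok = o + (size_t)co * kh * kw * Cin + (size_t)ci * kh * kw;
      for (int v = 0; v < kw; ++v) {
        for (int u = 0; u < kh; ++u) {
          double acc = 0.0;
          for (int j = 0; j < Wd; ++j) {
            int jj = j + v - pw;
            if (jj < 0 || jj >= Wd) continue;
            for (int i = 0; i < H; ++i) {
              int ii = i + u - ph;
              if (ii < 0 || ii >= H) continue;
              acc += gc[i + (size_t)j * H] * xc[ii + (size_t)jj * H];
            }
          }
          ok[u + kh * v] = acc;
        }
      }
    }
  }
  return out;
}

// 2x2 non-overlapping max pool. Returns pooled array plus 1-based argmax
// linear indices into the input plane, for exact gradient routing.
// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward(NumericVector X) {
  IntegerVector dx = X.attr("dim");
  const int H = dx[0], Wd = dx[1], C = dx[2];
  if (H % 2 || Wd % 2) stop("max pooling needs even spatial dimensions");
  const int Ho = H / 2, Wo = Wd / 2;
  NumericVector out((size_t)Ho * Wo * C);
  IntegerVector arg((size_t)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double* x = X.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * Wd;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = R_NegInf; int bidx = 0;
        for (int v = 0; v < 2; ++v) {
          for (int u = 0; u < 2; ++u) {
            int ii = 2 * i + u, jj = 2 * j + v;
            int idx = ii + jj * H;
            if (xc[idx] > best) { best = xc[idx]; bidx = idx; }
          }
        }
        out[i + (size_t)j * Ho + (size_t)c * Ho * Wo] = best;
        arg[i + (size_t)j * Ho + (size_t)c * Ho * Wo] = bidx + 1;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward(NumericVector dOut, IntegerVector argmax,
                               int H, int W) {
  IntegerVector dg = dOut.attr("dim");
  const int Ho = dg[0], Wo = dg[1], C = dg[2];
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Ho * Wo; ++t) {
      size_t src = (size_t)c * Ho * Wo + t;
      out[(size_t)c * H * W + (argmax[src] - 1)] += dOut[src];
    }
  }
  return out;
}
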
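#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are (H, W, C) numeric arrays, column-major. im2col flattens
// sliding k x k patches into a (Hout*Wout) x (k*k*C) matrix so convolution
// becomes one GEMM; col2im is its adjoint (used for input gradients).
// Patch column layout: col = ci*k*k + kx*k + ky (0-based).

// [[Rcpp::export(name = ".c_im2col")]]
NumericMatrix c_im2col(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericMatrix P(Hout * Wout, k * k * C);
  const double *px = x.begin();
  double *pp = P.begin();
  const int rows = Hout * Wout;
  for (int ci = 0; ci < C; ++ci) {
    const double *xc = px + (R_xlen_t)ci * H * W;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        double *col = pp + (R_xlen_t)(ci * k * k + kx * k + ky) * rows;
        for (int ox = 0; ox < Wout; ++ox) {
          int ix = ox * stride - pad + kx;
          double *dst = col + (R_xlen_t)ox * Hout;
          if (ix < 0 || ix >= W) {
            for (int oy = 0; oy < Hout; ++oy) dst[oy] = 0.0;
            continue;
          }
          const double *src = xc + (R_xlen_t)ix * H;
          for (int oy = 0; oy < Hout; ++oy) {
            int iy = oy * stride - pad + ky;
            dst[oy] = (iy < 0 || iy >= H) ? 0.0 : src[iy];
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export(name = ".c_col2im")]]
NumericVector c_col2im(NumericMatrix dP, int H, int W, int C, int k,
                       int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * C);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  double *pdx = dx.begin();
  const double *pp = dP.begin();
  const int rows = Hout * Wout;
  for (int ci = 0; ci < C; ++ci) {
    double *xc = pdx + (R_xlen_t)ci * H * W;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const double *col = pp + (R_xlen_t)(ci * k * k + kx * k + ky) * rows;
        for (int ox = 0; ox < Wout; ++ox) {
          int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          double *dst = xc + (R_xlen_t)ix * H;
          const double *src = col + (R_xlen_t)ox * Hout;
          for (int oy = 0; oy < Hout; ++oy) {
            int iy = oy * stride - pad + ky;
            if (iy >= 0 && iy < H) dst[iy] += src[oy];
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling, stride 1, "same" padding (k odd). Returns pooled map and the
// 0-based linear argmax per output element for the backward pass.
// [[Rcpp::export(name = ".c_maxpool")]]
List c_maxpool(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int pad = (k - 1) / 2;
  NumericVector y((R_xlen_t)H * W * C);
  IntegerVector amax((R_xlen_t)H * W * C);
  y.attr("dim") = d;
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = amax.begin();
  for (int ci = 0; ci < C; ++ci) {
    const double *xc = px + (R_xlen_t)ci * H * W;
    for (int ox = 0; ox < W; ++ox) {
      for (int oy = 0; oy < H; ++oy) {
        double best = R_NegInf; int bi = -1;
        for (int kx = 0; kx < k; ++kx) {
          int ix = ox - pad + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            int iy = oy - pad + ky;
            if (iy < 0 || iy >= H) continue;
            double v = xc[(R_xlen_t)ix * H + iy];
            if (v > best) { best = v; bi = ix * H + iy; }
          }
        }
        R_xlen_t o = (R_xlen_t)ci * H * W + (R_xlen_t)ox * H + oy;
        py[o] = best;
        pa[o] = bi + ci * H * W;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".c_maxpool_bwd")]]
NumericVector c_maxpool_bwd(NumericVector dy, IntegerVector amax) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double *pdy = dy.begin();
  const int *pa = amax.begin();
  double *pdx = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) pdx[pa[i]] += pdy[i];
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export(name = ".c_upsample2")]]
NumericVector c_upsample2(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector y((R_xlen_t)4 * H * W * C);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C);
  const double *px = x.begin();
  double *py = y.begin();
  for (int ci = 0; ci < C; ++ci)
    for (int ox = 0; ox < 2 * W; ++ox)
      for (int oy = 0; oy < 2 * H; ++oy)
        py[(R_xlen_t)ci * 4 * H * W + (R_xlen_t)ox * 2 * H + oy] =
          px[(R_xlen_t)ci * H * W + (R_xlen_t)(ox / 2) * H + oy / 2];
  return y;
}

// [[Rcpp::export(name = ".c_upsample2_bwd")]]
NumericVector c_upsample2_bwd(NumericVector dy) {
  IntegerVector d = dy.attr("dim");
  const int H2 = d[0], W2 = d[1], C = d[2];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((R_xlen_t)H * W * C);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  for (int ci = 0; ci < C; ++ci)
    for (int ox = 0; ox < W2; ++ox)
      for (int oy = 0; oy < H2; ++oy)
        pdx[(R_xlen_t)ci * H * W + (R_xlen_t)(ox / 2) * H + oy / 2] +=
          pdy[(R_xlen_t)ci * H2 * W2 + (R_xlen_t)ox * H2 + oy];
  return dx;
}
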
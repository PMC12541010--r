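#include <Rcpp.h>
using namespace Rcpp;

// Dense 2D convolution kernels for (H, W, C, N) column-major arrays.
// Stride is always 1 with "same" zero padding; pooling and transposed
// convolution use the fixed 2x2/stride-2 geometry of the U-Net ladder.

static inline R_xlen_t idx4(int i, int j, int c, int n, int H, int W, int C) {
  return i + (R_xlen_t)H * (j + (R_xlen_t)W * (c + (R_xlen_t)C * n));
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y((R_xlen_t)H * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  const double *px = x.begin(), *pw_ = w.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double bb = b[co];
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double acc = bb;
          for (int ci = 0; ci < Ci; ++ci)
            for (int kj = 0; kj < kw; ++kj) {
              int jj = j + kj - pw;
              if (jj < 0 || jj >= W) continue;
              const double *xcol = px + idx4(0, jj, ci, n, H, W, Ci);
              const double *wcol = pw_ + (R_xlen_t)kh * (kj + (R_xlen_t)kw * (ci + (R_xlen_t)Ci * co));
              for (int ki = 0; ki < kh; ++ki) {
                int ii = i + ki - ph;
                if (ii < 0 || ii >= H) continue;
                acc += xcol[ii] * wcol[ki];
              }
            }
          py[idx4(i, j, co, n, H, W, Co)] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector gx((R_xlen_t)H * W * Ci * N), gw(w.size()), gb(Co);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *px = x.begin(), *pw_ = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double gbacc = 0.0;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double g = pg[idx4(i, j, co, n, H, W, Co)];
          gbacc += g;
          if (g == 0.0) continue;
          for (int ci = 0; ci < Ci; ++ci)
            for (int kj = 0; kj < kw; ++kj) {
              int jj = j + kj - pw;
              if (jj < 0 || jj >= W) continue;
              const R_xlen_t xoff = idx4(0, jj, ci, n, H, W, Ci);
              const R_xlen_t woff = (R_xlen_t)kh * (kj + (R_xlen_t)kw * (ci + (R_xlen_t)Ci * co));
              for (int ki = 0; ki < kh; ++ki) {
                int ii = i + ki - ph;
                if (ii < 0 || ii >= H) continue;
                pgx[xoff + ii] += g * pw_[woff + ki];
                pgw[woff + ki] += g * px[xoff + ii];
              }
            }
        }
      gb[co] += gbacc;
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and the flat argmax
// offset (0..3, column-major within the window) needed by the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector amax((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  amax.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = amax.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double best = -R_PosInf;
          int barg = 0;
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              double v = px[idx4(2 * i + a, 2 * j + b, c, n, H, W, C)];
              if (v > best) { best = v; barg = a + 2 * b; }
            }
          R_xlen_t o = idx4(i, j, c, n, Ho, Wo, C);
          py[o] = best;
          pa[o] = barg;
        }
  return List::create(_["y"] = y, _["arg"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector gy, IntegerVector arg, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *pg = gy.begin();
  const int *pa = arg.begin();
  double *px = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          R_xlen_t o = idx4(i, j, c, n, Ho, Wo, C);
          int a = pa[o] % 2, b = pa[o] / 2;
          px[idx4(2 * i + a, 2 * j + b, c, n, H, W, C)] += pg[o];
        }
  return gx;
}

// Transposed convolution, kernel 2x2, stride 2 (learnable 2x upsampling).
// w has dim (2, 2, Cin, Cout); output is (2H, 2W, Cout, N).
// [[Rcpp::export]]
NumericVector cpp_convt2_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  int Co = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (R_xlen_t k = 0; k < y.size(); ++k) py[k] = 0.0;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double bb = b[co];
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          py[idx4(i, j, co, n, Ho, Wo, Co)] = bb;
      for (int ci = 0; ci < Ci; ++ci) {
        const double *wblk = pw + 4 * (ci + (R_xlen_t)Ci * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = px[idx4(i, j, ci, n, H, W, Ci)];
            if (v == 0.0) continue;
            for (int bq = 0; bq < 2; ++bq)
              for (int aq = 0; aq < 2; ++aq)
                py[idx4(2 * i + aq, 2 * j + bq, co, n, Ho, Wo, Co)] += v * wblk[aq + 2 * bq];
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  int Co = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(x.size()), gw(w.size()), gb(Co);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double gbacc = 0.0;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          gbacc += pg[idx4(i, j, co, n, Ho, Wo, Co)];
      gb[co] += gbacc;
      for (int ci = 0; ci < Ci; ++ci) {
        const double *wblk = pw + 4 * (ci + (R_xlen_t)Ci * co);
        double *gwblk = pgw + 4 * (ci + (R_xlen_t)Ci * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = px[idx4(i, j, ci, n, H, W, Ci)];
            double acc = 0.0;
            for (int bq = 0; bq < 2; ++bq)
              for (int aq = 0; aq < 2; ++aq) {
                const double g = pg[idx4(2 * i + aq, 2 * j + bq, co, n, Ho, Wo, Co)];
                acc += g * wblk[aq + 2 * bq];
                gwblk[aq + 2 * bq] += g * v;
              }
            pgx[idx4(i, j, ci, n, H, W, Ci)] += acc;
          }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
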
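// Low-level tensor ops for the detector. All tensors are R 4-d arrays with
// dim = c(N, C, H, W); element (n,c,h,w) sits at n + N*(c + C*(h + H*w))
// because R arrays are column-major. Convolutions use im2col + GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t ix4(int n, int c, int h, int w, int N, int C, int H) {
  return n + (R_xlen_t)N * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (N,C,H,W)");
  return d;
}

// repack sample n into a contiguous buffer xl[w + W*(h + H*c)]
static void pack_one(const double* x, int n, int N, int C, int H, int W,
                     std::vector<double>& xl) {
  xl.resize((size_t)C * H * W);
  for (int c = 0; c < C; ++c)
    for (int h = 0; h < H; ++h) {
      const double* src = x + ix4(n, c, h, 0, N, C, H);
      double* dst = &xl[(size_t)(c * H + h) * W];
      R_xlen_t strd = (R_xlen_t)N * C * H;
      for (int w = 0; w < W; ++w) dst[w] = src[w * strd];
    }
}

static void unpack_add_one(const std::vector<double>& xl, double* gx, int n,
                           int N, int C, int H, int W) {
  for (int c = 0; c < C; ++c)
    for (int h = 0; h < H; ++h) {
      const double* src = &xl[(size_t)(c * H + h) * W];
      double* dst = gx + ix4(n, c, h, 0, N, C, H);
      R_xlen_t strd = (R_xlen_t)N * C * H;
      for (int w = 0; w < W; ++w) dst[w * strd] += src[w];
    }
}

// im2col from packed layout: rows r = (c*kh + a)*kw + b, cols p = oh*OW + ow
static void im2col_one(const std::vector<double>& xl, int C, int H, int W,
                       int kh, int kw, int stride, int pad,
                       int OH, int OW, arma::mat& A) {
  for (int c = 0; c < C; ++c) {
    for (int a = 0; a < kh; ++a) {
      for (int b = 0; b < kw; ++b) {
        int r = (c * kh + a) * kw + b;
        double* Arow = A.memptr() + r;  // column-major: stride = n_rows
        size_t nr = A.n_rows;
        for (int oh = 0; oh < OH; ++oh) {
          int h = oh * stride + a - pad;
          bool hok = (h >= 0 && h < H);
          const double* base = hok ? &xl[(size_t)(c * H + h) * W] : nullptr;
          for (int ow = 0; ow < OW; ++ow) {
            int w = ow * stride + b - pad;
            double v = (hok && w >= 0 && w < W) ? base[w] : 0.0;
            Arow[(size_t)(oh * OW + ow) * nr] = v;
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& A, std::vector<double>& gxl, int C,
                       int H, int W, int kh, int kw, int stride, int pad,
                       int OH, int OW) {
  std::fill(gxl.begin(), gxl.end(), 0.0);
  gxl.resize((size_t)C * H * W, 0.0);
  for (int c = 0; c < C; ++c) {
    for (int a = 0; a < kh; ++a) {
      for (int b = 0; b < kw; ++b) {
        int r = (c * kh + a) * kw + b;
        const double* Arow = A.memptr() + r;
        size_t nr = A.n_rows;
        for (int oh = 0; oh < OH; ++oh) {
          int h = oh * stride + a - pad;
          if (h < 0 || h >= H) continue;
          double* base = &gxl[(size_t)(c * H + h) * W];
          for (int ow = 0; ow < OW; ++ow) {
            int w = ow * stride + b - pad;
            if (w < 0 || w >= W) continue;
            base[w] += Arow[(size_t)(oh * OW + ow) * nr];
          }
        }
      }
    }
  }
}

static arma::mat flatten_weights(const NumericVector& wt, int OC, int IC,
                                 int kh, int kw) {
  arma::mat Wm(OC, (size_t)IC * kh * kw);
  const double* w = wt.begin();
  for (int o = 0; o < OC; ++o)
    for (int i = 0; i < IC; ++i)
      for (int a = 0; a < kh; ++a)
        for (int b = 0; b < kw; ++b)
          Wm(o, (i * kh + a) * kw + b) =
            w[o + (R_xlen_t)OC * (i + (R_xlen_t)IC * (a + (R_xlen_t)kh * b))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector wt,
                            NumericVector bias, int stride, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(wt);
  int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  int OC = dw[0], IC = dw[1], kh = dw[2], kw = dw[3];
  if (IC != C) stop("channel mismatch between input and kernel");
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  NumericVector y((R_xlen_t)N * OC * OH * OW);
  y.attr("dim") = IntegerVector::create(N, OC, OH, OW);
  arma::mat Wm = flatten_weights(wt, OC, IC, kh, kw);
  arma::mat A((size_t)C * kh * kw, (size_t)OH * OW);
  std::vector<double> xl;
  double* py = y.begin();
  const double* pb = bias.begin();
  for (int n = 0; n < N; ++n) {
    pack_one(x.begin(), n, N, C, H, W, xl);
    im2col_one(xl, C, H, W, kh, kw, stride, pad, OH, OW, A);
    arma::mat Y = Wm * A;  // OC x P
    for (int oc = 0; oc < OC; ++oc) {
      double bo = pb[oc];
      R_xlen_t strd = (R_xlen_t)N * OC * OH;
      for (int oh = 0; oh < OH; ++oh) {
        double* dst = py + ix4(n, oc, oh, 0, N, OC, OH);
        const double* yr = Y.memptr() + oc;
        for (int ow = 0; ow < OW; ++ow)
          dst[ow * strd] = yr[(size_t)(oh * OW + ow) * OC] + bo;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector wt, NumericVector gy,
                   int stride, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(wt), dg = dims4(gy);
  int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  int OC = dw[0], kh = dw[2], kw = dw[3];
  int OH = dg[2], OW = dg[3];
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = dx;
  NumericVector gwv(wt.size());
  gwv.attr("dim") = dw;
  NumericVector gb(OC);
  arma::mat Wm = flatten_weights(wt, OC, C, kh, kw);
  arma::mat Gw(OC, (size_t)C * kh * kw, arma::fill::zeros);
  arma::mat A((size_t)C * kh * kw, (size_t)OH * OW);
  arma::mat Gy(OC, (size_t)OH * OW);
  std::vector<double> xl, gxl((size_t)C * H * W);
  double* pgb = gb.begin();
  for (int n = 0; n < N; ++n) {
    const double* pg = gy.begin();
    for (int oc = 0; oc < OC; ++oc) {
      double acc = 0.0;
      R_xlen_t strd = (R_xlen_t)N * OC * OH;
      double* Gr = Gy.memptr() + oc;
      for (int oh = 0; oh < OH; ++oh) {
        const double* src = pg + ix4(n, oc, oh, 0, N, OC, OH);
        for (int ow = 0; ow < OW; ++ow) {
          double g = src[ow * strd];
          Gr[(size_t)(oh * OW + ow) * OC] = g;
          acc += g;
        }
      }
      pgb[oc] += acc;
    }
    pack_one(x.begin(), n, N, C, H, W, xl);
    im2col_one(xl, C, H, W, kh, kw, stride, pad, OH, OW, A);
    Gw += Gy * A.t();
    arma::mat GA = Wm.t() * Gy;  // (C*kh*kw) x P
    col2im_one(GA, gxl, C, H, W, kh, kw, stride, pad, OH, OW);
    unpack_add_one(gxl, gx.begin(), n, N, C, H, W);
  }
  double* pgw = gwv.begin();
  for (int o = 0; o < OC; ++o)
    for (int i = 0; i < C; ++i)
      for (int a = 0; a < kh; ++a)
        for (int b = 0; b < kw; ++b)
          pgw[o + (R_xlen_t)OC * (i + (R_xlen_t)C * (a + (R_xlen_t)kh * b))] =
            Gw(o, (i * kh + a) * kw + b);
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gb);
}

// Batch norm over (N,H,W) per channel. training: use batch stats and return
// them so the caller can update running stats; eval: use supplied stats.
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector mean_in, NumericVector var_in, double eps,
               bool training) {
  IntegerVector dx = dims4(x);
  int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  NumericVector y(x.size());
  y.attr("dim") = dx;
  NumericVector mu(C), v(C);
  const double* px = x.begin();
  double cnt = (double)N * H * W;
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int h = 0; h < H; ++h)
        for (int w = 0; w < W; ++w)
          for (int n = 0; n < N; ++n) {
            double t = px[ix4(n, c, h, w, N, C, H)];
            s += t; s2 += t * t;
          }
      mu[c] = s / cnt;
      v[c] = s2 / cnt - mu[c] * mu[c];
      if (v[c] < 0) v[c] = 0;
    }
  } else {
    mu = clone(mean_in); v = clone(var_in);
  }
  double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    double inv = gamma[c] / std::sqrt(v[c] + eps);
    double sh = beta[c] - mu[c] * inv;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int n = 0; n < N; ++n) {
          R_xlen_t i = ix4(n, c, h, w, N, C, H);
          py[i] = px[i] * inv + sh;
        }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = v);
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, NumericVector gamma, NumericVector mu,
               NumericVector v, double eps, NumericVector gy) {
  IntegerVector dx = dims4(x);
  int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  double cnt = (double)N * H * W;
  NumericVector gx(x.size());
  gx.attr("dim") = dx;
  NumericVector gg(C), gb(C);
  const double* px = x.begin();
  const double* pg = gy.begin();
  double* pgx = gx.begin();
  for (int c = 0; c < C; ++c) {
    double istd = 1.0 / std::sqrt(v[c] + eps);
    double sg = 0, sgx = 0;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int n = 0; n < N; ++n) {
          R_xlen_t i = ix4(n, c, h, w, N, C, H);
          double xh = (px[i] - mu[c]) * istd;
          sg += pg[i];
          sgx += pg[i] * xh;
        }
    gg[c] = sgx;
    gb[c] = sg;
    double k1 = gamma[c] * istd;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int n = 0; n < N; ++n) {
          R_xlen_t i = ix4(n, c, h, w, N, C, H);
          double xh = (px[i] - mu[c]) * istd;
          pgx[i] = k1 * (pg[i] - sg / cnt - xh * sgx / cnt);
        }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = gg, _["gbeta"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_silu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    y[i] = x[i] * s;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_silu_bw(NumericVector x, NumericVector gy) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    gx[i] = gy[i] * (s + x[i] * s * (1.0 - s));
  }
  return gx;
}

// Max pooling, stride 1 usage in SPPF but general stride supported.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector dx = dims4(x);
  int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  int OH = (H + 2 * pad - k) / stride + 1;
  int OW = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)N * C * OH * OW);
  y.attr("dim") = IntegerVector::create(N, C, OH, OW);
  IntegerVector am(y.size());  // flat index into x of the winner, or -1
  const double* px = x.begin();
  double* py = y.begin();
  R_xlen_t q = 0;
  for (int w = 0; w < OW; ++w)
    for (int h = 0; h < OH; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = -std::numeric_limits<double>::infinity();
          R_xlen_t bi = -1;
          for (int a = 0; a < k; ++a) {
            int hh = h * stride + a - pad;
            if (hh < 0 || hh >= H) continue;
            for (int b = 0; b < k; ++b) {
              int ww = w * stride + b - pad;
              if (ww < 0 || ww >= W) continue;
              R_xlen_t i = ix4(n, c, hh, ww, N, C, H);
              if (px[i] > best) { best = px[i]; bi = i; }
            }
          }
          R_xlen_t o = ix4(n, c, h, w, N, C, OH);
          py[o] = (bi >= 0) ? best : 0.0;
          am[o] = (int)bi;
          ++q;
        }
  (void)q;
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector argmax, NumericVector gy,
                             IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (argmax[i] >= 0) gx[argmax[i]] += gy[i];
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  IntegerVector dx = dims4(x);
  int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  NumericVector y((R_xlen_t)N * C * 4 * H * W);
  y.attr("dim") = IntegerVector::create(N, C, 2 * H, 2 * W);
  const double* px = x.begin();
  double* py = y.begin();
  for (int w = 0; w < 2 * W; ++w)
    for (int h = 0; h < 2 * H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          py[ix4(n, c, h, w, N, C, 2 * H)] =
            px[ix4(n, c, h / 2, w / 2, N, C, H)];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector gy) {
  IntegerVector dg = dims4(gy);
  int N = dg[0], C = dg[1], H2 = dg[2], W2 = dg[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  const double* pg = gy.begin();
  double* px = gx.begin();
  for (int w = 0; w < W2; ++w)
    for (int h = 0; h < H2; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          px[ix4(n, c, h / 2, w / 2, N, C, H)] +=
            pg[ix4(n, c, h, w, N, C, H2)];
  return gx;
}

// Bilinear sampling with zero padding outside the map.
// positions: px, py arrays of dim (N, K, OH, OW) in 0-based pixel coords
// (px = column/x axis, py = row/y axis). Output S: dim (N, C, K, OH*OW)
// flattened spatially; value S(n,c,k,p) = bilinear(x[n,c,,], py, px).
// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericVector x, NumericVector py,
                                  NumericVector px) {
  IntegerVector dx = dims4(x), dp = dims4(py);
  int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  int K = dp[1], OH = dp[2], OW = dp[3];
  R_xlen_t P = (R_xlen_t)OH * OW;
  NumericVector S((R_xlen_t)N * C * K * P);
  S.attr("dim") = IntegerVector::create(N, C, K, (int)P);
  const double* vx = x.begin();
  double* vs = S.begin();
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh) {
      int p = oh * OW + ow;  // row-major pixel id, matches im2col col order? no
      // use column-major id to keep R-side reshaping simple:
      p = ow * OH + oh;
      for (int k = 0; k < K; ++k)
        for (int n = 0; n < N; ++n) {
          double yy = py[ix4(n, k, oh, ow, N, K, OH)];
          double xx = px[ix4(n, k, oh, ow, N, K, OH)];
          int y0 = (int)std::floor(yy), x0 = (int)std::floor(xx);
          double fy = yy - y0, fx = xx - x0;
          for (int c = 0; c < C; ++c) {
            double acc = 0.0;
            for (int dy = 0; dy <= 1; ++dy) {
              int ys = y0 + dy;
              if (ys < 0 || ys >= H) continue;
              double wy = dy ? fy : 1.0 - fy;
              for (int dxx = 0; dxx <= 1; ++dxx) {
                int xs = x0 + dxx;
                if (xs < 0 || xs >= W) continue;
                double wx = dxx ? fx : 1.0 - fx;
                acc += wy * wx * vx[ix4(n, c, ys, xs, N, C, H)];
              }
            }
            vs[n + (R_xlen_t)N * (c + (R_xlen_t)C * (k + (R_xlen_t)K * p))] = acc;
          }
        }
    }
  return S;
}

// Backward of bilinear sampling: given gS (N,C,K,P), return gx (N,C,H,W) and
// position gradients gpy, gpx (N,K,OH,OW) summed over channels.
// [[Rcpp::export]]
List cpp_bilinear_sample_bw(NumericVector x, NumericVector py,
                            NumericVector px, NumericVector gS) {
  IntegerVector dx = dims4(x), dp = dims4(py);
  int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  int K = dp[1], OH = dp[2], OW = dp[3];
  NumericVector gx(x.size());
  gx.attr("dim") = dx;
  NumericVector gpy(py.size()), gpx(px.size());
  gpy.attr("dim") = dp; gpx.attr("dim") = dp;
  const double* vx = x.begin();
  const double* vg = gS.begin();
  double* vgx = gx.begin();
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh) {
      int p = ow * OH + oh;
      for (int k = 0; k < K; ++k)
        for (int n = 0; n < N; ++n) {
          double yy = py[ix4(n, k, oh, ow, N, K, OH)];
          double xx = px[ix4(n, k, oh, ow, N, K, OH)];
          int y0 = (int)std::floor(yy), x0 = (int)std::floor(xx);
          double fy = yy - y0, fx = xx - x0;
          double gy_acc = 0.0, gx_acc = 0.0;
          for (int c = 0; c < C; ++c) {
            double g = vg[n + (R_xlen_t)N * (c + (R_xlen_t)C *
                          (k + (R_xlen_t)K * p))];
            if (g == 0.0) continue;
            double v[2][2] = {{0, 0}, {0, 0}};
            for (int dy = 0; dy <= 1; ++dy) {
              int ys = y0 + dy;
              if (ys < 0 || ys >= H) continue;
              for (int dxx = 0; dxx <= 1; ++dxx) {
                int xs = x0 + dxx;
                if (xs < 0 || xs >= W) continue;
                v[dy][dxx] = vx[ix4(n, c, ys, xs, N, C, H)];
                double wy = dy ? fy : 1.0 - fy;
                double wx = dxx ? fx : 1.0 - fx;
                vgx[ix4(n, c, ys, xs, N, C, H)] += g * wy * wx;
              }
            }
            // d value / d fy and / d fx
            gy_acc += g * ((v[1][0] - v[0][0]) * (1.0 - fx) +
                           (v[1][1] - v[0][1]) * fx);
            gx_acc += g * ((v[0][1] - v[0][0]) * (1.0 - fy) +
                           (v[1][1] - v[1][0]) * fy);
          }
          gpy[ix4(n, k, oh, ow, N, K, OH)] = gy_acc;
          gpx[ix4(n, k, oh, ow, N, K, OH)] = gx_acc;
        }
    }
  return List::create(_["gx"] = gx, _["gpy"] = gpy, _["gpx"] = gpx);
}

// [[Rcpp::export]]
NumericVector cpp_leaky_fw(NumericVector x, double alpha) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : alpha * x[i];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_leaky_bw(NumericVector x, NumericVector gy, double alpha) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    gx[i] = x[i] > 0 ? gy[i] : alpha * gy[i];
  return gx;
}
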
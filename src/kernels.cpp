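#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Tensors are R arrays in column-major order with dim = (H, W, C, N).
// Conv weights have dim = (K, K, C_in/groups, C_out).

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xd, NumericVector wt,
                         IntegerVector wd, NumericVector bias, int stride,
                         int pad, int groups) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cg = wd[2], Cout = wd[3];
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const int cpg_out = Cout / groups;
  const bool has_bias = bias.size() > 0;
  NumericVector y(R_xlen_t(Ho) * Wo * Cout * N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const int g = co / cpg_out;
      const double b = has_bias ? bias[co] : 0.0;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b;
          for (int ci = 0; ci < Cg; ++ci) {
            const int cin = g * Cg + ci;
            for (int kj = 0; kj < K; ++kj) {
              const int wi = wo * stride - pad + kj;
              if (wi < 0 || wi >= W) continue;
              for (int ki = 0; ki < K; ++ki) {
                const int hi = ho * stride - pad + ki;
                if (hi < 0 || hi >= H) continue;
                acc += x[idx4(hi, wi, cin, n, H, W, C)] *
                       wt[ki + K * (kj + K * (ci + Cg * co))];
              }
            }
          }
          y[idx4(ho, wo, co, n, Ho, Wo, Cout)] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd_input")]]
NumericVector conv2d_bwd_input(NumericVector dy, IntegerVector yd,
                               NumericVector wt, IntegerVector wd,
                               IntegerVector xd, int stride, int pad,
                               int groups) {
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  const int H = xd[0], W = xd[1], C = xd[2];
  const int K = wd[0], Cg = wd[2];
  const int cpg_out = Cout / groups;
  NumericVector dx(R_xlen_t(H) * W * C * N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const int g = co / cpg_out;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double d = dy[idx4(ho, wo, co, n, Ho, Wo, Cout)];
          if (d == 0.0) continue;
          for (int ci = 0; ci < Cg; ++ci) {
            const int cin = g * Cg + ci;
            for (int kj = 0; kj < K; ++kj) {
              const int wi = wo * stride - pad + kj;
              if (wi < 0 || wi >= W) continue;
              for (int ki = 0; ki < K; ++ki) {
                const int hi = ho * stride - pad + ki;
                if (hi < 0 || hi >= H) continue;
                dx[idx4(hi, wi, cin, n, H, W, C)] +=
                    d * wt[ki + K * (kj + K * (ci + Cg * co))];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// [[Rcpp::export(name = ".conv2d_bwd_weight")]]
List conv2d_bwd_weight(NumericVector x, IntegerVector xd, NumericVector dy,
                       IntegerVector yd, IntegerVector wd, int stride, int pad,
                       int groups, bool want_bias) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  const int K = wd[0], Cg = wd[2];
  const int cpg_out = Cout / groups;
  NumericVector dw(R_xlen_t(K) * K * Cg * Cout);
  NumericVector db(want_bias ? Cout : 0);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const int g = co / cpg_out;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double d = dy[idx4(ho, wo, co, n, Ho, Wo, Cout)];
          if (want_bias) db[co] += d;
          if (d == 0.0) continue;
          for (int ci = 0; ci < Cg; ++ci) {
            const int cin = g * Cg + ci;
            for (int kj = 0; kj < K; ++kj) {
              const int wi = wo * stride - pad + kj;
              if (wi < 0 || wi >= W) continue;
              for (int ki = 0; ki < K; ++ki) {
                const int hi = ho * stride - pad + ki;
                if (hi < 0 || hi >= H) continue;
                dw[ki + K * (kj + K * (ci + Cg * co))] +=
                    d * x[idx4(hi, wi, cin, n, H, W, C)];
              }
            }
          }
        }
      }
    }
  }
  dw.attr("dim") = wd;
  return List::create(Named("dw") = dw, Named("db") = db);
}

// 8-connectivity connected-component labeling of a binary matrix.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int w0 = 0; w0 < W; ++w0) {
    for (int h0 = 0; h0 < H; ++h0) {
      if (mask(h0, w0) == 0 || lab(h0, w0) != 0) continue;
      ++next;
      lab(h0, w0) = next;
      q.push(std::make_pair(h0, w0));
      while (!q.empty()) {
        const int h = q.front().first, w = q.front().second;
        q.pop();
        for (int dw = -1; dw <= 1; ++dw) {
          for (int dh = -1; dh <= 1; ++dh) {
            if (dh == 0 && dw == 0) continue;
            const int hh = h + dh, ww = w + dw;
            if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
            if (mask(hh, ww) != 0 && lab(hh, ww) == 0) {
              lab(hh, ww) = next;
              q.push(std::make_pair(hh, ww));
            }
          }
        }
      }
    }
  }
  return lab;
}
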
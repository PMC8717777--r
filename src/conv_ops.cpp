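#include <Rcpp.h>
using namespace Rcpp;

// im2col over a whole (H, W, C, N) batch (column-major). Output is a
// (kh*kw*C) x (Ho*Wo*N) matrix: row order kh fastest, then kw, then c
// (matching the column-major layout of a (kh, kw, C, Cout) weight array);
// columns are sample-major blocks, within each block ho fastest then wo.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C;
  R_xlen_t P = (R_xlen_t)Ho * Wo;
  NumericMatrix out(K, P * N);
  double *po = out.begin();
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    const double *pxn = px + (R_xlen_t)n * H * W * C;
    double *pon = po + (R_xlen_t)n * P * K;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double *pc = pon + ((R_xlen_t)wo * Ho + ho) * K;
        int i0 = ho * stride - pad;
        int j0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *pxc = pxn + (R_xlen_t)c * H * W;
          for (int dj = 0; dj < kw; ++dj) {
            int j = j0 + dj;
            bool jin = (j >= 0 && j < W);
            for (int di = 0; di < kh; ++di) {
              int i = i0 + di;
              double v = 0.0;
              if (jin && i >= 0 && i < H) v = pxc[(R_xlen_t)j * H + i];
              pc[c * kh * kw + dj * kh + di] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add a (kh*kw*C) x (Ho*Wo*N) gradient matrix
// back into an (H, W, C, N) batch.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C;
  R_xlen_t P = (R_xlen_t)Ho * Wo;
  NumericVector out((R_xlen_t)H * W * C * N);
  double *po = out.begin();
  const double *pc0 = cols.begin();
  for (int n = 0; n < N; ++n) {
    double *pon = po + (R_xlen_t)n * H * W * C;
    const double *pcn = pc0 + (R_xlen_t)n * P * K;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double *pc = pcn + ((R_xlen_t)wo * Ho + ho) * K;
        int i0 = ho * stride - pad;
        int j0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double *poc = pon + (R_xlen_t)c * H * W;
          for (int dj = 0; dj < kw; ++dj) {
            int j = j0 + dj;
            if (j < 0 || j >= W) continue;
            for (int di = 0; di < kh; ++di) {
              int i = i0 + di;
              if (i < 0 || i >= H) continue;
              poc[(R_xlen_t)j * H + i] += pc[c * kh * kw + dj * kh + di];
            }
          }
        }
      }
    }
  }
  return out;
}

// (Ho*Wo*N) x Cout GEMM result -> (Ho, Wo, Cout, N) batch with bias add.
// y columns are sample-major as produced by crossprod(W, im2col(...)).
// [[Rcpp::export]]
NumericVector conv_pack_cpp(NumericMatrix y, NumericVector b,
                            int Ho, int Wo, int cout, int N) {
  R_xlen_t P = (R_xlen_t)Ho * Wo;
  NumericVector out(P * cout * N);
  double *po = out.begin();
  const double *py = y.begin();   // y is cout x (P*N)
  for (int n = 0; n < N; ++n) {
    for (R_xlen_t p = 0; p < P; ++p) {
      const double *col = py + (((R_xlen_t)n * P) + p) * cout;
      for (int c = 0; c < cout; ++c) {
        po[((R_xlen_t)n * cout + c) * P + p] = col[c] + b[c];
      }
    }
  }
  return out;
}

// (Ho, Wo, Cout, N) gradient -> cout x (Ho*Wo*N) sample-major matrix
// (adjoint of conv_pack_cpp, bias excluded).
// [[Rcpp::export]]
NumericMatrix conv_unpack_cpp(NumericVector g, int Ho, int Wo, int cout, int N) {
  R_xlen_t P = (R_xlen_t)Ho * Wo;
  NumericMatrix out(cout, P * N);
  double *po = out.begin();
  const double *pg = g.begin();
  for (int n = 0; n < N; ++n) {
    for (R_xlen_t p = 0; p < P; ++p) {
      double *col = po + (((R_xlen_t)n * P) + p) * cout;
      for (int c = 0; c < cout; ++c) {
        col[c] = pg[((R_xlen_t)n * cout + c) * P + p];
      }
    }
  }
  return out;
}

// Per-channel mean and (biased) variance of an (H, W, C, N) batch.
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x, int HW, int C, int N) {
  NumericVector mean(C), var(C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *p = px + ((R_xlen_t)n * C + c) * HW;
      for (int i = 0; i < HW; ++i) {
        s += p[i];
        s2 += p[i] * p[i];
      }
    }
    double m = s / ((double)HW * N);
    mean[c] = m;
    double v = s2 / ((double)HW * N) - m * m;
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// Channel-broadcast affine map y = x * sc[c] + shift[c] on (H, W, C, N).
// [[Rcpp::export]]
NumericVector bn_affine_cpp(NumericVector x, NumericVector sc,
                            NumericVector shift, int HW, int C, int N) {
  NumericVector out(x.size());
  const double *px = x.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      double a = sc[c], b = shift[c];
      for (int i = 0; i < HW; ++i) po[off + i] = px[off + i] * a + b;
    }
  }
  return out;
}

// Per-channel sums of g and of g * xhat (dbeta and dgamma).
// [[Rcpp::export]]
List bn_dots_cpp(NumericVector g, NumericVector xhat, int HW, int C, int N) {
  NumericVector dbeta(C), dgamma(C);
  const double *pg = g.begin();
  const double *ph = xhat.begin();
  for (int c = 0; c < C; ++c) {
    double sb = 0, sg = 0;
    for (int n = 0; n < N; ++n) {
      R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      for (int i = 0; i < HW; ++i) {
        sb += pg[off + i];
        sg += pg[off + i] * ph[off + i];
      }
    }
    dbeta[c] = sb;
    dgamma[c] = sg;
  }
  return List::create(_["dbeta"] = dbeta, _["dgamma"] = dgamma);
}

// dx = a[c] * g + b[c] + cc[c] * xhat, channel-broadcast on (H, W, C, N).
// [[Rcpp::export]]
NumericVector bn_bwd_cpp(NumericVector g, NumericVector xhat,
                         NumericVector a, NumericVector b, NumericVector cc,
                         int HW, int C, int N) {
  NumericVector out(g.size());
  const double *pg = g.begin();
  const double *ph = xhat.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      double ka = a[c], kb = b[c], kc = cc[c];
      for (int i = 0; i < HW; ++i) {
        po[off + i] = ka * pg[off + i] + kb + kc * ph[off + i];
      }
    }
  }
  return out;
}

// One Adam update. m and v are updated in place (they are private to the
// optimiser); the returned vector is a fresh copy of the updated parameter.
// [[Rcpp::export]]
NumericVector adam_update_cpp(NumericVector value, NumericVector grad,
                              NumericVector m, NumericVector v,
                              double lr, double b1, double b2, double eps,
                              double bc1, double bc2) {
  R_xlen_t n = value.size();
  NumericVector out(n);
  double *pm = m.begin(), *pv = v.begin(), *po = out.begin();
  const double *pval = value.begin(), *pg = grad.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double g = pg[i];
    pm[i] = b1 * pm[i] + (1 - b1) * g;
    pv[i] = b2 * pv[i] + (1 - b2) * g * g;
    double mhat = pm[i] / bc1;
    double vhat = pv[i] / bc2;
    po[i] = pval[i] - lr * mhat / (std::sqrt(vhat) + eps);
  }
  return out;
}
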
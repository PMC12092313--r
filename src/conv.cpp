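#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout: column-major R arrays with dim (H, W, C, N).
// "Same" padding: out = ceil(in / stride); total pad =
// max(0, (out-1)*stride + (k-1)*dilation + 1 - in), split floor-half before.

static inline int out_dim(int in, int stride) { return (in + stride - 1) / stride; }

static inline int pad_before(int in, int out, int k, int stride, int dil) {
  int tot = (out - 1) * stride + (k - 1) * dil + 1 - in;
  if (tot < 0) tot = 0;
  return tot / 2;
}

// x: (H,W,Cin,N); w: (kh,kw,Cin/groups,Cout) -> y: (Ho,Wo,Cout,N)
// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         int stride, int dilation, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cin_g = wd[2], Cout = wd[3];
  if (C / groups != cin_g) stop("conv2d: channel/group mismatch");
  const int cout_g = Cout / groups;
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const int ph = pad_before(H, Ho, kh, stride, dilation);
  const int pw = pad_before(W, Wo, kw, stride, dilation);

  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double *px = x.begin(), *pw_ = w.begin();
  double *py = y.begin();

  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g)
      for (int co = 0; co < cout_g; ++co) {
        const int coAbs = g * cout_g + co;
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho) {
            double acc = 0.0;
            for (int ci = 0; ci < cin_g; ++ci) {
              const int ciAbs = g * cin_g + ci;
              const double *xb = px + (static_cast<R_xlen_t>(n) * C + ciAbs) * H * W;
              const double *wb = pw_ + (static_cast<R_xlen_t>(coAbs) * cin_g + ci) * kh * kw;
              for (int j = 0; j < kw; ++j) {
                const int wi = wo * stride - pw + j * dilation;
                if (wi < 0 || wi >= W) continue;
                for (int i = 0; i < kh; ++i) {
                  const int hi = ho * stride - ph + i * dilation;
                  if (hi < 0 || hi >= H) continue;
                  acc += xb[hi + static_cast<R_xlen_t>(wi) * H] * wb[i + j * kh];
                }
              }
            }
            py[ho + static_cast<R_xlen_t>(Ho) * (wo + static_cast<R_xlen_t>(Wo) * (coAbs + static_cast<R_xlen_t>(Cout) * n))] = acc;
          }
      }
  return y;
}

// gradient wrt input and weights; gy: (Ho,Wo,Cout,N)
// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int dilation, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cin_g = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int cout_g = Cout / groups;
  const int ph = pad_before(H, Ho, kh, stride, dilation);
  const int pw = pad_before(W, Wo, kw, stride, dilation);

  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  const double *px = x.begin(), *pw_ = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();

  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g)
      for (int co = 0; co < cout_g; ++co) {
        const int coAbs = g * cout_g + co;
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho) {
            const double gval = pgy[ho + static_cast<R_xlen_t>(Ho) * (wo + static_cast<R_xlen_t>(Wo) * (coAbs + static_cast<R_xlen_t>(Cout) * n))];
            if (gval == 0.0) continue;
            for (int ci = 0; ci < cin_g; ++ci) {
              const int ciAbs = g * cin_g + ci;
              const double *xb = px + (static_cast<R_xlen_t>(n) * C + ciAbs) * H * W;
              double *gxb = pgx + (static_cast<R_xlen_t>(n) * C + ciAbs) * H * W;
              const double *wb = pw_ + (static_cast<R_xlen_t>(coAbs) * cin_g + ci) * kh * kw;
              double *gwb = pgw + (static_cast<R_xlen_t>(coAbs) * cin_g + ci) * kh * kw;
              for (int j = 0; j < kw; ++j) {
                const int wi = wo * stride - pw + j * dilation;
                if (wi < 0 || wi >= W) continue;
                for (int i = 0; i < kh; ++i) {
                  const int hi = ho * stride - ph + i * dilation;
                  if (hi < 0 || hi >= H) continue;
                  const R_xlen_t xi = hi + static_cast<R_xlen_t>(wi) * H;
                  gxb[xi] += gval * wb[i + j * kh];
                  gwb[i + j * kh] += gval * xb[xi];
                }
              }
            }
          }
      }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// 3x3 max pooling, same padding (pad with -inf); returns y and flat argmax
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const int ph = pad_before(H, Ho, k, stride, 1);
  const int pw = pad_before(W, Wo, k, stride, 1);
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size());
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = arg.begin();
  R_xlen_t oi = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (static_cast<R_xlen_t>(n) * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; R_xlen_t bestIdx = -1;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pw + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - ph + i;
              if (hi < 0 || hi >= H) continue;
              const R_xlen_t xi = base + hi + static_cast<R_xlen_t>(wi) * H;
              if (px[xi] > best) { best = px[xi]; bestIdx = xi; }
            }
          }
          // column-major order of y matches iteration only per (c,n) plane; compute explicitly
          oi = ho + static_cast<R_xlen_t>(Ho) * (wo + static_cast<R_xlen_t>(Wo) * (c + static_cast<R_xlen_t>(C) * n));
          py[oi] = best;
          pa[oi] = static_cast<int>(bestIdx);
        }
    }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(IntegerVector arg, NumericVector gy, IntegerVector xdim) {
  R_xlen_t nx = 1; for (int i = 0; i < xdim.size(); ++i) nx *= xdim[i];
  NumericVector gx(nx); gx.attr("dim") = xdim;
  double *pgx = gx.begin(); const double *pgy = gy.begin(); const int *pa = arg.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) pgx[pa[i]] += pgy[i];
  return gx;
}

// 3x3 average pooling, same padding; divisor = count of valid (in-frame) taps
// [[Rcpp::export(name = ".avgpool_fwd")]]
NumericVector avgpool_fwd(NumericVector x, int k, int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const int ph = pad_before(H, Ho, k, stride, 1);
  const int pw = pad_before(W, Wo, k, stride, 1);
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *px = x.begin(); double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (static_cast<R_xlen_t>(n) * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0; int cnt = 0;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pw + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - ph + i;
              if (hi < 0 || hi >= H) continue;
              acc += px[base + hi + static_cast<R_xlen_t>(wi) * H];
              ++cnt;
            }
          }
          py[ho + static_cast<R_xlen_t>(Ho) * (wo + static_cast<R_xlen_t>(Wo) * (c + static_cast<R_xlen_t>(C) * n))] = acc / cnt;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".avgpool_bwd")]]
NumericVector avgpool_bwd(NumericVector gy, IntegerVector xdim, int k, int stride) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const int ph = pad_before(H, Ho, k, stride, 1);
  const int pw = pad_before(W, Wo, k, stride, 1);
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = xdim;
  double *pgx = gx.begin(); const double *pgy = gy.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (static_cast<R_xlen_t>(n) * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double gval = pgy[ho + static_cast<R_xlen_t>(Ho) * (wo + static_cast<R_xlen_t>(Wo) * (c + static_cast<R_xlen_t>(C) * n))];
          int cnt = 0;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pw + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - ph + i;
              if (hi < 0 || hi >= H) continue;
              ++cnt;
            }
          }
          if (cnt == 0) continue;
          const double share = gval / cnt;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pw + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - ph + i;
              if (hi < 0 || hi >= H) continue;
              pgx[base + hi + static_cast<R_xlen_t>(wi) * H] += share;
            }
          }
        }
    }
  return gx;
}
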
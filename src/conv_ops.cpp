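// Compiled numerical kernels for the network forward/backward passes.
// Array layout convention throughout: feature maps are R arrays with
// dim = (H, W, C, B), column-major, so a single image is an arma::cube.
// Convolution weights have dim = (kh, kw, C_in/groups, C_out).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& B) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, B)");
  H = d[0]; W = d[1]; C = d[2]; B = d[3];
}

// im2col for one image restricted to one channel group.
// col is (kh*kw*cg) x (Ho*Wo); row index k = ki + kj*kh + c*kh*kw,
// matching the column-major vectorisation of a (kh, kw, cg) weight slab.
static void im2col(const double* xp, int H, int W, int c0, int cg,
                   int kh, int kw, int pad, arma::mat& col) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  for (int c = 0; c < cg; ++c) {
    const double* plane = xp + (size_t)(c0 + c) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int krow = ki + kj * kh + c * kh * kw;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + kj - pad;
          double* dst = col.colptr(0) + krow; // stride col.n_rows between cols
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(krow, ho + wo * Ho) = 0.0;
            continue;
          }
          const double* src = plane + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + ki - pad;
            col(krow, ho + wo * Ho) =
              (hi >= 0 && hi < H) ? src[hi] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

// scatter-add the column matrix back into an image (transpose of im2col)
static void col2im_add(const arma::mat& col, int H, int W, int c0, int cg,
                       int kh, int kw, int pad, double* xp) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  for (int c = 0; c < cg; ++c) {
    double* plane = xp + (size_t)(c0 + c) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int krow = ki + kj * kh + c * kh * kw;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + kj - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = plane + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + ki - pad;
            if (hi >= 0 && hi < H)
              dst[hi] += col(krow, ho + wo * Ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                            int pad, int groups) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cing = wd[2], cout = wd[3];
  if (C != cing * groups) stop("conv2d: input channels inconsistent with kernel/groups");
  if (cout % groups != 0) stop("conv2d: output channels not divisible by groups");
  const int coutg = cout / groups;
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: spatial dims too small for kernel");

  NumericVector y((size_t)Ho * Wo * cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, B);

  const int K = kh * kw * cing;
  arma::mat col(K, (size_t)Ho * Wo);
  const double* xp0 = x.begin();
  double* yp0 = y.begin();

  for (int bi = 0; bi < B; ++bi) {
    const double* xp = xp0 + (size_t)bi * H * W * C;
    double* yp = yp0 + (size_t)bi * Ho * Wo * cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xp, H, W, g * cing, cing, kh, kw, pad, col);
      // weight slab for this group's output channels, as K x coutg
      arma::mat wg(const_cast<double*>(w.begin()) + (size_t)g * coutg * K,
                   K, coutg, false, true);
      arma::mat out = col.t() * wg; // (Ho*Wo) x coutg
      for (int oc = 0; oc < coutg; ++oc) {
        const double bias = b[g * coutg + oc];
        double* dst = yp + (size_t)(g * coutg + oc) * Ho * Wo;
        const double* src = out.colptr(oc);
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dst[i] = src[i] + bias;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                   int pad, int groups) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cing = wd[2], cout = wd[3];
  const int coutg = cout / groups;
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;

  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(cout);

  const int K = kh * kw * cing;
  arma::mat col(K, (size_t)Ho * Wo);
  const double* xp0 = x.begin();
  const double* dyp0 = dy.begin();

  for (int bi = 0; bi < B; ++bi) {
    const double* xp = xp0 + (size_t)bi * H * W * C;
    const double* dyp = dyp0 + (size_t)bi * Ho * Wo * cout;
    double* dxp = dx.begin() + (size_t)bi * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xp, H, W, g * cing, cing, kh, kw, pad, col);
      arma::mat dyg(const_cast<double*>(dyp) + (size_t)g * coutg * Ho * Wo,
                    (size_t)Ho * Wo, coutg, false, true);
      arma::mat wg(const_cast<double*>(w.begin()) + (size_t)g * coutg * K,
                   K, coutg, false, true);
      arma::mat dwg(dw.begin() + (size_t)g * coutg * K, K, coutg, false, true);
      dwg += col * dyg;                    // K x coutg
      arma::mat dcol = wg * dyg.t();       // K x (Ho*Wo)
      col2im_add(dcol, H, W, g * cing, cing, kh, kw, pad, dxp);
      for (int oc = 0; oc < coutg; ++oc)
        db[g * coutg + oc] += arma::accu(dyg.col(oc));
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2.  idx stores the 0-based linear offset of the
// argmax within the (H, W) plane so the backward pass can scatter.
// [[Rcpp::export]]
List maxpool2_fw_cpp(NumericVector x) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  if (H % 2 != 0 || W % 2 != 0) stop("maxpool2: H and W must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const size_t planes = (size_t)C * B;
  for (size_t p = 0; p < planes; ++p) {
    const double* src = xp + p * H * W;
    double* dst = yp + p * Ho * Wo;
    int* id = ip + p * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = 2 * ho, w0 = 2 * wo;
        int best = h0 + w0 * H;
        double bv = src[best];
        const int cand[3] = { h0 + 1 + w0 * H, h0 + (w0 + 1) * H, h0 + 1 + (w0 + 1) * H };
        for (int k = 0; k < 3; ++k)
          if (src[cand[k]] > bv) { bv = src[cand[k]]; best = cand[k]; }
        dst[ho + wo * Ho] = bv;
        id[ho + wo * Ho] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw_cpp(IntegerVector idx, NumericVector dy, int H, int W) {
  int Ho, Wo, C, B;
  get_dims4(dy, Ho, Wo, C, B);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  const size_t planes = (size_t)C * B;
  for (size_t p = 0; p < planes; ++p) {
    const double* g = dy.begin() + p * Ho * Wo;
    const int* id = idx.begin() + p * Ho * Wo;
    double* out = dx.begin() + p * H * W;
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) out[id[i]] += g[i];
  }
  return dx;
}

// weights for 2x bilinear upsampling without corner alignment:
// output index i samples input coordinate (i + 0.5)/2 - 0.5
static void up2_weights(int n, std::vector<int>& i0, std::vector<int>& i1,
                        std::vector<double>& w0) {
  i0.resize(2 * n); i1.resize(2 * n); w0.resize(2 * n);
  for (int i = 0; i < 2 * n; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    int f = (int)std::floor(s);
    double t = s - f;
    int a = std::min(std::max(f, 0), n - 1);
    int b = std::min(std::max(f + 1, 0), n - 1);
    i0[i] = a; i1[i] = b; w0[i] = 1.0 - t;
  }
}

// [[Rcpp::export]]
NumericVector upsample2_fw_cpp(NumericVector x) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  std::vector<int> h0, h1, w0i, w1i; std::vector<double> hw, ww;
  up2_weights(H, h0, h1, hw);
  up2_weights(W, w0i, w1i, ww);
  const size_t planes = (size_t)C * B;
  for (size_t p = 0; p < planes; ++p) {
    const double* src = x.begin() + p * H * W;
    double* dst = y.begin() + p * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* cA = src + (size_t)w0i[wo] * H;
      const double* cB = src + (size_t)w1i[wo] * H;
      const double a = ww[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double b = hw[ho];
        const double top = b * cA[h0[ho]] + (1 - b) * cA[h1[ho]];
        const double bot = b * cB[h0[ho]] + (1 - b) * cB[h1[ho]];
        dst[ho + (size_t)wo * Ho] = a * top + (1 - a) * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw_cpp(NumericVector dy, int H, int W) {
  int Ho, Wo, C, B;
  get_dims4(dy, Ho, Wo, C, B);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  std::vector<int> h0, h1, w0i, w1i; std::vector<double> hw, ww;
  up2_weights(H, h0, h1, hw);
  up2_weights(W, w0i, w1i, ww);
  const size_t planes = (size_t)C * B;
  for (size_t p = 0; p < planes; ++p) {
    const double* g = dy.begin() + p * Ho * Wo;
    double* out = dx.begin() + p * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      double* cA = out + (size_t)w0i[wo] * H;
      double* cB = out + (size_t)w1i[wo] * H;
      const double a = ww[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double b = hw[ho];
        const double v = g[ho + (size_t)wo * Ho];
        cA[h0[ho]] += a * b * v;
        cA[h1[ho]] += a * (1 - b) * v;
        cB[h0[ho]] += (1 - a) * b * v;
        cB[h1[ho]] += (1 - a) * (1 - b) * v;
      }
    }
  }
  return dx;
}

// symmetric average Hausdorff distance between two point sets (rows = points)
// [[Rcpp::export]]
double avg_hausdorff_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  if (n == 0 || m == 0) stop("avg_hausdorff: empty point set");
  double sab = 0.0, sba = 0.0;
  std::vector<double> minb(m, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double ax = a(i, 0), ay = a(i, 1);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1);
      const double d = dx * dx + dy * dy;
      if (d < best) best = d;
      if (d < minb[j]) minb[j] = d;
    }
    sab += std::sqrt(best);
  }
  for (int j = 0; j < m; ++j) sba += std::sqrt(minb[j]);
  return 0.5 * (sab / n + sba / m);
}
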
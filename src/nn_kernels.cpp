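// Minimal single-threaded CNN primitives used by the network code in R/.
// Layout convention: activations are H x W x C arrays (R dim order), conv
// weights are K x (C*k*k) matrices with patch columns ordered
// (kernel col, kernel row, channel), transposed-conv weights (K*4) x C.
// Arithmetic is single precision; the im2col buffer is (H*W) x (C*k*k) so
// patch gathers and GEMM outputs are contiguous. Inputs/outputs cross the
// R boundary as doubles.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fcube as_fcube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  arma::fcube out(d[0], d[1], d[2]);
  const double* p = x.begin();
  float* q = out.memptr();
  const size_t n = out.n_elem;
  for (size_t i = 0; i < n; ++i) q[i] = static_cast<float>(p[i]);
  return out;
}

static NumericVector as_rarray(const arma::fcube& x) {
  NumericVector out(x.n_elem);
  const float* p = x.memptr();
  for (size_t i = 0; i < x.n_elem; ++i) out[i] = p[i];
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

static arma::fmat as_fmat(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  const double* p = x.begin();
  float* q = out.memptr();
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = static_cast<float>(p[i]);
  return out;
}

static arma::fvec as_fvec(const NumericVector& x) {
  arma::fvec out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = static_cast<float>(x[i]);
  return out;
}

// gather k x k patches (zero padding k/2) into a (H*W) x (C*k*k) matrix;
// row = pixel (row-fastest), column j = kc + k*kr + k*k*c. Each (j, w)
// pair is one contiguous copy of up to H floats.
static void im2col_t(const arma::fcube& x, const int k, arma::fmat& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  cols.zeros(H * W, C * k * k);
  for (int c = 0; c < C; ++c) {
    const float* xs = x.slice_memptr(c);
    for (int kr = 0; kr < k; ++kr) {
      for (int kc = 0; kc < k; ++kc) {
        const int j = c * k * k + kr * k + kc;
        float* dst = cols.colptr(j);
        const int h0 = std::max(0, p - kr);           // first valid out row
        const int h1 = std::min(H, H + p - kr);       // one past last
        if (h1 <= h0) continue;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kc - p;
          if (sw < 0 || sw >= W) continue;
          std::memcpy(dst + (size_t)w * H + h0,
                      xs + (size_t)sw * H + h0 + kr - p,
                      (size_t)(h1 - h0) * sizeof(float));
        }
      }
    }
  }
}

// adjoint: scatter-add a (H*W) x (C*k*k) gradient back to H x W x C
static void col2im_t(const arma::fmat& cols, const int k, arma::fcube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  x.zeros();
  for (int c = 0; c < C; ++c) {
    float* xs = x.slice_memptr(c);
    for (int kr = 0; kr < k; ++kr) {
      for (int kc = 0; kc < k; ++kc) {
        const int j = c * k * k + kr * k + kc;
        const float* src = cols.colptr(j);
        const int h0 = std::max(0, p - kr);
        const int h1 = std::min(H, H + p - kr);
        if (h1 <= h0) continue;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kc - p;
          if (sw < 0 || sw >= W) continue;
          float* d = xs + (size_t)sw * H + h0 + kr - p;
          const float* s = src + (size_t)w * H + h0;
          for (int h = 0; h < h1 - h0; ++h) d[h] += s[h];
        }
      }
    }
  }
}

// alias the cube memory as a (H*W) x C matrix (no copy)
static arma::fmat alias_hw_c(const arma::fcube& x) {
  return arma::fmat(const_cast<float*>(x.memptr()), x.n_rows * x.n_cols,
                    x.n_slices, false, true);
}

// y = conv(x, w) + b, same resolution, stride 1, zero padding
static arma::fcube conv_fwd(const arma::fcube& x, const arma::fmat& w,
                            const arma::fvec& b, const int k,
                            arma::fmat& scratch) {
  const int H = x.n_rows, W = x.n_cols, K = w.n_rows;
  arma::fcube y(H, W, K);
  arma::fmat ym = alias_hw_c(y);
  if (k == 1) {
    ym = alias_hw_c(x) * w.t();
  } else {
    im2col_t(x, k, scratch);
    ym = scratch * w.t();
  }
  for (int kk = 0; kk < K; ++kk) y.slice(kk) += b[kk];
  return y;
}

// gradient w.r.t. the conv input
static arma::fcube conv_bwd_data(const arma::fcube& dy, const arma::fmat& w,
                                 const int k, const int C) {
  const int H = dy.n_rows, W = dy.n_cols;
  arma::fcube dx(H, W, C);
  if (k == 1) {
    arma::fmat dxm = alias_hw_c(dx);
    dxm = alias_hw_c(dy) * w;
  } else {
    arma::fmat dcols = alias_hw_c(dy) * w;  // (HW) x (C*k*k)
    col2im_t(dcols, k, dx);
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                             int k) {
  arma::fcube xc = as_fcube(x);
  arma::fmat scratch;
  arma::fcube y = conv_fwd(xc, as_fmat(w), as_fvec(b), k, scratch);
  return as_rarray(y);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy, int k,
                    bool need_dx, bool need_dw) {
  arma::fcube xc = as_fcube(x);
  arma::fcube dyc = as_fcube(dy);
  arma::fmat wf = as_fmat(w);
  arma::fmat dym = alias_hw_c(dyc);
  List out;
  if (need_dx) out["dx"] = as_rarray(conv_bwd_data(dyc, wf, k, xc.n_slices));
  if (need_dw) {
    arma::fmat dw;
    if (k == 1) {
      dw = dym.t() * alias_hw_c(xc);
    } else {
      arma::fmat cols;
      im2col_t(xc, k, cols);
      dw = dym.t() * cols;
    }
    NumericMatrix dwr(dw.n_rows, dw.n_cols);
    for (size_t i = 0; i < dw.n_elem; ++i) dwr[i] = dw.memptr()[i];
    out["dw"] = dwr;
    arma::fvec db = arma::sum(dym, 0).t();
    out["db"] = NumericVector(db.begin(), db.end());
  }
  return out;
}

// transposed convolution, kernel 2x2 stride 2: each input pixel paints a
// 2x2 output block; weight layout (K*4) x C with the 4 sub-positions
// ordered (dr, dc) in {(0,0),(1,0),(0,1),(1,1)} blocks of K rows each.
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericMatrix w, NumericVector b) {
  arma::fcube xc = as_fcube(x);
  arma::fmat wf = as_fmat(w);
  const int H = xc.n_rows, W = xc.n_cols;
  const int K = wf.n_rows / 4;
  arma::fmat y = alias_hw_c(xc) * wf.t();  // (HW) x (K*4)
  arma::fcube out(2 * H, 2 * W, K);
  for (int kk = 0; kk < K; ++kk) {
    float* os = out.slice_memptr(kk);
    const float bk = (float)b[kk];
    for (int q = 0; q < 4; ++q) {
      const int dr = q % 2, dc = q / 2;
      const float* src = y.colptr(q * K + kk);
      for (int ww = 0; ww < W; ++ww) {
        float* od = os + (size_t)(2 * ww + dc) * 2 * H + dr;
        const float* s = src + (size_t)ww * H;
        for (int hh = 0; hh < H; ++hh) od[2 * hh] = s[hh] + bk;
      }
    }
  }
  return as_rarray(out);
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                    bool need_dx, bool need_dw) {
  arma::fcube xc = as_fcube(x);
  arma::fcube dyc = as_fcube(dy);
  arma::fmat wf = as_fmat(w);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int K = wf.n_rows / 4;
  arma::fmat dym(H * W, 4 * K);
  for (int kk = 0; kk < K; ++kk) {
    const float* ds = dyc.slice_memptr(kk);
    for (int q = 0; q < 4; ++q) {
      const int dr = q % 2, dc = q / 2;
      float* dst = dym.colptr(q * K + kk);
      for (int ww = 0; ww < W; ++ww) {
        const float* s = ds + (size_t)(2 * ww + dc) * 2 * H + dr;
        float* d = dst + (size_t)ww * H;
        for (int hh = 0; hh < H; ++hh) d[hh] = s[2 * hh];
      }
    }
  }
  List out;
  if (need_dx) {
    arma::fcube dx(H, W, C);
    arma::fmat dxm = alias_hw_c(dx);
    dxm = dym * wf;
    out["dx"] = as_rarray(dx);
  }
  if (need_dw) {
    arma::fmat dw = dym.t() * alias_hw_c(xc);
    NumericMatrix dwr(dw.n_rows, dw.n_cols);
    for (size_t i = 0; i < dw.n_elem; ++i) dwr[i] = dw.memptr()[i];
    out["dw"] = dwr;
    arma::fvec db(K, arma::fill::zeros);
    for (int kk = 0; kk < K; ++kk)
      for (int q = 0; q < 4; ++q) db[kk] += arma::accu(dym.col(q * K + kk));
    out["db"] = NumericVector(db.begin(), db.end());
  }
  return out;
}

// ---- 2x2 max pooling, stride 2 (even H, W; the R side pads) ----------------

static arma::fcube pool_fwd(const arma::fcube& x, arma::uvec& idx) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::fcube y(Ho, Wo, C);
  idx.set_size((size_t)Ho * Wo * C);
  size_t p = 0;
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        float best = -std::numeric_limits<float>::infinity();
        size_t bi = 0;
        for (int dc = 0; dc < 2; ++dc) {
          for (int dr = 0; dr < 2; ++dr) {
            const int hh = 2 * h + dr, ww = 2 * w + dc;
            const float v = x(hh, ww, c);
            if (v > best) { best = v; bi = (size_t)c * H * W + (size_t)ww * H + hh; }
          }
        }
        y(h, w, c) = best;
        idx[p++] = bi;  // p follows column-major order of y
      }
    }
  }
  return y;
}

static arma::fcube pool_bwd(const arma::uvec& idx, const arma::fcube& dy,
                            const int H, const int W, const int C) {
  arma::fcube dx(H, W, C, arma::fill::zeros);
  const float* s = dy.memptr();
  float* d = dx.memptr();
  for (size_t i = 0; i < idx.n_elem; ++i) d[idx[i]] += s[i];
  return dx;
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  arma::fcube xc = as_fcube(x);
  arma::uvec idx;
  arma::fcube y = pool_fwd(xc, idx);
  IntegerVector ridx(idx.n_elem);
  for (size_t i = 0; i < idx.n_elem; ++i) ridx[i] = (int)idx[i];
  return List::create(Named("y") = as_rarray(y), Named("idx") = ridx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy, int H,
                               int W, int C) {
  NumericVector dx(H * W * C);
  for (int i = 0; i < idx.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// ---- fused feature-extractor pass for the perceptual loss ------------------
// Fixed VGG19-shaped layout up to the third tap: conv conv pool conv conv
// pool conv conv conv conv, ReLU after every conv, feature taps (post-ReLU)
// after convs 2, 4 and 8. The whole forward (and, when target taps are
// given, the backward to the input) runs in single precision without
// touching R, which keeps the per-step training cost near the GEMM floor.

#define N_EXT_CONV 8
static const int EXT_POOL_AFTER[N_EXT_CONV] = {0, 1, 0, 1, 0, 0, 0, 0};
static const int EXT_TAP[N_EXT_CONV] = {0, 1, 0, 1, 0, 0, 0, 1};

// [[Rcpp::export]]
List cpp_extractor_run(NumericMatrix x, List wlist, List blist,
                       NumericVector mu, Nullable<List> target_taps_,
                       bool want_taps, bool want_grad) {
  const int H = x.nrow(), W = x.ncol();
  std::vector<arma::fmat> ws(N_EXT_CONV);
  std::vector<arma::fvec> bs(N_EXT_CONV);
  for (int i = 0; i < N_EXT_CONV; ++i) {
    ws[i] = as_fmat(as<NumericMatrix>(wlist[i]));
    bs[i] = as_fvec(as<NumericVector>(blist[i]));
  }
  arma::fcube a(H, W, 3);
  for (int c = 0; c < 3; ++c) {
    float* q = a.slice_memptr(c);
    const double* p = x.begin();
    for (int i = 0; i < H * W; ++i) q[i] = (float)p[i];
  }
  std::vector<arma::fcube> outs(N_EXT_CONV);   // post-ReLU activations
  std::vector<arma::uvec> pidx(N_EXT_CONV);    // pool argmax indices
  std::vector<arma::ivec> pdims(N_EXT_CONV);
  arma::fmat scratch;
  std::vector<arma::fcube> taps;
  for (int i = 0; i < N_EXT_CONV; ++i) {
    arma::fcube z = conv_fwd(a, ws[i], bs[i], 3, scratch);
    z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    outs[i] = z;
    if (EXT_TAP[i]) taps.push_back(z);
    if (EXT_POOL_AFTER[i]) {
      pdims[i] = arma::ivec{(int)z.n_rows, (int)z.n_cols, (int)z.n_slices};
      a = pool_fwd(z, pidx[i]);
    } else {
      a = outs[i];
    }
  }
  List res;
  if (want_taps) {
    List rt(taps.size());
    for (size_t t = 0; t < taps.size(); ++t) rt[t] = as_rarray(taps[t]);
    res["taps"] = rt;
  }
  if (!want_grad) return res;
  if (target_taps_.isNull())
    stop("target taps are required to compute the perceptual gradient");
  List tt(target_taps_);
  // per-tap loss terms and gradients: mu_n / numel * sum((F - F_t)^2)
  NumericVector terms(taps.size());
  std::vector<arma::fcube> dtap(taps.size());
  for (size_t t = 0; t < taps.size(); ++t) {
    arma::fcube ft = as_fcube(as<NumericVector>(tt[t]));
    arma::fcube diff = taps[t] - ft;
    const double scale = mu[t] / (double)diff.n_elem;
    terms[t] = scale * (double)arma::accu(arma::square(diff));
    dtap[t] = (float)(2.0 * scale) * diff;
  }
  res["terms"] = terms;
  // backward (data gradients only)
  arma::fcube da;
  int tap_i = (int)taps.size() - 1;
  for (int i = N_EXT_CONV - 1; i >= 0; --i) {
    if (EXT_POOL_AFTER[i])
      da = pool_bwd(pidx[i], da, pdims[i][0], pdims[i][1], pdims[i][2]);
    if (EXT_TAP[i]) {
      if (da.n_elem == 0) da = dtap[tap_i];
      else da += dtap[tap_i];
      --tap_i;
    }
    // ReLU mask from the post-ReLU activation
    const arma::fcube& o = outs[i];
    for (size_t e = 0; e < da.n_elem; ++e)
      if (o.memptr()[e] <= 0.0f) da.memptr()[e] = 0.0f;
    const int cin = (i == 0) ? 3 : (int)ws[i].n_cols / 9;
    da = conv_bwd_data(da, ws[i], 3, cin);
  }
  NumericMatrix dpred(H, W);
  const float* d0 = da.slice_memptr(0);
  const float* d1 = da.slice_memptr(1);
  const float* d2 = da.slice_memptr(2);
  for (int i = 0; i < H * W; ++i) dpred[i] = d0[i] + d1[i] + d2[i];
  res["dpred"] = dpred;
  return res;
}

// ---- Zhang-Suen topology-preserving thinning --------------------------------

static inline int at(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  const int H = m.nrow(), W = m.ncol();
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          if (!m(r, c)) continue;
          // neighbours p2..p9 clockwise from north
          const int p2 = at(m, r - 1, c),     p3 = at(m, r - 1, c + 1),
                    p4 = at(m, r, c + 1),     p5 = at(m, r + 1, c + 1),
                    p6 = at(m, r + 1, c),     p7 = at(m, r + 1, c - 1),
                    p8 = at(m, r, c - 1),     p9 = at(m, r - 1, c - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          const int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                        (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                        (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                        (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      for (size_t i = 0; i < kill.size(); ++i)
        m(kill[i].first, kill[i].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return m;
}

// count of 8-connected foreground components
// [[Rcpp::export]]
int cpp_label_count(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<char> seen(H * W, 0);
  std::vector<int> stack;
  int n = 0;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      const int i0 = c0 * H + r0;
      if (!mask[i0] || seen[i0]) continue;
      ++n;
      stack.clear();
      stack.push_back(i0);
      seen[i0] = 1;
      while (!stack.empty()) {
        const int i = stack.back();
        stack.pop_back();
        const int r = i % H, c = i / H;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || cc < 0 || rr >= H || cc >= W) continue;
            const int j = cc * H + rr;
            if (mask[j] && !seen[j]) { seen[j] = 1; stack.push_back(j); }
          }
        }
      }
    }
  }
  return n;
}

// ---- tolerance point matching ----------------------------------------------
// a point of A matches when its nearest point of B is strictly closer than
// tau; uniform-grid bucketing keeps this near-linear in |A| + |B|.
// [[Rcpp::export]]
LogicalVector cpp_match_points(NumericMatrix A, NumericMatrix B, double tau) {
  const int nA = A.nrow(), nB = B.nrow();
  LogicalVector out(nA);
  if (nA == 0 || nB == 0) return out;
  double rmin = B(0, 0), cmin = B(0, 1);
  for (int i = 0; i < nB; ++i) {
    rmin = std::min(rmin, B(i, 0));
    cmin = std::min(cmin, B(i, 1));
  }
  const double cell = std::max(tau, 1e-9);
  std::map<std::pair<long, long>, std::vector<int> > grid;
  for (int i = 0; i < nB; ++i) {
    const long gr = (long)std::floor((B(i, 0) - rmin) / cell);
    const long gc = (long)std::floor((B(i, 1) - cmin) / cell);
    grid[std::make_pair(gr, gc)].push_back(i);
  }
  const double t2 = tau * tau;
  for (int i = 0; i < nA; ++i) {
    const long gr = (long)std::floor((A(i, 0) - rmin) / cell);
    const long gc = (long)std::floor((A(i, 1) - cmin) / cell);
    bool hit = false;
    for (long dr = -1; dr <= 1 && !hit; ++dr) {
      for (long dc = -1; dc <= 1 && !hit; ++dc) {
        std::map<std::pair<long, long>, std::vector<int> >::const_iterator it =
            grid.find(std::make_pair(gr + dr, gc + dc));
        if (it == grid.end()) continue;
        const std::vector<int>& bucket = it->second;
        for (size_t j = 0; j < bucket.size(); ++j) {
          const double d0 = A(i, 0) - B(bucket[j], 0);
          const double d1 = A(i, 1) - B(bucket[j], 1);
          if (d0 * d0 + d1 * d1 < t2) { hit = true; break; }
        }
      }
    }
    out[i] = hit;
  }
  return out;
}
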
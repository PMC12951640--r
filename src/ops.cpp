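#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Dense tensor layout throughout: column-major R arrays.
// Feature maps are [H, W, C, N]; kernels are [kh, kw, Cin, Cout].

static inline int dim4(const NumericVector& x, int i) {
  IntegerVector d = x.attr("dim");
  return d[i];
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  const int kh = dim4(w, 0), kw = dim4(w, 1), Ci = dim4(w, 2), Co = dim4(w, 3);
  if (Ci != C) stop("conv2d: input channel mismatch (%d vs %d)", C, Ci);
  const int ph = kh / 2, pw = kw / 2;  // "same" padding, odd kernels
  NumericVector y(static_cast<R_xlen_t>(H) * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  const double* px = x.begin();
  const double* pw_ = w.begin();
  double* py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      double* yc = py + (static_cast<R_xlen_t>(n) * Co + co) * H * W;
      const double bias = b[co];
      for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(H) * W; ++i) yc[i] = bias;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = px + (static_cast<R_xlen_t>(n) * C + ci) * H * W;
        for (int j = 0; j < kw; ++j) {
          for (int i = 0; i < kh; ++i) {
            const double wv = pw_[i + kh * (j + kw * (ci + static_cast<R_xlen_t>(C) * co))];
            if (wv == 0.0) continue;
            const int dh = i - ph, dw = j - pw;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
            for (int wc = w0; wc < w1; ++wc) {
              const double* xcol = xc + static_cast<R_xlen_t>(wc + dw) * H + dh;
              double* ycol = yc + static_cast<R_xlen_t>(wc) * H;
              for (int hc = h0; hc < h1; ++hc) ycol[hc] += wv * xcol[hc];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  const int kh = dim4(w, 0), kw = dim4(w, 1), Co = dim4(w, 3);
  const int ph = kh / 2, pw = kw / 2;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Co);
  const double* px = x.begin();
  const double* pw_ = w.begin();
  const double* pg = gy.begin();
  double* pgx = gx.begin();
  double* pgw = gw.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double* gc = pg + (static_cast<R_xlen_t>(n) * Co + co) * H * W;
      double acc = 0.0;
      for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(H) * W; ++i) acc += gc[i];
      gb[co] += acc;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = px + (static_cast<R_xlen_t>(n) * C + ci) * H * W;
        double* gxc = pgx + (static_cast<R_xlen_t>(n) * C + ci) * H * W;
        for (int j = 0; j < kw; ++j) {
          for (int i = 0; i < kh; ++i) {
            const R_xlen_t widx = i + kh * (j + kw * (ci + static_cast<R_xlen_t>(C) * co));
            const double wv = pw_[widx];
            const int dh = i - ph, dw = j - pw;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
            double wacc = 0.0;
            for (int wc = w0; wc < w1; ++wc) {
              const double* xcol = xc + static_cast<R_xlen_t>(wc + dw) * H + dh;
              double* gxcol = gxc + static_cast<R_xlen_t>(wc + dw) * H + dh;
              const double* gcol = gc + static_cast<R_xlen_t>(wc) * H;
              for (int hc = h0; hc < h1; ++hc) {
                wacc += xcol[hc] * gcol[hc];
                gxcol[hc] += wv * gcol[hc];
              }
            }
            pgw[widx] += wacc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  if (H % 2 || W % 2) stop("maxpool2: spatial extents must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 0-based linear index into x of each max
  const double* px = x.begin();
  double* py = y.begin();
  int* pi = idx.begin();
  R_xlen_t o = 0;
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double* xc = px + cn * H * W;
    const R_xlen_t base = cn * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h = 2 * ho, w = 2 * wo;
        R_xlen_t best = static_cast<R_xlen_t>(w) * H + h;
        double bv = xc[best];
        const R_xlen_t cands[3] = {best + 1, best + H, best + H + 1};
        for (int k = 0; k < 3; ++k)
          if (xc[cands[k]] > bv) { bv = xc[cands[k]]; best = cands[k]; }
        py[o] = bv;
        pi[o] = static_cast<int>(base + best);
        ++o;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gy, IntegerVector idx,
                                    IntegerVector xdim) {
  R_xlen_t n = static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  const double* pg = gy.begin();
  double* px = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) px[idx[i]] += pg[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x) {
  const int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  NumericVector y(static_cast<R_xlen_t>(4) * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double* px = x.begin();
  double* py = y.begin();
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double* xc = px + cn * H * W;
    double* yc = py + cn * 4 * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = xc[static_cast<R_xlen_t>(w) * H + h];
        double* o = yc + static_cast<R_xlen_t>(2 * w) * 2 * H + 2 * h;
        o[0] = v; o[1] = v; o[2 * H] = v; o[2 * H + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector gy) {
  const int H2 = dim4(gy, 0), W2 = dim4(gy, 1), C = dim4(gy, 2), N = dim4(gy, 3);
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* pg = gy.begin();
  double* px = gx.begin();
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double* gc = pg + cn * H2 * W2;
    double* xc = px + cn * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* o = gc + static_cast<R_xlen_t>(2 * w) * H2 + 2 * h;
        xc[static_cast<R_xlen_t>(w) * H + h] = o[0] + o[1] + o[H2] + o[H2 + 1];
      }
  }
  return gx;
}

// Connected-component labeling of a binary 3D mask (BFS).
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, int connectivity = 26) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("label3d: expected a 3D array");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int maxman = connectivity == 6 ? 1 : (connectivity == 18 ? 2 : 3);
  const int X = d[0], Y = d[1], Z = d[2];
  const R_xlen_t n = static_cast<R_xlen_t>(X) * Y * Z;
  IntegerVector lab(n);
  lab.attr("dim") = d;
  const int* pm = mask.begin();
  int* pl = lab.begin();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (pm[s] == 0 || pl[s] != 0) continue;
    ++next;
    pl[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = v % X, y = (v / X) % Y, z = v / (static_cast<R_xlen_t>(X) * Y);
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= Z) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= Y) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (std::abs(dx) + std::abs(dy) + std::abs(dz) > maxman) continue;
            const int xx = x + dx;
            if (xx < 0 || xx >= X) continue;
            const R_xlen_t u = xx + static_cast<R_xlen_t>(X) * (yy + static_cast<R_xlen_t>(Y) * zz);
            if (pm[u] != 0 && pl[u] == 0) {
              pl[u] = next;
              stack.push_back(u);
            }
          }
        }
      }
    }
  }
  return lab;
}
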
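// Stride-1, same-padded 2-D convolution (zero padding) plus the small
// elementwise/rearrangement kernels of the network, via im2col + GEMM.
//
// Feature arrays use the layout (h, w, n, c) in R's column-major order:
// for a fixed channel the (h, w, n) slab is contiguous, so the im2col
// matrix — (h*w*n) rows x (k*k*c_in) columns, one column per kernel tap —
// is filled with one large shifted block copy per (channel, tap, sample)
// and the GEMM result maps directly onto the output array (no scatter).
// 1x1 convolutions skip im2col entirely: the input already is the matrix.
// Kernels are (k, k, c_in, c_out), k odd.
//
// `single = TRUE` runs the GEMMs in float32 (the usual deep-learning
// precision, roughly twice the throughput); weights and activations stay
// doubles at the R level either way. Large scratch buffers are reused
// across calls (R is single-threaded) to avoid repeated page-faulting
// allocations inside the training loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

template <typename T>
static T* workspace(int which, std::size_t elems) {
  static std::vector<T> buf[4];
  if (buf[which].size() < elems) buf[which].resize(elems);
  return buf[which].data();
}

template <typename T>
static void im2col_fill(T* colsp, const double* x,
                        int h, int w, int ci, int n, int k, int pad) {
  const int hw = h * w;
  const std::size_t hwn = (std::size_t)hw * n;
  for (int c = 0; c < ci; ++c) {
    const double* xc = x + hwn * c;
    for (int dc = 0; dc < k; ++dc) {
      const int jlo = std::max(0, pad - dc), jhi = std::min(w, w + pad - dc);
      for (int dr = 0; dr < k; ++dr) {
        const int r = dr + k * dc + k * k * c;
        const int ilo = std::max(0, pad - dr), ihi = std::min(h, h + pad - dr);
        T* dst = colsp + hwn * r;
        const long off = (dr - pad) + (long)h * (dc - pad);
        for (int nn = 0; nn < n; ++nn) {
          T* dp = dst + (std::size_t)hw * nn;
          const double* sp = xc + (std::size_t)hw * nn + off;
          const long b0 = (long)h * jlo, b1 = (long)h * jhi;
          for (long t = b0; t < b1; ++t) dp[t] = (T)sp[t];
          for (int j = 0; j < jlo; ++j)
            std::fill(dp + (std::size_t)h * j, dp + (std::size_t)h * (j + 1), (T)0);
          for (int j = jhi; j < w; ++j)
            std::fill(dp + (std::size_t)h * j, dp + (std::size_t)h * (j + 1), (T)0);
          if (ilo > 0 || ihi < h) {
            for (int j = jlo; j < jhi; ++j) {
              T* col = dp + (std::size_t)h * j;
              for (int i = 0; i < ilo; ++i) col[i] = (T)0;
              for (int i = ihi; i < h; ++i) col[i] = (T)0;
            }
          }
        }
      }
    }
  }
}

// Returns an (hwn x K) im2col matrix in workspace 0; for k == 1 in double
// precision this is a zero-copy view of x itself.
template <typename T>
static arma::Mat<T> make_cols(const double* x, int h, int w, int ci, int n,
                              int k, int pad, bool& view) {
  const std::size_t hwn = (std::size_t)h * w * n;
  const int K = k * k * ci;
  view = false;
  if (k == 1 && std::is_same<T, double>::value) {
    view = true;
    return arma::Mat<T>((T*)x, hwn, K, false, true);
  }
  T* colsp = workspace<T>(0, hwn * K);
  if (k == 1) {
    for (std::size_t i = 0; i < hwn * K; ++i) colsp[i] = (T)x[i];
  } else {
    im2col_fill<T>(colsp, x, h, w, ci, n, k, pad);
  }
  return arma::Mat<T>(colsp, hwn, K, false, true);
}

template <typename T>
static void conv_fwd_impl(const double* x, const double* w, const double* b,
                          double* y, int h, int wid, int ci, int n, int k,
                          int co) {
  const int pad = (k - 1) / 2;
  const std::size_t hwn = (std::size_t)h * wid * n;
  const int K = k * k * ci;
  bool view;
  arma::Mat<T> cols = make_cols<T>(x, h, wid, ci, n, k, pad, view);
  arma::Mat<T> W(workspace<T>(1, (std::size_t)K * co), K, co, false, true);
  for (long i = 0; i < (long)K * co; ++i) W.memptr()[i] = (T)w[i];
  arma::Mat<T> Y(workspace<T>(2, hwn * co), hwn, co, false, true);
  Y = cols * W;
  for (int c = 0; c < co; ++c) {
    const T* src = Y.colptr(c);
    double* dst = y + hwn * c;
    const double bc = b[c];
    for (std::size_t p = 0; p < hwn; ++p) dst[p] = (double)src[p] + bc;
  }
}


// Direct convolution for a single output channel (the network's final HR
// projection): im2col would blow the data up k*k*ci-fold for a GEMV, so
// loop channels/taps directly; all three arrays stay cache-resident.
static void conv_fwd_co1(const double* x, const double* w, double b0,
                         double* y, int h, int wid, int ci, int n, int k) {
  const int pad = (k - 1) / 2;
  const int hw = h * wid;
  const std::size_t hwn = (std::size_t)hw * n;
  for (std::size_t i = 0; i < hwn; ++i) y[i] = b0;
  for (int c = 0; c < ci; ++c) {
    const double* xc = x + hwn * c;
    for (int dc = 0; dc < k; ++dc) {
      const int jlo = std::max(0, pad - dc), jhi = std::min(wid, wid + pad - dc);
      for (int dr = 0; dr < k; ++dr) {
        const double wv = w[dr + k * dc + k * k * c];
        const int ilo = std::max(0, pad - dr), ihi = std::min(h, h + pad - dr);
        const long off = (dr - pad) + (long)h * (dc - pad);
        for (int nn = 0; nn < n; ++nn) {
          const double* sp = xc + (std::size_t)hw * nn + off;
          double* yp = y + (std::size_t)hw * nn;
          for (int j = jlo; j < jhi; ++j) {
            const long base = (long)h * j;
            for (int i = ilo; i < ihi; ++i) yp[base + i] += wv * sp[base + i];
          }
        }
      }
    }
  }
}

static void conv_bwd_co1(const double* x, const double* w, const double* dy,
                         double* dwp, double* dbp, double* dxp, bool need_dx,
                         int h, int wid, int ci, int n, int k) {
  const int pad = (k - 1) / 2;
  const int hw = h * wid;
  const std::size_t hwn = (std::size_t)hw * n;
  double db = 0;
  for (std::size_t i = 0; i < hwn; ++i) db += dy[i];
  dbp[0] = db;
  if (need_dx) std::memset(dxp, 0, hwn * ci * sizeof(double));
  for (int c = 0; c < ci; ++c) {
    const double* xc = x + hwn * c;
    double* dxc = need_dx ? dxp + hwn * c : nullptr;
    for (int dc = 0; dc < k; ++dc) {
      const int jlo = std::max(0, pad - dc), jhi = std::min(wid, wid + pad - dc);
      for (int dr = 0; dr < k; ++dr) {
        const int r = dr + k * dc + k * k * c;
        const double wv = w[r];
        const int ilo = std::max(0, pad - dr), ihi = std::min(h, h + pad - dr);
        const long off = (dr - pad) + (long)h * (dc - pad);
        double s = 0;
        for (int nn = 0; nn < n; ++nn) {
          const double* sp = xc + (std::size_t)hw * nn + off;
          const double* dp = dy + (std::size_t)hw * nn;
          double* dd = need_dx ? dxc + (std::size_t)hw * nn + off : nullptr;
          for (int j = jlo; j < jhi; ++j) {
            const long base = (long)h * j;
            if (need_dx) {
              for (int i = ilo; i < ihi; ++i) {
                s += sp[base + i] * dp[base + i];
                dd[base + i] += wv * dp[base + i];
              }
            } else {
              for (int i = ilo; i < ihi; ++i) s += sp[base + i] * dp[base + i];
            }
          }
        }
        dwp[r] = s;
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         bool single = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int h = xd[0], wid = xd[1], n = xd[2], ci = xd[3];
  const int k = wd[0], co = wd[3];
  if (wd[1] != k || wd[2] != ci) stop("kernel/input channel mismatch");
  if (k % 2 == 0) stop("kernel size must be odd");
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)h * wid * n * co));
  y.attr("dim") = IntegerVector::create(h, wid, n, co);
  if (co == 1)
    conv_fwd_co1(x.begin(), w.begin(), b[0], y.begin(), h, wid, ci, n, k);
  else if (single)
    conv_fwd_impl<float>(x.begin(), w.begin(), b.begin(), y.begin(),
                         h, wid, ci, n, k, co);
  else
    conv_fwd_impl<double>(x.begin(), w.begin(), b.begin(), y.begin(),
                          h, wid, ci, n, k, co);
  return y;
}

template <typename T>
static void conv_bwd_impl(const double* x, const double* w, const double* dy,
                          double* dwp, double* dbp, double* dxp, bool need_dx,
                          int h, int wid, int ci, int n, int k, int co) {
  const int pad = (k - 1) / 2;
  const int hw = h * wid;
  const std::size_t hwn = (std::size_t)hw * n;
  const int K = k * k * ci;
  arma::Mat<T> dY(workspace<T>(2, hwn * co), hwn, co, false, true);
  for (std::size_t i = 0; i < hwn * co; ++i) dY.memptr()[i] = (T)dy[i];
  bool view;
  arma::Mat<T> cols = make_cols<T>(x, h, wid, ci, n, k, pad, view);
  arma::Mat<T> dW = cols.t() * dY;  // (K x co), matches kernel layout
  for (long i = 0; i < (long)K * co; ++i) dwp[i] = (double)dW.memptr()[i];
  for (int c = 0; c < co; ++c) {
    T s = 0;
    const T* p = dY.colptr(c);
    for (std::size_t i = 0; i < hwn; ++i) s += p[i];
    dbp[c] = (double)s;
  }
  if (!need_dx) return;
  arma::Mat<T> W(workspace<T>(1, (std::size_t)K * co), K, co, false, true);
  for (long i = 0; i < (long)K * co; ++i) W.memptr()[i] = (T)w[i];
  arma::Mat<T> dcols(workspace<T>(3, hwn * K), hwn, K, false, true);
  dcols = dY * W.t();  // (hwn x K)
  if (k == 1) {
    for (std::size_t i = 0; i < hwn * K; ++i) dxp[i] = (double)dcols.memptr()[i];
    return;
  }
  std::memset(dxp, 0, hwn * ci * sizeof(double));
  for (int c = 0; c < ci; ++c) {
    double* xc = dxp + hwn * c;
    for (int dc = 0; dc < k; ++dc) {
      const int jlo = std::max(0, pad - dc), jhi = std::min(wid, wid + pad - dc);
      for (int dr = 0; dr < k; ++dr) {
        const int r = dr + k * dc + k * k * c;
        const int ilo = std::max(0, pad - dr), ihi = std::min(h, h + pad - dr);
        const T* src = dcols.colptr(r);
        const long off = (dr - pad) + (long)h * (dc - pad);
        for (int nn = 0; nn < n; ++nn) {
          const T* sp = src + (std::size_t)hw * nn;
          double* dp = xc + (std::size_t)hw * nn + off;
          for (int j = jlo; j < jhi; ++j) {
            const long base = (long)h * j;
            for (int i = ilo; i < ihi; ++i) dp[base + i] += (double)sp[base + i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                bool need_dx, bool single = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int h = xd[0], wid = xd[1], n = xd[2], ci = xd[3];
  const int k = wd[0], co = wd[3];
  NumericVector dwv(Rf_allocVector(REALSXP, (R_xlen_t)k * k * ci * co));
  dwv.attr("dim") = wd;
  NumericVector dbv(co);
  NumericVector dx;
  double* dxp = nullptr;
  if (need_dx) {
    dx = NumericVector(Rf_allocVector(REALSXP, (R_xlen_t)h * wid * n * ci));
    dx.attr("dim") = xd;
    dxp = dx.begin();
  }
  if (co == 1)
    conv_bwd_co1(x.begin(), w.begin(), dy.begin(), dwv.begin(),
                 dbv.begin(), dxp, need_dx, h, wid, ci, n, k);
  else if (single)
    conv_bwd_impl<float>(x.begin(), w.begin(), dy.begin(), dwv.begin(),
                         dbv.begin(), dxp, need_dx, h, wid, ci, n, k, co);
  else
    conv_bwd_impl<double>(x.begin(), w.begin(), dy.begin(), dwv.begin(),
                          dbv.begin(), dxp, need_dx, h, wid, ci, n, k, co);
  return List::create(_["dw"] = dwv, _["db"] = dbv,
                      _["dx"] = need_dx ? dx : NumericVector(0));
}

// [[Rcpp::export(name = ".lrelu_fwd")]]
NumericVector lrelu_fwd(NumericVector z, double slope) {
  NumericVector y(Rf_allocVector(REALSXP, z.size()));
  y.attr("dim") = z.attr("dim");
  const double* zp = z.begin();
  double* yp = y.begin();
  const R_xlen_t m = z.size();
  for (R_xlen_t i = 0; i < m; ++i)
    yp[i] = zp[i] * (slope + (1.0 - slope) * (zp[i] > 0));
  return y;
}

// dy * d/dz LeakyReLU(z)
// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd(NumericVector dy, NumericVector z, double slope) {
  NumericVector g(Rf_allocVector(REALSXP, z.size()));
  g.attr("dim") = dy.attr("dim");
  const double* zp = z.begin();
  const double* dp = dy.begin();
  double* gp = g.begin();
  const R_xlen_t m = z.size();
  for (R_xlen_t i = 0; i < m; ++i)
    gp[i] = dp[i] * (slope + (1.0 - slope) * (zp[i] > 0));
  return g;
}

// (h, w, n, a^2*m) -> (a*h, a*w, n, m); channel index c = dc + a*dr + a^2*mm.
// Loops are ordered so each destination column is completed in one visit.
// [[Rcpp::export(name = ".ps_fwd")]]
NumericVector ps_fwd_cpp(NumericVector x, int a) {
  IntegerVector d = x.attr("dim");
  const int h = d[0], w = d[1], n = d[2], C = d[3];
  const int m = C / (a * a);
  const int ah = a * h, aw = a * w;
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = IntegerVector::create(ah, aw, n, m);
  const double* xp = x.begin();
  double* yp = y.begin();
  const std::size_t hwn = (std::size_t)h * w * n;
  for (int mm = 0; mm < m; ++mm)
    for (int nn = 0; nn < n; ++nn)
      for (int j = 0; j < w; ++j)
        for (int dc = 0; dc < a; ++dc) {
          double* dcol = yp + (std::size_t)ah *
            ((a * j + dc) + (std::size_t)aw * (nn + (std::size_t)n * mm));
          for (int dr = 0; dr < a; ++dr) {
            const int c = dc + a * dr + a * a * mm;
            const double* sp = xp + hwn * c +
              (std::size_t)h * (j + (std::size_t)w * nn);
            double* dp = dcol + dr;
            for (int i = 0; i < h; ++i) dp[(std::size_t)a * i] = sp[i];
          }
        }
  return y;
}

// exact inverse of ps_fwd (space-to-depth)
// [[Rcpp::export(name = ".ps_bwd")]]
NumericVector ps_bwd_cpp(NumericVector y, int a) {
  IntegerVector d = y.attr("dim");
  const int ah = d[0], aw = d[1], n = d[2], m = d[3];
  const int h = ah / a, w = aw / a;
  NumericVector x(Rf_allocVector(REALSXP, y.size()));
  x.attr("dim") = IntegerVector::create(h, w, n, a * a * m);
  const double* yp = y.begin();
  double* xp = x.begin();
  const std::size_t hwn = (std::size_t)h * w * n;
  for (int mm = 0; mm < m; ++mm)
    for (int nn = 0; nn < n; ++nn)
      for (int j = 0; j < w; ++j)
        for (int dc = 0; dc < a; ++dc) {
          const double* scol = yp + (std::size_t)ah *
            ((a * j + dc) + (std::size_t)aw * (nn + (std::size_t)n * mm));
          for (int dr = 0; dr < a; ++dr) {
            const int c = dc + a * dr + a * a * mm;
            double* dp = xp + hwn * c +
              (std::size_t)h * (j + (std::size_t)w * nn);
            const double* sp = scol + dr;
            for (int i = 0; i < h; ++i) dp[i] = sp[(std::size_t)a * i];
          }
        }
  return x;
}

// contiguous channel-block slice: channels lo..hi (1-based) of (h, w, n, c)
// [[Rcpp::export(name = ".slice4")]]
NumericVector slice4(NumericVector x, int lo, int hi) {
  IntegerVector d = x.attr("dim");
  const std::size_t n0 = (std::size_t)d[0] * d[1] * d[2];
  const int nc = hi - lo + 1;
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)n0 * nc));
  out.attr("dim") = IntegerVector::create(d[0], d[1], d[2], nc);
  std::memcpy(out.begin(), x.begin() + n0 * (lo - 1),
              n0 * nc * sizeof(double));
  return out;
}
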
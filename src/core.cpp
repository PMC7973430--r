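#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 2-D correlation with replicate (nearest-edge) borders. Replicate padding is
// load-bearing: together with zero-mean kernels it guarantees that constant
// images produce exactly zero band-pass response.
// [[Rcpp::export]]
NumericMatrix cpp_conv2(const NumericMatrix& img, const NumericMatrix& kernel) {
  const int h = img.nrow(), w = img.ncol();
  const int kh = kernel.nrow(), kw = kernel.ncol();
  const int cy = kh / 2, cx = kw / 2;
  NumericMatrix out(h, w);
  const double* im = img.begin();
  const double* kn = kernel.begin();
  double* ot = out.begin();
  // interior: no border clamping, tight pointer loops
  const int y0 = cy, y1 = h - (kh - 1 - cy);
  const int x0 = cx, x1 = w - (kw - 1 - cx);
  for (int x = x0; x < x1; ++x) {
    for (int y = y0; y < y1; ++y) {
      double s = 0.0;
      for (int j = 0; j < kw; ++j) {
        const double* col = im + (size_t)(x + j - cx) * h + (y - cy);
        const double* kc = kn + (size_t)j * kh;
        for (int i = 0; i < kh; ++i) s += col[i] * kc[i];
      }
      ot[(size_t)x * h + y] = s;
    }
  }
  // borders: replicate-clamped
  for (int x = 0; x < w; ++x) {
    const bool xin = (x >= x0 && x < x1);
    for (int y = 0; y < h; ++y) {
      if (xin && y >= y0 && y < y1) { if (y == y0 && xin) y = y1 - 1; continue; }
      double s = 0.0;
      for (int j = 0; j < kw; ++j) {
        int xx = x + j - cx;
        if (xx < 0) xx = 0; else if (xx >= w) xx = w - 1;
        const double* col = im + (size_t)xx * h;
        const double* kc = kn + (size_t)j * kh;
        for (int i = 0; i < kh; ++i) {
          int yy = y + i - cy;
          if (yy < 0) yy = 0; else if (yy >= h) yy = h - 1;
          s += col[yy] * kc[i];
        }
      }
      ot[(size_t)x * h + y] = s;
    }
  }
  return out;
}

static void binomial5_blur(const NumericMatrix& img, NumericMatrix& out) {
  // separable [1 4 6 4 1]/16 with replicate borders
  const int h = img.nrow(), w = img.ncol();
  static const double k[5] = {1.0/16, 4.0/16, 6.0/16, 4.0/16, 1.0/16};
  NumericMatrix tmp(h, w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      double s = 0.0;
      for (int i = -2; i <= 2; ++i) {
        int yy = y + i; if (yy < 0) yy = 0; else if (yy >= h) yy = h - 1;
        s += img(yy, x) * k[i + 2];
      }
      tmp(y, x) = s;
    }
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      double s = 0.0;
      for (int j = -2; j <= 2; ++j) {
        int xx = x + j; if (xx < 0) xx = 0; else if (xx >= w) xx = w - 1;
        s += tmp(y, xx) * k[j + 2];
      }
      out(y, x) = s;
    }
}

// Binomial low-pass then take every other sample (rows/cols 1,3,5,... in R
// indexing), giving ceil(n/2) samples per axis.
// [[Rcpp::export]]
NumericMatrix cpp_decimate2(const NumericMatrix& img) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix blurred(h, w);
  binomial5_blur(img, blurred);
  const int oh = (h + 1) / 2, ow = (w + 1) / 2;
  NumericMatrix out(oh, ow);
  for (int x = 0; x < ow; ++x)
    for (int y = 0; y < oh; ++y)
      out(y, x) = blurred(2 * y, 2 * x);
  return out;
}

// Opponent Reichardt correlation between two same-size response maps.
// R(x) = prev(x) * curr(x + d) - curr(x) * prev(x + d); cells where x + d
// falls outside the array are 0.  signed_out = FALSE returns |R|.
// [[Rcpp::export]]
NumericMatrix cpp_reichardt(const NumericMatrix& prev, const NumericMatrix& curr,
                            int dx, int dy, bool signed_out) {
  const int h = prev.nrow(), w = prev.ncol();
  if (curr.nrow() != h || curr.ncol() != w)
    stop("frame response maps must have identical shape");
  NumericMatrix out(h, w);
  for (int x = 0; x < w; ++x) {
    const int xs = x + dx;
    for (int y = 0; y < h; ++y) {
      const int ys = y + dy;
      if (xs < 0 || xs >= w || ys < 0 || ys >= h) { out(y, x) = 0.0; continue; }
      const double r = prev(y, x) * curr(ys, xs) - curr(y, x) * prev(ys, xs);
      out(y, x) = signed_out ? r : std::fabs(r);
    }
  }
  return out;
}

// Resample to (oh, ow): box-average when shrinking on both axes, bilinear
// otherwise.  Pixel centres are aligned (centre of output cell maps to the
// corresponding fractional position in the input).
// [[Rcpp::export]]
NumericMatrix cpp_resize(const NumericMatrix& img, int oh, int ow) {
  const int h = img.nrow(), w = img.ncol();
  if (oh < 1 || ow < 1) stop("output size must be positive");
  if (oh == h && ow == w) return clone(img);
  NumericMatrix out(oh, ow);
  if (oh <= h && ow <= w) {
    // fractional box average
    const double sy = (double)h / oh, sx = (double)w / ow;
    for (int x = 0; x < ow; ++x) {
      const double x0 = x * sx, x1 = (x + 1) * sx;
      for (int y = 0; y < oh; ++y) {
        const double y0 = y * sy, y1 = (y + 1) * sy;
        double s = 0.0, area = 0.0;
        for (int xi = (int)std::floor(x0); xi < (int)std::ceil(x1); ++xi) {
          const double wx = std::min((double)xi + 1, x1) - std::max((double)xi, x0);
          for (int yi = (int)std::floor(y0); yi < (int)std::ceil(y1); ++yi) {
            const double wy = std::min((double)yi + 1, y1) - std::max((double)yi, y0);
            const int xc = std::min(xi, w - 1), yc = std::min(yi, h - 1);
            s += img(yc, xc) * wx * wy;
            area += wx * wy;
          }
        }
        out(y, x) = s / area;
      }
    }
  } else {
    // bilinear, clamped
    for (int x = 0; x < ow; ++x) {
      double fx = (x + 0.5) * (double)w / ow - 0.5;
      if (fx < 0) fx = 0; if (fx > w - 1) fx = w - 1;
      const int x0 = (int)std::floor(fx), x1 = std::min(x0 + 1, w - 1);
      const double ax = fx - x0;
      for (int y = 0; y < oh; ++y) {
        double fy = (y + 0.5) * (double)h / oh - 0.5;
        if (fy < 0) fy = 0; if (fy > h - 1) fy = h - 1;
        const int y0 = (int)std::floor(fy), y1 = std::min(y0 + 1, h - 1);
        const double ay = fy - y0;
        out(y, x) = (1 - ay) * ((1 - ax) * img(y0, x0) + ax * img(y0, x1)) +
                    ay       * ((1 - ax) * img(y1, x0) + ax * img(y1, x1));
      }
    }
  }
  return out;
}

// Distance-falloff kernel F(i,j) = exp(-d^2/(2 sigma^2)) over the cells of an
// h x w grid in R column-major order.  sigma = Inf gives F identically 1.
// [[Rcpp::export]]
NumericMatrix cpp_dist_kernel(int h, int w, double sigma) {
  const int n = h * w;
  NumericMatrix F(n, n);
  const bool flat = !R_finite(sigma);
  const double denom = 2.0 * sigma * sigma;
  for (int j = 0; j < n; ++j) {
    const int cj = j / h, rj = j % h;
    for (int i = 0; i < n; ++i) {
      if (flat) { F(i, j) = 1.0; continue; }
      const int ci = i / h, ri = i % h;
      const double d2 = (double)(ri - rj) * (ri - rj) + (double)(ci - cj) * (ci - cj);
      F(i, j) = std::exp(-d2 / denom);
    }
  }
  return F;
}

// Stationary distribution of the Markov chain obtained by row-normalising a
// non-negative weight matrix W.  Rows with zero total weight become uniform
// rows; an all-zero W yields the uniform distribution.
//
// method 0 (default): direct dense solve of pi (P - I) = 0 with sum(pi) = 1
// by Gaussian elimination with partial pivoting — exact and total, including
// on periodic chains where undamped power iteration oscillates.
// method 1: damped ("lazy") power iteration x <- (x + x P) / 2 with an L1
// stopping rule; same fixed point, kept as an independent cross-check.
static std::vector<double> stationary_from_W(const NumericMatrix& W,
                                             double tol, int maxit,
                                             int method = 0) {
  const int n = W.nrow();
  std::vector<double> d(n, 0.0);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += W(i, j);
    d[i] = s;
    total += s;
  }
  std::vector<double> x(n, 1.0 / n);
  if (total <= 0.0) return x;  // fully degenerate: uniform

  if (method == 1) {
    std::vector<double> y(n), xn(n);
    for (int it = 0; it < maxit; ++it) {
      double zero_mass = 0.0;
      for (int i = 0; i < n; ++i) {
        if (d[i] > 0.0) y[i] = x[i] / d[i];
        else { y[i] = 0.0; zero_mass += x[i]; }
      }
      const double base = zero_mass / n;
      for (int j = 0; j < n; ++j) {
        double s = base;
        for (int i = 0; i < n; ++i) s += W(i, j) * y[i];
        xn[j] = 0.5 * x[j] + 0.5 * s;
      }
      double sum = 0.0;
      for (int j = 0; j < n; ++j) sum += xn[j];
      double diff = 0.0;
      for (int j = 0; j < n; ++j) {
        xn[j] /= sum;
        diff += std::fabs(xn[j] - x[j]);
      }
      x.swap(xn);
      if (diff < tol) break;
    }
    return x;
  }

  // direct solve: A^T pi = b where A = P^T - I with first row replaced by 1s
  std::vector<double> A((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const double pij = (d[i] > 0.0) ? W(i, j) / d[i] : 1.0 / n;
      // row j of the system, column i: coefficient of pi_i
      A[(size_t)i * n + j] = pij - (i == j ? 1.0 : 0.0);
    }
  }
  std::vector<double> b(n, 0.0);
  for (int i = 0; i < n; ++i) A[(size_t)i * n + 0] = 1.0;  // sum constraint
  b[0] = 1.0;
  // Gaussian elimination with partial pivoting on column-major A
  std::vector<int> piv(n);
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int k = 0; k < n; ++k) {
    int p = k;
    double best = std::fabs(A[(size_t)k * n + k]);
    for (int r = k + 1; r < n; ++r) {
      const double v = std::fabs(A[(size_t)k * n + r]);
      if (v > best) { best = v; p = r; }
    }
    if (p != k) {
      for (int c = k; c < n; ++c)
        std::swap(A[(size_t)c * n + k], A[(size_t)c * n + p]);
      std::swap(b[k], b[p]);
    }
    const double akk = A[(size_t)k * n + k];
    if (akk == 0.0) continue;  // singular direction; handled by clamp below
    for (int r = k + 1; r < n; ++r) {
      const double f = A[(size_t)k * n + r] / akk;
      if (f == 0.0) continue;
      for (int c = k + 1; c < n; ++c)
        A[(size_t)c * n + r] -= f * A[(size_t)c * n + k];
      b[r] -= f * b[k];
      A[(size_t)k * n + r] = 0.0;
    }
  }
  for (int k = n - 1; k >= 0; --k) {
    double s = b[k];
    for (int c = k + 1; c < n; ++c) s -= A[(size_t)c * n + k] * x[c];
    const double akk = A[(size_t)k * n + k];
    x[k] = (akk != 0.0) ? s / akk : 1.0 / n;
  }
  double sum = 0.0;
  for (int k = 0; k < n; ++k) { if (x[k] < 0.0) x[k] = 0.0; sum += x[k]; }
  if (sum <= 0.0) return std::vector<double>(n, 1.0 / n);
  for (int k = 0; k < n; ++k) x[k] /= sum;
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_stationary(const NumericMatrix& W, double tol, int maxit,
                             int method = 0) {
  std::vector<double> x = stationary_from_W(W, tol, maxit, method);
  return NumericVector(x.begin(), x.end());
}

static NumericMatrix activation_W(const NumericVector& f, const NumericMatrix& F,
                                  double eps) {
  const int n = f.size();
  NumericMatrix W(n, n);
  std::vector<double> L(n);
  for (int i = 0; i < n; ++i) L[i] = std::log(f[i] + eps);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      W(i, j) = std::fabs(L[i] - L[j]) * F(i, j);
  return W;
}

// Activation chain: w(i->j) = |log((f_i+eps)/(f_j+eps))| * F(i,j).
// [[Rcpp::export]]
NumericMatrix cpp_gbvs_activation(const NumericMatrix& feature, const NumericMatrix& F,
                                  double eps, double tol, int maxit, int method = 0) {
  const int h = feature.nrow(), w = feature.ncol();
  NumericVector f(feature.begin(), feature.end());
  NumericMatrix W = activation_W(f, F, eps);
  std::vector<double> x = stationary_from_W(W, tol, maxit, method);
  NumericMatrix out(h, w);
  std::copy(x.begin(), x.end(), out.begin());
  return out;
}

// Normalisation chain: w(i->j) = a_j * F(i,j); concentrates mass on
// high-activation cells.
// [[Rcpp::export]]
NumericMatrix cpp_gbvs_normalize(const NumericMatrix& activation, const NumericMatrix& F,
                                 double tol, int maxit, int method = 0) {
  const int h = activation.nrow(), w = activation.ncol();
  const int n = h * w;
  NumericVector a(activation.begin(), activation.end());
  NumericMatrix W(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      W(i, j) = a[j] * F(i, j);
  std::vector<double> x = stationary_from_W(W, tol, maxit, method);
  NumericMatrix out(h, w);
  std::copy(x.begin(), x.end(), out.begin());
  return out;
}

struct Pyramid {
  // resp[orientation][level]
  std::vector< std::vector<NumericMatrix> > resp;
};

static void build_pyramid(const NumericMatrix& frame, const List& cosK,
                          const List& sinK, int n_levels, Pyramid& pyr) {
  const int n_orient = cosK.size();
  std::vector<NumericMatrix> imgs(n_levels);
  imgs[0] = frame;
  for (int k = 1; k < n_levels; ++k) imgs[k] = cpp_decimate2(imgs[k - 1]);
  pyr.resp.assign(n_orient, std::vector<NumericMatrix>(n_levels));
  for (int o = 0; o < n_orient; ++o) {
    NumericMatrix ck = cosK[o], sk = sinK[o];
    for (int k = 0; k < n_levels; ++k) {
      NumericMatrix ce = cpp_conv2(imgs[k], ck);
      NumericMatrix se = cpp_conv2(imgs[k], sk);
      const int m = ce.nrow() * ce.ncol();
      NumericMatrix r(ce.nrow(), ce.ncol());
      for (int i = 0; i < m; ++i)
        r[i] = std::sqrt(ce[i] * ce[i] + se[i] * se[i]);
      pyr.resp[o][k] = r;
    }
  }
}

// Full motion-channel saliency driver for an image sequence.  Returns one
// master map per frame pair (unscaled stationary-mass maps at frame
// resolution); rescaling to [0,1] is done by the R wrapper so that per-frame
// and per-sequence normalisation share one code path.
//
// Frame pairs whose motion responses are identically zero everywhere yield an
// identically zero map (no motion channel input), and all-zero orientation/
// level feature maps contribute nothing to the cross-level sum.
// [[Rcpp::export]]
List cpp_saliency_sequence(const List& frames, const List& cosK, const List& sinK,
                           const IntegerMatrix& dirs, int n_levels,
                           int work_h, int work_w, const NumericMatrix& F,
                           double eps, double tol, int maxit, int shift) {
  const int nf = frames.size();
  if (nf < 2) stop("need >= 2 frames");
  const int n_orient = cosK.size();
  NumericMatrix f0 = frames[0];
  const int fh = f0.nrow(), fw = f0.ncol();
  const int n = work_h * work_w;

  List out(nf - 1);
  Pyramid prev, curr;
  build_pyramid(f0, cosK, sinK, n_levels, prev);
  NumericMatrix sum_map(work_h, work_w);

  for (int t = 1; t < nf; ++t) {
    NumericMatrix ft = frames[t];
    if (ft.nrow() != fh || ft.ncol() != fw) stop("frames must share one shape");
    build_pyramid(ft, cosK, sinK, n_levels, curr);
    std::fill(sum_map.begin(), sum_map.end(), 0.0);
    bool any_motion = false;

    // first pass: opponent Reichardt magnitudes at every orientation/level,
    // and the pair-global response maximum.  All maps of one frame pair are
    // normalised by this single scale (with a 1% noise floor) before the
    // graph stage: per-map peak normalisation would erase the relative
    // strength of movers within the scene, and with an exactly static
    // background the unnormalised log-dissimilarity saturates at |log eps|
    // for every moving cell.
    std::vector<NumericMatrix> feats(n_orient * n_levels);
    double gmax = 0.0;
    for (int o = 0; o < n_orient; ++o) {
      const int dx = dirs(o, 0) * shift, dy = dirs(o, 1) * shift;
      for (int k = 0; k < n_levels; ++k) {
        NumericMatrix rp = cpp_reichardt(prev.resp[o][k], curr.resp[o][k], dx, dy, false);
        NumericMatrix rm = cpp_reichardt(prev.resp[o][k], curr.resp[o][k], -dx, -dy, false);
        const int m = rp.nrow() * rp.ncol();
        for (int i = 0; i < m; ++i) {
          rp[i] += rm[i];
          if (rp[i] > gmax) gmax = rp[i];
        }
        feats[o * n_levels + k] = rp;
      }
    }

    if (gmax > 0.0) {
      for (int f = 0; f < n_orient * n_levels; ++f) {
        NumericMatrix& rp = feats[f];
        const int m = rp.nrow() * rp.ncol();
        double fmax = 0.0;
        for (int i = 0; i < m; ++i) if (rp[i] > fmax) fmax = rp[i];
        // silence gate: a channel below the pair noise floor carries no
        // resolvable motion and casts no vote (its whole map would sit at
        // the floor and contribute only diffuse mass)
        if (fmax <= 0.01 * gmax) continue;
        any_motion = true;
        NumericMatrix feat = cpp_resize(rp, work_h, work_w);
        double lo = 1.0, hi = 0.0;
        for (int i = 0; i < n; ++i) {
          feat[i] /= gmax;
          if (feat[i] < 0.01) feat[i] = 0.01;
          if (feat[i] < lo) lo = feat[i];
          if (feat[i] > hi) hi = feat[i];
        }
        if (hi - lo <= 0.0) {
          // uniform feature: dissimilarities all zero -> uniform activation
          for (int i = 0; i < n; ++i) sum_map[i] += 1.0 / n;
          continue;
        }
        NumericVector fv(feat.begin(), feat.end());
        NumericMatrix W = activation_W(fv, F, eps);
        std::vector<double> act = stationary_from_W(W, tol, maxit);
        for (int i = 0; i < n; ++i) sum_map[i] += act[i];
      }
    }

    NumericMatrix master(fh, fw);  // zeros
    if (any_motion) {
      NumericMatrix norm = cpp_gbvs_normalize(sum_map, F, tol, maxit);
      master = cpp_resize(norm, fh, fw);
      for (int i = 0; i < fh * fw; ++i)
        if (master[i] < 0.0) master[i] = 0.0;
    }
    out[t - 1] = master;
    std::swap(prev.resp, curr.resp);
  }
  return out;
}
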
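#include <Rcpp.h>
using namespace Rcpp;

// Mirror an index into [0, n): reflection about the array edge.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

//' Separable 2-D convolution with mirrored boundaries.
//'
//' Convolves `img` with the outer product of `k1` (applied along the first
//' dimension, i.e. down columns) and `k2` (along the second dimension).
//' Kernels must have odd length.
//'
//' @keywords internal
// [[Rcpp::export(name = ".conv_sep")]]
NumericMatrix conv_sep(const NumericMatrix& img,
                       const NumericVector& k1,
                       const NumericVector& k2) {
  const int nr = img.nrow(), nc = img.ncol();
  const int m1 = k1.size(), m2 = k2.size();
  const int h1 = m1 / 2, h2 = m2 / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);

  // pass 1: along dim 1, per column, shifted accumulation (cache friendly)
  for (int j = 0; j < nc; ++j) {
    const double* c = &img(0, j);
    double* o = &tmp(0, j);
    for (int t = 0; t < m1; ++t) {
      const int shift = t - h1;
      const double w = k1[t];
      const int lo = std::max(0, -shift), hi = std::min(nr, nr - shift);
      for (int i = lo; i < hi; ++i) o[i] += w * c[i + shift];
    }
    // recompute edge rows exactly with reflection
    for (int i = 0; i < std::min(h1, nr); ++i) {
      double s = 0;
      for (int t = 0; t < m1; ++t) s += k1[t] * c[reflect_idx(i + t - h1, nr)];
      o[i] = s;
    }
    for (int i = std::max(0, nr - h1); i < nr; ++i) {
      double s = 0;
      for (int t = 0; t < m1; ++t) s += k1[t] * c[reflect_idx(i + t - h1, nr)];
      o[i] = s;
    }
  }
  // pass 2: along dim 2, column AXPY over shifted source columns
  for (int j = 0; j < nc; ++j) {
    double* o = &out(0, j);
    for (int t = 0; t < m2; ++t) {
      const double w = k2[t];
      const double* c = &tmp(0, reflect_idx(j + t - h2, nc));
      for (int i = 0; i < nr; ++i) o[i] += w * c[i];
    }
  }
  return out;
}

//' 8-neighbourhood local maxima of a matrix.
//'
//' A pixel is a local maximum when no in-bounds neighbour exceeds it.
//'
//' @keywords internal
// [[Rcpp::export(name = ".local_maxima8")]]
LogicalMatrix local_maxima8(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double v = img(i, j);
      bool ismax = true;
      for (int dj = -1; dj <= 1 && ismax; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -1; di <= 1; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nr || (di == 0 && dj == 0)) continue;
          if (img(ii, jj) > v) { ismax = false; break; }
        }
      }
      out(i, j) = ismax;
    }
  }
  return out;
}

//' Render radially decaying (parabolic-cap) blobs into a zero image.
//'
//' Each blob adds `peak * max(0, 1 - (d/R)^2)`; coordinates are 0-based
//' (x = column, y = row).
//'
//' @keywords internal
// [[Rcpp::export(name = ".render_blobs")]]
NumericMatrix render_blobs(int nrow, int ncol,
                           const NumericVector& x, const NumericVector& y,
                           const NumericVector& radius,
                           const NumericVector& peak) {
  NumericMatrix img(nrow, ncol);
  for (int b = 0; b < x.size(); ++b) {
    const double cx = x[b], cy = y[b], R = radius[b], pk = peak[b];
    const double R2 = R * R;
    const int c0 = std::max(0, (int)std::floor(cx - R));
    const int c1 = std::min(ncol - 1, (int)std::ceil(cx + R));
    const int r0 = std::max(0, (int)std::floor(cy - R));
    const int r1 = std::min(nrow - 1, (int)std::ceil(cy + R));
    for (int j = c0; j <= c1; ++j) {
      const double dx2 = (j - cx) * (j - cx);
      for (int i = r0; i <= r1; ++i) {
        const double d2 = dx2 + (i - cy) * (i - cy);
        if (d2 < R2) img(i, j) += pk * (1.0 - d2 / R2);
      }
    }
  }
  return img;
}

//' Render isotropic Gaussian spots (truncated at 4 sigma) into a zero image.
//'
//' @keywords internal
// [[Rcpp::export(name = ".render_spots")]]
NumericMatrix render_spots(int nrow, int ncol,
                           const NumericVector& x, const NumericVector& y,
                           double sigma, const NumericVector& peak) {
  NumericMatrix img(nrow, ncol);
  const double h = 4.0 * sigma, s2 = 2.0 * sigma * sigma;
  for (int b = 0; b < x.size(); ++b) {
    const double cx = x[b], cy = y[b], pk = peak[b];
    const int c0 = std::max(0, (int)std::floor(cx - h));
    const int c1 = std::min(ncol - 1, (int)std::ceil(cx + h));
    const int r0 = std::max(0, (int)std::floor(cy - h));
    const int r1 = std::min(nrow - 1, (int)std::ceil(cy + h));
    for (int j = c0; j <= c1; ++j) {
      const double dx2 = (j - cx) * (j - cx);
      for (int i = r0; i <= r1; ++i) {
        const double d2 = dx2 + (i - cy) * (i - cy);
        img(i, j) += pk * std::exp(-d2 / s2);
      }
    }
  }
  return img;
}
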
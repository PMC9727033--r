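// Image kernels for the segmentation and detection stages.
// Images are R matrices (column-major); all filters use replicate padding at
// the borders unless stated otherwise.
#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 2D correlation with an arbitrary kernel, replicate padding, "same" output.
// Kernel anchor is its centre element (dimensions must be odd).
// [[Rcpp::export(name = ".conv2_replicate")]]
NumericMatrix conv2_replicate(NumericMatrix img, NumericMatrix kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kernel.nrow(), kc = kernel.ncol();
  if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
  const int ar = kr / 2, ac = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int dj = -ac; dj <= ac; ++dj) {
        const int jj = clampi(j + dj, 0, nc - 1);
        for (int di = -ar; di <= ar; ++di) {
          const int ii = clampi(i + di, 0, nr - 1);
          acc += img(ii, jj) * kernel(di + ar, dj + ac);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Square median filter of width `w`. Even widths are anchored towards the
// top-left: offsets run from -ceil((w-1)/2) to +floor((w-1)/2).
// [[Rcpp::export(name = ".median_filter")]]
NumericMatrix median_filter(NumericMatrix img, int w) {
  if (w < 1) stop("window width must be >= 1");
  const int nr = img.nrow(), nc = img.ncol();
  const int lo = -((w - 1 + 1) / 2);  // -ceil((w-1)/2)
  const int hi = (w - 1) / 2;         //  floor((w-1)/2)
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)w * w);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = lo; dj <= hi; ++dj) {
        const int jj = clampi(j + dj, 0, nc - 1);
        for (int di = lo; di <= hi; ++di) {
          buf.push_back(img(clampi(i + di, 0, nr - 1), jj));
        }
      }
      const size_t n = buf.size(), m = n / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
        med = 0.5 * (med + buf[m - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Binary erosion/dilation with a flat structuring element given as a logical
// matrix (odd dimensions, centre anchored). Outside the image counts as
// background (0) for dilation and as background for erosion too, so objects
// touching the border are eroded there — the conservative convention.
static LogicalMatrix morph(LogicalMatrix img, LogicalMatrix se, bool erode) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = se.nrow(), kc = se.ncol();
  if (kr % 2 == 0 || kc % 2 == 0) stop("structuring element must be odd-sized");
  const int ar = kr / 2, ac = kc / 2;
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool val = erode;
      for (int dj = -ac; dj <= ac && (erode ? val : !val); ++dj) {
        for (int di = -ar; di <= ar && (erode ? val : !val); ++di) {
          if (!se(di + ar, dj + ac)) continue;
          const int ii = i + di, jj = j + dj;
          const bool px = (ii >= 0 && ii < nr && jj >= 0 && jj < nc) ?
                          (img(ii, jj) != 0) : false;
          if (erode && !px) val = false;
          if (!erode && px) val = true;
        }
      }
      out(i, j) = val;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".binary_erode")]]
LogicalMatrix binary_erode(LogicalMatrix img, LogicalMatrix se) {
  return morph(img, se, true);
}

// [[Rcpp::export(name = ".binary_dilate")]]
LogicalMatrix binary_dilate(LogicalMatrix img, LogicalMatrix se) {
  return morph(img, se, false);
}

// Connected-component labelling of a binary image, 8-connectivity.
// Labels are assigned in raster (column-major) order of first encounter, so
// the output is deterministic. 0 = background.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!img(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (img(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
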
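#include <Rcpp.h>
#include <queue>
#include <cstring>
using namespace Rcpp;

// Activation arrays are R arrays [h, w, c] (column-major).
// im2col row ordering is (dr, dc, ch) fastest-to-slowest; weight matrices
// used with these patches must share that ordering.

// Patch matrix in "patches as rows" layout: out is (oh*ow) x (k*k*c),
// column index = dr + k*dc + k*k*ch, row index = orow + oh*oc (the
// column-major layout of the output feature map). Every inner copy is a
// contiguous run of oh values.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int h, int w, int c, int k) {
  const int oh = h - k + 1, ow = w - k + 1;
  if (oh < 1 || ow < 1) stop("kernel larger than input");
  const size_t npix = (size_t)oh * ow;
  NumericMatrix out(oh * ow, k * k * c);
  const double* px = x.begin();
  double* po = out.begin();
  for (int ch = 0; ch < c; ++ch) {
    const double* plane = px + (size_t)ch * h * w;
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        double* col = po + ((size_t)ch * k * k + (size_t)dc * k + dr) * npix;
        for (int oc = 0; oc < ow; ++oc)
          std::memcpy(col + (size_t)oc * oh,
                      plane + (size_t)(oc + dc) * h + dr,
                      sizeof(double) * oh);
      }
    }
  }
  return out;
}

// Scatter-add of patch-matrix gradients back to the input array.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int h, int w, int c, int k) {
  const int oh = h - k + 1, ow = w - k + 1;
  const size_t npix = (size_t)oh * ow;
  NumericVector out((size_t)h * w * c);
  double* po = out.begin();
  const double* pc = cols.begin();
  for (int ch = 0; ch < c; ++ch) {
    double* plane = po + (size_t)ch * h * w;
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        const double* col = pc +
          ((size_t)ch * k * k + (size_t)dc * k + dr) * npix;
        for (int oc = 0; oc < ow; ++oc) {
          double* dst = plane + (size_t)(oc + dc) * h + dr;
          const double* src = col + (size_t)oc * oh;
          for (int r = 0; r < oh; ++r) dst[r] += src[r];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(h, w, c);
  return out;
}

// 2x2 stride-2 max pooling; ceil_mode pads the bottom/right edge window.
// Returns pooled array and 1-based argmax linear indices into the input.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int h, int w, int c, bool ceil_mode) {
  const int s = 2;
  int oh = ceil_mode ? (h + s - 1) / s : h / s;
  int ow = ceil_mode ? (w + s - 1) / s : w / s;
  NumericVector out((size_t)oh * ow * c);
  IntegerVector idx((size_t)oh * ow * c);
  const double* px = x.begin();
  for (int ch = 0; ch < c; ++ch) {
    const double* plane = px + (size_t)ch * h * w;
    for (int oc = 0; oc < ow; ++oc) {
      for (int orow = 0; orow < oh; ++orow) {
        int r0 = orow * s, c0 = oc * s;
        int r1 = std::min(r0 + s, h), c1 = std::min(c0 + s, w);
        double best = R_NegInf; int bi = -1;
        for (int cc = c0; cc < c1; ++cc)
          for (int rr = r0; rr < r1; ++rr) {
            double v = plane[(size_t)cc * h + rr];
            if (v > best) { best = v; bi = rr + h * cc; }
          }
        size_t o = (size_t)ch * oh * ow + (size_t)oc * oh + orow;
        out[o] = best;
        idx[o] = bi + (int)((size_t)ch * h * w) + 1;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, c);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector grad, IntegerVector idx,
                              int h, int w, int c) {
  NumericVector out((size_t)h * w * c);
  for (R_xlen_t i = 0; i < grad.size(); ++i) out[idx[i] - 1] += grad[i];
  out.attr("dim") = IntegerVector::create(h, w, c);
  return out;
}

// 8-connectivity labeling of a binary matrix (BFS flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        int cr = q.front().first, cc = q.front().second;
        q.pop();
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int nr = cr + dr, nc = cc + dc;
            if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
            if (mask(nr, nc) && !lab(nr, nc)) {
              lab(nr, nc) = next;
              q.push(std::make_pair(nr, nc));
            }
          }
      }
    }
  }
  return lab;
}

// Inverse-mapping bilinear warp. inv maps output (x=col, y=row, 0-based)
// to source coordinates: xs = inv[0]*x + inv[1]*y + inv[2], ys = inv[3..5].
// Returns warped [oh, ow, c] plus a margin mask of unmapped output pixels.
// [[Rcpp::export]]
List cpp_warp_affine(NumericVector img, int h, int w, int c,
                     NumericVector inv, int oh, int ow) {
  NumericVector out((size_t)oh * ow * c);
  LogicalMatrix margin(oh, ow);
  const double* p = img.begin();
  for (int oc = 0; oc < ow; ++oc) {
    for (int orow = 0; orow < oh; ++orow) {
      double xs = inv[0] * oc + inv[1] * orow + inv[2];
      double ys = inv[3] * oc + inv[4] * orow + inv[5];
      if (xs < 0 || ys < 0 || xs > w - 1 || ys > h - 1) {
        margin(orow, oc) = true;
        continue;
      }
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      int x1 = std::min(x0 + 1, w - 1), y1 = std::min(y0 + 1, h - 1);
      double fx = xs - x0, fy = ys - y0;
      for (int ch = 0; ch < c; ++ch) {
        const double* pl = p + (size_t)ch * h * w;
        double v00 = pl[(size_t)x0 * h + y0], v01 = pl[(size_t)x1 * h + y0];
        double v10 = pl[(size_t)x0 * h + y1], v11 = pl[(size_t)x1 * h + y1];
        out[(size_t)ch * oh * ow + (size_t)oc * oh + orow] =
          (1 - fy) * ((1 - fx) * v00 + fx * v01) +
          fy * ((1 - fx) * v10 + fx * v11);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, c);
  return List::create(_["image"] = out, _["margin"] = margin);
}
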
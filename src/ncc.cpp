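#include <Rcpp.h>
using namespace Rcpp;

// Normalized cross-correlation of a template against every placement
// inside a search region of an image.
//
// img:  image matrix (rows = y, cols = x)
// tmpl: template matrix
// r0, c0: 1-based row/col of the top-left corner of the first placement
// nr, nc: number of placements along rows / cols
//
// Returns an nr x nc matrix of NCC values in [-1, 1]; placements whose
// patch has (near-)zero variance score 0.
// [[Rcpp::export]]
NumericMatrix ncc_surface_cpp(NumericMatrix img, NumericMatrix tmpl,
                              int r0, int c0, int nr, int nc) {
  const int th = tmpl.nrow(), tw = tmpl.ncol();
  const int ih = img.nrow(), iw = img.ncol();
  const int n = th * tw;

  double tmean = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) tmean += tmpl(i, j);
  tmean /= n;
  std::vector<double> tz(n);
  double tss = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) {
      double v = tmpl(i, j) - tmean;
      tz[j * th + i] = v;
      tss += v * v;
    }

  NumericMatrix out(nr, nc);
  if (tss <= 1e-12) return out;  // featureless template

  for (int dc = 0; dc < nc; ++dc) {
    for (int dr = 0; dr < nr; ++dr) {
      int rr = r0 - 1 + dr, cc = c0 - 1 + dc;
      if (rr < 0 || cc < 0 || rr + th > ih || cc + tw > iw) {
        out(dr, dc) = NA_REAL;
        continue;
      }
      double psum = 0.0, pss = 0.0, cross = 0.0;
      for (int j = 0; j < tw; ++j) {
        for (int i = 0; i < th; ++i) {
          double p = img(rr + i, cc + j);
          psum += p;
          pss += p * p;
          cross += p * tz[j * th + i];
        }
      }
      double pvar = pss - psum * psum / n;
      out(dr, dc) = (pvar <= 1e-12) ? 0.0 : cross / std::sqrt(pvar * tss);
    }
  }
  return out;
}
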
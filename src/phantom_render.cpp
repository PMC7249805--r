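// Rendering of a vessel tree into a 2D intensity image, a lumen (body) mask
// and, optionally, a slice stack. Intensity follows a Gaussian cross-profile
// peaking on the centerline (sigma = width/4); the body is the set of pixels
// within width/2 of the centerline polyline. Volume voxels copy the in-plane
// profile into the slices within width/2 of the branch's local depth, so the
// noise-free maximum intensity projection reproduces the 2D rendering
// exactly.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_render_tree(List branches, NumericVector widths,
                     NumericVector contrasts, int H, int W, int S) {
  NumericMatrix intensity(H, W);
  IntegerMatrix body(H, W);
  NumericVector vol;
  if (S > 0) {
    vol = NumericVector(H * W * S);
    vol.attr("dim") = IntegerVector::create(H, W, S);
  }
  std::vector<double> d2best(H * W), depth(H * W);
  const int nb = branches.size();
  for (int b = 0; b < nb; ++b) {
    NumericMatrix pts = branches[b];
    const int n = pts.nrow();
    if (n < 2) continue;
    const double w = widths[b], cst = contrasts[b];
    const double sigma = std::max(w / 4.0, 1e-6);
    const double cutoff = std::max(3.0 * sigma, w / 2.0 + 0.8);
    const double bodyr = std::max(w / 2.0, 0.71);  // keeps 1-px lines inside
    std::fill(d2best.begin(), d2best.end(), 1e30);
    std::vector<int> touched;
    for (int s = 0; s + 1 < n; ++s) {
      const double r0 = pts(s, 0), c0 = pts(s, 1);
      const double r1 = pts(s + 1, 0), c1 = pts(s + 1, 1);
      const double z0 = pts(s, 2), z1 = pts(s + 1, 2);
      const double dr = r1 - r0, dc = c1 - c0;
      const double len2 = dr * dr + dc * dc;
      const int rlo = std::max(0, (int)std::floor(std::min(r0, r1) - cutoff));
      const int rhi = std::min(H - 1, (int)std::ceil(std::max(r0, r1) + cutoff));
      const int clo = std::max(0, (int)std::floor(std::min(c0, c1) - cutoff));
      const int chi = std::min(W - 1, (int)std::ceil(std::max(c0, c1) + cutoff));
      for (int cc = clo; cc <= chi; ++cc) {
        for (int rr = rlo; rr <= rhi; ++rr) {
          double t = 0.0;
          if (len2 > 0.0)
            t = std::max(0.0, std::min(1.0, ((rr - r0) * dr + (cc - c0) * dc) / len2));
          const double pr = r0 + t * dr, pc = c0 + t * dc;
          const double d2 = (rr - pr) * (rr - pr) + (cc - pc) * (cc - pc);
          if (d2 > cutoff * cutoff) continue;
          const int i = cc * H + rr;
          if (d2best[i] >= 1e29) touched.push_back(i);
          if (d2 < d2best[i]) {
            d2best[i] = d2;
            depth[i] = z0 + t * (z1 - z0);
          }
        }
      }
    }
    for (size_t k = 0; k < touched.size(); ++k) {
      const int i = touched[k];
      const double d2 = d2best[i];
      const double val = cst * std::exp(-d2 / (2.0 * sigma * sigma));
      if (val > intensity[i]) intensity[i] = val;
      if (d2 <= bodyr * bodyr) body[i] = 1;
      if (S > 0) {
        double z = depth[i];
        if (z < 0) z = 0;
        if (z > S - 1) z = S - 1;
        int slo = (int)std::ceil(z - w / 2.0);
        int shi = (int)std::floor(z + w / 2.0);
        if (slo < 0) slo = 0;
        if (shi > S - 1) shi = S - 1;
        // an integer slice always exists: |round(z) - z| <= 1/2 <= w/2
        for (int s = slo; s <= shi; ++s) {
          const int j = s * H * W + i;
          if (val > vol[j]) vol[j] = val;
        }
      }
    }
  }
  List out;
  out["intensity"] = intensity;
  out["body"] = body;
  if (S > 0) out["volume"] = vol;
  return out;
}
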
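// SLIC superpixels restricted to a binary mask, clustering on (row, col,
// depth).  Depth is rescaled to [0, 100] over the mask; the distance is
// D^2 = d_depth^2 + m^2 * (d_xy / S)^2 with S = sqrt(area / K).
// A post-pass reattaches disconnected fragments so every superpixel is a
// single 4-connected region and the labels partition the mask exactly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export(name = ".slic_cpp")]]
List slic_cpp(LogicalMatrix mask, NumericMatrix depth, int K, double m,
              int max_iter) {
  int h = mask.nrow(), w = mask.ncol();
  int r0 = h, r1 = -1, c0 = w, c1 = -1;
  long area = 0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      if (mask(r, c)) {
        ++area;
        if (r < r0) r0 = r;
        if (r > r1) r1 = r;
        if (c < c0) c0 = c;
        if (c > c1) c1 = c;
      }
  if (area == 0) stop("empty silhouette");

  double dmin = R_PosInf, dmax = R_NegInf;
  for (int c = c0; c <= c1; ++c)
    for (int r = r0; r <= r1; ++r)
      if (mask(r, c)) {
        double d = depth(r, c);
        if (d < dmin) dmin = d;
        if (d > dmax) dmax = d;
      }
  double dscale = dmax > dmin ? 100.0 / (dmax - dmin) : 0.0;
  NumericMatrix ds(h, w);
  for (int c = c0; c <= c1; ++c)
    for (int r = r0; r <= r1; ++r)
      if (mask(r, c)) ds(r, c) = (depth(r, c) - dmin) * dscale;

  double S = std::sqrt((double)area / (double)K);
  if (S < 1.0) S = 1.0;

  // grid seeding, snapped onto the mask
  std::vector<double> cr, cc, cd;
  if (K == 1) {
    double sr = 0, sc = 0, sd = 0;
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r)
        if (mask(r, c)) { sr += r; sc += c; sd += ds(r, c); }
    cr.push_back(sr / area); cc.push_back(sc / area); cd.push_back(sd / area);
  } else {
    for (double gr = r0 + S / 2; gr <= r1 + S / 2; gr += S) {
      for (double gc = c0 + S / 2; gc <= c1 + S / 2; gc += S) {
        int br = -1, bc = -1;
        double bd2 = std::numeric_limits<double>::max();
        int rr0 = std::max(0, (int)(gr - S / 2)), rr1 = std::min(h - 1, (int)(gr + S / 2));
        int cc0 = std::max(0, (int)(gc - S / 2)), cc1 = std::min(w - 1, (int)(gc + S / 2));
        for (int c = cc0; c <= cc1; ++c)
          for (int r = rr0; r <= rr1; ++r)
            if (mask(r, c)) {
              double d2 = (r - gr) * (r - gr) + (c - gc) * (c - gc);
              if (d2 < bd2) { bd2 = d2; br = r; bc = c; }
            }
        if (br >= 0) {
          cr.push_back(br); cc.push_back(bc); cd.push_back(ds(br, bc));
        }
      }
    }
  }
  int k = (int)cr.size();
  if (k == 0) stop("seeding failed");

  IntegerMatrix lab(h, w);
  std::fill(lab.begin(), lab.end(), -1);
  NumericMatrix dist(h, w);
  std::vector<double> objective;
  double invS2 = 1.0 / (S * S), m2 = m * m;

  for (int it = 0; it < max_iter; ++it) {
    std::fill(dist.begin(), dist.end(), std::numeric_limits<double>::max());
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r)
        if (mask(r, c)) lab(r, c) = -1;
    for (int j = 0; j < k; ++j) {
      int rr0 = std::max(0, (int)(cr[j] - S)), rr1 = std::min(h - 1, (int)(cr[j] + S));
      int cw0 = std::max(0, (int)(cc[j] - S)), cw1 = std::min(w - 1, (int)(cc[j] + S));
      for (int c = cw0; c <= cw1; ++c)
        for (int r = rr0; r <= rr1; ++r) {
          if (!mask(r, c)) continue;
          double dxy2 = (r - cr[j]) * (r - cr[j]) + (c - cc[j]) * (c - cc[j]);
          double dd = ds(r, c) - cd[j];
          double D2 = dd * dd + m2 * dxy2 * invS2;
          if (D2 < dist(r, c)) { dist(r, c) = D2; lab(r, c) = j; }
        }
    }
    // pixels outside every search window: assign to the nearest center
    double obj = 0;
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        if (!mask(r, c)) continue;
        if (lab(r, c) < 0) {
          for (int j = 0; j < k; ++j) {
            double dxy2 = (r - cr[j]) * (r - cr[j]) + (c - cc[j]) * (c - cc[j]);
            double dd = ds(r, c) - cd[j];
            double D2 = dd * dd + m2 * dxy2 * invS2;
            if (D2 < dist(r, c)) { dist(r, c) = D2; lab(r, c) = j; }
          }
        }
        obj += dist(r, c);
      }
    objective.push_back(obj);
    // center update
    std::vector<double> sr(k, 0), sc(k, 0), sd(k, 0);
    std::vector<long> cnt(k, 0);
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r)
        if (mask(r, c) && lab(r, c) >= 0) {
          int j = lab(r, c);
          sr[j] += r; sc[j] += c; sd[j] += ds(r, c); ++cnt[j];
        }
    for (int j = 0; j < k; ++j)
      if (cnt[j] > 0) {
        cr[j] = sr[j] / cnt[j]; cc[j] = sc[j] / cnt[j]; cd[j] = sd[j] / cnt[j];
      }
  }

  // connectivity enforcement: per label keep the largest 4-connected
  // fragment; orphan pixels take the label of the 4-neighbour whose center
  // is nearest, iterated to convergence.
  {
    IntegerMatrix frag(h, w);
    std::vector<long> fsize;
    std::vector<int> flab, stack;
    int nf = 0;
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        if (!mask(r, c) || frag(r, c)) continue;
        int L = lab(r, c);
        ++nf;
        long sz = 0;
        frag(r, c) = nf;
        stack.push_back(r + c * h);
        while (!stack.empty()) {
          int p = stack.back(); stack.pop_back();
          int pr = p % h, pc = p / h;
          ++sz;
          const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
          for (int q = 0; q < 4; ++q) {
            int nr = pr + dr[q], nc = pc + dc[q];
            if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
            if (mask(nr, nc) && !frag(nr, nc) && lab(nr, nc) == L) {
              frag(nr, nc) = nf;
              stack.push_back(nr + nc * h);
            }
          }
        }
        fsize.push_back(sz);
        flab.push_back(L);
      }
    std::vector<long> best(k, -1);
    std::vector<int> bestf(k, -1);
    for (int f = 0; f < nf; ++f) {
      int L = flab[f];
      if (fsize[f] > best[L]) { best[L] = fsize[f]; bestf[L] = f + 1; }
    }
    std::vector<char> orphan((size_t)h * w, 0);
    long norph = 0;
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r)
        if (mask(r, c) && frag(r, c) != bestf[lab(r, c)]) {
          orphan[(size_t)r + (size_t)c * h] = 1;
          ++norph;
        }
    while (norph > 0) {
      long changed = 0;
      for (int c = c0; c <= c1; ++c)
        for (int r = r0; r <= r1; ++r) {
          size_t i = (size_t)r + (size_t)c * h;
          if (!orphan[i]) continue;
          int bestL = -1;
          double bd = std::numeric_limits<double>::max();
          const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
          for (int q = 0; q < 4; ++q) {
            int nr = r + dr[q], nc = c + dc[q];
            if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
            if (!mask(nr, nc) || orphan[(size_t)nr + (size_t)nc * h]) continue;
            int L = lab(nr, nc);
            double d2 = (r - cr[L]) * (r - cr[L]) + (c - cc[L]) * (c - cc[L]);
            if (d2 < bd) { bd = d2; bestL = L; }
          }
          if (bestL >= 0) {
            lab(r, c) = bestL;
            orphan[i] = 0;
            ++changed; --norph;
          }
        }
      if (changed == 0) break;  // cannot happen for a connected mask
    }
  }

  // drop empty labels and compact ids
  std::vector<long> cnt(k, 0);
  for (int c = c0; c <= c1; ++c)
    for (int r = r0; r <= r1; ++r)
      if (mask(r, c)) ++cnt[lab(r, c)];
  std::vector<int> newid(k, -1);
  int k2 = 0;
  for (int j = 0; j < k; ++j)
    if (cnt[j] > 0) newid[j] = k2++;
  std::vector<double> sr(k2, 0), sc(k2, 0), sd(k2, 0);
  std::vector<long> n2(k2, 0);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c)) { lab(r, c) = NA_INTEGER; continue; }
      int j = newid[lab(r, c)];
      lab(r, c) = j;
      sr[j] += r; sc[j] += c; sd[j] += depth(r, c); ++n2[j];
    }
  NumericMatrix centers(k2, 4);
  for (int j = 0; j < k2; ++j) {
    centers(j, 0) = sr[j] / n2[j];
    centers(j, 1) = sc[j] / n2[j];
    centers(j, 2) = sd[j] / n2[j];
    centers(j, 3) = (double)n2[j];
  }
  return List::create(_["labels"] = lab, _["centers"] = centers,
                      _["K"] = k2, _["step"] = S,
                      _["objective"] = wrap(objective));
}
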
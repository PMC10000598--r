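// Capsule-union z-buffer renderer.  The synthetic subject is a union of
// capsules (segment + radius); each pixel ray is intersected with every
// capsule whose projected bounding rectangle covers it and the nearest hit
// wins.  Depth is returned as z-depth (mm along the optical axis), the
// convention of structured-light sensors.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Cap {
  double ax, ay, az, bx, by, bz, r;
  int part;
  int u0, u1, v0, v1;  // pixel rect
};

// Nearest positive intersection of the unit ray `d` (origin 0) with a
// capsule; returns -1 if none.
static double ray_capsule(double dx, double dy, double dz, const Cap &C) {
  double bax = C.bx - C.ax, bay = C.by - C.ay, baz = C.bz - C.az;
  double oax = -C.ax, oay = -C.ay, oaz = -C.az;
  double baba = bax * bax + bay * bay + baz * baz;
  double best = -1.0;
  if (baba > 1e-12) {
    double bard = bax * dx + bay * dy + baz * dz;
    double baoa = bax * oax + bay * oay + baz * oaz;
    double rdoa = dx * oax + dy * oay + dz * oaz;
    double oaoa = oax * oax + oay * oay + oaz * oaz;
    double a = baba - bard * bard;
    double b = baba * rdoa - baoa * bard;
    double c = baba * oaoa - baoa * baoa - C.r * C.r * baba;
    if (std::fabs(a) > 1e-12) {
      double h = b * b - a * c;
      if (h >= 0.0) {
        double t = (-b - std::sqrt(h)) / a;
        double y = baoa + t * bard;
        if (t > 0.0 && y > 0.0 && y < baba) best = t;
      }
    }
  }
  // spherical caps
  for (int e = 0; e < 2; ++e) {
    double cx = e == 0 ? C.ax : C.bx;
    double cy = e == 0 ? C.ay : C.by;
    double cz = e == 0 ? C.az : C.bz;
    double ocx = -cx, ocy = -cy, ocz = -cz;
    double b = dx * ocx + dy * ocy + dz * ocz;
    double c = ocx * ocx + ocy * ocy + ocz * ocz - C.r * C.r;
    double h = b * b - c;
    if (h >= 0.0) {
      double t = -b - std::sqrt(h);
      if (t > 0.0 && (best < 0.0 || t < best)) best = t;
    }
  }
  return best;
}

// capsules: n x 8 matrix (ax ay az bx by bz r part) in CAMERA coordinates
// (x right, y up, z along the optical axis away from the camera).
// Returns list(depth = h x w numeric (mm, background_distance where no
// body), part = h x w integer (0 = background, else part id)).
// [[Rcpp::export(name = ".render_capsules")]]
List render_capsules(NumericMatrix capsules, int width, int height,
                     double fx, double fy, double cx, double cy,
                     double background_distance) {
  int n = capsules.nrow();
  std::vector<Cap> caps(n);
  for (int i = 0; i < n; ++i) {
    Cap &C = caps[i];
    C.ax = capsules(i, 0); C.ay = capsules(i, 1); C.az = capsules(i, 2);
    C.bx = capsules(i, 3); C.by = capsules(i, 4); C.bz = capsules(i, 5);
    C.r = capsules(i, 6);
    C.part = (int)capsules(i, 7);
    // conservative pixel rect from the AABB expanded by r
    double xmin = std::min(C.ax, C.bx) - C.r, xmax = std::max(C.ax, C.bx) + C.r;
    double ymin = std::min(C.ay, C.by) - C.r, ymax = std::max(C.ay, C.by) + C.r;
    double zmin = std::min(C.az, C.bz) - C.r, zmax = std::max(C.az, C.bz) + C.r;
    if (zmin <= 1.0) stop("capsule too close to the camera");
    auto ulo = [&](double x) { return cx + fx * x / (x < 0 ? zmin : zmax); };
    auto uhi = [&](double x) { return cx + fx * x / (x > 0 ? zmin : zmax); };
    C.u0 = std::max(0, (int)std::floor(ulo(xmin)) - 2);
    C.u1 = std::min(width - 1, (int)std::ceil(uhi(xmax)) + 2);
    // v grows downward: v = cy - fy*y/z
    auto vlo = [&](double y) { return cy - fy * y / (y > 0 ? zmin : zmax); };
    auto vhi = [&](double y) { return cy - fy * y / (y < 0 ? zmin : zmax); };
    C.v0 = std::max(0, (int)std::floor(vlo(ymax)) - 2);
    C.v1 = std::min(height - 1, (int)std::ceil(vhi(ymin)) + 2);
  }

  NumericMatrix depth(height, width);
  IntegerMatrix part(height, width);
  std::fill(depth.begin(), depth.end(), background_distance);

  for (int i = 0; i < n; ++i) {
    const Cap &C = caps[i];
    for (int v = C.v0; v <= C.v1; ++v) {
      double ry = (cy - v) / fy;
      for (int u = C.u0; u <= C.u1; ++u) {
        double rx = (u - cx) / fx;
        double nrm = std::sqrt(rx * rx + ry * ry + 1.0);
        double t = ray_capsule(rx / nrm, ry / nrm, 1.0 / nrm, C);
        if (t > 0.0) {
          double z = t / nrm;  // z-depth since dir z-component is 1/nrm
          if (z < depth(v, u)) {
            depth(v, u) = z;
            part(v, u) = C.part;
          }
        }
      }
    }
  }
  return List::create(_["depth"] = depth, _["part"] = part);
}
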
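#include <Rcpp.h>
using namespace Rcpp;

// Convex-polygon machinery shared by the R-level ellipse predicates and the
// base-disc packer. Ellipses are approximated by regular inscribed polygons
// (vertex count chosen at the R level, default 64) and tested for overlap
// with the separating-axis theorem, which is exact for convex polygons.

static void ellipse_poly(double cx, double cy, double a, double b,
                         double theta, int n, std::vector<double>& px,
                         std::vector<double>& py) {
  px.resize(n); py.resize(n);
  double ct = std::cos(theta), st = std::sin(theta);
  for (int i = 0; i < n; ++i) {
    double t = 2.0 * M_PI * i / n;
    double x = a * std::cos(t), y = b * std::sin(t);
    px[i] = cx + x * ct - y * st;
    py[i] = cy + x * st + y * ct;
  }
}

// project both polygons on every edge normal of `ax/ay`; true if a
// separating axis exists
static bool separated_on(const std::vector<double>& axx,
                         const std::vector<double>& axy,
                         const std::vector<double>& px,
                         const std::vector<double>& py,
                         const std::vector<double>& qx,
                         const std::vector<double>& qy) {
  int n = axx.size();
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double nx = -(axy[j] - axy[i]);
    double ny = axx[j] - axx[i];
    double pmin = R_PosInf, pmax = R_NegInf, qmin = R_PosInf, qmax = R_NegInf;
    for (size_t k = 0; k < px.size(); ++k) {
      double v = nx * px[k] + ny * py[k];
      if (v < pmin) pmin = v;
      if (v > pmax) pmax = v;
    }
    for (size_t k = 0; k < qx.size(); ++k) {
      double v = nx * qx[k] + ny * qy[k];
      if (v < qmin) qmin = v;
      if (v > qmax) qmax = v;
    }
    if (pmax < qmin || qmax < pmin) return true;
  }
  return false;
}

static bool polys_overlap(const std::vector<double>& px,
                          const std::vector<double>& py,
                          const std::vector<double>& qx,
                          const std::vector<double>& qy) {
  if (separated_on(px, py, px, py, qx, qy)) return false;
  if (separated_on(qx, qy, px, py, qx, qy)) return false;
  return true;
}

// [[Rcpp::export(name = ".convex_polys_overlap")]]
bool convex_polys_overlap(NumericMatrix P, NumericMatrix Q) {
  std::vector<double> px(P.nrow()), py(P.nrow()), qx(Q.nrow()), qy(Q.nrow());
  for (int i = 0; i < P.nrow(); ++i) { px[i] = P(i, 0); py[i] = P(i, 1); }
  for (int i = 0; i < Q.nrow(); ++i) { qx[i] = Q(i, 0); qy[i] = Q(i, 1); }
  return polys_overlap(px, py, qx, qy);
}

struct ZonePair {
  double x, y, ecc, a, b;
  std::vector<double> rx, ry, tx, ty;  // radial / tangential zone polygons
};

// Flanker-room probe: does side s of the designated zone contain at least
// one position (probed on a fixed grid over the half-zone) where a flanker
// disc would lie outside the central lens of the two zones, at least one
// disc diameter from the base center, wholly inside the field, and wholly
// outside the exclusion circle?  Static constraints only; disc-disc
// conflicts with other flankers are resolved at placement time.
#define NA_PROBE_U 10
#define NA_PROBE_V 9
static bool side_feasible(double x, double y, double dx, double dy,
                          double s, double a, double b, double disc_radius,
                          double w2, double h2, double min_ecc) {
  double xmax = w2 - disc_radius, ymax = h2 - disc_radius;
  for (int iu = 0; iu < NA_PROBE_U; ++iu) {
    double u = a * (0.02 + 0.978 * iu / (NA_PROBE_U - 1));
    double vmax = b * std::sqrt(std::max(0.0, 1.0 - (u / a) * (u / a))) *
                  0.999;
    for (int iv = 0; iv < NA_PROBE_V; ++iv) {
      double v = vmax * (2.0 * iv / (NA_PROBE_V - 1) - 1.0);
      // outside the lens: not inside the 90-degree-rotated ellipse
      if ((v / a) * (v / a) + (u / b) * (u / b) <= 1.0) continue;
      if (u * u + v * v < 4.0 * disc_radius * disc_radius) continue;
      double px = x + s * u * dx - v * dy;
      double py = y + s * u * dy + v * dx;
      if (std::fabs(px) > xmax || std::fabs(py) > ymax) continue;
      if (px * px + py * py < min_ecc * min_ecc) continue;
      return true;
    }
  }
  return false;
}

// Rejection-sampling packer. Candidate base-disc centers are drawn
// uniformly over the positions where the disc fits wholly inside the field;
// a candidate is accepted iff its whole disc lies outside the fixation
// exclusion circle, (when require_room) both sides of its designated zone
// admit an on-axis flanker position, and neither of its two interference
// zones overlaps any zone (either kind) of an already accepted base.
// Packing stops after `maxfail` consecutive rejections, or once `target`
// bases are accepted (target < 0 means pack to saturation). Uses R's RNG.
// [[Rcpp::export(name = ".pack_bases")]]
NumericMatrix pack_bases(double field_w, double field_h, double disc_radius,
                         double excl_radius, double major_factor,
                         double minor_factor, int maxfail, int nverts,
                         int target, int arr_radial, int require_room) {
  RNGScope scope;
  std::vector<ZonePair> accepted;
  double xmax = field_w / 2.0 - disc_radius;
  double ymax = field_h / 2.0 - disc_radius;
  double min_ecc = excl_radius + disc_radius;
  int fails = 0;
  if (xmax <= 0 || ymax <= 0) {
    return NumericMatrix(0, 2);
  }
  while (fails < maxfail && (target < 0 || (int)accepted.size() < target)) {
    double x = R::runif(-xmax, xmax);
    double y = R::runif(-ymax, ymax);
    double ecc = std::sqrt(x * x + y * y);
    if (ecc < min_ecc) { ++fails; continue; }
    double a = major_factor * ecc, b = minor_factor * ecc;
    double th = std::atan2(y, x);
    if (require_room) {
      double dx, dy;
      if (arr_radial) { dx = x / ecc; dy = y / ecc; }
      else { dx = -y / ecc; dy = x / ecc; }
      if (!side_feasible(x, y, dx, dy, 1.0, a, b, disc_radius,
                         field_w / 2.0, field_h / 2.0, min_ecc) ||
          !side_feasible(x, y, dx, dy, -1.0, a, b, disc_radius,
                         field_w / 2.0, field_h / 2.0, min_ecc)) {
        ++fails; continue;
      }
    }
    bool ok = true;
    ZonePair cand;
    bool built = false;
    for (size_t j = 0; j < accepted.size() && ok; ++j) {
      const ZonePair& z = accepted[j];
      double dx = x - z.x, dy = y - z.y;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > a + z.a) continue;           // beyond any possible contact
      if (d <= b + z.b) { ok = false; break; }  // inscribed circles meet
      if (!built) {
        ellipse_poly(x, y, a, b, th, nverts, cand.rx, cand.ry);
        ellipse_poly(x, y, a, b, th + M_PI / 2.0, nverts, cand.tx, cand.ty);
        built = true;
      }
      if (polys_overlap(cand.rx, cand.ry, z.rx, z.ry) ||
          polys_overlap(cand.rx, cand.ry, z.tx, z.ty) ||
          polys_overlap(cand.tx, cand.ty, z.rx, z.ry) ||
          polys_overlap(cand.tx, cand.ty, z.tx, z.ty)) ok = false;
    }
    if (ok) {
      if (!built) {
        ellipse_poly(x, y, a, b, th, nverts, cand.rx, cand.ry);
        ellipse_poly(x, y, a, b, th + M_PI / 2.0, nverts, cand.tx, cand.ty);
      }
      cand.x = x; cand.y = y; cand.ecc = ecc; cand.a = a; cand.b = b;
      accepted.push_back(cand);
      fails = 0;
    } else {
      ++fails;
    }
  }
  NumericMatrix out(accepted.size(), 2);
  for (size_t i = 0; i < accepted.size(); ++i) {
    out(i, 0) = accepted[i].x;
    out(i, 1) = accepted[i].y;
  }
  return out;
}
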
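// Weighted-photon Monte Carlo transport through a stack of plane-parallel
// turbid layers (hop / drop / spin with Henyey-Greenstein scattering,
// Fresnel boundaries, Russian roulette, (r, z) fluence scoring).
//
// Geometry convention: z = 0 at the scalp surface, z increases downward.
// All lengths in cm, attenuation coefficients in cm^-1.
//
// Random deviates come from R's generator (unif_rand), so runs are
// reproducible with set.seed().  Per interaction the draw order is fixed:
// step, azimuth, zenith, boundary decision, roulette.

#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double DIR_EPS = 1e-12;
static const double PLANE_TOL = 1e-9;

//' @noRd
// [[Rcpp::export]]
double cpp_specular_reflectance(double n1, double n2) {
  double d = (n1 - n2) / (n1 + n2);
  return d * d;
}

// Unpolarized Fresnel reflectance for a ray with incidence cosine
// cos_incidence in medium n1 meeting medium n2.  Angle-sum form, which is
// numerically stable away from the trivial limits handled explicitly.
// [[Rcpp::export]]
double cpp_fresnel_unpolarized(double n1, double n2, double cos_incidence) {
  double ca1 = cos_incidence;
  if (n1 == n2) return 0.0;
  if (ca1 > 1.0 - 1e-12) {  // normal incidence
    double r = (n2 - n1) / (n2 + n1);
    return r * r;
  }
  if (ca1 < 1e-6) return 1.0;  // grazing incidence
  double sa1 = std::sqrt(1.0 - ca1 * ca1);
  double sa2 = n1 / n2 * sa1;
  if (sa2 >= 1.0) return 1.0;  // total internal reflection
  double ca2 = std::sqrt(1.0 - sa2 * sa2);
  double cap = ca1 * ca2 - sa1 * sa2;
  double cam = ca1 * ca2 + sa1 * sa2;
  double sap = sa1 * ca2 + ca1 * sa2;
  double sam = sa1 * ca2 - ca1 * sa2;
  return 0.5 * sam * sam * (cam * cam + cap * cap) / (sap * sap * cam * cam);
}

// Inverse-CDF sample of the Henyey-Greenstein deflection cosine.
// |g| = 1 degenerates to deterministic forward/backward scattering.
// [[Rcpp::export]]
double cpp_hg_cos_theta(double g, double xi) {
  if (g >= 1.0 - DIR_EPS) return 1.0;
  if (g <= -1.0 + DIR_EPS) return -1.0;
  if (std::fabs(g) < 1e-12) return 2.0 * xi - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double ct = (1.0 + g * g - t * t) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

static inline double next_unif() {
  double u;
  do {
    u = unif_rand();
  } while (u <= 0.0 || u >= 1.0);
  return u;
}

// Full transport run.
//
// layers:   nlayer x 4 matrix, columns n, mu_a, mu_s, g (top to bottom)
// z_bounds: nlayer + 1 boundary depths (cm), strictly increasing
// n_above:  refractive index of the ambient medium above the top layer
// source_type: 0 = pencil beam entering the top surface heading +z,
//              1 = isotropic point source at (src_r, 0, src_z)
// mode:     0 = "fresnel_full" (probabilistic unpolarized Fresnel),
//           1 = "paper_eq1" (deterministic: total internal reflection above
//               the critical angle, otherwise transmit with the weight
//               stripped by the normal-incidence reflectance)
// n_below:  refractive index of the medium below the bottom boundary.  When
//           NA (the default wrapper behaviour) the bottom is a perfect sink:
//           photons crossing it are terminated and tallied as transmitted
//           (the bottom layer stands in for a semi-infinite substrate).
//           When finite, the bottom is a true optical interface: photons
//           reflect or refract there like at any other boundary, and
//           transmitted ones are terminated (optionally recorded).
// plane_z:  depths at which downward plane crossings within plane_radius of
//           the axis are scored (weight and count per plane)
// [[Rcpp::export]]
List cpp_run_transport(NumericMatrix layers, NumericVector z_bounds,
                       double n_above, int source_type, double src_z,
                       double src_r, double w0, double n_photons, int mode,
                       double roulette_threshold, double roulette_m,
                       double dr, double dz, int nr, int nz, double z_grid0,
                       NumericVector plane_z, double plane_radius,
                       bool plane_first_only, bool record_exits,
                       double n_below, bool record_bottom_exits) {
  const int nlay = layers.nrow();
  const long long nph = (long long)n_photons;
  const int npl = plane_z.size();

  std::vector<double> Ln(nlay), La(nlay), Ls(nlay), Lg(nlay);
  for (int i = 0; i < nlay; ++i) {
    Ln[i] = layers(i, 0);
    La[i] = layers(i, 1);
    Ls[i] = layers(i, 2);
    Lg[i] = layers(i, 3);
  }
  std::vector<double> zb(z_bounds.begin(), z_bounds.end());

  NumericMatrix A(nr, nz);
  double overflow = 0.0;
  double specular = 0.0, absorbed = 0.0, escaped = 0.0, transmitted = 0.0,
         roulette_lost = 0.0, roulette_boost = 0.0, boundary_stripped = 0.0;

  std::vector<double> plane_w(npl, 0.0), plane_n(npl, 0.0);
  // planes that coincide with an internal boundary are scored at the moment
  // of downward transmission through that boundary (a photon that merely
  // reaches the boundary and reflects has not crossed the plane)
  std::vector<int> plane_at_boundary(npl, -1);
  for (int p = 0; p < npl; ++p)
    for (int b = 0; b < (int)zb.size(); ++b)
      if (std::fabs(plane_z[p] - zb[b]) < PLANE_TOL) plane_at_boundary[p] = b;

  std::vector<double> ex_r, ex_ct, ex_w;
  if (record_exits) {
    ex_r.reserve(4096);
    ex_ct.reserve(4096);
    ex_w.reserve(4096);
  }
  std::vector<double> bex_r, bex_ct, bex_w;
  const bool fresnel_bottom = R_finite(n_below) && n_below > 0.0;

  std::vector<char> counted(npl, 0);
  const double inv_m = 1.0 / roulette_m;
  const double plane_r2 = plane_radius * plane_radius;

  for (long long ip = 0; ip < nph; ++ip) {
    if ((ip & 0x3fff) == 0) Rcpp::checkUserInterrupt();

    double x, y, z, ux, uy, uz, W;
    int li;
    if (source_type == 0) {
      x = 0.0;
      y = 0.0;
      z = zb[0];
      ux = 0.0;
      uy = 0.0;
      uz = 1.0;
      li = 0;
      double rsp = cpp_specular_reflectance(n_above, Ln[0]);
      specular += w0 * rsp;
      W = w0 * (1.0 - rsp);
    } else {
      x = src_r;
      y = 0.0;
      z = src_z;
      li = nlay - 1;  // exact-boundary depths resolve to the layer below
      for (int i = 0; i < nlay; ++i)
        if (src_z >= zb[i] && src_z < zb[i + 1]) {
          li = i;
          break;
        }
      double xi1 = next_unif(), xi2 = next_unif();
      uz = 2.0 * xi1 - 1.0;
      double st = std::sqrt(std::max(0.0, 1.0 - uz * uz));
      double psi = 2.0 * M_PI * xi2;
      ux = st * std::cos(psi);
      uy = st * std::sin(psi);
      W = w0;
    }
    if (npl) std::fill(counted.begin(), counted.end(), 0);

    double sleft = 0.0;  // dimensionless step remainder (s * mu_t)
    bool alive = true;
    long long guard = 0;
    while (alive) {
      if (++guard > 100000000LL) {  // pathological-configuration guard
        roulette_lost += W;
        break;
      }
      double mua = La[li], mus = Ls[li], g = Lg[li];
      double mut = mua + mus;

      double db = DBL_MAX;
      int dirb = 0;  // -1 heading to the top of the layer, +1 to the bottom
      if (uz > DIR_EPS) {
        db = (zb[li + 1] - z) / uz;
        dirb = 1;
      } else if (uz < -DIR_EPS) {
        db = (zb[li] - z) / uz;
        dirb = -1;
      }
      if (db < 0.0) db = 0.0;

      bool to_boundary;
      double step;
      if (mut <= 0.0) {
        // vacuum guard layer: ballistic traversal to the boundary
        if (dirb == 0) {  // horizontal flight in vacuum never terminates
          roulette_lost += W;
          break;
        }
        to_boundary = true;
        step = db;
      } else {
        if (sleft <= 0.0) sleft = -std::log(next_unif());
        double s = sleft / mut;
        to_boundary = (dirb != 0 && db <= s);
        step = to_boundary ? db : s;
      }

      // move, scoring strictly interior downward plane crossings
      double zn = z + step * uz;
      if (npl && uz > DIR_EPS) {
        for (int p = 0; p < npl; ++p) {
          double zp = plane_z[p];
          if (z < zp && zn > zp) {
            double t = (zp - z) / (zn - z);
            double xc = x + t * step * ux, yc = y + t * step * uy;
            if (xc * xc + yc * yc <= plane_r2 &&
                !(plane_first_only && counted[p])) {
              plane_w[p] += W;
              plane_n[p] += 1.0;
              counted[p] = 1;
            }
          }
        }
      }
      x += step * ux;
      y += step * uy;
      z = zn;

      if (to_boundary) {
        if (mut > 0.0) sleft -= step * mut;
        int other = li + dirb;
        if (other >= nlay && !fresnel_bottom) {
          // semi-infinite floor: terminate as transmitted
          transmitted += W;
          alive = false;
          continue;
        }
        double n1 = Ln[li];
        double n2 = (other < 0) ? n_above : (other >= nlay ? n_below : Ln[other]);
        double ca1 = std::fabs(uz);
        bool reflect;
        double strip = 0.0;
        if (mode == 0) {
          double R = cpp_fresnel_unpolarized(n1, n2, ca1);
          reflect = (R >= 1.0) ? true : (next_unif() <= R);
        } else {
          reflect = false;
          if (n2 < n1) {
            double sa1 = std::sqrt(std::max(0.0, 1.0 - ca1 * ca1));
            if (sa1 >= n2 / n1) reflect = true;
          }
          if (!reflect && n1 != n2) strip = W * cpp_specular_reflectance(n1, n2);
        }
        if (reflect) {
          uz = -uz;
          continue;
        }
        if (strip > 0.0) {
          boundary_stripped += strip;
          W -= strip;
        }
        double ratio = n1 / n2;
        double sa1sq = std::max(0.0, 1.0 - ca1 * ca1);
        double ca2 = std::sqrt(std::max(0.0, 1.0 - ratio * ratio * sa1sq));
        ux *= ratio;
        uy *= ratio;
        uz = (uz > 0.0) ? ca2 : -ca2;
        if (other < 0) {  // escaped through the top surface into the ambient
          escaped += W;
          if (record_exits) {
            ex_r.push_back(std::sqrt(x * x + y * y));
            ex_ct.push_back(ca2);
            ex_w.push_back(W);
          }
          alive = false;
          continue;
        }
        if (other >= nlay) {  // transmitted through the refracting bottom
          transmitted += W;
          if (record_bottom_exits) {
            bex_r.push_back(std::sqrt(x * x + y * y));
            bex_ct.push_back(ca2);
            bex_w.push_back(W);
          }
          alive = false;
          continue;
        }
        li = other;
        if (uz > 0.0 && npl) {
          for (int p = 0; p < npl; ++p)
            if (plane_at_boundary[p] == li && !(plane_first_only && counted[p])) {
              if (x * x + y * y <= plane_r2) {
                plane_w[p] += W;
                plane_n[p] += 1.0;
                counted[p] = 1;
              }
            }
        }
        continue;
      }

      // interaction site: drop
      sleft = 0.0;
      if (mua > 0.0) {
        double dw = W * mua / mut;
        int ir = (int)(std::sqrt(x * x + y * y) / dr);
        int iz = (int)std::floor((z - z_grid0) / dz);
        if (ir >= 0 && ir < nr && iz >= 0 && iz < nz)
          A(ir, iz) += dw;
        else
          overflow += dw;
        absorbed += dw;
        W -= dw;
        if (W <= 0.0) {
          alive = false;
          continue;
        }
      }
      // spin: azimuth, then Henyey-Greenstein zenith
      double psi = 2.0 * M_PI * next_unif();
      double ct = cpp_hg_cos_theta(g, next_unif());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double cp = std::cos(psi), sp = std::sin(psi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp;
        uy = st * sp;
        uz = (uz >= 0.0 ? ct : -ct);
      } else {
        double tmp = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / tmp + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / tmp + uy * ct;
        double nuz = -st * cp * tmp + uz * ct;
        ux = nux;
        uy = nuy;
        uz = nuz;
      }
      double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= nrm;
      uy /= nrm;
      uz /= nrm;
      // roulette
      if (W < roulette_threshold) {
        if (next_unif() < inv_m) {
          roulette_boost += W * (roulette_m - 1.0);  // survivor weight gain
          W *= roulette_m;
        } else {
          roulette_lost += W;
          alive = false;
        }
      }
    }
  }

  List ledger = List::create(
      _["launched_weight"] = (double)nph * w0, _["specular"] = specular,
      _["absorbed"] = absorbed, _["escaped_top"] = escaped,
      _["transmitted_bottom"] = transmitted,
      _["roulette_killed"] = roulette_lost,
      _["roulette_boost"] = roulette_boost,
      _["boundary_stripped"] = boundary_stripped);

  return List::create(
      _["A"] = A, _["overflow"] = overflow, _["ledger"] = ledger,
      _["plane_weight"] = NumericVector(plane_w.begin(), plane_w.end()),
      _["plane_count"] = NumericVector(plane_n.begin(), plane_n.end()),
      _["exit_r"] = NumericVector(ex_r.begin(), ex_r.end()),
      _["exit_cos"] = NumericVector(ex_ct.begin(), ex_ct.end()),
      _["exit_w"] = NumericVector(ex_w.begin(), ex_w.end()),
      _["bottom_r"] = NumericVector(bex_r.begin(), bex_r.end()),
      _["bottom_cos"] = NumericVector(bex_ct.begin(), bex_ct.end()),
      _["bottom_w"] = NumericVector(bex_w.begin(), bex_w.end()));
}
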
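// Layered Monte Carlo photon transport (hop-drop-spin) with a hexagonal
// fiber probe at the top surface.  Two engines share the same geometry code:
//   * mc_run_wavelength_cpp  - discrete absorption weighting (classic MCML),
//   * mc_run_white_cpp       - scattering-only trajectories with analytic
//                              Beer-Lambert absorption weighting, evaluated
//                              for many absorption states in one pass.
// The RNG is MRG32k3a in its double-precision form so that a pure-R loop can
// reproduce the engine's stream bit for bit.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double M1 = 4294967087.0;
const double M2 = 4294944443.0;
const double NORM = 2.328306549295727688e-10;

// remainder of exact non-negative integer-valued doubles (all operands and
// results below 2^53, so every operation is exact)
inline double imod(double a, double b) {
  double r = a - std::trunc(a / b) * b;
  if (r < 0.0) r += b;
  if (r >= b) r -= b;
  return r;
}

struct Mrg32k3a {
  double s10, s11, s12, s20, s21, s22;

  // substream scrambler: MINSTD iterates seeded from (seed, stream);
  // iterates lie in [1, 2147483646], valid and nonzero for both components
  void seed_stream(double seed, double stream) {
    double h = imod(seed + 20010927.0 * (stream + 1.0), 2147483646.0) + 1.0;
    double st[6];
    for (int i = 0; i < 6; ++i) {
      h = imod(16807.0 * h, 2147483647.0);
      st[i] = h;
    }
    s10 = st[0]; s11 = st[1]; s12 = st[2];
    s20 = st[3]; s21 = st[4]; s22 = st[5];
    for (int i = 0; i < 8; ++i) next();  // warm-up
  }

  double next() {
    double p1 = 1403580.0 * s11 - 810728.0 * s10;
    double k = std::trunc(p1 / M1);
    p1 -= k * M1;
    if (p1 < 0.0) p1 += M1;
    s10 = s11; s11 = s12; s12 = p1;
    double p2 = 527612.0 * s22 - 1370589.0 * s20;
    k = std::trunc(p2 / M2);
    p2 -= k * M2;
    if (p2 < 0.0) p2 += M2;
    s20 = s21; s21 = s22; s22 = p2;
    double v = p1 - p2;
    if (v <= 0.0) v += M1;
    return v * NORM;  // in (0, 1)
  }
};

// unpolarized Fresnel reflectance; cos_t returned for the refracted ray
double fresnel(double n1, double n2, double cos_i, double *cos_t) {
  if (cos_i > 0.999999) {
    double r = (n1 - n2) / (n1 + n2);
    *cos_t = 1.0;
    return r * r;
  }
  double sin_i = std::sqrt(1.0 - cos_i * cos_i);
  double sin_t = sin_i * n1 / n2;
  if (sin_t >= 1.0) {  // total internal reflection
    *cos_t = 0.0;
    return 1.0;
  }
  double ct = std::sqrt(1.0 - sin_t * sin_t);
  *cos_t = ct;
  double rs = (n1 * cos_i - n2 * ct) / (n1 * cos_i + n2 * ct);
  double rp = (n1 * ct - n2 * cos_i) / (n1 * ct + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

double hg_cos(double u, double g) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - tmp * tmp) / (2.0 * g);
}

void spin(double *ux, double *uy, double *uz, double cost, double phi) {
  double sint = std::sqrt(1.0 - cost * cost);
  double cosp = std::cos(phi);
  double sinp = std::sin(phi);
  if (std::fabs(*uz) > 0.99999) {
    *ux = sint * cosp;
    *uy = sint * sinp;
    *uz = (*uz >= 0.0) ? cost : -cost;
  } else {
    double tmp = std::sqrt(1.0 - (*uz) * (*uz));
    double nux = sint * ((*ux) * (*uz) * cosp - (*uy) * sinp) / tmp + (*ux) * cost;
    double nuy = sint * ((*uy) * (*uz) * cosp + (*ux) * sinp) / tmp + (*uy) * cost;
    double nuz = -sint * cosp * tmp + (*uz) * cost;
    *ux = nux; *uy = nuy; *uz = nuz;
  }
}

int which_fiber(double x, double y, const NumericMatrix &det, double r2) {
  for (int f = 0; f < det.nrow(); ++f) {
    double dx = x - det(f, 0);
    double dy = y - det(f, 1);
    if (dx * dx + dy * dy <= r2) return f;
  }
  return -1;
}

}  // namespace

// Uniform draws from one engine substream (for RNG parity tests).
// [[Rcpp::export]]
NumericVector mrg_uniforms_cpp(double seed, double stream, int n) {
  Mrg32k3a rng;
  rng.seed_stream(seed, stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.next();
  return out;
}

// Discrete-absorption-weighting MCML engine at one wavelength.
// All lengths in cm; det_xy is n_det x 2 detector centers.
// cos_accept: minimum |cos(exit angle)| accepted by a fiber (-1: accept all).
// [[Rcpp::export]]
List mc_run_wavelength_cpp(NumericVector mua, NumericVector mus, NumericVector g,
                           NumericVector n, NumericVector thick, double n_above,
                           double n_below, double src_radius, NumericMatrix det_xy,
                           double det_radius, double cos_accept, int n_photons,
                           double seed, double stream, double w_threshold,
                           double w_chance, int max_steps) {
  const int L = mua.size();
  const int ND = det_xy.nrow();
  std::vector<double> zb(L + 1), mut(L);
  zb[0] = 0.0;
  for (int l = 0; l < L; ++l) {
    zb[l + 1] = zb[l] + thick[l];
    mut[l] = mua[l] + mus[l];
  }
  const double det_r2 = det_radius * det_radius;
  const double rsp = std::pow((n_above - n[0]) / (n_above + n[0]), 2.0);
  const double TWOPI = 2.0 * M_PI;

  Mrg32k3a rng;
  rng.seed_stream(seed, stream);

  NumericVector fiber(ND), fiber_sq(ND);
  double top_diffuse = 0.0, transmitted = 0.0, absorbed = 0.0;
  double specular = rsp;  // per-photon constant; fractions reported per photon
  int n_detected = 0, n_capped = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double u = rng.next();
    double r = src_radius * std::sqrt(u);
    u = rng.next();
    double phi0 = TWOPI * u;
    double x = r * std::cos(phi0), y = r * std::sin(phi0), z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    int lay = 0;
    bool alive = true;
    int steps = 0;

    while (alive) {
      if (++steps > max_steps) { ++n_capped; absorbed += w; break; }
      u = rng.next();
      double s = -std::log(u) / mut[lay];
      // propagate, handling interface crossings within the sampled step
      for (;;) {
        double db;
        if (uz > 0.0) db = (zb[lay + 1] - z) / uz;
        else if (uz < 0.0) db = (zb[lay] - z) / uz;
        else db = 1e300;
        if (s < db) {
          x += s * ux; y += s * uy; z += s * uz;
          break;
        }
        x += db * ux; y += db * uy;
        s -= db;
        bool up = (uz < 0.0);
        z = up ? zb[lay] : zb[lay + 1];
        double n1 = n[lay];
        double n2 = up ? (lay == 0 ? n_above : n[lay - 1])
                       : (lay == L - 1 ? n_below : n[lay + 1]);
        double cos_t;
        double R = fresnel(n1, n2, std::fabs(uz), &cos_t);
        u = rng.next();
        if (u > R) {  // transmit
          if (up && lay == 0) {  // exits into the ambient medium above
            double exz = -cos_t;
            top_diffuse += w;
            if (cos_accept <= -1.0 || std::fabs(exz) >= cos_accept) {
              int f = which_fiber(x, y, det_xy, det_r2);
              if (f >= 0) { fiber[f] += w; fiber_sq[f] += w * w; ++n_detected; }
            }
            alive = false;
            break;
          }
          if (!up && lay == L - 1) {  // into the bottom medium
            transmitted += w;
            alive = false;
            break;
          }
          double scale = n1 / n2;
          ux *= scale; uy *= scale;
          uz = up ? -cos_t : cos_t;
          int nl = up ? lay - 1 : lay + 1;
          s *= mut[lay] / mut[nl];
          lay = nl;
        } else {
          uz = -uz;  // internal reflection
        }
      }
      if (!alive) break;
      // drop
      double dep = w * mua[lay] / mut[lay];
      w -= dep;
      absorbed += dep;
      // spin
      u = rng.next();
      double cost = hg_cos(u, g[lay]);
      u = rng.next();
      spin(&ux, &uy, &uz, cost, TWOPI * u);
      // roulette
      if (w < w_threshold) {
        u = rng.next();
        if (u < w_chance) w /= w_chance;
        else alive = false;
      }
    }
  }

  double np = static_cast<double>(n_photons);
  for (int f = 0; f < ND; ++f) { fiber[f] /= np; fiber_sq[f] /= np; }
  return List::create(_["fiber"] = fiber,
                      _["fiber_sumsq"] = fiber_sq,
                      _["top_diffuse"] = top_diffuse / np,
                      _["transmitted"] = transmitted / np,
                      _["absorbed"] = absorbed / np,
                      _["specular"] = specular,
                      _["n_detected"] = n_detected,
                      _["n_capped"] = n_capped);
}

// Scattering-only trajectories with analytic absorption weighting.
// mua_cond is n_cond x n_layer: each row an absorption state evaluated on the
// shared trajectory set (exact per-photon energy ledger for every state).
// [[Rcpp::export]]
List mc_run_white_cpp(NumericVector mus, NumericVector g, NumericVector n,
                      NumericVector thick, double n_above, double n_below,
                      double src_radius, NumericMatrix det_xy, double det_radius,
                      double cos_accept, int n_photons, double seed, double stream,
                      NumericMatrix mua_cond, int max_steps) {
  const int L = mus.size();
  const int ND = det_xy.nrow();
  const int NC = mua_cond.nrow();
  std::vector<double> zb(L + 1);
  zb[0] = 0.0;
  for (int l = 0; l < L; ++l) zb[l + 1] = zb[l] + thick[l];
  const double det_r2 = det_radius * det_radius;
  const double rsp = std::pow((n_above - n[0]) / (n_above + n[0]), 2.0);
  const double TWOPI = 2.0 * M_PI;

  Mrg32k3a rng;
  rng.seed_stream(seed, stream);

  NumericMatrix fiber(NC, ND);
  NumericVector top_diffuse(NC), transmitted(NC), absorbed(NC);
  std::vector<double> path(L);
  int n_capped = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double u = rng.next();
    double r = src_radius * std::sqrt(u);
    u = rng.next();
    double phi0 = TWOPI * u;
    double x = r * std::cos(phi0), y = r * std::sin(phi0), z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    const double w0 = 1.0 - rsp;
    int lay = 0;
    int exit_kind = 2;  // 0 top, 1 bottom, 2 capped
    double exit_x = 0.0, exit_y = 0.0, exit_cos = 1.0;
    std::fill(path.begin(), path.end(), 0.0);
    int steps = 0;
    bool alive = true;

    while (alive) {
      if (++steps > max_steps) { ++n_capped; exit_kind = 2; break; }
      u = rng.next();
      double s = -std::log(u) / mus[lay];
      for (;;) {
        double db;
        if (uz > 0.0) db = (zb[lay + 1] - z) / uz;
        else if (uz < 0.0) db = (zb[lay] - z) / uz;
        else db = 1e300;
        if (s < db) {
          x += s * ux; y += s * uy; z += s * uz;
          path[lay] += s;
          break;
        }
        x += db * ux; y += db * uy;
        path[lay] += db;
        s -= db;
        bool up = (uz < 0.0);
        z = up ? zb[lay] : zb[lay + 1];
        double n1 = n[lay];
        double n2 = up ? (lay == 0 ? n_above : n[lay - 1])
                       : (lay == L - 1 ? n_below : n[lay + 1]);
        double cos_t;
        double R = fresnel(n1, n2, std::fabs(uz), &cos_t);
        u = rng.next();
        if (u > R) {
          if (up && lay == 0) {
            exit_kind = 0; exit_x = x; exit_y = y; exit_cos = cos_t;
            alive = false;
            break;
          }
          if (!up && lay == L - 1) {
            exit_kind = 1;
            alive = false;
            break;
          }
          double scale = n1 / n2;
          ux *= scale; uy *= scale;
          uz = up ? -cos_t : cos_t;
          int nl = up ? lay - 1 : lay + 1;
          s *= mus[lay] / mus[nl];
          lay = nl;
        } else {
          uz = -uz;
        }
      }
      if (!alive) break;
      u = rng.next();
      double cost = hg_cos(u, g[lay]);
      u = rng.next();
      spin(&ux, &uy, &uz, cost, TWOPI * u);
    }

    int f = -1;
    if (exit_kind == 0 &&
        (cos_accept <= -1.0 || std::fabs(exit_cos) >= cos_accept))
      f = which_fiber(exit_x, exit_y, det_xy, det_r2);
    for (int c = 0; c < NC; ++c) {
      double att = 0.0;
      for (int l = 0; l < L; ++l) att += mua_cond(c, l) * path[l];
      double wex = w0 * std::exp(-att);
      absorbed[c] += w0 - wex;
      if (exit_kind == 0) {
        top_diffuse[c] += wex;
        if (f >= 0) fiber(c, f) += wex;
      } else if (exit_kind == 1) {
        transmitted[c] += wex;
      } else {
        absorbed[c] += wex;  // capped trajectories scored as absorbed
      }
    }
  }

  double np = static_cast<double>(n_photons);
  for (int c = 0; c < NC; ++c) {
    for (int f = 0; f < ND; ++f) fiber(c, f) /= np;
    top_diffuse[c] /= np; transmitted[c] /= np; absorbed[c] /= np;
  }
  return List::create(_["fiber"] = fiber,
                      _["top_diffuse"] = top_diffuse,
                      _["transmitted"] = transmitted,
                      _["absorbed"] = absorbed,
                      _["specular"] = rsp,
                      _["n_capped"] = n_capped);
}
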
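#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Counter-free xoshiro256+ generator with splitmix64 seeding: one substream
// per photon so results are independent of execution order and runs with a
// common master seed share photon paths (common random numbers).
namespace {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9e3779b97f4a7c15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // strictly inside (0,1)
  inline double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Unpolarized Fresnel reflectance; returns 1 at/beyond the critical angle.
inline double fresnel(double ni, double nt, double ci) {
  if (ni == nt) return 0.0;
  if (ci > 0.999999) {
    double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  if (ci < 1e-6) return 1.0; // grazing incidence
  double si = std::sqrt(1.0 - ci * ci);
  double st = si * ni / nt;
  if (st >= 1.0) return 1.0; // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double sim = si * ct - ci * st; // sin(i - t)
  double sip = si * ct + ci * st; // sin(i + t)
  double cim = ci * ct + si * st; // cos(i - t)
  double cip = ci * ct - si * st; // cos(i + t)
  double rs = sim / sip;
  double rp = (sim * cip) / (sip * cim);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine by inverse-CDF sampling.
inline double hg_cosine(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Henyey-Greenstein phase function over solid angle (sr^-1).
inline double hg_pdf(double g, double mu) {
  if (g == 0.0) return 1.0 / (4.0 * M_PI);
  double d = 1.0 + g * g - 2.0 * g * mu;
  return (1.0 - g * g) / (4.0 * M_PI * d * std::sqrt(d));
}

} // namespace

// [[Rcpp::export]]
double fresnel_cpp(double ni, double nt, double ci) {
  return fresnel(ni, nt, ci);
}

// [[Rcpp::export]]
double hg_cosine_cpp(double g, double u) { return hg_cosine(g, u); }

// Photon transport through a plane-parallel layer stack with a flat-top
// collimated beam, probabilistic Fresnel boundaries and NA-limited coaxial
// detection on the exit face.
//
// Scattering paths are sampled from the pure-scattering process
// (step = -ln(xi)/mu_s); absorption enters as the exact Beer factor
// exp(-sum mu_a * pathlength), which is identical in law to per-collision
// weighting with survival mu_s/mu_t and lets one photon ensemble be
// re-weighted over a whole absorption grid for the sweep layer
// (correlated sampling).
//
// The detected intensity uses a local (next-event) estimator: at every
// scattering event the expected contribution of a direct, scatter-free
// flight into the detector acceptance cone is accumulated analytically
// (phase-function density x cone solid angle x Fresnel transmissions x
// scattering attenuation x Beer absorption), and never-scattered photons
// are detected analogically.  Detection paths that undergo an internal
// reflection after their last scattering event are neglected (relative
// weight ~R * exp(-2 mu_s d) ~ 1e-8 for the stacks of interest).
//
// layers: matrix with columns n, mu_a (cm^-1), mu_s (cm^-1), g, d (cm).
// sweep_layer: 1-based index of the layer whose mu_a is evaluated on
//   mua_grid; if mua_grid has length 0 the layer's own mu_a is used.
// [[Rcpp::export]]
List mc_transport_cpp(NumericMatrix layers, double n_above, double n_below,
                      double beam_radius, double det_radius, double det_na,
                      double n_photons, double seed, int sweep_layer,
                      NumericVector mua_grid, double roulette_threshold,
                      double roulette_survival) {
  const int nl = layers.nrow();
  if (nl < 1) stop("empty layer stack");
  std::vector<double> n(nl), mua(nl), mus(nl), g(nl), z0(nl), z1(nl);
  double zcum = 0.0;
  for (int l = 0; l < nl; ++l) {
    n[l] = layers(l, 0); mua[l] = layers(l, 1); mus[l] = layers(l, 2);
    g[l] = layers(l, 3);
    z0[l] = zcum; zcum += layers(l, 4); z1[l] = zcum;
  }
  const int sw = sweep_layer - 1;
  if (sw < 0 || sw >= nl) stop("sweep_layer out of range");
  int K = mua_grid.size();
  std::vector<double> grid(K > 0 ? K : 1);
  if (K == 0) { K = 1; grid[0] = mua[sw]; }
  else for (int k = 0; k < K; ++k) grid[k] = mua_grid[k];
  bool grid_uniform = true;
  double dgrid = (K > 1) ? grid[1] - grid[0] : 0.0;
  for (int k = 2; k < K; ++k)
    if (std::fabs(grid[k] - grid[k - 1] - dgrid) > 1e-12) grid_uniform = false;

  const uint64_t nph = static_cast<uint64_t>(n_photons);
  if (nph < 1) stop("n_photons must be >= 1");
  const uint64_t base_seed = static_cast<uint64_t>(seed);

  // detector cone in each layer: n sin(theta) is conserved down to the
  // ambient exit, so acceptance inside layer l means sin(theta) <= NA/n_l
  std::vector<double> cone_cmin(nl), cone_omega(nl), mus_below(nl);
  for (int l = 0; l < nl; ++l) {
    double smax = det_na / n[l];
    cone_cmin[l] = std::sqrt(std::max(0.0, 1.0 - smax * smax));
    cone_omega[l] = 2.0 * M_PI * (1.0 - cone_cmin[l]);
  }
  mus_below[nl - 1] = 0.0;
  for (int l = nl - 2; l >= 0; --l)
    mus_below[l] = mus_below[l + 1] + mus[l + 1] * (z1[l + 1] - z0[l + 1]);

  // specular reflection at the top interface, deducted before propagation
  const double r_sp = fresnel(n_above, n[0], 1.0);
  const double w0 = 1.0 - r_sp;

  std::vector<double> det_sum(K, 0.0), det_sq(K, 0.0), tr_sum(K, 0.0),
      rf_sum(K, 0.0), ab_sum(K, 0.0), wprev(K), wcur(K), Dk(K);
  const double log_thr = std::log(roulette_threshold);
  const long max_steps = 20000000L;

  for (uint64_t i = 0; i < nph; ++i) {
    uint64_t sd = base_seed * 0x9e3779b97f4a7c15ULL + i;
    Xoshiro rng(sd);
    // launch: uniform over the beam disc, collimated +z
    double r0 = beam_radius * std::sqrt(rng.unif());
    double phi0 = 2.0 * M_PI * rng.unif();
    double x = r0 * std::cos(phi0), y = r0 * std::sin(phi0), z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int c = 0;
    double tau = -std::log(rng.unif()); // dimensionless scattering depth
    double Ls = 0.0;       // pathlength in the sweep layer
    double a_other = 0.0;  // absorption depth accumulated outside it
    double boost = 1.0;    // Russian-roulette weight multiplier
    long n_scat = 0;
    for (int k = 0; k < K; ++k) { wprev[k] = w0; Dk[k] = 0.0; }
    long steps = 0;
    int status = -1; // 0 refl, 1 trans undetected, 2 detected, 3 absorbed

    while (true) {
      if (++steps > max_steps) { status = 3; break; }
      double db; // distance to boundary along current direction
      int to;    // layer index crossed into (-1 above, nl below)
      if (uz > 0.0) { db = (z1[c] - z) / uz; to = c + 1; }
      else if (uz < 0.0) { db = (z0[c] - z) / uz; to = c - 1; }
      else { db = 1e30; to = c; }
      if (db < 0.0) db = 0.0;
      double s_scat = (mus[c] > 0.0) ? tau / mus[c] : 1e30;

      if (s_scat < db) {
        // interior scattering event
        x += ux * s_scat; y += uy * s_scat; z += uz * s_scat;
        if (c == sw) Ls += s_scat; else a_other += mua[c] * s_scat;
        ++n_scat;

        // --- local detector estimator -------------------------------
        // one polar cone sample with an antithetic azimuth pair; the layer
        // traversal (scattering depth, Fresnel product, lateral offset)
        // depends only on the polar angle and is shared by the pair.
        double tau_vert = mus[c] * (z1[c] - z) + mus_below[c];
        if (tau_vert < 30.0) {
          double uc0 = rng.unif();
          double phv = 2.0 * M_PI * rng.unif();
          double cpv = std::cos(phv), spv = std::sin(phv);
          do { // single-pass block so early exits can use `continue`
            double cz = cone_cmin[c] + (1.0 - cone_cmin[c]) * uc0;
            double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
            double nsin = n[c] * sz; // Snell invariant
            double taus = 0.0, a_path = 0.0, Ls_path = 0.0, lat = 0.0;
            double T = 1.0;
            double vert = z1[c] - z;
            double segl = (cz > 1e-9) ? vert / cz : 1e30;
            taus += mus[c] * segl; lat += (sz / cz) * vert;
            if (c == sw) Ls_path += segl; else a_path += mua[c] * segl;
            double n_prev = n[c], c_prev = cz;
            bool dead = false;
            for (int l2 = c + 1; l2 < nl; ++l2) {
              double s2 = nsin / n[l2];
              if (s2 >= 1.0) { dead = true; break; }
              double c2 = std::sqrt(1.0 - s2 * s2);
              T *= 1.0 - fresnel(n_prev, n[l2], c_prev);
              double d2 = z1[l2] - z0[l2];
              double seg2 = d2 / c2;
              taus += mus[l2] * seg2; lat += (s2 / c2) * d2;
              if (l2 == sw) Ls_path += seg2; else a_path += mua[l2] * seg2;
              n_prev = n[l2]; c_prev = c2;
            }
            if (dead || taus >= 30.0) continue;
            T *= 1.0 - fresnel(n_prev, n_below, c_prev);
            double uperp = ux * cpv + uy * spv; // in-plane projection
            double coeff = 0.0;
            for (int iaz = 0; iaz < 2; ++iaz) {
              double sgn = (iaz == 0) ? 1.0 : -1.0; // antithetic azimuth
              double xe = x + sgn * cpv * lat, ye = y + sgn * spv * lat;
              if (xe * xe + ye * ye > det_radius * det_radius) continue;
              double mu_sc = sgn * uperp * sz + uz * cz;
              coeff += hg_pdf(g[c], mu_sc);
            }
            if (coeff == 0.0) continue;
            double base = 0.5 * w0 * boost * coeff * T * cone_omega[c] *
                          std::exp(-taus - a_other - a_path);
            double Ltot = Ls + Ls_path;
            if (grid_uniform && K > 1) {
              double e = std::exp(-grid[0] * Ltot);
              double r = std::exp(-dgrid * Ltot);
              for (int k = 0; k < K; ++k) { Dk[k] += base * e; e *= r; }
            } else {
              for (int k = 0; k < K; ++k)
                Dk[k] += base * std::exp(-grid[k] * Ltot);
            }
          } while (false);
        }
        // ------------------------------------------------------------

        tau = -std::log(rng.unif());
        double ct = hg_cosine(g[c], rng.unif());
        double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        double ph = 2.0 * M_PI * rng.unif();
        double cp = std::cos(ph), sp = std::sin(ph);
        if (std::fabs(uz) > 0.99999) {
          ux = st * cp; uy = st * sp; uz = (uz >= 0.0 ? ct : -ct);
        } else {
          double den = std::sqrt(1.0 - uz * uz);
          double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
          double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
          double nz = -st * cp * den + uz * ct;
          ux = nx; uy = ny; uz = nz;
        }
        // roulette on the running weight at the stack's own absorption
        double a_ref = a_other + mua[sw] * Ls;
        if (std::log(w0 * boost) - a_ref < log_thr) {
          for (int k = 0; k < K; ++k)
            wcur[k] = w0 * boost * std::exp(-a_other - grid[k] * Ls);
          if (rng.unif() < roulette_survival) {
            for (int k = 0; k < K; ++k) {
              ab_sum[k] += wprev[k] - wcur[k];
              wcur[k] /= roulette_survival;
              wprev[k] = wcur[k];
            }
            boost /= roulette_survival;
          } else {
            for (int k = 0; k < K; ++k) ab_sum[k] += wprev[k]; // rest absorbed
            status = 3;
            break;
          }
        }
      } else {
        // propagate to the boundary
        x += ux * db; y += uy * db; z += uz * db;
        if (c == sw) Ls += db; else a_other += mua[c] * db;
        tau -= db * mus[c];
        if (tau < 0.0) tau = 0.0;
        double nt = (to < 0) ? n_above : (to >= nl ? n_below : n[to]);
        double ci = std::fabs(uz);
        double R = fresnel(n[c], nt, ci);
        if (rng.unif() < R) {
          uz = -uz; // internal reflection, stay in layer
        } else {
          // refract
          double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
          double stf = si * n[c] / nt;
          double ctf = std::sqrt(std::max(0.0, 1.0 - stf * stf));
          double scale = (si > 1e-12) ? (n[c] / nt) : 0.0;
          ux *= scale; uy *= scale;
          uz = (uz >= 0.0 ? ctf : -ctf);
          if (to < 0 || to >= nl) {
            // escaped into ambient
            for (int k = 0; k < K; ++k)
              wcur[k] = w0 * boost * std::exp(-a_other - grid[k] * Ls);
            if (to < 0) status = 0;
            else {
              double rr = std::sqrt(x * x + y * y);
              double sin_exit = std::sqrt(std::max(0.0, 1.0 - uz * uz));
              status = (n_scat == 0 && rr <= det_radius &&
                        sin_exit <= det_na + 1e-12) ? 2 : 1;
            }
            break;
          }
          c = to;
        }
      }
    }

    if (status == 3) {
      if (steps > max_steps) { // guard: deposit all remaining weight
        for (int k = 0; k < K; ++k) ab_sum[k] += wprev[k];
      }
      // roulette death already tallied above
    } else {
      for (int k = 0; k < K; ++k) {
        ab_sum[k] += wprev[k] - wcur[k]; // absorption along the path
        if (status == 0) rf_sum[k] += wcur[k];
        else {
          tr_sum[k] += wcur[k];
          if (status == 2) Dk[k] += wcur[k]; // unscattered analog detection
        }
      }
    }
    for (int k = 0; k < K; ++k) {
      det_sum[k] += Dk[k]; det_sq[k] += Dk[k] * Dk[k];
    }
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  const double nd = static_cast<double>(nph);
  NumericVector det(K), det_se(K), tr(K), rf(K), ab(K);
  for (int k = 0; k < K; ++k) {
    double m = det_sum[k] / nd;
    det[k] = m;
    double var = det_sq[k] / nd - m * m;
    if (var < 0.0) var = 0.0;
    det_se[k] = std::sqrt(var / nd);
    tr[k] = tr_sum[k] / nd;
    rf[k] = rf_sum[k] / nd + r_sp;
    ab[k] = ab_sum[k] / nd;
  }
  return List::create(_["detected"] = det, _["detected_se"] = det_se,
                      _["transmitted"] = tr, _["reflected"] = rf,
                      _["absorbed"] = ab, _["specular"] = r_sp,
                      _["mua_grid"] = NumericVector(grid.begin(), grid.end()),
                      _["n_photons"] = nd);
}
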
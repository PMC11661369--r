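#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic, R-RNG-independent generator: xoroshiro128+ seeded via splitmix64.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoro {
  uint64_t s0, s1;
  explicit Xoro(uint64_t seed) {
    uint64_t x = seed;
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  inline uint64_t next() {
    uint64_t a = s0, b = s1, r = a + b;
    b ^= a;
    s0 = rotl(a, 24) ^ b ^ (b << 16);
    s1 = rotl(b, 37);
    return r;
  }
  inline double unif() { return (next() >> 11) * 1.1102230246251565e-16; } // [0,1)
  inline double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
};

// Unpolarized Fresnel reflectance, photon inside medium of index n_rel hitting
// the planar boundary to index 1.0 with incidence cosine cosi (> 0).
static inline double fresnel_R(double n_rel, double cosi) {
  if (n_rel == 1.0) return 0.0;
  if (cosi > 1.0) cosi = 1.0;
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n_rel * sini;
  if (sint >= 1.0) return 1.0; // total internal reflection
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n_rel * cosi - cost) / (n_rel * cosi + cost);
  double rp = (cosi - n_rel * cost) / (cosi + n_rel * cost);
  return 0.5 * (rs * rs + rp * rp);
}

// White Monte Carlo in a semi-infinite half-space z > 0, pencil beam at the
// origin along +z.  No absorption during transport; per-photon exit radius,
// accumulated pathlength and residual weight are recorded.
// [[Rcpp::export]]
List wmc_simulate_cpp(double n_rel, double g, double mus, double n_photons_d,
                      double seed_d, double max_path, bool record_first,
                      double iso_after) {
  const long n_photons = (long)n_photons_d;
  Xoro rng((uint64_t)seed_d ^ 0xD1B54A32D192ED03ULL);
  const double rsp = (n_rel > 1.0) ? std::pow((n_rel - 1.0) / (n_rel + 1.0), 2.0) : 0.0;
  const double w0 = 1.0 - rsp; // specular loss applied by weight deduction at launch
  const double mus_iso = mus * (1.0 - g); // reduced rate for the isotropic tail

  std::vector<double> out_r, out_L, first_z;
  out_r.reserve((size_t)(n_photons * 0.6) + 16);
  out_L.reserve((size_t)(n_photons * 0.6) + 16);
  if (record_first) first_z.reserve((size_t)n_photons);

  for (long p = 0; p < n_photons; ++p) {
    double x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1.0, path = 0.0;
    bool alive = true, first = true;
    long n_scat = 0;
    while (alive) {
      // after iso_after Henyey-Greenstein scatters the direction is fully
      // decorrelated; continue the walk isotropically at the reduced rate
      // (same diffusion constant and pathlength statistics, fewer steps)
      const bool iso = (n_scat >= iso_after) && g != 0.0;
      double s = -std::log(rng.unif_pos()) / (iso ? mus_iso : mus);
      // propagate, possibly interacting with the boundary multiple times
      while (s > 0) {
        if (uz < 0.0) {
          double dist_b = -z / uz;
          if (dist_b <= s) {
            x += ux * dist_b; y += uy * dist_b; path += dist_b;
            z = 0.0; s -= dist_b;
            double R = fresnel_R(n_rel, -uz);
            if (rng.unif() < R) {
              uz = -uz; // internally reflected, finish remaining substep
              continue;
            }
            out_r.push_back(std::sqrt(x * x + y * y));
            out_L.push_back(path);
            alive = false;
            break;
          }
        }
        x += ux * s; y += uy * s; z += uz * s; path += s;
        s = 0.0;
      }
      if (!alive) break;
      if (record_first && first) { first_z.push_back(z); first = false; }
      if (path > max_path) break; // terminated (weight discarded)
      // Henyey-Greenstein scattering (isotropic in the decorrelated tail)
      n_scat++;
      double ct;
      if (g == 0.0 || iso) {
        ct = 2.0 * rng.unif() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      }
      if (ct > 1.0) ct = 1.0;
      if (ct < -1.0) ct = -1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double phi = 2.0 * M_PI * rng.unif();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
      }
    }
    if ((p & 0x3FFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector r(out_r.begin(), out_r.end());
  NumericVector L(out_L.begin(), out_L.end());
  NumericVector w(out_r.size(), w0);
  List out = List::create(_["r"] = r, _["L"] = L, _["w"] = w,
                          _["specular"] = rsp);
  if (record_first) out["first_depth"] = NumericVector(first_z.begin(), first_z.end());
  return out;
}

// Bin similarity-rescaled, absorption-weighted detected photons into uniform
// radial bins; the final slot accumulates the overflow (r >= last break).
// [[Rcpp::export]]
NumericVector wmc_bin_cpp(NumericVector r, NumericVector L, NumericVector w,
                          double k, double mua, NumericVector breaks) {
  const int nb = breaks.size();
  NumericVector out(nb); // nb-1 bins + overflow at index nb-1
  const double lo = breaks[0], hi = breaks[nb - 1];
  const double inv_dw = (nb - 1) / (hi - lo);
  const int n = r.size();
  for (int i = 0; i < n; ++i) {
    double rr = r[i] * k;
    double ww = w[i] * std::exp(-mua * L[i] * k);
    int b;
    if (rr >= hi || rr < lo) b = nb - 1;
    else {
      b = (int)((rr - lo) * inv_dw);
      if (b >= nb - 1) b = nb - 2;
    }
    out[b] += ww;
  }
  return out;
}

static inline double bilin(const NumericMatrix &M, double a, double b) {
  int nm = M.nrow(), ns = M.ncol();
  if (a < 0) a = 0; if (a > nm - 1) a = nm - 1;
  if (b < 0) b = 0; if (b > ns - 1) b = ns - 1;
  int i = (int)a; if (i > nm - 2) i = nm - 2;
  int j = (int)b; if (j > ns - 2) j = ns - 2;
  double fa = a - i, fb = b - j;
  return M(i, j) * (1 - fa) * (1 - fb) + M(i + 1, j) * fa * (1 - fb) +
         M(i, j + 1) * (1 - fa) * fb + M(i + 1, j + 1) * fa * fb;
}

// Two-frequency LUT inversion.  Within a grid cell both reflectance surfaces
// are bilinear, so Rd0 = t0, Rd1 = t1 reduces to a quadratic in one local
// coordinate: every cell is solved exactly and the root closest to the best
// coarse node wins.  When no cell contains an exact crossing (observation
// outside the attainable set) a shrinking local search supplies the
// least-squares projection, whose residual then drives the validity mask.
// [[Rcpp::export]]
List lut_invert_cpp(NumericVector rd0, NumericVector rd1,
                    NumericVector mua, NumericVector musp,
                    NumericMatrix RD0, NumericMatrix RD1) {
  const int n = rd0.size();
  const int nm = mua.size(), ns = musp.size();
  NumericVector mua_hat(n), musp_hat(n), resid(n);
  for (int q = 0; q < n; ++q) {
    double t0 = rd0[q], t1 = rd1[q];
    double best = R_PosInf;
    int bi = 0, bj = 0;
    for (int i = 0; i < nm; ++i) {
      for (int j = 0; j < ns; ++j) {
        double d0 = RD0(i, j) - t0, d1 = RD1(i, j) - t1;
        double d = d0 * d0 + d1 * d1;
        if (d < best) { best = d; bi = i; bj = j; }
      }
    }
    // exact per-cell solve
    double sol_a = NA_REAL, sol_b = NA_REAL, sol_dist = R_PosInf;
    const double eps = 1e-9;
    for (int i = 0; i < nm - 1; ++i) {
      for (int j = 0; j < ns - 1; ++j) {
        double a0 = RD0(i, j), b0 = RD0(i + 1, j) - a0,
               c0 = RD0(i, j + 1) - a0,
               d0 = RD0(i + 1, j + 1) - RD0(i + 1, j) - RD0(i, j + 1) + a0;
        double a1 = RD1(i, j), b1 = RD1(i + 1, j) - a1,
               c1 = RD1(i, j + 1) - a1,
               d1 = RD1(i + 1, j + 1) - RD1(i + 1, j) - RD1(i, j + 1) + a1;
        double A = c1 * d0 - c0 * d1;
        double B = c1 * b0 + (a1 - t1) * d0 + (t0 - a0) * d1 - c0 * b1;
        double C = (a1 - t1) * b0 + (t0 - a0) * b1;
        double roots[2]; int nr = 0;
        if (std::fabs(A) < 1e-14) {
          if (std::fabs(B) > 1e-14) roots[nr++] = -C / B;
        } else {
          double disc = B * B - 4 * A * C;
          if (disc >= 0) {
            double sq = std::sqrt(disc);
            roots[nr++] = (-B + sq) / (2 * A);
            roots[nr++] = (-B - sq) / (2 * A);
          }
        }
        for (int r = 0; r < nr; ++r) {
          double fb = roots[r];
          if (fb < -eps || fb > 1 + eps) continue;
          double den = b0 + d0 * fb;
          double fa;
          if (std::fabs(den) > 1e-14) fa = (t0 - a0 - c0 * fb) / den;
          else {
            double den1 = b1 + d1 * fb;
            if (std::fabs(den1) < 1e-14) continue;
            fa = (t1 - a1 - c1 * fb) / den1;
          }
          if (fa < -eps || fa > 1 + eps) continue;
          if (fa < 0) fa = 0; if (fa > 1) fa = 1;
          if (fb < 0) fb = 0; if (fb > 1) fb = 1;
          double da = i + fa - bi, db = j + fb - bj;
          double dist = da * da + db * db;
          if (dist < sol_dist) { sol_dist = dist; sol_a = i + fa; sol_b = j + fb; }
        }
      }
    }
    double a, b;
    if (R_finite(sol_dist)) {
      a = sol_a; b = sol_b;
      double e0 = bilin(RD0, a, b) - t0, e1 = bilin(RD1, a, b) - t1;
      best = e0 * e0 + e1 * e1;
    } else {
      a = bi; b = bj;
      double win = 1.0;
      for (int it = 0; it < 6; ++it) {
        double ba = a, bb = b;
        for (int ii = 0; ii <= 8; ++ii) {
          for (int jj = 0; jj <= 8; ++jj) {
            double ca = a + win * (ii - 4) / 4.0;
            double cb = b + win * (jj - 4) / 4.0;
            if (ca < 0) ca = 0;
            if (ca > nm - 1) ca = nm - 1;
            if (cb < 0) cb = 0;
            if (cb > ns - 1) cb = ns - 1;
            double d0 = bilin(RD0, ca, cb) - t0;
            double d1 = bilin(RD1, ca, cb) - t1;
            double d = d0 * d0 + d1 * d1;
            if (d < best) { best = d; ba = ca; bb = cb; }
          }
        }
        a = ba; b = bb; win *= 0.4;
      }
    }
    // map continuous index back to parameter values (piecewise linear)
    int i = (int)a; if (i > nm - 2) i = nm - 2;
    int j = (int)b; if (j > ns - 2) j = ns - 2;
    mua_hat[q] = mua[i] + (a - i) * (mua[i + 1] - mua[i]);
    musp_hat[q] = musp[j] + (b - j) * (musp[j + 1] - musp[j]);
    resid[q] = std::sqrt(best);
  }
  return List::create(_["mua"] = mua_hat, _["musp"] = musp_hat, _["resid"] = resid);
}
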
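// Weighted-packet voxel Monte Carlo photon transport.
//
// Scheme: scattering interactions are sampled from mu_s; absorption is
// deposited continuously along each traversed segment as W*(1 - exp(-mu_a*l))
// so the packet weight decays smoothly (MCX-style hybrid). With mu_s = 0 the
// packet flies straight and the scored fluence reduces exactly to
// Beer-Lambert attenuation, which the test suite exploits.
//
// Geometry is handled in voxel units (pitch = 1); optical coefficients are
// pre-multiplied by the voxel pitch in cm so path lengths are dimensionless.
//
// RNG: one xoshiro256+ stream per packet, seeded by splitmix64 from
// (seed, packet index), so results are reproducible regardless of execution
// order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s0, s1, s2, s3;
  void seed(uint64_t key) {
    uint64_t x = key;
    s0 = splitmix64(x); s1 = splitmix64(x);
    s2 = splitmix64(x); s3 = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = s0 + s3;
    uint64_t t = s1 << 17;
    s2 ^= s0; s3 ^= s1; s1 ^= s2; s0 ^= s3; s2 ^= t;
    s3 = rotl(s3, 45);
    return r;
  }
  // uniform in the open interval (0,1): never 0, safe for log()
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// unpolarized Fresnel reflectance; total internal reflection -> 1
inline double fresnel(double n1, double n2, double cos_i) {
  if (n1 == n2) return 0.0;
  double ratio = n1 / n2;
  double sin_t2 = ratio * ratio * (1.0 - cos_i * cos_i);
  if (sin_t2 >= 1.0) return 1.0;
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein inverse-CDF sample of cos(theta)
inline double hg_cosine(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - t * t) / (2.0 * g);
}

inline void rotate_direction(double &ux, double &uy, double &uz,
                             double cos_t, double phi) {
  double sin_t = std::sqrt(std::max(0.0, 1.0 - cos_t * cos_t));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sin_t * cp;
    uy = sin_t * sp;
    uz = cos_t * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nux = sin_t * (ux * uz * cp - uy * sp) / den + ux * cos_t;
    double nuy = sin_t * (uy * uz * cp + ux * sp) / den + uy * cos_t;
    double nuz = -sin_t * cp * den + uz * cos_t;
    ux = nux; uy = nuy; uz = nuz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

} // namespace

// [[Rcpp::export]]
List mc_transport_cpp(IntegerVector tissue, IntegerVector dims,
                      NumericMatrix props, double pitch_cm,
                      int field_is_disc,
                      double fx0, double fx1, double fy0, double fy1,
                      double disc_cx, double disc_cy, double disc_r,
                      double n_photons, int seed, int internal_fresnel,
                      double roulette_threshold, double roulette_survival) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> dep((size_t)nvox, 0.0);

  const int nlab = props.nrow();
  std::vector<double> mua(nlab), mus(nlab), nref(nlab), gani(nlab);
  for (int l = 0; l < nlab; ++l) {
    mua[l] = props(l, 0) * pitch_cm;  // per voxel-edge length
    mus[l] = props(l, 1) * pitch_cm;
    nref[l] = props(l, 2);
    gani[l] = props(l, 3);
  }

  double absorbed = 0.0, reflected = 0.0, transmitted = 0.0;
  const int64_t npk = (int64_t)n_photons;
  const int64_t max_steps = 50000000LL;  // defensive guard, never hit in practice
  Xoshiro rng;

  for (int64_t p = 0; p < npk; ++p) {
    rng.seed(((uint64_t)(uint32_t)seed << 32) ^ (uint64_t)p);

    // launch uniformly over the beam field on the z=0 face, direction +z
    double x, y;
    if (field_is_disc) {
      double r = disc_r * std::sqrt(rng.unif());
      double th = 2.0 * M_PI * rng.unif();
      x = disc_cx + r * std::cos(th);
      y = disc_cy + r * std::sin(th);
    } else {
      x = fx0 + rng.unif() * (fx1 - fx0);
      y = fy0 + rng.unif() * (fy1 - fy0);
    }
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0, w = 1.0;
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = 0;
    if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
    if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;

    // specular reflection at entry from ambient n = 1
    {
      int t0 = tissue[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)];
      double nf = nref[t0];
      if (nf != 1.0 && rng.unif() < fresnel(1.0, nf, 1.0)) {
        reflected += w;
        continue;
      }
    }

    double tau = -std::log(rng.unif());  // dimensionless scattering depth
    int64_t steps = 0;
    for (;;) {
      if (++steps > max_steps) { absorbed += w; break; }
      R_xlen_t idx = (R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
      int t = tissue[idx];
      double ma = mua[t], ms = mus[t];

      // distance to next voxel face
      double tx = (ux > 0) ? ((ix + 1) - x) / ux : (ux < 0 ? (ix - x) / ux : INF);
      double ty = (uy > 0) ? ((iy + 1) - y) / uy : (uy < 0 ? (iy - y) / uy : INF);
      double tz = (uz > 0) ? ((iz + 1) - z) / uz : (uz < 0 ? (iz - z) / uz : INF);
      int axis = 0; double dface = tx;
      if (ty < dface) { dface = ty; axis = 1; }
      if (tz < dface) { dface = tz; axis = 2; }
      if (dface < 0) dface = 0;

      double dint = (ms > 0) ? tau / ms : INF;

      if (dint < dface) {
        // scattering interaction inside this voxel
        if (ma > 0) {
          double da = w * (1.0 - std::exp(-ma * dint));
          dep[idx] += da; absorbed += da; w -= da;
        }
        x += ux * dint; y += uy * dint; z += uz * dint;
        double ct = hg_cosine(gani[t], rng.unif());
        rotate_direction(ux, uy, uz, ct, 2.0 * M_PI * rng.unif());
        tau = -std::log(rng.unif());
      } else {
        // traverse to the voxel face
        if (ma > 0) {
          double da = w * (1.0 - std::exp(-ma * dface));
          dep[idx] += da; absorbed += da; w -= da;
        }
        if (ms > 0) tau -= ms * dface;
        x += ux * dface; y += uy * dface; z += uz * dface;
        int step = 0;
        if (axis == 0) { step = ux > 0 ? 1 : -1; x = ix + (step > 0 ? 1.0 : 0.0); }
        else if (axis == 1) { step = uy > 0 ? 1 : -1; y = iy + (step > 0 ? 1.0 : 0.0); }
        else { step = uz > 0 ? 1 : -1; z = iz + (step > 0 ? 1.0 : 0.0); }

        int jx = ix, jy = iy, jz = iz;
        if (axis == 0) jx += step; else if (axis == 1) jy += step; else jz += step;

        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) {
          // escape through the grid boundary; the entry (z=0) face counts
          // as diffuse reflectance, everything else as transmittance
          if (axis == 2 && step < 0) reflected += w; else transmitted += w;
          break;
        }
        if (internal_fresnel) {
          R_xlen_t jdx = (R_xlen_t)jx + nx * ((R_xlen_t)jy + (R_xlen_t)ny * jz);
          double n1 = nref[t], n2 = nref[tissue[jdx]];
          if (n1 != n2) {
            double cos_i = (axis == 0) ? std::fabs(ux)
                          : (axis == 1) ? std::fabs(uy) : std::fabs(uz);
            if (rng.unif() < fresnel(n1, n2, cos_i)) {
              // reflect: flip the normal component, stay in the current voxel
              if (axis == 0) ux = -ux; else if (axis == 1) uy = -uy; else uz = -uz;
              continue;
            } else {
              // refract (Snell): scale tangential components
              double ratio = n1 / n2;
              double sin_t2 = ratio * ratio * (1.0 - cos_i * cos_i);
              double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t2));
              if (axis == 0) { uy *= ratio; uz *= ratio; ux = (step > 0 ? 1.0 : -1.0) * cos_t; }
              else if (axis == 1) { ux *= ratio; uz *= ratio; uy = (step > 0 ? 1.0 : -1.0) * cos_t; }
              else { ux *= ratio; uy *= ratio; uz = (step > 0 ? 1.0 : -1.0) * cos_t; }
              double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
              ux /= norm; uy /= norm; uz /= norm;
            }
          }
        }
        ix = jx; iy = jy; iz = jz;
      }

      // Russian roulette; the net created/destroyed weight is folded into
      // the absorbed ledger entry so the run conserves weight exactly
      if (w < roulette_threshold) {
        if (rng.unif() < roulette_survival) {
          double wnew = w / roulette_survival;
          absorbed -= (wnew - w);
          w = wnew;
        } else {
          absorbed += w;
          break;
        }
      }
    }
  }

  NumericVector deposit(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) deposit[i] = dep[(size_t)i];
  return List::create(_["deposit"] = deposit,
                      _["absorbed"] = absorbed / (double)npk,
                      _["reflected"] = reflected / (double)npk,
                      _["transmitted"] = transmitted / (double)npk,
                      _["launched"] = 1.0);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared, voxel units) to the nearest
// TRUE ("feature") voxel; separable lower-envelope algorithm.

namespace {

// BIG stands in for "no feature on this line"; large enough to dominate any
// true squared distance, small enough that the envelope arithmetic stays finite
const double BIG = 1e20;

void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
          std::vector<int> &v, std::vector<double> &zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -INF; zbuf[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = (f[q] + (double)q * q - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= zbuf[k]) {
      --k;
      s = (f[q] + (double)q * q - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; zbuf[k] = s; zbuf[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[j + 1] < q) ++j;
    double dq = (double)q - (double)v[j];
    d[q] = dq * dq + f[v[j]];
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> d((size_t)nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) d[(size_t)i] = feature[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      R_xlen_t base = nx * ((R_xlen_t)ky + (R_xlen_t)ny * kz);
      for (int q = 0; q < nx; ++q) f[q] = d[(size_t)(base + q)];
      dt1d(f, out, nx, v, zbuf);
      for (int q = 0; q < nx; ++q) d[(size_t)(base + q)] = out[q];
    }
  // pass along y
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)kx + (R_xlen_t)nx * ny * (R_xlen_t)kz;
      for (int q = 0; q < ny; ++q) f[q] = d[(size_t)(base + (R_xlen_t)q * nx)];
      dt1d(f, out, ny, v, zbuf);
      for (int q = 0; q < ny; ++q) d[(size_t)(base + (R_xlen_t)q * nx)] = out[q];
    }
  // pass along z
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)kx + (R_xlen_t)nx * ky;
      for (int q = 0; q < nz; ++q) f[q] = d[(size_t)(base + (R_xlen_t)q * plane)];
      dt1d(f, out, nz, v, zbuf);
      for (int q = 0; q < nz; ++q) d[(size_t)(base + (R_xlen_t)q * plane)] = out[q];
    }

  NumericVector res(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) res[i] = d[(size_t)i];
  return res;
}
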
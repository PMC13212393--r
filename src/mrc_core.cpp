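#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: fast, high-quality, and fully
// deterministic across platforms for a given integer seed.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {                 // uniform in (0, 1)
    return ((next() >> 11) + 0.5) * 1.1102230246251565e-16; // 2^-53
  }
  // Marsaglia polar method with one cached deviate
  bool has_spare = false;
  double spare = 0.0;
  inline double rnorm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

// Two-compartment exchange propagation over a piecewise-constant waveform.
// qbar2: step-averaged q^2 for the unit-amplitude waveform; scale2: per-b
// (gamma * g_b)^2 factors. The per-step 2x2 matrix exponential is evaluated
// in closed form, exact for a piecewise-constant generator.
// [[Rcpp::export]]
NumericVector exchange_propagate(NumericVector qbar2, double dt,
                                 NumericVector scale2, double D1, double D2,
                                 double kin, double kex, double v_in) {
  const int nb = scale2.size();
  const int nt = qbar2.size();
  NumericVector S(nb);
  for (int j = 0; j < nb; ++j) {
    double M1 = v_in, M2 = 1.0 - v_in;
    const double s2 = scale2[j];
    for (int i = 0; i < nt; ++i) {
      const double q2 = s2 * qbar2[i];
      const double a11 = -q2 * D1 - kin;
      const double a22 = -q2 * D2 - kex;
      const double m = 0.5 * (a11 + a22);
      const double half_diff = 0.5 * (a11 - a22);
      const double disc = half_diff * half_diff + kex * kin;
      const double s = disc > 0 ? std::sqrt(disc) : 0.0;
      const double h = s * dt;
      // both eigenvalues m +- s are <= 0, so E1, E2 <= 1: overflow-safe
      double ech, etshc; // e^{m dt} cosh(h), e^{m dt} dt sinh(h)/h
      if (h < 1e-6) {
        const double em = std::exp(m * dt);
        ech = em * (1.0 + 0.5 * h * h);
        etshc = em * dt * (1.0 + h * h / 6.0);
      } else {
        const double E1 = std::exp((m + s) * dt);
        const double E2 = std::exp((m - s) * dt);
        ech = 0.5 * (E1 + E2);
        etshc = 0.5 * (E1 - E2) / s;
      }
      const double b11 = ech + etshc * half_diff;
      const double b22 = ech - etshc * half_diff;
      const double b12 = etshc * kex;
      const double b21 = etshc * kin;
      const double n1 = b11 * M1 + b12 * M2;
      const double n2 = b21 * M1 + b22 * M2;
      M1 = n1; M2 = n2;
    }
    S[j] = M1 + M2;
  }
  return S;
}

// Random-walk Monte-Carlo diffusion in sphere geometries under a sampled
// effective gradient waveform (unit amplitude). Returns the per-walker
// accumulated unit phase integral sum(g_t * x_t * dt) plus the intracellular
// occupancy fraction at requested times. Geometry modes:
//   0 free diffusion (no barriers, diffusivity D_in)
//   1 single sphere of radius R, walkers start inside; membrane
//     permeability P (um/ms), 0 = impermeable
//   2 periodic packing: sphere of radius R centred in a cubic cell of side
//     `box`; walkers start uniformly, both compartments populated
// Membrane transits use the hybrid-reflection rule
// p = P * sqrt(pi * dt / D_from), clipped to [0, 1]; otherwise reflection
// is elastic (radial mirror about the surface).
// [[Rcpp::export]]
List mc_walk(NumericVector g, double dt, int mode, double R, double box,
             double D_in, double D_ex, double P, int n_walkers, int seed,
             NumericVector record_steps) {
  const int nt = g.size();
  const int nrec = record_steps.size();
  NumericVector phase(n_walkers);
  NumericVector inside_frac(nrec);
  IntegerVector rec_idx(nrec);
  for (int r = 0; r < nrec; ++r) rec_idx[r] = (int)record_steps[r];

  Xoshiro rng(static_cast<uint64_t>(seed));
  const double* gp = REAL(g);

  const double sig_in = std::sqrt(2.0 * D_in * dt);
  const double sig_ex = std::sqrt(2.0 * D_ex * dt);
  const double p_in = std::min(1.0, P * std::sqrt(M_PI * dt / D_in));
  const double p_ex = D_ex > 0 ? std::min(1.0, P * std::sqrt(M_PI * dt / D_ex))
                               : 0.0;
  const double R2 = R * R;

  for (int wkr = 0; wkr < n_walkers; ++wkr) {
    double x = 0, y = 0, z = 0;      // geometry coordinates (wrapped)
    double xt = 0;                   // true x displacement for the phase
    bool inside = true;
    if (mode == 1) {
      do {
        x = R * (2 * rng.runif() - 1);
        y = R * (2 * rng.runif() - 1);
        z = R * (2 * rng.runif() - 1);
      } while (x * x + y * y + z * z > R2);
    } else if (mode == 2) {
      x = box * (rng.runif() - 0.5);
      y = box * (rng.runif() - 0.5);
      z = box * (rng.runif() - 0.5);
      inside = (x * x + y * y + z * z <= R2);
    }
    xt = x;
    double phi = 0.0;
    int ri = 0;
    for (int i = 0; i < nt; ++i) {
      const double sig = (mode == 0 || inside) ? sig_in : sig_ex;
      double dx = sig * rng.rnorm();
      double dy = sig * rng.rnorm();
      double dz = sig * rng.rnorm();
      if (mode == 0) {
        x += dx; y += dy; z += dz;
        xt = x;
      } else {
        double nx = x + dx, ny = y + dy, nz = z + dz;
        if (mode == 2) {
          // wrap into the periodic cell
          if (nx > 0.5 * box) nx -= box; else if (nx < -0.5 * box) nx += box;
          if (ny > 0.5 * box) ny -= box; else if (ny < -0.5 * box) ny += box;
          if (nz > 0.5 * box) nz -= box; else if (nz < -0.5 * box) nz += box;
        }
        const double r2 = nx * nx + ny * ny + nz * nz;
        const bool now_inside = (r2 <= R2);
        if (now_inside != inside) {
          const double p_cross = inside ? p_in : p_ex;
          if (rng.runif() < p_cross) {
            inside = now_inside;       // transmit
          } else {
            // elastic reflection: mirror the radius about the surface
            const double r = std::sqrt(r2);
            double rref = 2.0 * R - r;
            if (rref < 1e-9) rref = 1e-9;
            const double f = rref / r;
            nx *= f; ny *= f; nz *= f;
          }
        }
        // physical x displacement actually taken (undo any wrap jump)
        double dxp = nx - x;
        if (mode == 2) {
          if (dxp > 0.5 * box) dxp -= box;
          else if (dxp < -0.5 * box) dxp += box;
        }
        x = nx; y = ny; z = nz;
        xt += dxp;
      }
      phi += gp[i] * xt * dt;
      if (ri < nrec && (i + 1) == rec_idx[ri]) {
        if (mode == 0 || inside) inside_frac[ri] += 1.0;
        ++ri;
      }
    }
    phase[wkr] = phi;
  }
  for (int r = 0; r < nrec; ++r) inside_frac[r] /= n_walkers;
  return List::create(_["phase"] = phase, _["inside_frac"] = inside_frac);
}
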
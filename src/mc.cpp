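#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Self-contained counter-independent RNG (xoshiro256++) so Monte Carlo runs are
// reproducible from an integer seed without touching R's RNG state.
namespace {

inline std::uint64_t splitmix64(std::uint64_t &x) {
  std::uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  std::uint64_t s[4];
  explicit Xoshiro(std::uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline std::uint64_t next() {
    std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]; never 0 so -log(u) is finite
  inline double unif_pos() {
    double u = (next() >> 11) * 0x1.0p-53;
    return u > 0.0 ? u : 0x1.0p-53;
  }
  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Unpolarized Fresnel reflectance for internal incidence, cosine ci >= 0.
inline double fresnel(double ni, double nt, double ci) {
  if (ni == nt) return 0.0;
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(1.0 - ci * ci);
  double st = ni / nt * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".mc_simulate_cpp")]]
List mc_simulate_cpp(double mua, double mus, double g,
                     double n_rel, double n_out,
                     int n_photons, double dr, double dz, int nr, int nz,
                     double seed, double w_threshold, double roulette_p,
                     double max_steps) {
  Xoshiro rng(static_cast<std::uint64_t>(seed));

  NumericMatrix absorbed(nr, nz);   // absorbed weight per (r, z) bin
  NumericVector rd(nr);             // escaped weight per radial exit bin
  double specular = 0.0, diffuse = 0.0, diffuse_beyond = 0.0;
  double absorbed_in = 0.0, absorbed_out = 0.0;
  double roulette_net = 0.0, lost = 0.0;

  const double mut = mua + mus;
  const double rsp = fresnel(n_out, n_rel, 1.0);  // normal-incidence specular
  const double r_max = nr * dr, z_max = nz * dz;

  for (int ph = 0; ph < n_photons; ++ph) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    specular += rsp;
    bool alive = true;
    double steps = 0.0;

    while (alive) {
      if (++steps > max_steps) { lost += w; break; }
      double s = -std::log(rng.unif_pos()) / mut;

      // hop, handling the top boundary (possibly repeatedly under reflection)
      while (uz < 0.0 && z + s * uz < 0.0) {
        double s1 = -z / uz;
        x += s1 * ux; y += s1 * uy; z = 0.0;
        s -= s1;
        double R = fresnel(n_rel, n_out, -uz);
        if (rng.unif() < R) {
          uz = -uz;  // internal reflection, finish remaining step downward
        } else {
          double r = std::sqrt(x * x + y * y);
          int ir = static_cast<int>(r / dr);
          if (r < r_max) rd[ir] += w; else diffuse_beyond += w;
          diffuse += w;
          alive = false;
          break;
        }
      }
      if (!alive) break;
      x += s * ux; y += s * uy; z += s * uz;

      // drop
      if (mua > 0.0) {
        double dw = w * mua / mut;
        w -= dw;
        double r = std::sqrt(x * x + y * y);
        if (r < r_max && z < z_max) {
          int ir = static_cast<int>(r / dr);
          int iz = static_cast<int>(z / dz);
          absorbed(ir, iz) += dw;
          absorbed_in += dw;
        } else {
          absorbed_out += dw;
        }
      }

      // roulette
      if (w < w_threshold) {
        if (rng.unif() < roulette_p) {
          roulette_net -= w * (1.0 / roulette_p - 1.0);
          w /= roulette_p;
        } else {
          roulette_net += w;
          break;
        }
      }

      // spin: Henyey-Greenstein deflection, uniform azimuth
      double cost;
      if (g == 0.0) {
        cost = 2.0 * rng.unif() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
        cost = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (cost > 1.0) cost = 1.0; else if (cost < -1.0) cost = -1.0;
      }
      double sint = std::sqrt(1.0 - cost * cost);
      double phi = 2.0 * M_PI * rng.unif();
      double cosp = std::cos(phi), sinp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = sint * cosp;
        uy = sint * sinp;
        uz = cost * (uz >= 0.0 ? 1.0 : -1.0);
      } else {
        double temp = std::sqrt(1.0 - uz * uz);
        double nux = sint * (ux * uz * cosp - uy * sinp) / temp + ux * cost;
        double nuy = sint * (uy * uz * cosp + ux * sinp) / temp + uy * cost;
        double nuz = -sint * cosp * temp + uz * cost;
        ux = nux; uy = nuy; uz = nuz;
      }
      double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= norm; uy /= norm; uz /= norm;
    }
  }

  double n = static_cast<double>(n_photons);
  return List::create(
    _["absorbed"] = absorbed,
    _["rd_weight"] = rd,
    _["specular"] = specular / n,
    _["diffuse"] = diffuse / n,
    _["diffuse_beyond_grid"] = diffuse_beyond / n,
    _["absorbed_in_grid"] = absorbed_in / n,
    _["absorbed_beyond_grid"] = absorbed_out / n,
    _["roulette_net"] = roulette_net / n,
    _["lost"] = lost / n);
}
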
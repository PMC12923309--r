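// Weighted photon-packet Monte Carlo through a layered slab (hop-drop-spin),
// after the multi-layered tissue MC convention: exponential step sampling,
// partial-weight deposition by the local albedo, Henyey-Greenstein deflection,
// Fresnel/Snell boundary physics with partial steps preserved across
// interfaces, and unbiased Russian roulette below a weight threshold.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

namespace {

// Uniform double in the open interval (0,1): 53-bit mantissa shifted off the
// half-open lattice so log() is always finite.
inline double runif_open(std::mt19937_64 &rng) {
  return (static_cast<double>(rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

struct LayerRec {
  double z0, z1;      // top/bottom depth (mm)
  double mua, mus, g, n;
  double mut;         // mua + mus
};

// Unpolarized Fresnel reflectance for incidence cosine ci in [0,1].
double fresnel(double n1, double n2, double ci, double &ct) {
  if (n1 == n2) { ct = ci; return 0.0; }
  if (ci > 0.99999) {                       // normal incidence
    ct = 1.0;
    double r = (n2 - n1) / (n2 + n1);
    return r * r;
  }
  double si = std::sqrt(1.0 - ci * ci);
  double st = n1 * si / n2;
  if (st >= 1.0) { ct = 0.0; return 1.0; }  // total internal reflection
  ct = std::sqrt(1.0 - st * st);
  double sip = si * ct + ci * st;  // sin(ai+at)
  double sim = si * ct - ci * st;  // sin(ai-at)
  double cip = ci * ct - si * st;  // cos(ai+at)
  double cim = ci * ct + si * st;  // cos(ai-at)
  double rs = sim / sip;
  double rp = (sim * cip) / (sip * cim);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine.
inline double hg_cos(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - t * t) / (2.0 * g);
}

// Rotate a unit direction by polar cosine `cost` and azimuth `phi`.
void spin_dir(double &ux, double &uy, double &uz, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = (uz >= 0.0 ? cost : -cost);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    double ny = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    double nz = -sint * cosp * den + uz * cost;
    ux = nx; uy = ny; uz = nz;
  }
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

} // namespace

// [[Rcpp::export(name = ".mc_kernel")]]
Rcpp::List mc_kernel(Rcpp::NumericMatrix layers,  // cols: thickness, mua, mus, g, n
                     double n_above, double n_below,
                     double dz, double dr, int nz, int nr,
                     double n_photons, double w_threshold, int roulette_m,
                     double seed) {
  const int L = layers.nrow();
  std::vector<LayerRec> lay(L);
  double z = 0.0;
  for (int i = 0; i < L; ++i) {
    lay[i].z0 = z;
    z += layers(i, 0);
    lay[i].z1 = z;
    lay[i].mua = layers(i, 1);
    lay[i].mus = layers(i, 2);
    lay[i].g   = layers(i, 3);
    lay[i].n   = layers(i, 4);
    lay[i].mut = lay[i].mua + lay[i].mus;
  }

  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));

  std::vector<double> A(static_cast<size_t>(nr) * nz, 0.0);
  double Rd = 0.0, Tt = 0.0, Atot = 0.0, overflow_r = 0.0;

  // Specular reflection at entry (non-glass first layer).
  double rsp_r = (n_above - lay[0].n) / (n_above + lay[0].n);
  double Rsp = rsp_r * rsp_r;

  const long long N = static_cast<long long>(n_photons);
  const double CHANCE = 1.0 / static_cast<double>(roulette_m);

  for (long long ip = 0; ip < N; ++ip) {
    double x = 0.0, y = 0.0, pz = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - Rsp;
    int il = 0;
    double s = 0.0;          // residual dimensionless step
    bool alive = true;

    while (alive) {
      const LayerRec &ly = lay[il];
      if (s <= 0.0) s = -std::log(runif_open(rng));

      // distance to the layer boundary along uz
      double db;
      int hit = 0;           // -1 top, +1 bottom, 0 none
      if (uz > 0.0)      { db = (ly.z1 - pz) / uz; hit = 1; }
      else if (uz < 0.0) { db = (ly.z0 - pz) / uz; hit = -1; }
      else               { db = 1e30; }

      double sphys = (ly.mut > 0.0) ? s / ly.mut : 1e30;

      if (db <= sphys) {
        // hop to the boundary, keep the residual step
        x += ux * db; y += uy * db;
        pz = (hit > 0) ? ly.z1 : ly.z0;
        if (ly.mut > 0.0) s -= db * ly.mut;

        double n2 = (hit > 0) ? (il == L - 1 ? n_below : lay[il + 1].n)
                              : (il == 0     ? n_above : lay[il - 1].n);
        double ci = std::fabs(uz), ct;
        double R = fresnel(ly.n, n2, ci, ct);
        if (runif_open(rng) <= R) {
          uz = -uz;          // reflect, stay in layer
        } else {
          // refract
          double ratio = ly.n / n2;
          ux *= ratio; uy *= ratio;
          uz = (uz >= 0.0 ? ct : -ct);
          if (hit > 0 && il == L - 1)      { Tt += w; alive = false; }
          else if (hit < 0 && il == 0)     { Rd += w; alive = false; }
          else il += (hit > 0 ? 1 : -1);
        }
        continue;
      }

      // interior hop
      x += ux * sphys; y += uy * sphys; pz += uz * sphys;
      s = 0.0;

      // drop: deposit the absorbed fraction of the weight
      if (ly.mut > 0.0 && ly.mua > 0.0) {
        double dw = w * ly.mua / ly.mut;
        double r = std::sqrt(x * x + y * y);
        int ir = static_cast<int>(r / dr);
        if (ir >= nr) { ir = nr - 1; overflow_r += dw; }
        int iz = static_cast<int>(pz / dz);
        if (iz >= nz) iz = nz - 1;
        if (iz < 0) iz = 0;
        A[static_cast<size_t>(ir) * nz + iz] += dw;
        Atot += dw;
        w -= dw;
      }
      if (w <= 0.0) { alive = false; continue; }

      // spin
      double cost = hg_cos(ly.g, runif_open(rng));
      double phi = 2.0 * M_PI * runif_open(rng);
      spin_dir(ux, uy, uz, cost, phi);

      // roulette
      if (w < w_threshold) {
        if (runif_open(rng) < CHANCE) w *= static_cast<double>(roulette_m);
        else alive = false;
      }
    }
  }

  // normalize: A_rz per mm^3 per launched photon (annular bin volumes)
  Rcpp::NumericMatrix Am(nr, nz);
  for (int ir = 0; ir < nr; ++ir) {
    double vol = 2.0 * M_PI * (ir + 0.5) * dr * dr * dz;
    for (int iz = 0; iz < nz; ++iz)
      Am(ir, iz) = A[static_cast<size_t>(ir) * nz + iz] / (N * vol);
  }

  return Rcpp::List::create(
      Rcpp::Named("A_rz") = Am,
      Rcpp::Named("R_sp") = Rsp,
      Rcpp::Named("R_d") = Rd / N,
      Rcpp::Named("T_t") = Tt / N,
      Rcpp::Named("A_total") = Atot / N,
      Rcpp::Named("overflow_frac") = overflow_r / N);
}

// [[Rcpp::export(name = ".hg_cos_samples")]]
Rcpp::NumericVector hg_cos_samples(double g, double n, double seed) {
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  long long N = static_cast<long long>(n);
  Rcpp::NumericVector out(N);
  for (long long i = 0; i < N; ++i) out[i] = hg_cos(g, runif_open(rng));
  return out;
}

// [[Rcpp::export(name = ".fresnel_cpp")]]
double fresnel_cpp(double n1, double n2, double cos_i) {
  double ct;
  return fresnel(n1, n2, cos_i, ct);
}
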
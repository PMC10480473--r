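// MCML-style photon transport in a layered slab, scored on an axisymmetric
// (r, z) grid. Hop / drop / spin with photon weights, Fresnel reflection and
// refraction at refractive-index mismatches, Henyey-Greenstein scattering,
// Russian roulette termination. Uses R's RNG so runs are reproducible from
// set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double runif01() {
  // open interval draw; R::unif_rand can touch the endpoints
  double u;
  do {
    u = R::unif_rand();
  } while (u <= 0.0 || u >= 1.0);
  return u;
}

static inline double fresnel_unpol(double n_i, double n_t, double cos_i) {
  if (n_i == n_t) return 0.0;
  if (cos_i > 1.0) cos_i = 1.0;
  double sin_i2 = 1.0 - cos_i * cos_i;
  double sin_t2 = (n_i / n_t) * (n_i / n_t) * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n_i * cos_i - n_t * cos_t) / (n_i * cos_i + n_t * cos_t);
  double rp = (n_i * cos_t - n_t * cos_i) / (n_i * cos_t + n_t * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

static inline double hg_cos(double g) {
  double u = runif01();
  if (g == 0.0) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// rotate (ux, uy, uz) by polar angle acos(ct) and uniform azimuth
static inline void spin(double &ux, double &uy, double &uz, double ct) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * runif01();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// [[Rcpp::export]]
List mc_transport_cpp(NumericVector z_bound, NumericVector mu_a,
                      NumericVector mu_s, NumericVector g_hg,
                      NumericVector n_layer, double n_above, double n_below,
                      double waist, NumericVector r_edges,
                      NumericVector z_edges, int n_photons, int n_batch,
                      double w_threshold, double p_survival) {
  const int L = mu_a.size();
  const int nr = r_edges.size() - 1;
  const int nz = z_edges.size() - 1;
  const double r_max = r_edges[nr];
  const double z_bot = z_bound[L];

  std::vector<double> absorbed(static_cast<size_t>(nr) * nz, 0.0);
  std::vector<double> batch(static_cast<size_t>(nr) * nz * n_batch, 0.0);
  std::vector<double> overflow(L, 0.0);   // absorbed outside the scoring grid
  std::vector<double> batch_total(n_batch, 0.0);
  double specular = 0.0, dref = 0.0, trans = 0.0, roulette_net = 0.0;

  for (int ph = 0; ph < n_photons; ++ph) {
    if ((ph & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    const int b = static_cast<int>(
        (static_cast<long long>(ph) * n_batch) / n_photons);
    double w = 1.0;
    // specular split at the ambient/top-layer interface (normal incidence)
    if (n_above != n_layer[0]) {
      double rsp = (n_above - n_layer[0]) / (n_above + n_layer[0]);
      rsp *= rsp;
      specular += rsp;
      w -= rsp;
    }
    double x = waist * std::sqrt(-std::log(runif01()) / 2.0);
    double y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int l = 0;
    double s = -std::log(runif01());  // dimensionless path length

    bool alive = true;
    while (alive) {
      const double mt = mu_a[l] + mu_s[l];
      double db = R_PosInf;
      if (uz > 0.0)      db = (z_bound[l + 1] - z) / uz;
      else if (uz < 0.0) db = (z_bound[l] - z) / uz;

      bool hit_boundary;
      if (mt <= 0.0) {
        if (!R_FINITE(db)) { trans += w; break; }  // gliding in a void layer
        hit_boundary = true;
      } else {
        hit_boundary = (db * mt <= s);
      }

      if (hit_boundary) {
        x += db * ux; y += db * uy; z += db * uz;
        if (mt > 0.0) s -= db * mt;
        // Fresnel at the interface the photon is crossing
        const bool down = uz > 0.0;
        const double n_i = n_layer[l];
        const double n_t = down ? (l + 1 < L ? n_layer[l + 1] : n_below)
                                : (l > 0 ? n_layer[l - 1] : n_above);
        const double cos_i = std::fabs(uz);
        const double refl = fresnel_unpol(n_i, n_t, cos_i);
        if (refl > 0.0 && runif01() < refl) {
          uz = -uz;  // stay in the layer
        } else {
          if (n_i != n_t) {  // Snell refraction
            double scale = n_i / n_t;
            double sin_t2 = scale * scale * (1.0 - cos_i * cos_i);
            double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t2));
            ux *= scale; uy *= scale;
            uz = (uz >= 0 ? cos_t : -cos_t);
            double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= norm; uy /= norm; uz /= norm;
          }
          if (down) {
            if (l + 1 >= L) { trans += w; alive = false; }
            else l += 1;
          } else {
            if (l == 0) { dref += w; alive = false; }
            else l -= 1;
          }
        }
        continue;
      }

      // hop to the interaction point
      const double step = s / mt;
      x += step * ux; y += step * uy; z += step * uz;

      // drop: deposit the absorbed share of the weight
      const double dw = w * mu_a[l] / mt;
      if (dw > 0.0) {
        const double r = std::sqrt(x * x + y * y);
        int iz = static_cast<int>(
            std::upper_bound(z_edges.begin(), z_edges.end(), z) -
            z_edges.begin()) - 1;
        if (iz >= nz) iz = nz - 1;
        if (r < r_max && iz >= 0 && z <= z_bot) {
          int ir = static_cast<int>(
              std::upper_bound(r_edges.begin(), r_edges.end(), r) -
              r_edges.begin()) - 1;
          if (ir >= nr) ir = nr - 1;
          const size_t cell = static_cast<size_t>(ir) +
                              static_cast<size_t>(iz) * nr;
          absorbed[cell] += dw;
          batch[cell * n_batch + b] += dw;
        } else {
          overflow[l] += dw;
        }
        batch_total[b] += dw;
        w -= dw;
      }
      if (w <= 0.0) break;

      // spin: Henyey-Greenstein deflection
      if (mu_s[l] > 0.0) spin(ux, uy, uz, hg_cos(g_hg[l]));
      s = -std::log(runif01());

      // Russian roulette on low weights (unbiased; net residual tracked so
      // the caller can close the energy books exactly)
      if (w < w_threshold) {
        if (runif01() < p_survival) {
          roulette_net -= w * (1.0 / p_survival - 1.0);
          w /= p_survival;
        } else {
          roulette_net += w;
          alive = false;
        }
      }
    }
  }

  NumericMatrix abs_mat(nr, nz);
  NumericMatrix abs_se(nr, nz);
  const double nb = static_cast<double>(n_batch);
  for (int jz = 0; jz < nz; ++jz) {
    for (int ir = 0; ir < nr; ++ir) {
      const size_t cell = static_cast<size_t>(ir) +
                          static_cast<size_t>(jz) * nr;
      abs_mat(ir, jz) = absorbed[cell];
      double m = absorbed[cell] / nb, v = 0.0;
      for (int bb = 0; bb < n_batch; ++bb) {
        const double d = batch[cell * n_batch + bb] - m;
        v += d * d;
      }
      // sd of the per-batch sums scaled up to the total
      abs_se(ir, jz) = std::sqrt(v / (nb - 1.0)) * std::sqrt(nb);
    }
  }

  double absorbed_total = 0.0;
  for (int bb = 0; bb < n_batch; ++bb) absorbed_total += batch_total[bb];

  return List::create(
      _["absorbed"] = abs_mat, _["absorbed_se"] = abs_se,
      _["overflow_by_layer"] = NumericVector(overflow.begin(), overflow.end()),
      _["specular"] = specular, _["diffuse_reflected"] = dref,
      _["transmitted"] = trans, _["absorbed_total"] = absorbed_total,
      _["roulette_net"] = roulette_net);
}
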
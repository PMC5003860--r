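// Monte Carlo photon transport in a homogeneous semi-infinite scattering
// medium, for wide-field diffuse-reflectance and epifluorescence geometries.
//
// Conventions: z positive downward from the surface (z = 0), x lateral.
// Photons are launched at the origin travelling +z (uniform planar
// illumination is equivalent, by lateral translation invariance, to
// recording exit position relative to the launch point; the sensitivity map
// is binned relative to the *detection* pixel, i.e. the exit position).
// Absorption is handled by continuous weight attenuation exp(-mua * s)
// along each path segment (pathlength-recording estimator), so one photon
// set supports mua-perturbation identities. Scattering uses Henyey-
// Greenstein sampling. Russian roulette below weight 1e-4 with survival
// probability 0.1. All randomness comes from R's RNG (set.seed upstream).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Deposit { double x0, z0, ux, uz, len; };

inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - f * f) / (2.0 * g);
}

// Rotate direction (ux,uy,uz) by polar angle with cosine ct and azimuth phi.
inline void spin(double &ux, double &uy, double &uz, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
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
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// Unpolarised Fresnel reflectance for internal incidence, cosine ci,
// relative index n (tissue) to 1 (air). Returns 1 beyond critical angle.
inline double fresnel_R(double n_rel, double ci) {
  if (n_rel <= 1.0) return 0.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n_rel * si;          // Snell: n1 sin(i) = n2 sin(t), n2 = 1
  if (st >= 1.0) return 1.0;       // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
  double rp = (n_rel * ct - ci) / (n_rel * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export(name = ".mc_reflectance")]]
List mc_reflectance(int n_photons, double mua, double mus, double g,
                    double n_rel, double na, double depth_cutoff,
                    double x_half_extent, double z_extent,
                    double bin_xy, double bin_z,
                    bool fresnel, double roulette_weight,
                    double roulette_survive, int max_steps) {
  if (n_photons < 1) stop("n_photons must be >= 1");
  if (mus <= 0.0) stop("mus must be > 0");
  if (mua < 0.0) stop("mua must be >= 0");
  if (g <= -1.0 || g >= 1.0) stop("g must be in (-1, 1)");
  if (na <= 0.0 || na > 1.0) stop("na must be in (0, 1]");
  if (bin_xy <= 0.0 || bin_z <= 0.0 || x_half_extent <= 0.0 || z_extent <= 0.0)
    stop("degenerate sensitivity grid");

  const int nx = std::max(1, (int)std::ceil(2.0 * x_half_extent / bin_xy));
  const int nz = std::max(1, (int)std::ceil(z_extent / bin_z));
  NumericMatrix sens(nx, nz);
  double overflow = 0.0;

  // substep length for binning path into the grid
  const double sub_max = 0.5 * std::min(bin_xy, bin_z);
  // acceptance: exit direction within NA cone after refraction
  // n_rel * sin(theta_tissue) <= na
  const double sin_acc = na / std::max(1.0, n_rel);
  const double cos_acc = std::sqrt(std::max(0.0, 1.0 - sin_acc * sin_acc));

  double w_detected = 0.0, w_escaped = 0.0, w_transmitted = 0.0;
  double w_absorbed = 0.0, w_roulette_loss = 0.0, w_roulette_gain = 0.0;
  double sum_wL = 0.0;  // detected-weighted total pathlength
  std::vector<double> det_L, det_w;
  std::vector<Deposit> path;
  path.reserve(4096);

  RNGScope scope;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0, L = 0.0;
    bool alive = true;
    int fate = 0;  // 1 detected, 2 escaped, 3 transmitted, 4 rouletted
    path.clear();

    for (int step = 0; step < max_steps && alive; ++step) {
      double s = -std::log(unif_rand()) / mus;

      // surface crossing?
      if (uz < 0.0 && z + uz * s < 0.0) {
        double sb = -z / uz;  // distance to surface
        path.push_back({x, z, ux, uz, sb});
        double wa = w * (1.0 - std::exp(-mua * sb));
        w_absorbed += wa;
        w -= wa;
        L += sb;
        x += sb * ux; y += sb * uy; z = 0.0;
        double ci = -uz;  // cosine with outward normal
        double Rf = fresnel ? fresnel_R(n_rel, ci) : 0.0;
        if (Rf > 0.0 && unif_rand() < Rf) {
          uz = -uz;  // internal reflection, photon continues
          continue;
        }
        // transmitted out of the tissue; accepted if within the NA cone
        // after refraction: n_rel * sin(theta_tissue) <= na
        fate = (ci >= cos_acc) ? 1 : 2;
        alive = false;
        break;
      }

      // full step inside the medium
      path.push_back({x, z, ux, uz, s});
      double wa = w * (1.0 - std::exp(-mua * s));
      w_absorbed += wa;
      w -= wa;
      L += s;
      x += s * ux; y += s * uy; z += s * uz;

      if (z >= depth_cutoff) {
        fate = 3;
        alive = false;
        break;
      }

      // scatter
      double ct = hg_cos(g, unif_rand());
      double phi = 2.0 * M_PI * unif_rand();
      spin(ux, uy, uz, ct, phi);

      // roulette
      if (w < roulette_weight) {
        if (unif_rand() < roulette_survive) {
          double gain = w * (1.0 / roulette_survive - 1.0);
          w_roulette_gain += gain;
          w /= roulette_survive;
        } else {
          fate = 4;
          alive = false;
          break;
        }
      }
    }

    if (fate == 1) {
      w_detected += w;
      sum_wL += w * L;
      det_L.push_back(L);
      det_w.push_back(w);
      // bin the stored path relative to the exit (= detection pixel)
      // position, subdividing segments so deposits land in the right bins
      for (const Deposit &d : path) {
        int nsub = std::max(1, (int)std::ceil(d.len / sub_max));
        double l = d.len / nsub;
        for (int k = 0; k < nsub; ++k) {
          double xm = d.x0 + d.ux * (k + 0.5) * l - x;  // relative to exit
          double zm = d.z0 + d.uz * (k + 0.5) * l;
          int ix = (int)std::floor((xm + x_half_extent) / bin_xy);
          int iz = (int)std::floor(zm / bin_z);
          if (ix >= 0 && ix < nx && iz >= 0 && iz < nz)
            sens(ix, iz) += w * l;
          else
            overflow += w * l;
        }
      }
    } else if (fate == 2) {
      w_escaped += w;
    } else if (fate == 3) {
      w_transmitted += w;
    } else if (fate == 4) {
      w_roulette_loss += w;
    } else {
      // max_steps exhausted; count as absorbed-equivalent loss
      w_roulette_loss += w;
    }
  }

  double dpf = w_detected > 0.0 ? sum_wL / w_detected : NA_REAL;

  return List::create(
    _["dpf_pathlength_mm"] = dpf,
    _["sensitivity_xz"] = sens,
    _["overflow"] = overflow,
    _["total_reflectance"] = w_detected / n_photons,
    _["w_detected"] = w_detected,
    _["w_escaped"] = w_escaped,
    _["w_transmitted"] = w_transmitted,
    _["w_absorbed"] = w_absorbed,
    _["w_roulette_loss"] = w_roulette_loss,
    _["w_roulette_gain"] = w_roulette_gain,
    _["detected_pathlengths"] = NumericVector(det_L.begin(), det_L.end()),
    _["detected_weights"] = NumericVector(det_w.begin(), det_w.end()),
    _["n_detected"] = (int)det_L.size());
}

// Fluorescence geometry, two passes.
// Pass 1 (excitation): transport at excitation-band properties, accumulate
// pathlength-weighted fluence per depth bin, plus the mean path travelled to
// reach each bin (the excitation leg).
// Pass 2 (emission): launch isotropically from depths sampled proportional
// to fluence x fluorophore depth profile; transport at emission-band
// properties; detect at the surface within the NA cone.
// [[Rcpp::export(name = ".mc_fluorescence")]]
List mc_fluorescence(int n_photons,
                     double mua_ex, double mus_ex, double g_ex,
                     double mua_em, double mus_em, double g_em,
                     double n_rel, double na, double depth_cutoff,
                     NumericVector depth_profile, double bin_z,
                     bool fresnel, double roulette_weight,
                     double roulette_survive, int max_steps) {
  if (n_photons < 1) stop("n_photons must be >= 1");
  if (mus_ex <= 0.0 || mus_em <= 0.0) stop("mus must be > 0");
  const int nz = depth_profile.size();
  if (nz < 1 || bin_z <= 0.0) stop("degenerate depth grid");
  double psum = 0.0;
  for (int i = 0; i < nz; ++i) {
    if (depth_profile[i] < 0.0) stop("depth profile must be non-negative");
    psum += depth_profile[i];
  }
  if (psum <= 0.0) stop("depth profile sums to zero");

  const double sin_acc = na / std::max(1.0, n_rel);
  const double cos_acc = std::sqrt(std::max(0.0, 1.0 - sin_acc * sin_acc));
  const double sub_max = 0.5 * bin_z;

  std::vector<double> fluence(nz, 0.0), fluence_L(nz, 0.0);

  RNGScope scope;

  // ---- pass 1: excitation transport ----
  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0, L = 0.0;
    for (int step = 0; step < max_steps; ++step) {
      double s = -std::log(unif_rand()) / mus_ex;
      bool exits = (uz < 0.0 && z + uz * s < 0.0);
      double seg = exits ? -z / uz : s;
      // deposit fluence along the segment in substeps
      int nsub = std::max(1, (int)std::ceil(seg / sub_max));
      double l = seg / nsub;
      for (int k = 0; k < nsub; ++k) {
        double zm = z + uz * (k + 0.5) * l;
        double wm = w * std::exp(-mua_ex * (k + 0.5) * l);
        int iz = (int)std::floor(zm / bin_z);
        if (iz >= 0 && iz < nz) {
          fluence[iz] += wm * l;
          fluence_L[iz] += wm * l * (L + (k + 0.5) * l);
        }
      }
      double wa = w * (1.0 - std::exp(-mua_ex * seg));
      w -= wa;
      L += seg;
      x += seg * ux; y += seg * uy; z += seg * uz;
      if (exits) {
        z = 0.0;
        double ci = -uz;
        double Rf = fresnel ? fresnel_R(n_rel, ci) : 0.0;
        if (Rf > 0.0 && unif_rand() < Rf) { uz = -uz; continue; }
        break;
      }
      if (z >= depth_cutoff) break;
      double ct = hg_cos(g_ex, unif_rand());
      double phi = 2.0 * M_PI * unif_rand();
      spin(ux, uy, uz, ct, phi);
      if (w < roulette_weight) {
        if (unif_rand() < roulette_survive) w /= roulette_survive;
        else break;
      }
    }
  }

  // emission source strength per bin: fluence x fluorophore density
  std::vector<double> src(nz), cum(nz);
  double src_tot = 0.0;
  for (int i = 0; i < nz; ++i) {
    src[i] = fluence[i] * depth_profile[i];
    src_tot += src[i];
    cum[i] = src_tot;
  }
  if (src_tot <= 0.0)
    stop("no excitation fluence overlaps the fluorophore depth profile");

  // ---- pass 2: emission transport ----
  std::vector<double> launched_w(nz, 0.0), detected_w(nz, 0.0);
  double sum_em_wL = 0.0, w_det_tot = 0.0;
  for (int ip = 0; ip < n_photons; ++ip) {
    // sample origin bin from the source pmf
    double u = unif_rand() * src_tot;
    int iz0 = 0;
    while (iz0 < nz - 1 && cum[iz0] < u) ++iz0;
    double z = (iz0 + unif_rand()) * bin_z;
    launched_w[iz0] += 1.0;
    // isotropic emission
    double ct0 = 2.0 * unif_rand() - 1.0;
    double phi0 = 2.0 * M_PI * unif_rand();
    double st0 = std::sqrt(std::max(0.0, 1.0 - ct0 * ct0));
    double ux = st0 * std::cos(phi0), uy = st0 * std::sin(phi0), uz = ct0;
    double x = 0.0, y = 0.0, w = 1.0, L = 0.0;
    for (int step = 0; step < max_steps; ++step) {
      double s = -std::log(unif_rand()) / mus_em;
      bool exits = (uz < 0.0 && z + uz * s < 0.0);
      double seg = exits ? -z / uz : s;
      double wa = w * (1.0 - std::exp(-mua_em * seg));
      w -= wa;
      L += seg;
      x += seg * ux; y += seg * uy; z += seg * uz;
      if (exits) {
        z = 0.0;
        double ci = -uz;
        double Rf = fresnel ? fresnel_R(n_rel, ci) : 0.0;
        if (Rf > 0.0 && unif_rand() < Rf) { uz = -uz; continue; }
        if (ci >= cos_acc) {
          detected_w[iz0] += w;
          w_det_tot += w;
          sum_em_wL += w * L;
        }
        break;
      }
      if (z >= depth_cutoff) break;
      double ct = hg_cos(g_em, unif_rand());
      double phi = 2.0 * M_PI * unif_rand();
      spin(ux, uy, uz, ct, phi);
      if (w < roulette_weight) {
        if (unif_rand() < roulette_survive) w /= roulette_survive;
        else break;
      }
    }
  }

  return List::create(
    _["fluence"] = NumericVector(fluence.begin(), fluence.end()),
    _["fluence_L"] = NumericVector(fluence_L.begin(), fluence_L.end()),
    _["source"] = NumericVector(src.begin(), src.end()),
    _["launched_w"] = NumericVector(launched_w.begin(), launched_w.end()),
    _["detected_w"] = NumericVector(detected_w.begin(), detected_w.end()),
    _["mean_emission_path_mm"] =
      w_det_tot > 0.0 ? sum_em_wL / w_det_tot : NA_REAL,
    _["w_detected_total"] = w_det_tot);
}
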
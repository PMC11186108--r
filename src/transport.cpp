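// Analog photon transport over a voxelized material grid.
//
// Woodcock (delta) tracking with an energy-dependent majorant, photoelectric
// absorption (full local deposit), incoherent scattering with Klein-Nishina
// free-electron sampling (electron energy deposited in the collision voxel),
// a low-energy cutoff with local deposit, and track-length fluence tallies
// in axis-aligned cubic scorers. Distances in mm, energies in keV,
// attenuation coefficients in mm^-1. Uses R's RNG so runs are reproducible
// from set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double runif_pos() {
  double r;
  do { r = unif_rand(); } while (r <= 0.0 || r >= 1.0);
  return r;
}

// sample the scattered-to-incident energy ratio from the Klein-Nishina
// distribution (composition-rejection, Penelope style)
static double kn_sample_eps(double k) {
  const double e0 = 1.0 / (1.0 + 2.0 * k);
  const double a1 = std::log(1.0 / e0);
  const double a2 = 0.5 * (1.0 - e0 * e0);
  double eps, t, sin2;
  for (;;) {
    if (unif_rand() * (a1 + a2) < a1)
      eps = std::exp(-a1 * runif_pos());
    else
      eps = std::sqrt(e0 * e0 + (1.0 - e0 * e0) * runif_pos());
    t = (1.0 - eps) / (k * eps);
    sin2 = t * (2.0 - t);
    if (unif_rand() <= 1.0 - eps * sin2 / (1.0 + eps * eps)) break;
  }
  return eps;
}

// rotate direction u by polar angle (cost) about itself with random azimuth
static void rotate_direction(double* u, double cost) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * unif_rand();
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 0.999999) {
    u[0] = sint * cphi;
    u[1] = sint * sphi;
    u[2] = cost * (uz > 0 ? 1.0 : -1.0);
  } else {
    double s = std::sqrt(1.0 - uz * uz);
    u[0] = ux * cost + sint * (ux * uz * cphi - uy * sphi) / s;
    u[1] = uy * cost + sint * (uy * uz * cphi + ux * sphi) / s;
    u[2] = uz * cost - sint * s * cphi;
  }
  double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= n; u[1] /= n; u[2] /= n;
}

struct ETable {
  double le0, dle;
  int n;
  const double* mumax;
  const double* mu;   // n x nmat, column-major
  const double* fpe;
  int nmat;
  inline void locate(double e, int& i, double& w) const {
    double t = (std::log(e) - le0) / dle;
    if (t < 0) t = 0;
    if (t > n - 1.000001) t = n - 1.000001;
    i = (int)t;
    w = t - i;
  }
  inline double majorant(double e) const {
    int i; double w; locate(e, i, w);
    return mumax[i] * (1 - w) + mumax[i + 1] * w;
  }
  inline double mu_at(double e, int m) const {
    int i; double w; locate(e, i, w);
    const double* c = mu + (size_t)m * n;
    return c[i] * (1 - w) + c[i + 1] * w;
  }
  inline double fpe_at(double e, int m) const {
    int i; double w; locate(e, i, w);
    const double* c = fpe + (size_t)m * n;
    return c[i] * (1 - w) + c[i + 1] * w;
  }
};

// distance to exit the box [lo, hi] from p along u (p assumed inside)
static double exit_distance(const double* p, const double* u,
                            const double* lo, const double* hi) {
  double t = R_PosInf;
  for (int a = 0; a < 3; ++a) {
    if (u[a] > 1e-12) t = std::min(t, (hi[a] - p[a]) / u[a]);
    else if (u[a] < -1e-12) t = std::min(t, (lo[a] - p[a]) / u[a]);
  }
  return t;
}

// [[Rcpp::export(name = ".transport_batch")]]
List transport_batch(NumericMatrix pos, NumericMatrix dir, NumericVector energy,
                     IntegerVector mat, IntegerVector dims,
                     NumericVector spacing, NumericVector origin,
                     NumericVector egrid, NumericMatrix mu_tab,
                     NumericMatrix fpe_tab, NumericVector mumax,
                     double cutoff_kev,
                     NumericMatrix scorer_centers, double scorer_edge,
                     double bin_kev, int nbins, NumericVector eps_mean) {
  const int nph = pos.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nsc = scorer_centers.nrow();
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (dims[a] - 0.5) * spacing[a];
  }
  ETable tab;
  tab.le0 = std::log(egrid[0]);
  tab.dle = (std::log(egrid[egrid.size() - 1]) - tab.le0) / (egrid.size() - 1);
  tab.n = egrid.size();
  tab.mumax = &mumax[0];
  tab.mu = &mu_tab(0, 0);
  tab.fpe = &fpe_tab(0, 0);
  tab.nmat = mu_tab.ncol();

  NumericVector edep((size_t)nx * ny * nz);
  NumericMatrix spectra(nbins, nsc > 0 ? nsc : 1);
  NumericVector tle(nsc > 0 ? nsc : 1);  // expected keV deposited per scorer
  double escaped = 0.0;
  int n_uncollided = 0;
  const double hs = scorer_edge / 2.0;

  GetRNGstate();
  for (int iph = 0; iph < nph; ++iph) {
    double p[3] = { pos(iph, 0), pos(iph, 1), pos(iph, 2) };
    double u[3] = { dir(iph, 0), dir(iph, 1), dir(iph, 2) };
    double e = energy[iph];
    int ncoll = 0;
    bool alive = true;

    // advance photons born outside the grid to its boundary (vacuum outside)
    if (p[0] < lo[0] || p[0] > hi[0] || p[1] < lo[1] || p[1] > hi[1] ||
        p[2] < lo[2] || p[2] > hi[2]) {
      double tin = -1.0, tout = R_PosInf;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(u[a]) > 1e-12) {
          double t1 = (lo[a] - p[a]) / u[a], t2 = (hi[a] - p[a]) / u[a];
          if (t1 > t2) std::swap(t1, t2);
          tin = std::max(tin, t1);
          tout = std::min(tout, t2);
        } else if (p[a] < lo[a] || p[a] > hi[a]) {
          tin = R_PosInf;
        }
      }
      if (tin > tout || !R_finite(tin) || tin < 0) {
        escaped += e;
        ++n_uncollided;
        continue;
      }
      double eps = 1e-9 * (hi[0] - lo[0]);
      for (int a = 0; a < 3; ++a) p[a] += (tin + eps) * u[a];
    }

    while (alive) {
      if (e < cutoff_kev) {
        int ix = std::min(nx - 1, std::max(0, (int)((p[0] - lo[0]) / spacing[0])));
        int iy = std::min(ny - 1, std::max(0, (int)((p[1] - lo[1]) / spacing[1])));
        int iz = std::min(nz - 1, std::max(0, (int)((p[2] - lo[2]) / spacing[2])));
        edep[(size_t)ix + (size_t)nx * (iy + (size_t)ny * iz)] += e;
        break;
      }
      double mumaj = tab.majorant(e);
      double s = -std::log(runif_pos()) / mumaj;
      double texit = exit_distance(p, u, lo, hi);
      double seg = std::min(s, texit);

      if (nsc > 0 && seg > 0) {
        int bin = (int)(e / bin_kev);
        if (bin >= nbins) bin = nbins - 1;
        for (int j = 0; j < nsc; ++j) {
          double tmin = 0.0, tmax = seg;
          bool hit = true;
          for (int a = 0; a < 3; ++a) {
            double cmin = scorer_centers(j, a) - hs;
            double cmax = scorer_centers(j, a) + hs;
            if (std::fabs(u[a]) > 1e-12) {
              double t1 = (cmin - p[a]) / u[a], t2 = (cmax - p[a]) / u[a];
              if (t1 > t2) std::swap(t1, t2);
              tmin = std::max(tmin, t1);
              tmax = std::min(tmax, t2);
              if (tmin >= tmax) { hit = false; break; }
            } else if (p[a] < cmin || p[a] > cmax) { hit = false; break; }
          }
          if (hit) {
            double len = tmax - tmin;
            spectra(bin, j) += len;
            // track-length (kerma) dose estimator: expected energy
            // deposited in the scorer by collisions of this segment,
            // using the material at the segment midpoint
            double tm = 0.5 * (tmin + tmax);
            double q[3] = { p[0] + tm * u[0], p[1] + tm * u[1],
                            p[2] + tm * u[2] };
            int qx = std::min(nx - 1, std::max(0, (int)((q[0] - lo[0]) / spacing[0])));
            int qy = std::min(ny - 1, std::max(0, (int)((q[1] - lo[1]) / spacing[1])));
            int qz = std::min(nz - 1, std::max(0, (int)((q[2] - lo[2]) / spacing[2])));
            int mq = mat[(size_t)qx + (size_t)nx * (qy + (size_t)ny * qz)] - 1;
            int ie; double we; tab.locate(e, ie, we);
            double em = eps_mean[ie] * (1 - we) + eps_mean[ie + 1] * we;
            double fq = tab.fpe_at(e, mq);
            double dbar = e * (fq + (1.0 - fq) * (1.0 - em));
            tle[j] += tab.mu_at(e, mq) * len * dbar;
          }
        }
      }

      if (s >= texit) {
        escaped += e;
        if (ncoll == 0) ++n_uncollided;
        break;
      }
      p[0] += s * u[0]; p[1] += s * u[1]; p[2] += s * u[2];
      int ix = std::min(nx - 1, std::max(0, (int)((p[0] - lo[0]) / spacing[0])));
      int iy = std::min(ny - 1, std::max(0, (int)((p[1] - lo[1]) / spacing[1])));
      int iz = std::min(nz - 1, std::max(0, (int)((p[2] - lo[2]) / spacing[2])));
      size_t v = (size_t)ix + (size_t)nx * (iy + (size_t)ny * iz);
      int m = mat[v] - 1;  // R codes are 1-based

      double mureal = tab.mu_at(e, m);
      if (unif_rand() < mureal / mumaj) {
        ++ncoll;
        if (unif_rand() < tab.fpe_at(e, m)) {
          edep[v] += e;
          break;
        }
        double k = e / 510.99895;
        double eps = kn_sample_eps(k);
        double cost = 1.0 - (1.0 / eps - 1.0) / k;
        if (cost < -1.0) cost = -1.0;
        if (cost > 1.0) cost = 1.0;
        edep[v] += e * (1.0 - eps);
        e *= eps;
        rotate_direction(u, cost);
      }
      // else fictitious collision: continue with same energy/direction
    }
  }
  PutRNGstate();

  return List::create(_["edep"] = edep, _["escaped_kev"] = escaped,
                      _["spectra_mm"] = spectra, _["tle_kev"] = tle,
                      _["n_uncollided"] = n_uncollided);
}

// [[Rcpp::export(name = ".kn_sample")]]
NumericVector kn_sample(double energy_kev, int n) {
  NumericVector out(n);
  double k = energy_kev / 510.99895;
  GetRNGstate();
  for (int i = 0; i < n; ++i) out[i] = kn_sample_eps(k);
  PutRNGstate();
  return out;
}
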
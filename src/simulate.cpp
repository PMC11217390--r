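// Monte-Carlo ray tracer for a simplified pinhole SANS beamline:
// source -> slit 1 -> (collimation length) -> slit 2 / sample -> detector.
//
// Forced-scattering importance sampling: every neutron scatters toward a
// point drawn uniformly on the detector, carrying a weight proportional to
// I(q) * dOmega * (1 - absorption). Uses the R RNG so that set.seed() on the
// R side makes runs reproducible.

#include <RcppArmadillo.h>
#include <cmath>
#include "kernels.h"

using namespace Rcpp;

// symmetric triangular deviate on [-a, a] (FWHM = a)
static inline double rtriang(double a) {
  return a * (unif_rand() + unif_rand() - 1.0);
}

// positive-truncated Gaussian by rejection (re-draw until > 0)
static inline double rtruncnorm_pos(double mean, double sd) {
  for (int i = 0; i < 1000; ++i) {
    double x = mean + sd * norm_rand();
    if (x > 0.0) return x;
  }
  return mean; // unreachable for sd <= mean/2
}

// [[Rcpp::export(name = ".simulate_pattern_cpp")]]
List simulate_pattern_cpp(int label,
                          NumericVector params,
                          NumericVector spreads,   // per-parameter: sd (length) or half-width (angle)
                          IntegerVector kind,      // 0 fixed, 1 polydisperse length, 2 orientation angle
                          double absorption,
                          double lambda0,          // A
                          double fwhm_frac,        // triangular FWHM as a fraction of lambda0
                          double coll_m,           // collimation length [m]
                          double sdd_m,            // sample-detector distance [m]
                          NumericVector slit1_m,   // full widths (x, y) [m]
                          NumericVector slit2_m,
                          int nx, int ny,
                          double pitch_x, double pitch_y,   // [m]
                          double beam_cx, double beam_cy,   // pixel coords of beam centre
                          NumericVector beamstop_m,         // full widths (x, y) [m]
                          double n_neutrons,
                          bool keep_sumsq) {
  const int np = params.size();
  if ((int)kind.size() != np || (int)spreads.size() != np)
    stop("params, spreads and kind must have equal length");
  const bool aniso = sas_is_aniso(label);

  arma::mat img(nx, ny, arma::fill::zeros);
  arma::mat img2;
  if (keep_sumsq) img2.zeros(nx, ny);

  std::vector<double> p(np);
  const double trans = 1.0 - absorption;
  const double a_lam = fwhm_frac * lambda0;
  const long long n_ev = (long long)n_neutrons;

  for (long long ev = 0; ev < n_ev; ++ev) {
    if ((ev & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    double lam = lambda0 + rtriang(a_lam);
    // collimation: entry point in slit 1, exit point in slit 2 (at the sample)
    double x1 = (unif_rand() - 0.5) * slit1_m[0];
    double y1 = (unif_rand() - 0.5) * slit1_m[1];
    double x2 = (unif_rand() - 0.5) * slit2_m[0];
    double y2 = (unif_rand() - 0.5) * slit2_m[1];
    double inx = x2 - x1, iny = y2 - y1, inz = coll_m;
    double innorm = std::sqrt(inx * inx + iny * iny + inz * inz);
    inx /= innorm; iny /= innorm; inz /= innorm;

    // target point: uniform over the detector face
    int i = (int)(nx * unif_rand()); if (i == nx) --i;
    int j = (int)(ny * unif_rand()); if (j == ny) --j;
    double xd = (i + unif_rand() - beam_cx - 0.5) * pitch_x;
    double yd = (j + unif_rand() - beam_cy - 0.5) * pitch_y;
    double ox = xd - x2, oy = yd - y2, oz = sdd_m;
    double onorm = std::sqrt(ox * ox + oy * oy + oz * oz);
    ox /= onorm; oy /= onorm; oz /= onorm;

    double k = 2.0 * M_PI / lam;
    double qx = k * (ox - inx), qy = k * (oy - iny), qz = k * (oz - inz);

    // per-event sample draws: polydisperse sizes, orientation jitter
    for (int m = 0; m < np; ++m) {
      double s = spreads[m];
      if (kind[m] == 1 && s > 0.0)      p[m] = rtruncnorm_pos(params[m], s);
      else if (kind[m] == 2 && s > 0.0) p[m] = params[m] + (2.0 * unif_rand() - 1.0) * s;
      else                              p[m] = params[m];
    }

    double I = aniso ? sas_iqxy(label, p.data(), qx, qy)
                     : sas_iq(label, p.data(), std::sqrt(qx * qx + qy * qy + qz * qz));
    double cosd = oz;                      // flat-detector solid-angle factor
    double w = I * cosd * cosd * cosd * trans;
    img(i, j) += w;
    if (keep_sumsq) img2(i, j) += w * w;
  }

  // beamstop: pixels whose centres are geometrically shadowed are zeroed
  for (int i = 0; i < nx; ++i) {
    double xc = (i - beam_cx) * pitch_x;
    if (std::fabs(xc) > 0.5 * beamstop_m[0]) continue;
    for (int j = 0; j < ny; ++j) {
      double yc = (j - beam_cy) * pitch_y;
      if (std::fabs(yc) <= 0.5 * beamstop_m[1]) {
        img(i, j) = 0.0;
        if (keep_sumsq) img2(i, j) = 0.0;
      }
    }
  }

  List out = List::create(_["counts"] = wrap(img));
  if (keep_sumsq) out["sumsq"] = wrap(img2);
  return out;
}

// Monte-Carlo polydispersity/orientation average of the kernel at fixed q
// points (no instrument): used by the polydisperse_average operation.
// [[Rcpp::export(name = ".poly_avg_cpp")]]
NumericMatrix poly_avg_cpp(int label, NumericVector params, NumericVector spreads,
                           IntegerVector kind,
                           NumericVector qx, NumericVector qy, bool planar,
                           double n_draws) {
  const int np = params.size();
  const bool aniso = sas_is_aniso(label);
  std::vector<double> p(np);
  const long long nd = (long long)n_draws;
  NumericMatrix out(qx.size(), 2); // mean, MC standard error
  std::vector<double> acc(qx.size(), 0.0), acc2(qx.size(), 0.0);
  for (long long d = 0; d < nd; ++d) {
    if ((d & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    for (int m = 0; m < np; ++m) {
      double s = spreads[m];
      if (kind[m] == 1 && s > 0.0)      p[m] = rtruncnorm_pos(params[m], s);
      else if (kind[m] == 2 && s > 0.0) p[m] = params[m] + (2.0 * unif_rand() - 1.0) * s;
      else                              p[m] = params[m];
    }
    for (R_xlen_t i = 0; i < qx.size(); ++i) {
      double I = (aniso && planar) ? sas_iqxy(label, p.data(), qx[i], qy[i])
                                   : sas_iq(label, p.data(), qx[i]);
      acc[i] += I; acc2[i] += I * I;
    }
  }
  for (R_xlen_t i = 0; i < qx.size(); ++i) {
    double mean = acc[i] / nd;
    double var = acc2[i] / nd - mean * mean;
    if (var < 0) var = 0;
    out(i, 0) = mean;
    out(i, 1) = (nd > 1) ? std::sqrt(var / (nd - 1)) : 0.0;
  }
  return out;
}
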
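// Analytic small-angle scattering intensity kernels.
//
// All intensities are in arbitrary (relative) units: absolute-calibration
// prefactors are omitted because only the image shape matters downstream.
// Scattering-length-density contrasts are in 1e-6/A^2-style user units,
// lengths in Angstrom, q in 1/Angstrom, angles in radian.

#include <RcppArmadillo.h>
#include <cmath>
#include <map>
#include "kernels.h"

using namespace Rcpp;

// ---- small numeric helpers -------------------------------------------------

static inline double sinc(double x) {
  if (std::fabs(x) < 1e-4) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

// 3 (sin x - x cos x) / x^3, the sphere amplitude factor; -> 1 as x -> 0.
static inline double sph_fq(double x) {
  if (std::fabs(x) < 1e-2) {
    double x2 = x * x;
    return 1.0 - x2 / 10.0 + x2 * x2 / 280.0;
  }
  return 3.0 * (std::sin(x) - x * std::cos(x)) / (x * x * x);
}

// 2 J1(x) / x ; -> 1 as x -> 0.
static inline double j1c(double x) {
  if (std::fabs(x) < 1e-4) return 1.0 - x * x / 8.0;
  return 2.0 * ::j1(x) / x;
}

// Gauss-Legendre nodes/weights on [-1, 1], cached by order.
static const std::pair<arma::vec, arma::vec>& gauss_legendre(int n) {
  static std::map<int, std::pair<arma::vec, arma::vec> > cache;
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  arma::vec x(n), w(n);
  for (int i = 0; i < n; ++i) {
    // Newton iteration from the Chebyshev-like initial guess.
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0.0;
    for (int iter = 0; iter < 100; ++iter) {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p2 = p1; p1 = p0;
        p0 = ((2.0 * j + 1.0) * z * p1 - j * p2) / (j + 1.0);
      }
      pp = n * (z * p0 - p1) / (z * z - 1.0);
      double z1 = z;
      z = z1 - p0 / pp;
      if (std::fabs(z - z1) < 1e-15) break;
    }
    x(i) = z;
    w(i) = 2.0 / ((1.0 - z * z) * pp * pp);
  }
  cache[n] = std::make_pair(x, w);
  return cache[n];
}

// ---- model metadata --------------------------------------------------------

bool sas_is_aniso(int label) {
  switch (label) {
  case LBL_CORE_SHELL_CYLINDER:
  case LBL_CYLINDER:
  case LBL_ELLIPSOID:
  case LBL_ELLIPTICAL_CYLINDER:
    return true;
  default:
    return false;
  }
}

int sas_n_params(int label) {
  switch (label) {
  case LBL_BROAD_PEAK:          return 7;
  case LBL_CORE_SHELL_CYLINDER: return 9;
  case LBL_CORE_SHELL_SPHERE:   return 6;
  case LBL_CYLINDER:            return 7;
  case LBL_DAB:                 return 3;
  case LBL_ELLIPSOID:           return 7;
  case LBL_ELLIPTICAL_CYLINDER: return 9;
  case LBL_FRACTAL:             return 6;
  case LBL_FUZZY_SPHERE:        return 5;
  case LBL_MASS_FRACTAL:        return 5;
  case LBL_MONO_GAUSS_COIL:     return 3;
  case LBL_SPHERE:              return 4;
  case LBL_TEUBNER_STREY:       return 4;
  default: return -1;
  }
}

// ---- isotropic kernels -----------------------------------------------------

static double iq_sphere(const double* p, double q) {
  // p: scale, contrast, radius, background
  double V = 4.0 * M_PI / 3.0 * p[2] * p[2] * p[2];
  double f = p[1] * sph_fq(q * p[2]);
  return p[0] * V * f * f + p[3];
}

static double iq_fuzzy_sphere(const double* p, double q) {
  // p: scale, contrast, radius, fuzziness, background
  double V = 4.0 * M_PI / 3.0 * p[2] * p[2] * p[2];
  double f = p[1] * sph_fq(q * p[2]) * std::exp(-0.5 * q * q * p[3] * p[3]);
  return p[0] * V * f * f + p[4];
}

static double iq_core_shell_sphere(const double* p, double q) {
  // p: scale, contrast_core (core-shell), contrast_shell (shell-solvent),
  //    radius, thickness, background
  double rc = p[3], ro = p[3] + p[4];
  double Vc = 4.0 * M_PI / 3.0 * rc * rc * rc;
  double Vo = 4.0 * M_PI / 3.0 * ro * ro * ro;
  double F = p[1] * Vc * sph_fq(q * rc) + p[2] * Vo * sph_fq(q * ro);
  return p[0] * F * F / Vo + p[5];
}

static double iq_mono_gauss_coil(const double* p, double q) {
  // p: i_zero, rg, background ; Debye function P(x) = 2 (e^-x + x - 1)/x^2
  double x = q * q * p[1] * p[1];
  double P;
  if (x < 1e-3) P = 1.0 - x / 3.0 + x * x / 12.0;
  else P = 2.0 * (std::exp(-x) + x - 1.0) / (x * x);
  return p[0] * P + p[2];
}

static double iq_dab(const double* p, double q) {
  // p: scale, cor_length, background
  double L = p[1], d = 1.0 + q * q * L * L;
  return p[0] * L * L * L / (d * d) + p[2];
}

static double iq_broad_peak(const double* p, double q) {
  // p: porod_scale, porod_exp, lorentz_scale, lorentz_length, peak_pos,
  //    lorentz_exp, background
  double lor = std::pow(std::fabs(q - p[4]) * p[3], p[5]);
  return p[0] / std::pow(q, p[1]) + p[2] / (1.0 + lor) + p[6];
}

static double iq_teubner_strey(const double* p, double q) {
  // p: scale, d_spacing, xi, background
  // I = scale * a2 / (a2 + c1 q^2 + q^4); a2 = (k^2 + 1/xi^2)^2,
  // c1 = 2 (1/xi^2 - k^2), k = 2 pi / d. Denominator always > 0.
  double k2 = std::pow(2.0 * M_PI / p[1], 2), ix2 = 1.0 / (p[2] * p[2]);
  double a2 = (k2 + ix2) * (k2 + ix2);
  double c1 = 2.0 * (ix2 - k2);
  double q2 = q * q;
  return p[0] * a2 / (a2 + c1 * q2 + q2 * q2) + p[3];
}

static double iq_mass_fractal(const double* p, double q) {
  // p: scale, radius, fractal_dim_mass, cutoff_length, background
  double R = p[1], D = p[2], z = p[3];
  double P = sph_fq(q * R); P *= P;
  double qz = q * z, Dm1 = D - 1.0;
  double S;
  if (qz < 1e-6) {
    S = std::tgamma(D) * std::pow(z, D);
  } else {
    S = std::tgamma(Dm1) * std::pow(z, Dm1)
      * std::sin(Dm1 * std::atan(qz))
      / (q * std::pow(1.0 + qz * qz, Dm1 / 2.0));
  }
  return p[0] * P * S + p[4];
}

static double iq_fractal(const double* p, double q) {
  // p: volfraction, radius, fractal_dim, cor_length, contrast, background
  double phi = p[0], R = p[1], D = p[2], xi = p[3], c = p[4];
  double V = 4.0 * M_PI / 3.0 * R * R * R;
  double f = sph_fq(q * R);
  double P = phi * V * c * c * f * f;
  double qR = q * R, qxi = q * xi;
  double S = 1.0;
  if (qR > 1e-9) {
    S += D * std::tgamma(D - 1.0)
       * std::sin((D - 1.0) * std::atan(qxi))
       / (std::pow(qR, D) * std::pow(1.0 + 1.0 / (qxi * qxi), (D - 1.0) / 2.0));
  }
  return P * S + p[5];
}

// ---- anisotropic amplitudes (axis at angle alpha to q) ---------------------

static double cyl_amp(double q, double sa, double ca, double R, double L) {
  return sinc(0.5 * q * L * ca) * j1c(q * R * sa);
}

static double iqxy_aniso(int label, const double* p,
                         double q, double sa, double ca, double psi_q) {
  // sa, ca: sine/cosine of the angle between q and the particle axis;
  // psi_q: azimuth of q around the axis (only elliptical cross-sections care).
  switch (label) {
  case LBL_CYLINDER: {
    // p: scale, contrast, radius, length, theta, phi, background
    double V = M_PI * p[2] * p[2] * p[3];
    double A = p[1] * V * cyl_amp(q, sa, ca, p[2], p[3]);
    return p[0] * A * A / V + p[6];
  }
  case LBL_ELLIPSOID: {
    // p: scale, contrast, radius_polar, radius_equatorial, theta, phi, background
    double Rp = p[2], Re = p[3];
    double r = std::sqrt(Re * Re * sa * sa + Rp * Rp * ca * ca);
    double V = 4.0 * M_PI / 3.0 * Rp * Re * Re;
    double A = p[1] * V * sph_fq(q * r);
    return p[0] * A * A / V + p[6];
  }
  case LBL_ELLIPTICAL_CYLINDER: {
    // p: scale, contrast, radius_minor, axis_ratio, length, theta, phi, psi,
    //    background
    double a = p[2], nu = p[3], L = p[4];
    double c = std::cos(psi_q), s = std::sin(psi_q);
    double reff = a * std::sqrt(c * c + nu * nu * s * s);
    double V = M_PI * a * (a * nu) * L;
    double A = p[1] * V * sinc(0.5 * q * L * ca) * j1c(q * reff * sa);
    return p[0] * A * A / V + p[8];
  }
  case LBL_CORE_SHELL_CYLINDER: {
    // p: scale, contrast_core, contrast_shell, radius, thickness, length,
    //    theta, phi, background
    double R = p[3], t = p[4], L = p[5];
    double Vc = M_PI * R * R * L;
    double Vo = M_PI * (R + t) * (R + t) * (L + 2.0 * t);
    double A = p[1] * Vc * cyl_amp(q, sa, ca, R, L)
             + p[2] * Vo * cyl_amp(q, sa, ca, R + t, L + 2.0 * t);
    return p[0] * A * A / Vo + p[8];
  }
  default:
    stop("not an anisotropic model label: %d", label);
  }
  return NA_REAL; // unreached
}

double sas_iqxy(int label, const double* p, double qx, double qy) {
  if (!sas_is_aniso(label)) return sas_iq(label, p, std::hypot(qx, qy));
  // orientation angles: theta (polar, from beam z), phi (azimuth); elliptical
  // cylinder adds psi (rotation of the cross-section about the axis).
  double th, ph, psi0 = 0.0;
  if (label == LBL_ELLIPTICAL_CYLINDER) { th = p[5]; ph = p[6]; psi0 = p[7]; }
  else if (label == LBL_CORE_SHELL_CYLINDER) { th = p[6]; ph = p[7]; }
  else { th = p[4]; ph = p[5]; }

  double q = std::hypot(qx, qy);
  if (q < 1e-12) q = 1e-12;
  double nqx = qx / q, nqy = qy / q;
  // particle axis in the beam frame (beam along +z)
  double nx = std::sin(th) * std::cos(ph);
  double ny = std::sin(th) * std::sin(ph);
  double nz = std::cos(th);
  double ca = nqx * nx + nqy * ny;            // q is in the detector plane
  if (ca > 1.0) ca = 1.0; if (ca < -1.0) ca = -1.0;
  double sa = std::sqrt(1.0 - ca * ca);

  double psi_q = 0.0;
  if (label == LBL_ELLIPTICAL_CYLINDER) {
    // frame perpendicular to the axis: e1 = z x n (or x if axis || z), e2 = n x e1
    double e1x, e1y, e1z;
    double sn = std::hypot(nx, ny);
    if (sn < 1e-9) { e1x = 1.0; e1y = 0.0; e1z = 0.0; }
    else { e1x = -ny / sn; e1y = nx / sn; e1z = 0.0; }
    double e2x = ny * e1z - nz * e1y;
    double e2y = nz * e1x - nx * e1z;
    double e2z = nx * e1y - ny * e1x;
    double q1 = nqx * e1x + nqy * e1y;        // q_z = 0 in small-angle plane
    double q2 = nqx * e2x + nqy * e2y;
    (void)e2z;
    psi_q = std::atan2(q2, q1) - psi0;
  }
  return iqxy_aniso(label, p, q, sa, ca, psi_q);
}

// ---- 1-D intensity (orientation average for anisotropic models) ------------

double sas_iq(int label, const double* p, double q) {
  switch (label) {
  case LBL_BROAD_PEAK:        return iq_broad_peak(p, q);
  case LBL_CORE_SHELL_SPHERE: return iq_core_shell_sphere(p, q);
  case LBL_DAB:               return iq_dab(p, q);
  case LBL_FRACTAL:           return iq_fractal(p, q);
  case LBL_FUZZY_SPHERE:      return iq_fuzzy_sphere(p, q);
  case LBL_MASS_FRACTAL:      return iq_mass_fractal(p, q);
  case LBL_MONO_GAUSS_COIL:   return iq_mono_gauss_coil(p, q);
  case LBL_SPHERE:            return iq_sphere(p, q);
  case LBL_TEUBNER_STREY:     return iq_teubner_strey(p, q);
  default: break;
  }
  // uniform-over-sphere average: the amplitude depends on q only through the
  // angle alpha between q and the axis (plus psi for elliptical sections), so
  // <I> = int_0^{pi/2} I(q, alpha) sin(alpha) d(alpha) [ x mean over psi ].
  const int n = 76;
  const std::pair<arma::vec, arma::vec>& gl = gauss_legendre(n);
  double acc = 0.0;
  if (label == LBL_ELLIPTICAL_CYLINDER) {
    const int npsi = 32;
    for (int i = 0; i < n; ++i) {
      double alpha = 0.25 * M_PI * (gl.first(i) + 1.0);
      double sa = std::sin(alpha), ca = std::cos(alpha);
      double sum_psi = 0.0;
      for (int j = 0; j < npsi; ++j) {
        double psi = 0.5 * M_PI * (j + 0.5) / npsi;
        sum_psi += iqxy_aniso(label, p, q, sa, ca, psi);
      }
      acc += gl.second(i) * 0.25 * M_PI * sa * (sum_psi / npsi);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double alpha = 0.25 * M_PI * (gl.first(i) + 1.0);
      double sa = std::sin(alpha), ca = std::cos(alpha);
      acc += gl.second(i) * 0.25 * M_PI * sa * iqxy_aniso(label, p, q, sa, ca, 0.0);
    }
  }
  return acc;
}

// ---- R interface -----------------------------------------------------------

// [[Rcpp::export(name = ".sas_iq_cpp")]]
NumericVector sas_iq_cpp(int label, NumericVector params, NumericVector q) {
  if ((int)params.size() != sas_n_params(label))
    stop("wrong parameter vector length for label %d", label);
  NumericVector out(q.size());
  for (R_xlen_t i = 0; i < q.size(); ++i) out[i] = sas_iq(label, params.begin(), q[i]);
  return out;
}

// [[Rcpp::export(name = ".sas_iqxy_cpp")]]
NumericVector sas_iqxy_cpp(int label, NumericVector params,
                           NumericVector qx, NumericVector qy) {
  if ((int)params.size() != sas_n_params(label))
    stop("wrong parameter vector length for label %d", label);
  if (qx.size() != qy.size()) stop("qx and qy must have equal length");
  NumericVector out(qx.size());
  for (R_xlen_t i = 0; i < qx.size(); ++i)
    out[i] = sas_iqxy(label, params.begin(), qx[i], qy[i]);
  return out;
}

// Uniform-over-sphere orientation average of the 2-D kernel at |q| = q,
// by Gauss-Legendre in cos(theta) x midpoint in phi (and psi where relevant).
// [[Rcpp::export(name = ".sas_orient_avg_cpp")]]
NumericVector sas_orient_avg_cpp(int label, NumericVector params,
                                 NumericVector q, int n_nodes) {
  if (!sas_is_aniso(label)) stop("orientation average requires an anisotropic model");
  if (n_nodes < 8) stop("n_nodes must be >= 8");
  std::vector<double> p(params.begin(), params.end());
  int ith, iph, ipsi = -1;
  if (label == LBL_ELLIPTICAL_CYLINDER) { ith = 5; iph = 6; ipsi = 7; }
  else if (label == LBL_CORE_SHELL_CYLINDER) { ith = 6; iph = 7; }
  else { ith = 4; iph = 5; }

  const std::pair<arma::vec, arma::vec>& gl = gauss_legendre(n_nodes);
  int nphi = 2 * n_nodes;
  int npsi = (ipsi >= 0) ? n_nodes : 1;
  NumericVector out(q.size());
  for (R_xlen_t k = 0; k < q.size(); ++k) {
    double acc = 0.0, wsum = 0.0;
    for (int i = 0; i < n_nodes; ++i) {
      double ct = gl.first(i);
      double th = std::acos(ct);
      for (int j = 0; j < nphi; ++j) {
        double ph = 2.0 * M_PI * (j + 0.5) / nphi;
        for (int m = 0; m < npsi; ++m) {
          p[ith] = th; p[iph] = ph;
          if (ipsi >= 0) p[ipsi] = M_PI * (m + 0.5) / npsi;
          acc += gl.second(i) * sas_iqxy(label, p.data(), q[k], 0.0);
          wsum += gl.second(i);
        }
      }
    }
    out[k] = acc / wsum;
  }
  return out;
}
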
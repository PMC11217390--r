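#ifndef SANSVEX_KERNELS_H
#define SANSVEX_KERNELS_H

// Catalogue labels of the implemented models (0-based lexicographic rank in
// the 46-name catalogue; the registry on the R side mirrors these).
enum SasLabel {
  LBL_BROAD_PEAK          = 4,
  LBL_CORE_SHELL_CYLINDER = 9,
  LBL_CORE_SHELL_SPHERE   = 12,
  LBL_CYLINDER            = 13,
  LBL_DAB                 = 14,
  LBL_ELLIPSOID           = 15,
  LBL_ELLIPTICAL_CYLINDER = 16,
  LBL_FRACTAL             = 19,
  LBL_FUZZY_SPHERE        = 21,
  LBL_MASS_FRACTAL        = 29,
  LBL_MONO_GAUSS_COIL     = 30,
  LBL_SPHERE              = 39,
  LBL_TEUBNER_STREY       = 44
};

bool sas_is_aniso(int label);
int  sas_n_params(int label);

// 1-D kernel: isotropic models directly, anisotropic models orientation-averaged.
double sas_iq(int label, const double* p, double q);

// 2-D kernel at fixed particle orientation (orientation angles live inside p).
double sas_iqxy(int label, const double* p, double qx, double qy);

#endif
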
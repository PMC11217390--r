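---
title: "Virtual SANS experiments and CNN model recommendation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual SANS experiments and CNN model recommendation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sansvex` simulates labelled two-dimensional small-angle neutron scattering
(SANS) patterns on a virtual pinhole beamline and trains an ensemble of
convolutional networks to rank candidate scattering models for a measured
pattern. This vignette is the package's own account of the science: the
models, the instrument, the sampling and cleaning rules, the network, the
numerical choices behind each, and the limits of what the synthetic
validation shows.

## Scattering models

The intensity scattered at momentum transfer $q = (4\pi/\lambda)
\sin(\theta/2)$ by a dilute suspension of particles is proportional to the
single-particle form factor $P(q)$. The package implements thirteen
analytic kernels in compiled code, nine isotropic — sphere, fuzzy sphere,
core–shell sphere, monodisperse Gaussian coil (Debye function
$P = 2(e^{-x}+x-1)/x^2$, $x=(qR_g)^2$), DAB
($I = c\,L^3/(1+(qL)^2)^2$), broad peak ($A/q^n + C/(1+(|q-q_0|\xi)^m)$),
Teubner–Strey, mass fractal, and the Teixeira volume fractal — and four
anisotropic: cylinder, elliptical cylinder, ellipsoid of revolution, and
core–shell cylinder. Amplitudes follow the standard small-angle literature
forms (e.g. the cylinder amplitude
$2\Delta\rho V\, \mathrm{sinc}(qL\cos\alpha/2)\, J_1(qR\sin\alpha)/(qR\sin\alpha)$
with $\alpha$ the angle between $q$ and the particle axis). Intensities are
kept in arbitrary relative units: the classifier sees only image shape, so
absolute-calibration constants would cancel in the log-normalization.

The catalogue carries 46 model names with integer class labels fixed as the
0-based lexicographic rank of the name, so labels are stable across runs
and machines (`sphere` = 39, `teubner strey` = 44). Names without kernels
are registry placeholders that reserve their label; sixteen of them are
inferred, order-consistent entries marked as such in the documentation. New
kernels can be added without shifting any class index.

The Teubner–Strey kernel is parameterised by the repeat distance $d$ and
correlation length $\xi$: with $k = 2\pi/d$,
$I(q) = s\,a_2/(a_2 + c_1 q^2 + q^4)$, $a_2 = (k^2+\xi^{-2})^2$,
$c_1 = 2(\xi^{-2}-k^2)$, normalised so $I(0)=s$; the denominator is
provably positive ($a_2 - c_1^2/4 = 4k^2\xi^{-2} > 0$). Fractal dimensions
are bounded in $[1.1, 2.9]$, which keeps
$\sin((D-1)\arctan(q\zeta)) \ge 0$ and hence the structure factor
non-negative for all admissible parameters.

**Orientation.** Particle orientation is the polar/azimuth pair
$(\theta,\phi)$ of the principal axis relative to the beam (radians,
beam along $+z$, right-handed). The elliptical cylinder carries a third
angle $\psi$ — the rotation of its cross-section about the axis — because
the elliptical section is unobservable without it. Orientation averages use
Gauss–Legendre quadrature in $\cos\theta$ (Newton-iterated nodes, cached)
with midpoint rules in the azimuths; the axisymmetric 1-D averages reduce
to $\int_0^{\pi/2} I(q,\alpha)\sin\alpha\, d\alpha$ on a 76-node rule.

**Polydispersity.** Size parameters follow positive-truncated Gaussians
(rejection sampling: redraw until positive) centred on the nominal value
with standard deviation $\Delta r \in [0, r/2]$; orientation angles follow
uniform windows $[\theta-\Delta\theta, \theta+\Delta\theta]$. At
$\Delta = 0$ the Monte-Carlo average reduces *exactly* to the monodisperse
kernel — a tested contract, not an approximation.

## The virtual instrument

The beamline is a two-slit pinhole geometry: source, slit 1, collimation
length $L_c$, slit 2 at the sample, sample–detector distance (SDD), a
144×256-pixel position-sensitive detector with a rectangular beamstop at
the beam centre. The discrete configuration set is the Cartesian grid of
2 wavelengths (4.5, 6 Å) × 3 distance pairs (8m–1m, 8m–8m, 20m–20m) ×
3 slit settings (1.0×1.0 cm, 1.2×1.2 cm, 0.7×1.0 cm apertures with 2, 2,
1 cm sample cells) × 2 holder thicknesses (1, 2 mm) = 36 configurations,
enumerated wavelength-outermost, holder-innermost.

Each neutron draws a wavelength from a symmetric triangular distribution
(FWHM 10% of nominal — a typical velocity-selector band, configurable),
entry and exit points uniform in the two slit apertures (fixing the
incident direction and sample position), per-event polydisperse sizes and
orientation angles, and a target point uniform over the detector face.
This is *forced scattering*: every event scatters, carrying an importance
weight $I(q)\cos^3\theta_d\,(1-\text{absorption})$, the $\cos^3$ factor
being the flat-detector solid angle. $q$ is computed from the exact
incident and scattered unit vectors, so instrumental smearing — divergence,
wavelength band, pixel size — emerges from the geometry rather than from a
convolution applied afterwards. The transmitted beam is omitted; the
beamstop (default 4×4 cm, sized to shadow the direct beam at all three
distances) zeroes the pixels it shadows. Absorption enters as a flat
per-event transmission factor with the discrete levels 0 and 10%; holder
thickness is metadata only. Pixel pitch is 5.25 mm (detector ≈ 0.76×1.34 m)
— chosen, with the beamstop and the wavelength band, as plausible values
for this instrument class since they are not fixed by the configuration
grid; all three are arguments of `instrument_config()`.

Simulation is deterministic given a seed (the compiled event loop consumes
the R RNG stream), to the point of bit-identical images.

**Reduction.** `azimuthal_average()` reports mean counts per $|q|$ annulus
(beamstop pixels excluded; empty annuli are flagged `NA`, never zero), with
Monte-Carlo standard errors from per-pixel summed squared weights when the
image carries them, else from the pixel scatter inside the annulus.
`smeared_intensity_curve()` is the analytic expectation of that curve: the
1-D kernel smeared by a per-axis Gaussian in scattering angle (variance
from the two uniform apertures and the in-pixel deposition,
$\sigma^2 = w_1^2/12L_c^2 + (w_2^2/12)(1/L_c+1/\mathrm{SDD})^2 +
p^2/12\,\mathrm{SDD}^2$, evaluated by 5-node Gauss–Hermite quadrature per
axis) and by the triangular wavelength band (9-node quadrature). The match
between the Monte-Carlo curve and this expectation, within Monte-Carlo
error bars bin by bin, is the package's simulator-fidelity test.

`azimuthal_uniformity_test()` referees isotropy: per-sector pixel means in
an annulus against their common mean, variance-weighted, on a
$\chi^2_{S-1}$ reference. Isotropic models pass at $\alpha = 0.01$;
a tightly oriented elliptical cylinder fails; the same cylinder with a full
$\Delta\theta = \pi$ orientation window passes again — anisotropic models
with unoriented ensembles produce isotropic patterns, which is exactly why
observing an isotropic pattern does not identify an isotropic model.

## Dataset factory

Exhaustive parameter grids are hopeless: $N = \prod_i n_i$ choices explode
to $2^{15} = 32768$ for a 15-parameter model at two values per parameter.
Parameters are instead sampled by latin hypercube: each continuous
dimension is stratified into $n$ equal bins of its sampling interval
$[\max(-3p_0, l_b), \min(3p_0, u_b)]$ (the printed rule; for positive
defaults with non-negative lower bounds the left arm collapses to $l_b$)
with exactly one point per bin — a tested design property, delegated to the
`lhs` package. Polydispersity spreads are additional LHS dimensions:
$\Delta r_i \in [0, r_i/2]$ relative to the drawn $r_i$, and
$\Delta\theta_i \in [0, \pi]$ so the orientation window spans everything
from fixed to fully disordered.

The sweep produces one image per (model, LHS point, absorption level,
configuration); per-record seeds are a deterministic integer mix of the
base seed with the record coordinates, so generation is reproducible and
embarrassingly parallel. Failures are flagged in metadata, never silently
dropped. The full published-scale plan (46 × 100 × 2 × 36) counts 331,200
records — the package verifies this arithmetic symbolically; desk-scale
plans generate hundreds to thousands.

**Cleaning** applies three rules in order: drop all-zero images; drop
images whose pixel standard deviation falls strictly below the empirical
0.02 quantile of per-image standard deviations; drop images whose maximum
pixel exceeds the empirical 0.99 quantile of per-image maxima. Quantiles
are type-7 order statistics computed on the set surviving the preceding
rules — the rules are sequential, so each threshold reflects the current
survivors — and ties survive. **Splitting** is label-stratified at
0.70/0.20/0.10 (train/test/validation) with largest-remainder rounding per
class; the proportions are configurable (a 0.95/validation-5% split is a
common alternative at larger scales). Partitions serialize to HDF5 (`data`
n×144×256 float, `target` n int) with a CSV metadata sibling; read∘write
is the identity.

## Preprocessing and network

Raw counts span orders of magnitude between configurations, so each image
is log-normalized, $x \leftarrow \log(x+1)/\mathrm{MaxLog}$, with
$\mathrm{MaxLog}$ the post-log maximum — the output is in $[0,1]$ with
maximum exactly 1, independent of counting statistics (the logarithm base
cancels in the ratio). Images are then resized 144×256 → 180×180 (the
square compromise between the two axes) by half-pixel-centred bilinear
interpolation; because interpolation averages, a final rescale restores the
unit maximum. Negative pixels are rejected, all-zero images raise an
explicit error (cleaning should have removed them). Preprocessing is
applied on the fly; stored partitions keep raw counts as the dataset of
record.

The classifier is a compact reference CNN: four blocks of 3×3 convolution
at stride 2 (16/32/64/128 channels; feature maps 90–45–23–12) →
per-channel batch normalization → ReLU, then global average pooling and a
C-way linear head (C = 46, so labels index the catalogue directly even
when only a subset of classes is present). Two choices in the block design
deserve comment. Batch normalization is essential here: the plain
conv–ReLU stack trains an order of magnitude more slowly from random
initialization at these data scales, and the from-scratch setting has no
pretrained weights to lean on (conv biases are folded into the BN shift).
Downsampling is done by the stride-2 convolution itself rather than by a
separate stride-2 max-pooling layer: the two are interchangeable as
spatial reductions, but the strided convolution computes each feature map
at the reduced resolution directly — four times fewer convolution
operations — and on this task it also converged faster and to higher
held-out accuracy than the pooled variant, so it is the reference block. Training minimizes the softmax cross-entropy
$l(x,y) = -\log(e^{\alpha_y}/\sum_c e^{\alpha_c})$ (log-sum-exp stabilised)
with Adam, mini-batches of 64, at most 30 epochs, recording per-epoch
train/test loss and accuracy. The package default learning rate is the
protocol value $10^{-5}$, appropriate for fine-tuning large pretrained
backbones; the desk-scale benchmark trains the compact network from random
initialization and uses $3\times10^{-3}$.

Two checkpoint rules are provided. The default keeps the weights with the
best test accuracy. The alternative, `checkpoint = "literal"`, keeps the
last epoch in which the test accuracy decreased relative to its previous
value — a rule sometimes quoted as an overfitting guard, but one that taken
literally keeps a *worse* epoch, which is why it is not the default. Ties in argmax and top-k rankings break toward
the lowest class index. Class imbalance after cleaning is left as is. One
seed governs weight initialization and batch shuffling; the compiled
implementation is single-threaded single-precision, so results are
reproducible on a given BLAS.

The ensemble averages the members' SoftMax vectors arithmetically;
`recommend()` preprocesses a raw image, ranks the catalogue by averaged
score, and reports the top-k with the uniform baseline $1/46 \approx
0.021$ plus each member's own ranking.

## Desk-scale benchmark and problem sizes

`run_benchmark()` is the package's end-to-end study at sizes a single CPU
handles in minutes: six visually distinct models (sphere, cylinder, dab,
broad peak, teubner strey, mass fractal) × 25 LHS points × 2 absorption
levels × 4 configurations spanning both wavelengths and all three distance
pairs = 200 images per model at $10^5$ events each, cleaned, split
0.70/0.20/0.10, three seed-varied members trained 12 epochs. The ensemble
reaches Top-1 ≥ 0.8 and Top-3 ≥ 0.95 on held-out data, and never falls
below its worst member. Class separability of the generated task was
verified independently (a random forest on 30×30 thumbnails classifies it
essentially perfectly), so the benchmark measures the network and pipeline
rather than an accident of the data. Other standing sizes: simulator
fidelity uses $10^6$-event images against the smeared analytic curve;
kernel-vs-oracle agreement is checked to $10^{-6}$ relative error;
orientation averages are validated against $10^6$-draw Monte Carlo.

## What the synthetic validation does and does not show

The generator emulates collimation and wavelength smearing, counting
statistics, polydispersity, orientational disorder, absorption and
beamstop shadowing — the features that make scattering-pattern
classification nontrivial. It does not emulate guide transport, gravity,
detector inhomogeneity or dead time, sample backgrounds (solvent,
incoherent), multiple scattering, or structure-factor effects outside the
dilute regime. Passing tests therefore establish that the pipeline is
internally correct and that the recommendation approach learns genuine
form-factor signatures under realistic instrumental smearing; they do not
by themselves establish accuracy on real measurements, where background
and instrument imperfections shift the image statistics. The 46-class,
331,200-record reproduction at $10^7$ events with GPU-scale backbones is
recorded as out of desk scale; the compact benchmark stands in for it.

## Known limitations

- Thirteen of 46 catalogue entries carry kernels; the rest are labelled
  placeholders (extensible registry).
- Intensities are relative; absolute cross-sections (cm$^{-1}$) are out of
  scope.
- The chi-square isotropy test is slightly conservative (per-sector
  variances absorb radial gradients), which is the safe direction for its
  use as a dichotomy check.
- Batch statistics are computed per 16-image GEMM group during training
  (ghost-batch behaviour); inference uses running statistics.
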
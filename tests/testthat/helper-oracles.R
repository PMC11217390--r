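# Independent numerical oracles, written as direct R transcriptions of the
# closed-form intensity expressions (separately from the package kernels),
# plus a deterministic instrument-smearing oracle and a cached toy
# classification task.

# ---- 1-D intensity oracles -------------------------------------------------

.o_phi <- function(x) 3 * (sin(x) - x * cos(x)) / x^3

oracle_iq <- list(
  "sphere" = function(p, q) {
    V <- 4 * pi / 3 * p[["radius"]]^3
    p[["scale"]] * V * (p[["contrast"]] * .o_phi(q * p[["radius"]]))^2 +
      p[["background"]]
  },
  "fuzzy sphere" = function(p, q) {
    V <- 4 * pi / 3 * p[["radius"]]^3
    amp <- p[["contrast"]] * .o_phi(q * p[["radius"]]) *
      exp(-q^2 * p[["fuzziness"]]^2 / 2)
    p[["scale"]] * V * amp^2 + p[["background"]]
  },
  "core shell sphere" = function(p, q) {
    rc <- p[["radius"]]; ro <- rc + p[["thickness"]]
    Vc <- 4 * pi / 3 * rc^3; Vo <- 4 * pi / 3 * ro^3
    FF <- p[["contrast_core"]] * Vc * .o_phi(q * rc) +
      p[["contrast_shell"]] * Vo * .o_phi(q * ro)
    p[["scale"]] * FF^2 / Vo + p[["background"]]
  },
  "mono gauss coil" = function(p, q) {
    x <- (q * p[["rg"]])^2
    p[["i_zero"]] * 2 * (exp(-x) + x - 1) / x^2 + p[["background"]]
  },
  "dab" = function(p, q) {
    L <- p[["cor_length"]]
    p[["scale"]] * L^3 / (1 + (q * L)^2)^2 + p[["background"]]
  },
  "broad peak" = function(p, q) {
    p[["porod_scale"]] / q^p[["porod_exp"]] +
      p[["lorentz_scale"]] /
        (1 + (abs(q - p[["peak_pos"]]) * p[["lorentz_length"]])^p[["lorentz_exp"]]) +
      p[["background"]]
  },
  "teubner strey" = function(p, q) {
    k2 <- (2 * pi / p[["d_spacing"]])^2
    ix2 <- 1 / p[["xi"]]^2
    a2 <- (k2 + ix2)^2
    c1 <- 2 * (ix2 - k2)
    p[["scale"]] * a2 / (a2 + c1 * q^2 + q^4) + p[["background"]]
  },
  "mass fractal" = function(p, q) {
    D <- p[["fractal_dim_mass"]]; z <- p[["cutoff_length"]]
    P <- .o_phi(q * p[["radius"]])^2
    S <- gamma(D - 1) * z^(D - 1) * sin((D - 1) * atan(q * z)) /
      (q * (1 + (q * z)^2)^((D - 1) / 2))
    p[["scale"]] * P * S + p[["background"]]
  },
  "fractal" = function(p, q) {
    R <- p[["radius"]]; D <- p[["fractal_dim"]]; xi <- p[["cor_length"]]
    V <- 4 * pi / 3 * R^3
    P <- p[["volfraction"]] * V * (p[["contrast"]] * .o_phi(q * R))^2
    S <- 1 + D * gamma(D - 1) * sin((D - 1) * atan(q * xi)) /
      ((q * R)^D * (1 + 1 / (q * xi)^2)^((D - 1) / 2))
    P * S + p[["background"]]
  })

# ---- fixed-orientation 2-D oracle (cylinder) -------------------------------

# |A(q, alpha)|^2 with A = contrast V sinc(q L cos(a)/2) * 2 J1(q R sin(a)) /
# (q R sin(a)), axis at polar theta / azimuth phi relative to the beam.
oracle_cylinder_iqxy <- function(p, qx, qy) {
  q <- sqrt(qx^2 + qy^2)
  nq <- cbind(qx, qy) / q
  ax <- c(sin(p[["theta"]]) * cos(p[["phi"]]),
          sin(p[["theta"]]) * sin(p[["phi"]]))
  ca <- pmin(1, pmax(-1, nq[, 1] * ax[1] + nq[, 2] * ax[2]))
  sa <- sqrt(1 - ca^2)
  R <- p[["radius"]]; L <- p[["length"]]
  V <- pi * R^2 * L
  sinc <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)
  j1c <- function(x) ifelse(abs(x) < 1e-8, 1, 2 * besselJ(x, 1) / x)
  A <- p[["contrast"]] * V * sinc(q * L * ca / 2) * j1c(q * R * sa)
  p[["scale"]] * A^2 / V + p[["background"]]
}

# brute-force Monte-Carlo orientation average of the cylinder oracle
oracle_cylinder_orient_mc <- function(p, q, n = 1e6, seed = 42) {
  set.seed(seed)
  u <- runif(n, -1, 1)           # cos(theta) uniform -> axis uniform on sphere
  ph <- runif(n, 0, 2 * pi)
  sa <- sqrt(1 - u^2)
  vapply(q, function(qi) {
    ca_q <- sa * cos(ph)         # q along x in the detector plane
    caq <- pmin(1, pmax(-1, ca_q))
    saq <- sqrt(1 - caq^2)
    R <- p[["radius"]]; L <- p[["length"]]
    V <- pi * R^2 * L
    sinc <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)
    j1c <- function(x) ifelse(abs(x) < 1e-8, 1, 2 * besselJ(x, 1) / x)
    A <- p[["contrast"]] * V * sinc(qi * L * caq / 2) * j1c(qi * R * saq)
    I <- p[["scale"]] * A^2 / V + p[["background"]]
    c(mean(I), sd(I) / sqrt(n))
  }, numeric(2))
}

# deterministic quadrature over a positive-truncated Gaussian radius
oracle_sphere_polydisperse <- function(p, dr, q) {
  norm <- 1 - pnorm(0, p[["radius"]], dr)
  vapply(q, function(qi) {
    stats::integrate(function(r) {
      pp <- p; # per-radius intensity weighted by the truncated density
      vapply(r, function(ri) {
        pr <- p; pr[["radius"]] <- ri
        oracle_iq[["sphere"]](pr, qi)
      }, numeric(1)) * dnorm(r, p[["radius"]], dr) / norm
    }, lower = 1e-6, upper = p[["radius"]] + 10 * dr,
    rel.tol = 1e-8)$value
  }, numeric(1))
}

# ---- instrument-smeared azimuthal-curve oracle -----------------------------

# Expected azimuthal-average curve for an isotropic model under the virtual
# instrument: per-pixel expectation of I(q) cos^3(theta) (1 - absorption)
# with the scattering-angle estimate smeared by collimation, in-pixel
# position and the triangular wavelength spread, averaged over each |q|
# annulus and scaled to counts per pixel.
oracle_smeared_curve <- function(model_name, p, config, n_events,
                                 absorption = 0, n_bins = 50) {
  nx <- config$nx; ny <- config$ny
  pitch <- config$pixel_m
  sdd <- config$sdd_m; lc <- config$collimation_m
  xc <- ((0:(nx - 1)) - config$beam_center[1]) * pitch
  yc <- ((0:(ny - 1)) - config$beam_center[2]) * pitch
  X <- matrix(rep(xc, times = ny), nx)
  Y <- matrix(rep(yc, each = nx), nx)
  mask <- beamstop_mask(config)
  use <- !mask
  ax <- X[use] / sdd
  ay <- Y[use] / sdd
  cos_t <- sdd / sqrt(X[use]^2 + Y[use]^2 + sdd^2)

  # angular smearing variance per axis: two slits + in-pixel deposition
  w1 <- c(config$slit_w_m, config$slit_h_m)
  var_ang <- function(w_slit) {
    (w_slit^2 / 12) / lc^2 +
      (w_slit^2 / 12) * (1 / lc + 1 / sdd)^2 +
      (pitch^2 / 12) / sdd^2
  }
  sx <- sqrt(var_ang(w1[1])); sy <- sqrt(var_ang(w1[2]))

  gh <- list(nodes = c(-2.0201828705, -0.9585724646, 0, 0.9585724646,
                       2.0201828705),
             weights = c(0.0199532421, 0.3936193232, 0.9453087205,
                         0.3936193232, 0.0199532421) / sqrt(pi))
  a_lam <- config$fwhm_frac * config$wavelength_A
  lam_nodes <- seq(-a_lam, a_lam, length.out = 9)
  lam_w <- (1 - abs(lam_nodes) / a_lam)
  lam_w <- lam_w / sum(lam_w)

  EI <- numeric(sum(use))
  oracle <- oracle_iq[[model_name]]
  for (i in seq_along(gh$nodes)) {
    dx <- sqrt(2) * sx * gh$nodes[i]
    for (j in seq_along(gh$nodes)) {
      dy <- sqrt(2) * sy * gh$nodes[j]
      wij <- gh$weights[i] * gh$weights[j] * sqrt(pi) * sqrt(pi) / pi
      rho <- sqrt((ax + dx)^2 + (ay + dy)^2)
      theta <- atan(rho)
      for (k in seq_along(lam_nodes)) {
        lam <- config$wavelength_A + lam_nodes[k]
        q <- 4 * pi / lam * sin(theta / 2)
        EI <- EI + wij * lam_w[k] * oracle(p, pmax(q, 1e-9))
      }
    }
  }
  e_pixel <- EI * cos_t^3 * (1 - absorption)

  qmap <- matrix(pixel_to_q(config,
                            row = rep(0:(nx - 1), times = ny),
                            col = rep(0:(ny - 1), each = nx))$q, nx, ny)
  breaks <- seq(0, max(qmap), length.out = n_bins + 1)
  bin <- cut(qmap[use], breaks, include.lowest = TRUE, labels = FALSE)
  scale <- n_events / (nx * ny)
  I_bin <- vapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NA_real_)
    scale * mean(e_pixel[sel])
  }, numeric(1))
  data.frame(q = (breaks[-1] + breaks[-length(breaks)]) / 2, I = I_bin)
}

# ---- cached toy classification task ----------------------------------------

.toy_env <- new.env(parent = emptyenv())

# two visually disjoint classes: spheres vs strongly oriented cylinders,
# random radii and instrument configs, preprocessed to the network input
toy_task <- function(n_per_class = 100, n_neutrons = 2e4) {
  key <- sprintf("toy_%d_%g", n_per_class, n_neutrons)
  if (!is.null(.toy_env[[key]])) return(.toy_env[[key]])
  set.seed(4242)
  cfg <- instrument_config(30)   # one setting: the classes differ by shape only
  mk <- function(i, model, params) {
    img <- simulate_pattern(model, params, n_neutrons = n_neutrons,
                            seed = 5000 + i, config = cfg)
    as.numeric(preprocess_image(img))
  }
  Xa <- t(vapply(seq_len(n_per_class), function(i)
    mk(i, "sphere", c(radius = runif(1, 30, 90))), numeric(32400)))
  Xb <- t(vapply(seq_len(n_per_class), function(i)
    mk(n_per_class + i, "cylinder",
       c(radius = runif(1, 10, 25), length = runif(1, 600, 1200),
         theta = pi / 2, phi = 0)), numeric(32400)))
  X <- rbind(Xa, Xb)
  y <- rep(c(39L, 13L), each = n_per_class)
  set.seed(77)
  idx <- sample(2 * n_per_class)
  n_tr <- floor(1.5 * n_per_class)
  out <- list(train = list(X = X[idx[1:n_tr], ], y = y[idx[1:n_tr]]),
              test = list(X = X[idx[(n_tr + 1):(2 * n_per_class)], ],
                          y = y[idx[(n_tr + 1):(2 * n_per_class)]]))
  .toy_env[[key]] <- out
  out
}

# nearest-centroid classifier: the separability oracle for the toy task
nearest_centroid_accuracy <- function(train, test) {
  labs <- sort(unique(train$y))
  centroids <- vapply(labs, function(l)
    colMeans(train$X[train$y == l, , drop = FALSE]), numeric(ncol(train$X)))
  d <- vapply(seq_along(labs), function(k)
    rowSums(sweep(test$X, 2, centroids[, k])^2), numeric(nrow(test$X)))
  mean(labs[max.col(-d)] == test$y)
}
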
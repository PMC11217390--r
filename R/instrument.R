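# Simplified virtual pinhole SANS beamline: configuration enumeration,
# pixel <-> q calibration, Monte-Carlo pattern simulation, and azimuthal
# reduction.

.DET_NX <- 144L   # horizontal pixels (first image axis)
.DET_NY <- 256L   # vertical pixels (second image axis)

.SLITS <- data.frame(
  slit_id = 1:3,
  slit_w_m = c(0.010, 0.012, 0.007),  # horizontal full aperture
  slit_h_m = c(0.010, 0.012, 0.010),  # vertical full aperture
  cell_cm = c(2, 2, 1))               # sample-cell width (metadata)

#' Enumerate the 36 instrument configurations
#'
#' The discrete configuration set of the virtual beamline: 2 wavelengths
#' (4.5 and 6 Angstrom) x 3 collimation/detector distance pairs (8m-1m,
#' 8m-8m, 20m-20m) x 3 slit settings x 2 sample-holder thicknesses (1, 2 mm),
#' in deterministic order (wavelength outermost, holder innermost).
#'
#' @return A 36-row `data.frame`, one row per configuration, `config_id`
#'   0..35.
#' @export
enumerate_configs <- function() {
  grid <- expand.grid(holder_mm = c(1, 2),
                      slit_id = 1:3,
                      dist = 1:3,
                      wavelength_A = c(4.5, 6.0))
  # expand.grid varies the first factor fastest = holder innermost
  dist_pairs <- cbind(collimation_m = c(8, 8, 20), sdd_m = c(1, 8, 20))
  data.frame(
    config_id = 0:35,
    wavelength_A = grid$wavelength_A,
    collimation_m = dist_pairs[grid$dist, "collimation_m"],
    sdd_m = dist_pairs[grid$dist, "sdd_m"],
    slit_id = grid$slit_id,
    slit_w_m = .SLITS$slit_w_m[grid$slit_id],
    slit_h_m = .SLITS$slit_h_m[grid$slit_id],
    cell_cm = .SLITS$cell_cm[grid$slit_id],
    holder_mm = grid$holder_mm)
}

#' Build a full instrument configuration
#'
#' Completes one row of [enumerate_configs()] with the geometry constants
#' (detector size and pitch, beam centre, beamstop, wavelength spread) that
#' are fixed across the configuration set but configurable here.
#'
#' @param config_id Integer 0..35, or a one-row data.frame as returned by
#'   [enumerate_configs()].
#' @param pixel_mm Detector pixel pitch (both axes), millimetre.
#' @param beamstop_cm Beamstop full widths (x, y), centimetre.
#' @param fwhm_frac Wavelength FWHM as a fraction of the nominal wavelength
#'   (triangular distribution).
#' @return Object of class `sans_config`.
#' @export
instrument_config <- function(config_id, pixel_mm = 5.25,
                              beamstop_cm = c(4, 4), fwhm_frac = 0.10) {
  cfgs <- enumerate_configs()
  if (is.data.frame(config_id)) {
    row <- config_id
  } else {
    stopifnot(config_id %in% cfgs$config_id)
    row <- cfgs[cfgs$config_id == config_id, ]
  }
  structure(c(as.list(row), list(
    nx = .DET_NX, ny = .DET_NY,
    pixel_m = pixel_mm * 1e-3,
    beam_center = c((.DET_NX - 1) / 2, (.DET_NY - 1) / 2),
    beamstop_m = beamstop_cm * 1e-2,
    fwhm_frac = fwhm_frac)), class = "sans_config")
}

#' @export
print.sans_config <- function(x, ...) {
  cat(sprintf(
    "<sans_config #%d> lambda %.1f A (FWHM %.0f%%), coll %gm / SDD %gm, slit %d (%.1fx%.1f cm), holder %d mm\n",
    x$config_id, x$wavelength_A, 100 * x$fwhm_frac, x$collimation_m, x$sdd_m,
    x$slit_id, 100 * x$slit_w_m, 100 * x$slit_h_m, x$holder_mm))
  invisible(x)
}

#' Detector pixel to scattering vector
#'
#' Converts pixel indices to momentum transfer using the scattering angle
#' `theta = atan(r / SDD)` and `|q| = (4 pi / lambda) sin(theta / 2)`.
#'
#' @param config A `sans_config`.
#' @param row,col 0-based pixel indices (vectors of equal length).
#' @return `data.frame` with `qx`, `qy`, `q` in 1/Angstrom.
#' @export
pixel_to_q <- function(config, row, col) {
  stopifnot(inherits(config, "sans_config"))
  stopifnot(all(row >= 0 & row < config$nx), all(col >= 0 & col < config$ny))
  sdd_A <- config$sdd_m * 1e10
  x <- (row - config$beam_center[1]) * config$pixel_m * 1e10
  y <- (col - config$beam_center[2]) * config$pixel_m * 1e10
  r <- sqrt(x^2 + y^2)
  theta <- atan(r / sdd_A)
  qmag <- 4 * pi / config$wavelength_A * sin(theta / 2)
  frac <- ifelse(r > 0, qmag / r, 0)
  data.frame(qx = x * frac, qy = y * frac, q = qmag)
}

# |q| of every pixel as an nx x ny matrix
.q_map <- function(config) {
  q <- pixel_to_q(config,
                  row = rep(0:(config$nx - 1), times = config$ny),
                  col = rep(0:(config$ny - 1), each = config$nx))
  matrix(q$q, config$nx, config$ny)
}

#' Beamstop shadow mask
#'
#' @param config A `sans_config`.
#' @return Logical `nx x ny` matrix, `TRUE` where the beamstop shadows the
#'   pixel centre.
#' @export
beamstop_mask <- function(config) {
  xc <- ((0:(config$nx - 1)) - config$beam_center[1]) * config$pixel_m
  yc <- ((0:(config$ny - 1)) - config$beam_center[2]) * config$pixel_m
  outer(abs(xc) <= config$beamstop_m[1] / 2,
        abs(yc) <= config$beamstop_m[2] / 2)
}

#' Direct-beam divergence at the detector plane
#'
#' Standard deviation (per axis, metres) of where the unscattered beam would
#' strike the detector, from the uniform-aperture geometry of the two
#' collimation slits: `x_d = x2 + SDD * (x2 - x1) / Lc` with `x1`, `x2`
#' uniform over the slit openings. Widening either aperture strictly
#' increases this width.
#'
#' @param config A `sans_config`.
#' @return Named numeric vector `c(x = , y = )` in metres.
#' @export
beam_divergence_sd <- function(config) {
  stopifnot(inherits(config, "sans_config"))
  f <- 1 + config$sdd_m / config$collimation_m
  g <- config$sdd_m / config$collimation_m
  v <- function(w) (w^2 / 12) * f^2 + (w^2 / 12) * g^2
  c(x = sqrt(v(config$slit_w_m)), y = sqrt(v(config$slit_h_m)))
}

#' Simulate a detector image for one virtual experiment
#'
#' Monte-Carlo ray tracing with forced scattering: each neutron draws a
#' wavelength from a triangular distribution, entry/exit points in the two
#' collimation slits, per-event polydisperse sizes and orientation angles,
#' and a target point uniform over the detector; it deposits an importance
#' weight proportional to `I(q) * dOmega * (1 - absorption)` in the hit
#' pixel. Pixels shadowed by the beamstop are zeroed. Deterministic for a
#' fixed `seed`.
#'
#' @inheritParams sas_Iq
#' @param poly A [poly_spec()] or `NULL`.
#' @param absorption Sample absorption, 0 or 0.10.
#' @param config A `sans_config` (or an integer config id).
#' @param n_neutrons Number of source events (>= 0).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param keep_sumsq Also accumulate per-pixel summed squared weights (for
#'   Monte-Carlo error bars in [azimuthal_average()]).
#' @return A `detector_image`: `nx x ny` matrix of non-negative counts with
#'   provenance attributes (`model`, `label`, `params`, `poly`, `absorption`,
#'   `config_id`, `n_neutrons`, `seed`).
#' @export
simulate_pattern <- function(model, params = NULL, poly = NULL,
                             absorption = 0, config = 0,
                             n_neutrons = 1e5, seed = NULL,
                             keep_sumsq = FALSE) {
  model <- .as_sas_model(model)
  if (!is.numeric(absorption) || !(absorption >= 0 && absorption < 1))
    stop("absorption must be in [0, 1)")
  if (!inherits(config, "sans_config")) config <- instrument_config(config)
  p <- .resolve_params(model, params)
  s <- .resolve_spreads(model, p, poly)
  stopifnot(n_neutrons >= 0)
  if (!is.null(seed)) set.seed(seed)
  res <- .simulate_pattern_cpp(
    model$label, unname(p), unname(s), .kind_codes(model),
    absorption,
    config$wavelength_A, config$fwhm_frac,
    config$collimation_m, config$sdd_m,
    c(config$slit_w_m, config$slit_h_m),
    c(config$slit_w_m, config$slit_h_m),
    config$nx, config$ny,
    config$pixel_m, config$pixel_m,
    config$beam_center[1], config$beam_center[2],
    config$beamstop_m,
    as.numeric(n_neutrons), isTRUE(keep_sumsq))
  img <- res$counts
  structure(img,
            class = c("detector_image", class(img)),
            sumsq = res$sumsq,
            model = model$name, label = model$label,
            params = p, poly = poly, absorption = absorption,
            config_id = config$config_id, config = config,
            n_neutrons = n_neutrons, seed = seed)
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf(
    "<detector_image> %dx%d, model '%s' (label %d), config %d, %g events, total counts %.4g\n",
    nrow(x), ncol(x), attr(x, "model"), attr(x, "label"),
    attr(x, "config_id"), attr(x, "n_neutrons"), sum(x)))
  invisible(x)
}

#' Azimuthal average of a detector image
#'
#' Mean counts per |q| annulus over pixels not shadowed by the beamstop.
#' The Monte-Carlo standard error per bin comes from the per-pixel summed
#' squared event weights when the image carries them (see
#' `keep_sumsq` in [simulate_pattern()]), otherwise from the pixel-to-pixel
#' scatter inside the annulus (which also absorbs the radial variation of
#' the intensity across the bin).
#'
#' @param image A `detector_image`, or a plain matrix.
#' @param config The `sans_config` used (taken from the image attributes if
#'   omitted).
#' @param n_bins Number of equal-width |q| bins (>= 2).
#' @return `data.frame` with `q` (bin centre, 1/Angstrom), `I`, `se`,
#'   `n_pixels`. Bins whose annulus contains no usable pixel have `I = NA`
#'   (flagged absent, not zero).
#' @export
azimuthal_average <- function(image, config = NULL, n_bins = 50) {
  if (is.null(config)) config <- attr(image, "config")
  stopifnot(inherits(config, "sans_config"), n_bins >= 2)
  qmap <- .q_map(config)
  mask <- beamstop_mask(config)
  sumsq <- attr(image, "sumsq")
  use <- !mask
  breaks <- seq(0, max(qmap), length.out = n_bins + 1)
  bin <- cut(qmap[use], breaks, include.lowest = TRUE, labels = FALSE)
  v <- as.numeric(image)[as.vector(use)]
  n_pix <- tabulate(bin, nbins = n_bins)
  tot <- vapply(seq_len(n_bins), function(b) sum(v[bin == b]), numeric(1))
  I <- ifelse(n_pix > 0, tot / n_pix, NA_real_)
  if (!is.null(sumsq)) {
    s2 <- as.numeric(sumsq)[as.vector(use)]
    se <- vapply(seq_len(n_bins), function(b)
      if (n_pix[b] > 0) sqrt(sum(s2[bin == b])) / n_pix[b] else NA_real_,
      numeric(1))
  } else {
    se <- vapply(seq_len(n_bins), function(b) {
      if (n_pix[b] > 1) sd(v[bin == b]) / sqrt(n_pix[b]) else NA_real_
    }, numeric(1))
  }
  data.frame(q = (breaks[-1] + breaks[-length(breaks)]) / 2,
             I = I, se = se, n_pixels = n_pix)
}

#' Resolution-smeared azimuthal intensity curve
#'
#' The analytic expectation of the azimuthal-average curve a Monte-Carlo run
#' of [simulate_pattern()] converges to: the model's 1-D intensity smeared
#' by the instrument resolution (slit collimation and in-pixel deposition as
#' a per-axis Gaussian in scattering angle; the triangular wavelength
#' spread by quadrature), weighted by the flat-detector solid-angle factor
#' and averaged over each |q| annulus. The scale matches an image
#' accumulated from `n_events` forced-scattering events.
#'
#' @inheritParams sas_Iq
#' @param config A `sans_config`.
#' @param n_bins Number of |q| bins (match the [azimuthal_average()] call).
#' @param n_events Event count of the image being compared.
#' @param absorption Sample absorption.
#' @return `data.frame` with `q` and `I` (NA for empty annuli).
#' @export
smeared_intensity_curve <- function(model, params = NULL, config,
                                    n_bins = 50, n_events = 1,
                                    absorption = 0) {
  stopifnot(inherits(config, "sans_config"))
  model <- .as_sas_model(model)
  p <- .resolve_params(model, params)
  nx <- config$nx; ny <- config$ny
  pitch <- config$pixel_m
  sdd <- config$sdd_m; lc <- config$collimation_m
  xc <- ((0:(nx - 1)) - config$beam_center[1]) * pitch
  yc <- ((0:(ny - 1)) - config$beam_center[2]) * pitch
  X <- matrix(rep(xc, times = ny), nx)
  Y <- matrix(rep(yc, each = nx), nx)
  use <- !beamstop_mask(config)
  ax <- X[use] / sdd; ay <- Y[use] / sdd
  cos_t <- sdd / sqrt(X[use]^2 + Y[use]^2 + sdd^2)

  var_ang <- function(w) (w^2 / 12) / lc^2 +
    (w^2 / 12) * (1 / lc + 1 / sdd)^2 + (pitch^2 / 12) / sdd^2
  sx <- sqrt(var_ang(config$slit_w_m)); sy <- sqrt(var_ang(config$slit_h_m))

  gh_x <- c(-2.0201828705, -0.9585724646, 0, 0.9585724646, 2.0201828705)
  gh_w <- c(0.0199532421, 0.3936193232, 0.9453087205, 0.3936193232,
            0.0199532421) / sqrt(pi)
  a_lam <- config$fwhm_frac * config$wavelength_A
  lam_nodes <- seq(-a_lam, a_lam, length.out = 9)
  lam_w <- 1 - abs(lam_nodes) / a_lam
  lam_w <- lam_w / sum(lam_w)

  EI <- numeric(sum(use))
  for (i in seq_along(gh_x)) {
    dx <- sqrt(2) * sx * gh_x[i]
    for (j in seq_along(gh_x)) {
      dy <- sqrt(2) * sy * gh_x[j]
      theta <- atan(sqrt((ax + dx)^2 + (ay + dy)^2))
      for (k in seq_along(lam_nodes)) {
        lam <- config$wavelength_A + lam_nodes[k]
        q <- pmax(4 * pi / lam * sin(theta / 2), 1e-9)
        EI <- EI + gh_w[i] * gh_w[j] * lam_w[k] * sas_Iq(model, p, q)
      }
    }
  }
  e_pixel <- EI * cos_t^3 * (1 - absorption)
  qmap <- .q_map(config)
  breaks <- seq(0, max(qmap), length.out = n_bins + 1)
  bin <- cut(qmap[use], breaks, include.lowest = TRUE, labels = FALSE)
  I <- vapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NA_real_)
    n_events / (nx * ny) * mean(e_pixel[sel])
  }, numeric(1))
  data.frame(q = (breaks[-1] + breaks[-length(breaks)]) / 2, I = I)
}

#' Azimuthal-uniformity chi-square test
#'
#' Tests whether the counts in an annulus are uniformly distributed over
#' azimuthal sectors: the isotropy signature of an unoriented sample.
#' The statistic compares per-sector pixel-mean intensities against their
#' common mean, with per-sector variances estimated from the pixel scatter;
#' it is referred to a chi-square with (sectors - 1) degrees of freedom.
#'
#' @param image A `detector_image` (or matrix with `config`).
#' @inheritParams azimuthal_average
#' @param q_range Annulus `[qmin, qmax]` in 1/Angstrom; defaults to the
#'   central 15-60% of the detector q range.
#' @param n_sectors Number of azimuthal sectors.
#' @return List with `statistic`, `df`, `p.value`, `sector_means`.
#' @export
azimuthal_uniformity_test <- function(image, config = NULL,
                                      q_range = NULL, n_sectors = 12) {
  if (is.null(config)) config <- attr(image, "config")
  stopifnot(inherits(config, "sans_config"))
  qmap <- .q_map(config)
  mask <- beamstop_mask(config)
  if (is.null(q_range)) {
    # widest fully-sampled annulus: radii up to the nearest detector edge
    qedge <- min(qmap[c(1, config$nx), ceiling(config$ny / 2)],
                 qmap[ceiling(config$nx / 2), c(1, config$ny)])
    q_range <- c(0.15, 0.6) * qedge
  }
  xc <- ((0:(config$nx - 1)) - config$beam_center[1])
  yc <- ((0:(config$ny - 1)) - config$beam_center[2])
  ang <- atan2(matrix(rep(yc, each = config$nx), config$nx),
               matrix(rep(xc, times = config$ny), config$nx))
  use <- !mask & qmap >= q_range[1] & qmap <= q_range[2]
  sector <- findInterval(ang[use], seq(-pi, pi, length.out = n_sectors + 1),
                         rightmost.closed = TRUE)
  v <- as.numeric(image)[as.vector(use)]
  means <- tapply(v, sector, mean)
  vars <- tapply(v, sector, function(z) stats::var(z) / length(z))
  mu <- mean(means)
  stat <- sum((means - mu)^2 / vars)
  df <- length(means) - 1
  list(statistic = unname(stat), df = df,
       p.value = unname(stats::pchisq(stat, df, lower.tail = FALSE)),
       sector_means = means)
}
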
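# Kernel evaluation, parameter validation, orientation and polydispersity
# averaging.

.as_sas_model <- function(model) {
  if (inherits(model, "sas_model")) model else sas_model(model)
}

# Resolve user parameters (named vector/list, defaults filled) into the fixed
# schema order; validates bounds, naming the offending parameter.
.resolve_params <- function(model, params) {
  sch <- model$params
  p <- sch$p0
  names(p) <- sch$name
  if (!is.null(params) && length(params)) {
    params <- unlist(params)
    if (is.null(names(params)) || any(!nzchar(names(params)))) {
      if (length(params) != nrow(sch))
        stop("unnamed parameter vector must have length ", nrow(sch))
      p[] <- as.numeric(params)
    } else {
      unknown <- setdiff(names(params), sch$name)
      if (length(unknown))
        stop("unknown parameter(s) for model '", model$name, "': ",
             paste(unknown, collapse = ", "))
      p[names(params)] <- as.numeric(params)
    }
  }
  bad <- which(p < sch$lb | p > sch$ub)
  if (length(bad))
    stop("parameter out of bounds for model '", model$name, "': ",
         paste(sprintf("%s = %g not in [%g, %g]", sch$name[bad], p[bad],
                       sch$lb[bad], sch$ub[bad]), collapse = "; "))
  p
}

#' Evaluate the 1-D scattering intensity I(q)
#'
#' Isotropic models are evaluated directly from their analytic kernel;
#' anisotropic models return the orientation-averaged (uniform over the
#' sphere) 1-D intensity.
#'
#' @param model Model name or [sas_model()] object.
#' @param params Named numeric vector of parameters (unspecified parameters
#'   take the schema defaults `p0`).
#' @param q Positive scattering-vector magnitudes, 1/Angstrom.
#' @return Numeric vector of intensities (arbitrary units), same length as `q`.
#' @examples
#' sas_Iq("sphere", c(radius = 60), q = c(0.01, 0.05, 0.1))
#' @export
sas_Iq <- function(model, params = NULL, q) {
  model <- .as_sas_model(model)
  p <- .resolve_params(model, params)
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q must be positive and finite")
  .sas_iq_cpp(model$label, unname(p), as.numeric(q))
}

#' Evaluate the 2-D scattering intensity I(qx, qy) at fixed orientation
#'
#' Only anisotropic models support a fixed-orientation 2-D evaluation; the
#' orientation angles (polar `theta` and azimuth `phi` of the particle
#' principal axis relative to the beam, plus `psi` for elliptical cross
#' sections) are model parameters and can be overridden via `orientation`.
#'
#' @inheritParams sas_Iq
#' @param qx,qy In-plane scattering-vector components, 1/Angstrom.
#' @param orientation Optional named numeric vector overriding the
#'   orientation parameters, e.g. `c(theta = pi/2, phi = 0)`.
#' @return Numeric vector of intensities (arbitrary units).
#' @export
sas_Iqxy <- function(model, params = NULL, qx, qy, orientation = NULL) {
  model <- .as_sas_model(model)
  if (!model$anisotropic)
    stop("model '", model$name, "' is strictly isotropic: ",
         "2-D fixed-orientation evaluation is unsupported")
  if (!is.null(orientation)) {
    params <- c(unlist(params), unlist(orientation))
    params <- params[!duplicated(names(params), fromLast = TRUE)]
  }
  p <- .resolve_params(model, params)
  if (length(qx) != length(qy)) stop("qx and qy must have equal length")
  .sas_iqxy_cpp(model$label, unname(p), as.numeric(qx), as.numeric(qy))
}

#' Uniform-over-sphere orientation average
#'
#' Averages the fixed-orientation 2-D kernel over a uniform distribution of
#' the particle axis on the sphere (and over the cross-section rotation for
#' elliptical sections), by Gauss-Legendre quadrature in the polar cosine and
#' midpoint rule in the azimuths. Converges with `n_nodes` to the model's
#' 1-D intensity.
#'
#' @inheritParams sas_Iq
#' @param n_nodes Number of polar quadrature nodes (>= 8).
#' @return Numeric vector of orientation-averaged intensities at `q`.
#' @export
orientation_average <- function(model, params = NULL, q, n_nodes = 32) {
  model <- .as_sas_model(model)
  if (!model$anisotropic)
    stop("model '", model$name, "' is isotropic; orientation average is moot")
  p <- .resolve_params(model, params)
  if (n_nodes < 8) stop("n_nodes must be >= 8")
  .sas_orient_avg_cpp(model$label, unname(p), as.numeric(q), as.integer(n_nodes))
}

#' Polydispersity and orientational-distribution specification
#'
#' Size parameters `r` follow positive-truncated Gaussians centred at the
#' sampled value with standard deviation `dr` (0 = monodisperse, up to `r/2`
#' = very polydisperse). Orientation angles follow uniform distributions on
#' `[theta - dtheta, theta + dtheta]`.
#'
#' @param dr Named numeric vector of Gaussian standard deviations for
#'   polydispersity-eligible length parameters (Angstrom).
#' @param dtheta Named numeric vector of uniform half-widths for orientation
#'   angle parameters (radian).
#' @return Object of class `sas_poly`.
#' @examples
#' poly_spec(dr = c(radius = 10), dtheta = c(theta = 0.2))
#' @export
poly_spec <- function(dr = numeric(0), dtheta = numeric(0)) {
  if (length(dr) && (is.null(names(dr)) || any(!nzchar(names(dr)))))
    stop("dr must be a named vector")
  if (length(dtheta) && (is.null(names(dtheta)) || any(!nzchar(names(dtheta)))))
    stop("dtheta must be a named vector")
  if (any(dr < 0) || any(dtheta < 0)) stop("spreads must be >= 0")
  structure(list(dr = dr, dtheta = dtheta), class = "sas_poly")
}

# spreads vector aligned with the schema; checks the dr <= r/2 invariant
.resolve_spreads <- function(model, p, poly) {
  sch <- model$params
  s <- rep(0, nrow(sch))
  names(s) <- sch$name
  if (is.null(poly)) return(s)
  stopifnot(inherits(poly, "sas_poly"))
  for (nm in names(poly$dr)) {
    i <- match(nm, sch$name)
    if (is.na(i) || !sch$poly[i])
      stop("parameter '", nm, "' of model '", model$name,
           "' is not polydispersity-eligible")
    if (poly$dr[[nm]] > p[[nm]] / 2)
      stop("spread for '", nm, "' exceeds r/2 = ", p[[nm]] / 2)
    s[i] <- poly$dr[[nm]]
  }
  for (nm in names(poly$dtheta)) {
    i <- match(nm, sch$name)
    if (is.na(i) || sch$kind[i] != "angle")
      stop("parameter '", nm, "' of model '", model$name,
           "' is not an orientation angle")
    s[i] <- poly$dtheta[[nm]]
  }
  s
}

# integer codes the C++ side uses to decide the per-event draw
.kind_codes <- function(model) {
  sch <- model$params
  ifelse(sch$kind == "angle", 2L, ifelse(sch$poly, 1L, 0L))
}

#' Monte-Carlo polydispersity / orientation average
#'
#' Expectation of the intensity over positive-truncated Gaussian size draws
#' and uniform orientation-angle draws, estimated with `n_draws` Monte-Carlo
#' samples. With all spreads zero this reduces exactly to the monodisperse
#' (oriented) kernel value. Deterministic for a fixed `seed`.
#'
#' @inheritParams sas_Iq
#' @param poly A [poly_spec()] (or `NULL` for monodisperse).
#' @param qx,qy Optional in-plane components for a 2-D (anisotropic)
#'   evaluation; otherwise supply the 1-D magnitudes in `q`.
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `I` (mean) and `se` (Monte-Carlo
#'   standard error).
#' @export
polydisperse_average <- function(model, params = NULL, poly = NULL,
                                 q = NULL, qx = NULL, qy = NULL,
                                 n_draws = 10000, seed = 1) {
  model <- .as_sas_model(model)
  p <- .resolve_params(model, params)
  s <- .resolve_spreads(model, p, poly)
  stopifnot(n_draws >= 1)
  planar <- !is.null(qx)
  if (planar) {
    stopifnot(length(qx) == length(qy))
  } else {
    stopifnot(!is.null(q))
    qx <- as.numeric(q); qy <- numeric(length(q))
  }
  set.seed(seed)
  m <- .poly_avg_cpp(model$label, unname(p), unname(s), .kind_codes(model),
                     as.numeric(qx), as.numeric(qy), planar,
                     as.numeric(n_draws))
  data.frame(I = m[, 1], se = m[, 2])
}

#' Latin-hypercube sampling bounds for a model's parameters
#'
#' Each continuous parameter is sampled in the interval
#' `[max(-3 * p0, lb), min(3 * p0, ub)]` centred (in the sense of the rule's
#' construction) on the schema default `p0`.
#'
#' @inheritParams sas_Iq
#' @return A `data.frame` with columns `name`, `lower`, `upper`.
#' @examples
#' sampling_bounds("sphere")
#' @export
sampling_bounds <- function(model) {
  model <- .as_sas_model(model)
  sch <- model$params
  lower <- pmax(-3 * sch$p0, sch$lb)
  upper <- pmin(3 * sch$p0, sch$ub)
  bad <- which(lower > upper)
  if (length(bad))
    stop("empty sampling interval for parameter(s): ",
         paste(sprintf("%s [%g, %g]", sch$name[bad], lower[bad], upper[bad]),
               collapse = "; "))
  data.frame(name = sch$name, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}
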
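# Dataset factory: combinatorics, latin-hypercube parameter sampling, the
# virtual-experiment sweep, quantile cleaning and stratified splitting.

#' Number of parameter combinations
#'
#' Exact product `N = prod(n_i)` of the per-parameter choice counts: the size
#' of an exhaustive grid, motivating stratified (latin-hypercube) sampling
#' instead.
#'
#' @param choices Integer vector of choices per parameter (all >= 1); an
#'   empty vector gives the empty product 1.
#' @return The exact integer product (as a double; an error is raised beyond
#'   2^53 where doubles lose exactness).
#' @examples
#' combinatorial_size(rep(2, 15))  # 32768
#' @export
combinatorial_size <- function(choices) {
  if (length(choices) == 0) return(1)
  if (any(!is.finite(choices)) || any(choices < 1) ||
      any(choices != floor(choices)))
    stop("all choice counts must be integers >= 1")
  n <- prod(as.numeric(choices))
  if (n > 2^53) stop("combination count exceeds exact integer range")
  n
}

#' Latin-hypercube sample of a model's parameter space
#'
#' Draws `n_points` parameter sets with each continuous dimension stratified
#' into `n_points` equal-width bins of its [sampling_bounds()] interval,
#' exactly one sample per bin. Polydispersity spreads are additional LHS
#' dimensions: for each polydispersity-eligible size parameter `r` a spread
#' in `[0, r/2]` (relative to that draw's `r`), and for each orientation
#' angle a uniform half-width in `[0, pi]`.
#'
#' @inheritParams sas_Iq
#' @param n_points Number of parameter sets (>= 1).
#' @param seed Integer seed.
#' @return List of length `n_points`; each element has `params` (named
#'   vector) and `poly` (a [poly_spec()]). The unit-hypercube design is
#'   attached as attribute `"unit"` (columns named after the dimensions).
#' @export
lhs_sample <- function(model, n_points = 100, seed = 1) {
  model <- .as_sas_model(model)
  stopifnot(n_points >= 1)
  b <- sampling_bounds(model)
  sch <- model$params
  poly_r <- sch$name[sch$poly]
  poly_th <- sch$name[sch$kind == "angle"]
  dims <- c(b$name, paste0("d", poly_r, recycle0 = TRUE),
            paste0("d", poly_th, recycle0 = TRUE))
  set.seed(seed)
  u <- lhs::randomLHS(n_points, length(dims))
  colnames(u) <- dims
  out <- lapply(seq_len(n_points), function(i) {
    p <- b$lower + u[i, seq_len(nrow(b))] * (b$upper - b$lower)
    names(p) <- b$name
    dr <- setNames(u[i, paste0("d", poly_r, recycle0 = TRUE)] * p[poly_r] / 2,
                   poly_r)
    dth <- setNames(u[i, paste0("d", poly_th, recycle0 = TRUE)] * pi, poly_th)
    list(params = p, poly = poly_spec(dr = dr, dtheta = dth))
  })
  attr(out, "unit") <- u
  out
}

#' Define a virtual-experiment sampling plan
#'
#' @param models Character vector of implemented model names.
#' @param points_per_model Latin-hypercube points per model.
#' @param absorption Absorption levels (default the discrete set 0 and 10%).
#' @param configs Integer config ids (subset of 0..35) or a data.frame from
#'   [enumerate_configs()].
#' @param n_neutrons Source events per simulation.
#' @param seed Base seed; per-record seeds are derived deterministically.
#' @return Object of class `sampling_plan` with an `expected_size` field
#'   equal to `models x points x absorptions x configs`.
#' @examples
#' plan <- sampling_plan(c("sphere", "dab"), points_per_model = 3,
#'                       configs = c(0, 18))
#' plan$expected_size  # 2 * 3 * 2 * 2 = 24
#' @export
sampling_plan <- function(models, points_per_model = 100,
                          absorption = c(0, 0.10), configs = 0:35,
                          n_neutrons = 1e5, seed = 1) {
  if (is.data.frame(configs)) configs <- configs$config_id
  stopifnot(length(models) >= 1, points_per_model >= 1,
            all(configs %in% 0:35), length(absorption) >= 1)
  structure(list(
    models = models, points_per_model = as.integer(points_per_model),
    absorption = absorption, configs = as.integer(configs),
    n_neutrons = n_neutrons, seed = as.integer(seed),
    expected_size = length(models) * points_per_model *
      length(absorption) * length(configs)), class = "sampling_plan")
}

#' Expected raw size of the full-catalogue sweep
#'
#' Convenience wrapper: the complete sweep over the 46-model catalogue, 100
#' latin-hypercube points per model, 2 absorption levels and 36 instrument
#' configurations has 46 * 100 * 2 * 36 = 331,200 records. Computed from the
#' plan arithmetic without generating anything.
#'
#' @return The expected record count of the full-catalogue plan.
#' @export
full_sweep_size <- function() {
  nrow(sas_models()) * 100 * 2 * length(enumerate_configs()$config_id)
}

# deterministic per-record seed below 2^31 - 1
.record_seed <- function(base, label, point, absorption, config_id) {
  m <- 2147483647
  s <- (as.numeric(base) %% m)
  s <- (s * 1103515245 + 12345 + label) %% m
  s <- (s * 1103515245 + 12345 + point) %% m
  s <- (s * 1103515245 + 12345 + config_id) %% m
  s <- (s * 1103515245 + 12345 + as.integer(absorption > 0)) %% m
  as.integer(s %% (m - 1)) + 1L
}

#' Run the virtual-experiment sweep of a sampling plan
#'
#' Simulates one detector image per (model, latin-hypercube point,
#' absorption level, instrument configuration). Individual simulation
#' failures are flagged in the metadata (`flagged = TRUE`, zero image), not
#' silently dropped. Fully deterministic for a fixed plan seed.
#'
#' @param plan A [sampling_plan()].
#' @param verbose Print progress.
#' @return A `sans_dataset`: list with `data` (n x 144 x 256 array),
#'   `target` (integer labels) and `metadata` (one row per record).
#' @export
generate_dataset <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "sampling_plan"))
  n <- plan$expected_size
  specs <- lapply(plan$models, sas_model)
  samples <- lapply(seq_along(specs), function(i)
    lhs_sample(specs[[i]], plan$points_per_model,
               seed = .record_seed(plan$seed, specs[[i]]$label, 0, 0, 0)))
  cfgs <- lapply(plan$configs, instrument_config)

  data <- array(0, dim = c(n, .DET_NX, .DET_NY))
  target <- integer(n)
  meta <- vector("list", n)
  r <- 0L
  for (i in seq_along(specs)) {
    mod <- specs[[i]]
    for (pt in seq_len(plan$points_per_model)) {
      smp <- samples[[i]][[pt]]
      for (ab in plan$absorption) {
        for (cf in cfgs) {
          r <- r + 1L
          seed_r <- .record_seed(plan$seed, mod$label, pt, ab, cf$config_id)
          img <- tryCatch(
            simulate_pattern(mod, smp$params, smp$poly, ab, cf,
                             plan$n_neutrons, seed = seed_r),
            error = function(e) NULL)
          flagged <- is.null(img)
          if (!flagged) data[r, , ] <- unclass(img)
          target[r] <- mod$label
          meta[[r]] <- c(
            list(model = mod$name, label = mod$label,
                 config_id = cf$config_id,
                 wavelength_A = cf$wavelength_A,
                 collimation_m = cf$collimation_m, sdd_m = cf$sdd_m,
                 slit_id = cf$slit_id, holder_mm = cf$holder_mm,
                 absorption = ab, seed = seed_r, flagged = flagged),
            setNames(as.list(smp$params),
                     paste0("param:", names(smp$params), recycle0 = TRUE)),
            setNames(as.list(smp$poly$dr),
                     paste0("dparam:", names(smp$poly$dr), recycle0 = TRUE)),
            setNames(as.list(smp$poly$dtheta),
                     paste0("dparam:", names(smp$poly$dtheta),
                            recycle0 = TRUE)))
        }
      }
      if (verbose) message(sprintf("model %s: point %d/%d", mod$name, pt,
                                   plan$points_per_model))
    }
  }
  metadata <- .rbind_fill(meta)
  structure(list(data = data, target = target, metadata = metadata),
            class = "sans_dataset")
}

# rbind a list of named lists, filling missing columns with NA
.rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  out <- lapply(cols, function(cn) {
    vals <- lapply(rows, function(r) r[[cn]])
    proto <- vals[[which(!vapply(vals, is.null, logical(1)))[1]]]
    miss <- if (is.character(proto)) NA_character_
            else if (is.logical(proto)) NA
            else NA_real_
    unlist(lapply(vals, function(v) if (is.null(v)) miss else v),
           use.names = FALSE)
  })
  names(out) <- cols
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.sans_dataset <- function(x, ...) {
  cat(sprintf("<sans_dataset> %d records, %d classes, %dx%d pixels\n",
              length(x$target), length(unique(x$target)),
              dim(x$data)[2], dim(x$data)[3]))
  invisible(x)
}

#' Clean a generated dataset
#'
#' Applies, in order: (a) removal of all-zero images; (b) removal of images
#' whose pixel standard deviation lies strictly below the empirical 0.02
#' quantile of the per-image standard deviations (low-statistics images);
#' (c) removal of images whose maximum pixel lies strictly above the
#' empirical 0.99 quantile of the per-image maxima (saturated images).
#' Quantiles are computed on the set surviving the preceding rules; ties
#' survive.
#'
#' @param ds A `sans_dataset`.
#' @param sd_quantile,max_quantile The two cleaning quantiles.
#' @return List with `dataset` (the filtered `sans_dataset`) and `report`
#'   (counts removed per rule).
#' @export
clean_dataset <- function(ds, sd_quantile = 0.02, max_quantile = 0.99) {
  stopifnot(inherits(ds, "sans_dataset"))
  n <- length(ds$target)
  if (n == 0) stop("empty collection")
  sds <- apply(ds$data, 1, sd)
  maxs <- apply(ds$data, 1, max)
  zero <- apply(ds$data, 1, function(m) all(m == 0))

  keep <- !zero
  q_sd <- quantile(sds[keep], sd_quantile, names = FALSE, type = 7)
  low <- keep & (sds < q_sd)
  keep <- keep & !low
  q_max <- quantile(maxs[keep], max_quantile, names = FALSE, type = 7)
  high <- keep & (maxs > q_max)
  keep <- keep & !high

  if (!any(keep)) stop("cleaning removed every image")
  out <- structure(list(
    data = ds$data[keep, , , drop = FALSE],
    target = ds$target[keep],
    metadata = ds$metadata[keep, , drop = FALSE]), class = "sans_dataset")
  rownames(out$metadata) <- NULL
  list(dataset = out,
       report = list(n_input = n,
                     removed_zero = sum(zero),
                     removed_low_sd = sum(low),
                     removed_high_max = sum(high),
                     sd_threshold = q_sd, max_threshold = q_max,
                     n_kept = sum(keep)))
}

#' Label-stratified train/test/validation split
#'
#' @param ds A `sans_dataset`.
#' @param proportions Positive, summing to 1; named train/test/validation.
#' @param seed Integer seed.
#' @return Named list of three `sans_partition` objects (train, test,
#'   validation). Classes with fewer records than partitions are kept wholly
#'   in train, with a warning.
#' @export
split_dataset <- function(ds, proportions = c(train = 0.70, test = 0.20,
                                              validation = 0.10),
                          seed = 1) {
  stopifnot(inherits(ds, "sans_dataset"))
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must be non-negative and sum to 1")
  if (is.null(names(proportions)))
    names(proportions) <- c("train", "test", "validation")
  set.seed(seed)
  nparts <- length(proportions)
  assign <- integer(length(ds$target))
  for (lab in unique(ds$target)) {
    idx <- which(ds$target == lab)
    nc <- length(idx)
    if (nc < nparts && any(proportions[-1] > 0)) {
      warning("class ", lab, " has only ", nc,
              " record(s); kept wholly in train")
      assign[idx] <- 1L
      next
    }
    idx <- sample(idx)
    counts <- floor(nc * proportions)
    rem <- nc - sum(counts)
    if (rem > 0) {
      frac <- nc * proportions - counts
      extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    assign[idx] <- rep(seq_len(nparts), times = counts)
  }
  parts <- lapply(seq_len(nparts), function(k) {
    sel <- assign == k
    structure(list(
      name = names(proportions)[k],
      data = ds$data[sel, , , drop = FALSE],
      target = ds$target[sel],
      metadata = {
        m <- ds$metadata[sel, , drop = FALSE]; rownames(m) <- NULL; m
      }), class = "sans_partition")
  })
  names(parts) <- names(proportions)
  parts
}

#' @export
print.sans_partition <- function(x, ...) {
  cat(sprintf("<sans_partition '%s'> %d records, %d classes\n",
              x$name, length(x$target), length(unique(x$target))))
  invisible(x)
}
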
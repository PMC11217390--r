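# Virtual beamline: configurations, q calibration, Monte-Carlo simulation.

test_that("configuration set is the 2 x 3 x 3 x 2 grid in stable order", {
  cfgs <- enumerate_configs()
  expect_equal(nrow(cfgs), 36)
  expect_identical(cfgs$config_id, 0:35)
  expect_setequal(unique(cfgs$wavelength_A), c(4.5, 6.0))
  expect_setequal(unique(paste(cfgs$collimation_m, cfgs$sdd_m)),
                  c("8 1", "8 8", "20 20"))
  expect_setequal(unique(cfgs$holder_mm), c(1, 2))
  key <- do.call(paste, cfgs[, -1])
  expect_false(any(duplicated(key)))
  # wavelength outermost, holder innermost
  expect_equal(cfgs$wavelength_A, rep(c(4.5, 6.0), each = 18))
  expect_equal(cfgs$holder_mm, rep(c(1, 2), times = 18))
  expect_identical(cfgs, enumerate_configs())
})

test_that("pixel-to-q calibration: zero at beam centre, known value, monotone", {
  cfg <- instrument_config(enumerate_configs()[
    enumerate_configs()$wavelength_A == 6 & enumerate_configs()$sdd_m == 8, ][1, ])
  ctr <- pixel_to_q(cfg, 71.5, 127.5)
  expect_equal(unlist(ctr), c(qx = 0, qy = 0, q = 0))
  # radial offset 0.1 m at SDD 8 m, lambda 6 A
  row <- 71.5 + 0.1 / cfg$pixel_m
  q <- pixel_to_q(cfg, row, 127.5)$q
  expect_equal(q, 4 * pi / 6 * sin(atan(0.1 / 8) / 2) * 1e-10 * 1e10,
               tolerance = 1e-6)
  expect_equal(q, 0.01309, tolerance = 1e-3)
  # monotone along a detector ray
  qs <- pixel_to_q(cfg, seq(72, 143), rep(127.5, 72))$q
  expect_true(all(diff(qs) > 0))
})

test_that("simulation honours the empty-stream, non-negativity and determinism contracts", {
  cfg <- instrument_config(30)
  z <- simulate_pattern("sphere", c(radius = 50), n_neutrons = 0, seed = 1,
                        config = cfg)
  expect_equal(dim(z), c(144, 256))
  expect_true(all(z == 0))

  a <- simulate_pattern("sphere", c(radius = 50), n_neutrons = 2e4, seed = 9,
                        config = cfg)
  b <- simulate_pattern("sphere", c(radius = 50), n_neutrons = 2e4, seed = 9,
                        config = cfg)
  expect_identical(unclass(a)[, ], unclass(b)[, ])   # bit-identical
  expect_true(all(a >= 0))
  expect_true(all(is.finite(a)))
  # beamstop shadow is zero
  expect_true(all(a[beamstop_mask(cfg)] == 0))
  # absorption scales every weight by (1 - 0.10)
  c10 <- simulate_pattern("sphere", c(radius = 50), absorption = 0.10,
                          n_neutrons = 2e4, seed = 9, config = cfg)
  expect_equal(unclass(c10)[, ], unclass(a)[, ] * 0.9, tolerance = 1e-12)
})

test_that("widening the slit apertures broadens the direct-beam divergence", {
  sds <- vapply(c(0.007, 0.010, 0.012), function(w) {
    cfg <- instrument_config(0)
    cfg$slit_w_m <- w
    beam_divergence_sd(cfg)["x"]
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
  # and the S1 < S2 ordering holds for the stock configs (same distances)
  expect_lt(beam_divergence_sd(instrument_config(0))["x"],
            beam_divergence_sd(instrument_config(2))["x"])
})

test_that("azimuthal average: constant field, single annulus, absent bins", {
  cfg <- instrument_config(30)
  const <- matrix(3.5, 144, 256)
  aa <- azimuthal_average(const, cfg, n_bins = 20)
  expect_true(all(abs(aa$I[aa$n_pixels > 0] - 3.5) < 1e-12))
  # counts in one annulus only
  qmap <- matrix(pixel_to_q(cfg, rep(0:143, times = 256),
                            rep(0:255, each = 144))$q, 144, 256)
  band <- qmap > 0.02 & qmap < 0.025
  img <- matrix(0, 144, 256); img[band] <- 7
  aa2 <- azimuthal_average(img, cfg, n_bins = 10)
  expect_true(sum(aa2$I > 0, na.rm = TRUE) >= 1)
  expect_true(all(aa2$I[aa2$q > 0.03] %in% c(0, NA)))
  # empty annuli are flagged absent (NA), not zero
  expect_true(all(is.na(aa2$I[aa2$n_pixels == 0])))
})

test_that("isotropic models yield azimuthally uniform patterns across seeded replicates", {
  iso <- c("sphere", "fuzzy sphere", "core shell sphere", "mono gauss coil",
           "dab", "broad peak", "teubner strey", "mass fractal", "fractal")
  cfg <- instrument_config(30)
  for (nm in iso) {
    pass <- vapply(1:20, function(r) {
      img <- simulate_pattern(nm, NULL, n_neutrons = 1e5, seed = 6000 + r,
                              config = cfg)
      azimuthal_uniformity_test(img)$p.value >= 0.01
    }, logical(1))
    expect_gte(mean(pass), 0.95)
  }
})

test_that("oriented anisotropic patterns fail the uniformity test; unoriented ones pass", {
  cfg <- instrument_config(30)
  oriented <- simulate_pattern("elliptical cylinder",
                               c(theta = pi / 2, phi = 0),
                               n_neutrons = 1e5, seed = 12, config = cfg)
  expect_lt(azimuthal_uniformity_test(oriented)$p.value, 0.01)
  unoriented <- simulate_pattern("elliptical cylinder",
                                 c(theta = pi / 2, phi = 0),
                                 poly = poly_spec(dtheta = c(theta = pi,
                                                             phi = pi)),
                                 n_neutrons = 1e5, seed = 12, config = cfg)
  expect_gte(azimuthal_uniformity_test(unoriented)$p.value, 0.01)
})
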
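# Form-factor catalogue and kernels.

test_that("catalogue labels are the lexicographic rank and match the published table", {
  cat46 <- sas_models()
  expect_equal(nrow(cat46), 46)
  expect_identical(cat46$label, 0:45)
  expect_identical(cat46$name, sort(cat46$name, method = "radix"))
  expect_false(any(duplicated(cat46$name)))
  # anchor points of the published label table
  anchors <- c("adsorbed layer" = 0, "barbell" = 1, "bcc paracrystal" = 2,
               "broad peak" = 4, "core shell cylinder" = 9,
               "core shell ellipsoid" = 10, "core shell sphere" = 12,
               "cylinder" = 13, "dab" = 14, "ellipsoid" = 15,
               "elliptical cylinder" = 16, "fcc paracrystal" = 17,
               "fractal" = 19, "fractal core shell" = 20,
               "fuzzy sphere" = 21, "gauss lorentz gel" = 22, "gel fit" = 23,
               "hollow rectangular prism" = 25, "lamellar hg" = 26,
               "lamellar stack paracrystal" = 28, "mass fractal" = 29,
               "mono gauss coil" = 30, "multilayer vesicle" = 31,
               "polymer micelle" = 35, "rectangular prism" = 37,
               "sc paracrystal" = 38, "sphere" = 39, "stacked disks" = 41,
               "star polymer" = 42, "teubner strey" = 44)
  expect_equal(cat46$label[match(names(anchors), cat46$name)],
               unname(anchors))
})

test_that("implemented subset covers the required models and placeholders refuse kernels", {
  cat46 <- sas_models()
  impl <- cat46$name[cat46$implemented]
  expect_gte(length(impl), 12)
  expect_true(all(c("sphere", "fuzzy sphere", "core shell sphere",
                    "mono gauss coil", "dab", "broad peak", "teubner strey",
                    "mass fractal", "fractal", "cylinder",
                    "elliptical cylinder", "ellipsoid",
                    "core shell cylinder") %in% impl))
  expect_error(sas_model("vesicle"), "placeholder")
  expect_error(sas_model("no such model"), "unknown")
})

test_that("1-D kernels match the independent oracles to 1e-6 relative error", {
  q <- exp(seq(log(5e-4), log(0.6), length.out = 20))
  for (nm in names(oracle_iq)) {
    m <- sas_model(nm)
    set.seed(m$label)
    draws <- lhs_sample(m, 5, seed = 1000 + m$label)
    for (d in draws) {
      got <- sas_Iq(m, d$params, q)
      want <- oracle_iq[[nm]](d$params, q)
      expect_equal(got, unname(want), tolerance = 1e-6,
                   info = paste("model", nm))
    }
  }
})

test_that("sphere kernel: zero contrast gives background; first intensity zero at qR = 4.4934", {
  q <- c(0.01, 0.05, 0.2)
  expect_equal(sas_Iq("sphere", c(contrast = 0, background = 0.07), q),
               rep(0.07, 3))
  f <- function(q) sas_Iq("sphere", c(radius = 60, background = 0), q)
  opt <- optimize(f, c(4.0 / 60, 4.9 / 60), tol = 1e-10)
  expect_equal(opt$minimum * 60, 4.493409, tolerance = 1e-4)
  expect_lt(opt$objective / f(4.0 / 60), 1e-10)
})

test_that("Debye coil at x = 1 and dab small-q limit", {
  # P(x) = 2(e^-x + x - 1)/x^2 at x = (q Rg)^2 = 1 is 2/e
  expect_equal(sas_Iq("mono gauss coil", c(i_zero = 1, background = 0), 1 / 75),
               2 * exp(-1), tolerance = 1e-9)
  expect_equal(sas_Iq("dab", c(scale = 3, cor_length = 50, background = 0.01),
                      1e-8),
               3 * 50^3 + 0.01, tolerance = 1e-9)
})

test_that("kernels are finite and non-negative over a q grid x LHS draws", {
  q <- exp(seq(log(1e-4), log(1), length.out = 100))
  for (nm in sas_models()$name[sas_models()$implemented]) {
    m <- sas_model(nm)
    draws <- lhs_sample(m, 50, seed = 31 + m$label)
    for (d in draws) {
      I <- sas_Iq(m, d$params, q)
      expect_true(all(is.finite(I)), info = nm)
      expect_true(all(I >= 0), info = nm)
    }
  }
})

test_that("parameter and domain validation name the offender", {
  expect_error(sas_Iq("sphere", c(radius = -5), 0.01), "radius")
  expect_error(sas_Iq("sphere", c(nonsense = 1), 0.01), "nonsense")
  expect_error(sas_Iq("sphere", NULL, c(0.01, -0.2)), "positive")
  expect_error(sas_Iq("sphere", NULL, 0), "positive")
})

test_that("2-D kernel: isotropic models refuse, symmetry properties hold", {
  expect_error(sas_Iqxy("dab", NULL, 0.01, 0.01), "unsupported|isotropic")
  # beam-axis-aligned cylinder is azimuthally symmetric in the plane
  qs <- 0.02
  ang <- seq(0, 2 * pi, length.out = 17)
  I <- sas_Iqxy("cylinder", NULL, qs * cos(ang), qs * sin(ang),
                orientation = c(theta = 0, phi = 0))
  expect_lt(diff(range(I)) / mean(I), 1e-10)
  # inversion symmetry of elastic scattering
  o <- c(theta = 1.1, phi = 0.4)
  expect_equal(sas_Iqxy("cylinder", NULL, 0.013, -0.007, orientation = o),
               sas_Iqxy("cylinder", NULL, -0.013, 0.007, orientation = o))
})

test_that("cylinder 2-D kernel matches the independent amplitude oracle", {
  p <- c(scale = 1, contrast = 2, radius = 25, length = 500,
         theta = 0.9, phi = 0.3, background = 0.001)
  qx <- c(0.01, -0.02, 0.004, 0.03)
  qy <- c(0.005, 0.015, -0.02, 0.001)
  expect_equal(sas_Iqxy("cylinder", p, qx, qy),
               unname(oracle_cylinder_iqxy(p, qx, qy)), tolerance = 1e-8)
})

test_that("orientation average agrees with brute-force Monte Carlo and converges", {
  p <- c(scale = 1, contrast = 2, radius = 20, length = 400,
         theta = 0, phi = 0, background = 0.001)
  q <- c(0.005, 0.01, 0.03, 0.08, 0.2)
  mc <- oracle_cylinder_orient_mc(p, q, n = 1e6, seed = 99)
  got <- orientation_average("cylinder", p, q, n_nodes = 48)
  expect_true(all(abs(got - mc[1, ]) <= 3 * mc[2, ]))
  # matches the model's 1-D intensity (same integral, different route)
  expect_equal(got, sas_Iq("cylinder", p, q), tolerance = 1e-6)
  # Cauchy criterion: doubling the node count moves the result < 0.1%
  g2 <- orientation_average("cylinder", p, q, n_nodes = 96)
  expect_lt(max(abs(g2 - got) / got), 1e-3)
})

test_that("polydisperse average: degenerate spreads reduce exactly; smoothing fills the sphere minimum", {
  q <- c(0.02, 0.074890, 0.12)   # middle point = first sphere zero for R = 60
  mono <- polydisperse_average("sphere", c(radius = 60), NULL, q = q,
                               n_draws = 5, seed = 3)
  expect_equal(mono$I, sas_Iq("sphere", c(radius = 60), q))
  expect_equal(mono$se, rep(0, 3))

  poly <- polydisperse_average("sphere", c(radius = 60),
                               poly_spec(dr = c(radius = 10)), q = q,
                               n_draws = 2e4, seed = 11)
  expect_gt(poly$I[2], mono$I[2])
  want <- oracle_sphere_polydisperse(
    c(scale = 1, contrast = 2, radius = 60, background = 0.001),
    dr = 10, q = q)
  expect_true(all(abs(poly$I - want) <= 3 * poly$se + 1e-9 * want))
  # determinism contract
  again <- polydisperse_average("sphere", c(radius = 60),
                                poly_spec(dr = c(radius = 10)), q = q,
                                n_draws = 2e4, seed = 11)
  expect_identical(poly, again)
})

test_that("polydispersity spec validation enforces the r/2 cap", {
  expect_error(poly_spec(dr = c(radius = -1)), ">= 0")
  expect_error(
    polydisperse_average("sphere", c(radius = 60),
                         poly_spec(dr = c(radius = 40)), q = 0.01,
                         n_draws = 2),
    "r/2")
  expect_error(
    polydisperse_average("dab", NULL, poly_spec(dr = c(cor_length = 1)),
                         q = 0.01, n_draws = 2),
    "not polydispersity-eligible")
})

test_that("sampling bounds follow the printed interval rule", {
  b <- sampling_bounds("fuzzy sphere")
  r <- b[b$name == "radius", ]
  expect_equal(c(r$lower, r$upper), c(1, 180))  # p0 = 60, lb = 1, ub = 1000
  # clamping at the schema upper bound
  ts <- sampling_bounds("teubner strey")
  expect_equal(ts$upper[ts$name == "xi"], 90)        # 3 * 30 < 500
  expect_equal(ts$upper[ts$name == "d_spacing"], 300)
  mgc <- sampling_bounds("mono gauss coil")
  expect_equal(mgc$upper[mgc$name == "i_zero"], 210) # 3 * 70 < 1000
})

test_that("catalogue JSON manifest round-trips names and labels", {
  js <- catalogue_json()
  parsed <- jsonlite::fromJSON(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed), 46)
  expect_equal(parsed$label, 0:45)
  expect_true("sampling_bounds" %in% names(parsed))
})
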
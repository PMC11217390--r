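# Log-normalization and resizing.

test_that("log-normalization reproduces the closed-form values", {
  img <- matrix(c(0, 3, 9), 1)
  out <- log_normalize(img)
  expect_equal(as.numeric(out), c(0, log10(4), 1), tolerance = 1e-10)
  expect_equal(as.numeric(out)[2], 0.60206, tolerance = 1e-5)
  expect_equal(attr(out, "MaxLog"), log(10))
  # constant image maps to all ones
  expect_true(all(log_normalize(matrix(4.2, 7, 9)) == 1))
})

test_that("log-normalization output is in [0,1] with max exactly 1 and is monotone", {
  set.seed(2)
  for (r in 1:30) {
    img <- matrix(rexp(144 * 256, rate = 1 / 10^runif(1, -1, 4)), 144, 256)
    out <- log_normalize(img)
    expect_gte(min(out), 0)
    expect_equal(max(out), 1)
    # pixelwise ordering preserved
    o <- order(img)
    expect_true(all(diff(out[o]) >= 0))
  }
})

test_that("log-normalization rejects negative and all-zero images", {
  expect_error(log_normalize(matrix(c(1, -0.1), 1)), "negative")
  expect_error(log_normalize(matrix(0, 4, 4)), "MaxLog")
})

test_that("bilinear resize: constant preservation, range containment, shape", {
  const <- matrix(0.37, 144, 256)
  out <- resize_image(const)
  expect_equal(dim(out), c(180, 180))
  expect_true(all(abs(out - 0.37) < 1e-12))
  set.seed(3)
  img <- matrix(runif(144 * 256), 144, 256)
  out <- resize_image(img)
  expect_gte(min(out), min(img))
  expect_lte(max(out), max(img))
})

test_that("bilinear resize agrees with an established implementation", {
  set.seed(4)
  img <- matrix(runif(144 * 256), 144, 256)
  ours <- resize_image(img, 180, 180)
  ref <- EBImage::resize(img, w = 180, h = 180)
  # interior pixels agree; border handling conventions may differ
  expect_equal(ours[3:178, 3:178], ref[3:178, 3:178], tolerance = 1e-6)
})

test_that("full preprocessing yields a 180x180 unit-max input", {
  img <- simulate_pattern("dab", NULL, n_neutrons = 2e4, seed = 5,
                          config = instrument_config(8))
  x <- preprocess_image(img)
  expect_equal(dim(x), c(180, 180))
  expect_gte(min(x), 0)
  expect_equal(max(x), 1)
  expect_true(is.numeric(attr(x, "MaxLog")))
  expect_error(preprocess_image(matrix(-1, 144, 256)), "negative")
})
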
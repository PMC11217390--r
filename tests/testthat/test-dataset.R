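# Dataset factory: combinatorics, LHS, sweep execution, cleaning, splitting.

test_that("combinatorial size is the exact product with domain checks", {
  expect_equal(combinatorial_size(rep(2, 15)), 32768)
  expect_equal(combinatorial_size(c(2, 2)), 4)
  expect_equal(combinatorial_size(integer(0)), 1)
  expect_equal(combinatorial_size(c(3, 4, 5)), 60)
  expect_error(combinatorial_size(c(2, 0)), ">= 1")
  expect_error(combinatorial_size(c(2, 1.5)), ">= 1")
})

test_that("latin-hypercube sampling is stratified with one point per bin", {
  for (nm in c("sphere", "elliptical cylinder", "broad peak")) {
    n <- 100
    s <- lhs_sample(nm, n, seed = 7)
    u <- attr(s, "unit")
    expect_equal(nrow(u), n)
    for (d in seq_len(ncol(u)))
      expect_equal(tabulate(ceiling(u[, d] * n), n), rep(1L, n),
                   info = paste(nm, colnames(u)[d]))
    # all draws respect the sampling bounds
    b <- sampling_bounds(nm)
    for (rec in s) {
      expect_true(all(rec$params >= b$lower - 1e-12 &
                        rec$params <= b$upper + 1e-12))
      expect_true(all(rec$poly$dr <= rec$params[names(rec$poly$dr)] / 2 + 1e-12))
    }
  }
  # degenerate single-point design stays inside bounds
  s1 <- lhs_sample("dab", 1, seed = 1)
  b <- sampling_bounds("dab")
  expect_true(all(s1[[1]]$params >= b$lower & s1[[1]]$params <= b$upper))
  # determinism
  expect_identical(attr(lhs_sample("sphere", 10, seed = 5), "unit"),
                   attr(lhs_sample("sphere", 10, seed = 5), "unit"))
})

test_that("generate_dataset produces the plan's record grid deterministically", {
  plan <- sampling_plan(c("sphere", "dab"), points_per_model = 3,
                        absorption = 0, configs = c(4, 22),
                        n_neutrons = 5e3, seed = 17)
  expect_equal(plan$expected_size, 12)
  ds <- generate_dataset(plan)
  expect_equal(length(ds$target), 12)
  expect_equal(dim(ds$data), c(12, 144, 256))
  expect_equal(nrow(ds$metadata), 12)
  expect_setequal(unique(ds$target), c(39L, 14L))
  expect_true(all(c("model", "label", "config_id", "wavelength_A",
                    "collimation_m", "sdd_m", "slit_id", "holder_mm",
                    "absorption", "seed", "param:radius") %in%
                    names(ds$metadata)))
  ds2 <- generate_dataset(plan)
  expect_identical(ds$metadata, ds2$metadata)
  expect_identical(ds$data, ds2$data)
})

test_that("cleaning removes zero images, the low-sd tail and the high-max tail", {
  # 1000 images with strictly ordered, distinct sd and max statistics
  ds <- make_synth_dataset(seq_len(1000))
  cl <- clean_dataset(ds)
  expect_equal(cl$report$removed_zero, 0)
  expect_equal(cl$report$removed_low_sd, 20)    # 0.02 quantile of 1000
  # expected high-max count from the quantile definition on the 980 survivors
  expect_equal(cl$report$removed_high_max, 10)
  expect_equal(cl$report$n_kept, 970)
  # the removed low-sd images are exactly the 20 smallest
  expect_false(any(seq_len(20) %in% cl$dataset$metadata$idx))

  # zero images never survive rule (a)
  ds0 <- make_synth_dataset(c(0, 0, 1:40))
  cl0 <- clean_dataset(ds0)
  expect_equal(cl0$report$removed_zero, 2)
  expect_false(any(cl0$dataset$metadata$idx %in% c(1, 2)))

  # identical nonzero images: degenerate quantiles, ties survive
  dsc <- make_synth_dataset(rep(5, 30))
  clc <- clean_dataset(dsc)
  expect_equal(clc$report$removed_low_sd, 0)
  expect_equal(clc$report$removed_high_max, 0)
  expect_equal(clc$report$n_kept, 30)

  expect_error(clean_dataset(make_synth_dataset(numeric(0))), "empty")
})

test_that("stratified split matches proportions per class and is exhaustive", {
  set.seed(1)
  labels <- rep(0:4, times = c(300, 250, 200, 150, 100))
  ds <- make_synth_dataset(seq_along(labels) + 10, labels)
  sp <- split_dataset(ds, c(train = 0.7, test = 0.2, validation = 0.1),
                      seed = 5)
  expect_equal(vapply(sp, function(p) length(p$target), integer(1)),
               c(train = 700, test = 200, validation = 100))
  # per-label proportions within +-1 of the stratum rounding
  for (l in 0:4) {
    nl <- sum(labels == l)
    got <- vapply(sp, function(p) sum(p$target == l), integer(1))
    expect_true(all(abs(got - nl * c(0.7, 0.2, 0.1)) <= 1), info = l)
  }
  # partitions disjoint and exhaustive
  ids <- sort(unname(unlist(lapply(sp, function(p) p$metadata$idx))))
  expect_identical(ids, seq_along(labels))
  # determinism
  sp2 <- split_dataset(ds, c(train = 0.7, test = 0.2, validation = 0.1),
                       seed = 5)
  expect_identical(sp$train$metadata, sp2$train$metadata)

  # degenerate split puts everything in train
  all_train <- split_dataset(ds, c(train = 1, test = 0, validation = 0),
                             seed = 1)
  expect_equal(length(all_train$train$target), length(labels))
  expect_equal(length(all_train$test$target), 0)

  # tiny class stays in train, with a warning
  tiny <- make_synth_dataset(1:21, c(rep(0L, 20), 1L))
  expect_warning(sp3 <- split_dataset(tiny, seed = 2), "kept wholly in train")
  expect_true(all(sp3$train$target[sp3$train$metadata$idx == 21] == 1L))

  expect_error(split_dataset(ds, c(0.5, 0.2, 0.1)), "sum to 1")
})

test_that("HDF5 + CSV round-trip is the identity on a 12-record partition", {
  plan <- sampling_plan(c("sphere", "teubner strey"), points_per_model = 3,
                        absorption = 0.10, configs = c(0, 31),
                        n_neutrons = 5e3, seed = 23)
  ds <- generate_dataset(plan)
  part <- structure(c(list(name = "train"), unclass(ds)),
                    class = "sans_partition")
  path <- file.path(tempdir(), "rt_train.h5")
  write_partition(part, path)
  back <- read_partition(path)
  expect_equal(back$data, part$data, tolerance = 0)
  expect_identical(back$target, part$target)
  expect_equal(nrow(back$metadata), nrow(part$metadata))
  expect_identical(names(back$metadata), names(part$metadata))
  expect_equal(back$metadata$`param:radius`, part$metadata$`param:radius`)
  expect_true(all(back$target >= 0 & back$target <= 45))
  # CSV row count equals HDF record count
  expect_equal(nrow(read.csv(sub("\\.h5$", ".csv", path))),
               length(back$target))
  # malformed file reports the missing group
  bad <- file.path(tempdir(), "bad.h5")
  rhdf5::h5createFile(bad)
  rhdf5::h5write(1:3, bad, "target"); rhdf5::H5close()
  expect_error(read_partition(bad), "data")
  file.remove(path, sub("\\.h5$", ".csv", path), bad)
})

test_that("full-catalogue plan arithmetic reports 331,200 records without generating", {
  expect_equal(full_sweep_size(), 331200)
  plan <- sampling_plan(sas_models()$name, points_per_model = 100,
                        absorption = c(0, 0.10), configs = 0:35,
                        n_neutrons = 1e7, seed = 1)
  expect_equal(plan$expected_size, 331200)
})
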
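# Classifier metrics, ensemble algebra, and learning on a separable toy task.

test_that("cross-entropy loss matches closed forms and is stable", {
  expect_equal(cross_entropy_loss(rep(0, 46), 7), log(46))
  expect_equal(cross_entropy_loss(c(1, 0, 0), 0), -log(exp(1) / (exp(1) + 2)))
  expect_equal(cross_entropy_loss(c(1, 0, 0), 0), 0.5514, tolerance = 1e-4)
  # loss decreases monotonically to 0 as the correct logit grows
  ls <- vapply(c(1, 5, 20, 100), function(a)
    cross_entropy_loss(c(a, 0, 0), 0), numeric(1))
  expect_true(all(diff(ls) < 0))
  expect_lt(ls[4], 1e-8)
  # log-sum-exp stability for huge logits
  expect_equal(cross_entropy_loss(c(1e4, 1e4 - 2), 0), log(1 + exp(-2)))
  expect_error(cross_entropy_loss(c(0, 0), 2), "label")
})

test_that("top-k accuracy: exhaustive rank, enumeration, ordering property", {
  probs <- rbind(c(0.7, 0.2, 0.1),   # true label ranks 1st
                 c(0.5, 0.3, 0.2),   # 3rd
                 c(0.3, 0.5, 0.2))   # 2nd
  labels <- c(0L, 2L, 0L)
  expect_equal(topk_accuracy(probs, labels, 1), 1 / 3)
  expect_equal(topk_accuracy(probs, labels, 2), 2 / 3)
  expect_equal(topk_accuracy(probs, labels, 3), 1)
  set.seed(6)
  P <- matrix(runif(200 * 10), 200)
  P <- P / rowSums(P)
  y <- sample(0:9, 200, TRUE)
  t1 <- topk_accuracy(P, y, 1); t3 <- topk_accuracy(P, y, 3)
  t5 <- topk_accuracy(P, y, 5)
  expect_true(t1 <= t3 && t3 <= t5)
  expect_equal(topk_accuracy(P, y, 10), 1)
})

test_that("classification report and confusion matrix are mutually consistent", {
  # hand-checked 2-class example
  rep2 <- classification_report(c(1L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L), 2)
  expect_equal(rep2$precision, c(1.0, 0.5))
  expect_equal(rep2$recall, c(2 / 3, 1.0))
  expect_equal(rep2$support, c(3L, 1L))
  # perfect predictions
  perf <- classification_report(0:3, 0:3, 4)
  expect_true(all(perf$precision == 1 & perf$recall == 1 & perf$f1 == 1))
  cmp <- confusion_matrix(0:3, 0:3, 4)
  expect_equal(cmp, diag(1L, 4), ignore_attr = TRUE)
  # F1 is 0 whenever precision is 0 (with nonzero support)
  r0 <- classification_report(c(1L, 1L), c(0L, 0L), 2)
  expect_equal(r0$recall[1], 0)
  expect_equal(r0$f1[1], 0)
  expect_true(is.nan(r0$precision[1]))   # no predicted positives for class 0
  # random-input consistency between the two reports
  set.seed(8)
  for (r in 1:10) {
    C <- sample(3:8, 1); n <- sample(20:60, 1)
    pred <- sample(0:(C - 1), n, TRUE); y <- sample(0:(C - 1), n, TRUE)
    cm <- confusion_matrix(pred, y, C)
    repn <- classification_report(pred, y, C)
    expect_equal(sum(cm), n)
    expect_equal(unname(rowSums(cm)), repn$support)
    expect_equal(unname(ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), NaN)),
                 repn$precision)
  }
})

test_that("ensemble averaging is the arithmetic mean with argmax prediction", {
  # hand average of two member outputs
  p1 <- matrix(c(0.6, 0.4), 1); p2 <- matrix(c(0.2, 0.8), 1)
  avg <- (p1 + p2) / 2
  expect_equal(avg, matrix(c(0.4, 0.6), 1))
  expect_equal(predict_label(avg), 1L)
  # ties break toward the lowest class index
  expect_equal(predict_label(matrix(c(0.5, 0.5), 1)), 0L)
})

test_that("probability predictions are normalized, deterministic, and shape-checked", {
  set.seed(10)
  w <- sansvex:::.cnn_init_cpp(5L)
  fake <- structure(list(weights = w, n_classes = 5L), class = "sans_cnn")
  X <- matrix(runif(3 * 32400), 3)
  p <- predict_proba(fake, X)
  expect_equal(dim(p), c(3, 5))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p, predict_proba(fake, X))
  expect_error(predict_proba(fake, matrix(0.5, 2, 100)), "preprocessed")
  expect_error(predict_proba(fake, matrix(2, 1, 32400)), "\\[0, 1\\]")
  # single-member ensemble equals the member; identical members too
  expect_equal(ensemble_proba(list(fake), X), p)
  expect_equal(ensemble_proba(list(fake, fake, fake), X), p)
})

test_that("the compact CNN learns a separable two-model task", {
  task <- toy_task(n_per_class = 100, n_neutrons = 2e4)
  # separability established by an independent nearest-centroid oracle
  nc <- nearest_centroid_accuracy(task$train, task$test)
  expect_gte(nc, 0.95)
  fit <- train_cnn(task$train, task$test,
                   training_config(epochs = 6, batch_size = 32, lr = 3e-3,
                                   seed = 303))
  h <- fit$history
  expect_lte(nrow(h), 30)
  expect_lte(h$train_loss[nrow(h)], h$train_loss[1])
  best <- max(h$test_acc)
  expect_gte(best, 0.95)
  p <- predict_proba(fit, task$test)
  expect_gte(topk_accuracy(p, task$test$y, 1), 0.95)
  .toy_env$fit <- fit     # reused by the recommendation test below
})

test_that("recommendation ranks catalogue models with the uniform baseline", {
  fit <- .toy_env$fit
  task <- toy_task(n_per_class = 100, n_neutrons = 2e4)
  # a fresh raw sphere image must put 'sphere' into the top-5
  img <- simulate_pattern("sphere", c(radius = 55), n_neutrons = 5e4,
                          seed = 777, config = instrument_config(30))
  rec <- recommend(list(fit, fit), img, k = 5)
  expect_equal(nrow(rec$ranking), 5)
  expect_equal(rec$baseline, 1 / 46)
  expect_true(all(diff(rec$ranking$score) <= 0))
  expect_true("sphere" %in% rec$ranking$model[1:5])
  expect_equal(length(rec$members), 2)
  # full ranking sums to one
  rec_all <- recommend(fit, img, k = 46)
  expect_equal(sum(rec_all$ranking$score), 1, tolerance = 1e-6)
  expect_error(recommend(fit, matrix(-1, 144, 256)), "negative")
})

test_that("training warns on single-class data and the literal checkpoint rule is available", {
  task <- toy_task(n_per_class = 100, n_neutrons = 2e4)
  one <- list(X = task$train$X[task$train$y == 39, ][1:20, ],
              y = rep(39L, 20))
  expect_warning(
    train_cnn(one, one, training_config(epochs = 1, batch_size = 8,
                                        lr = 1e-3, seed = 1)),
    "single-class")
  fit <- train_cnn(task$train, task$test,
                   training_config(epochs = 3, batch_size = 32, lr = 3e-3,
                                   checkpoint = "literal", seed = 11))
  expect_true(fit$best_epoch >= 0 && fit$best_epoch <= 3)
})
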
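# CNN training, SoftMax-averaging ensemble, and classification metrics.

#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam with learning rate
#' 1e-5, mini-batches of 64 images, 30 epochs, evaluation batch sizes of 500
#' (test) and 1000 (validation). For training the compact CNN from random
#' initialization on desk-scale tasks a larger learning rate (e.g. 1e-3) is
#' appropriate; the 1e-5 default matches fine-tuning of large pretrained
#' backbones.
#'
#' @param epochs Maximum number of epochs (history length never exceeds it).
#' @param batch_size Training mini-batch size.
#' @param lr Adam learning rate.
#' @param test_batch,validation_batch Evaluation batch sizes (metadata for
#'   batch-averaged reporting).
#' @param checkpoint `"best"` keeps the weights with the highest test
#'   accuracy; `"literal"` keeps the last epoch in which the test accuracy
#'   decreased relative to its previous value.
#' @param seed Integer seed governing weight initialization and batch
#'   shuffling.
#' @return Object of class `training_config`.
#' @export
training_config <- function(epochs = 30, batch_size = 64, lr = 1e-5,
                            test_batch = 500, validation_batch = 1000,
                            checkpoint = c("best", "literal"), seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 test_batch = as.integer(test_batch),
                 validation_batch = as.integer(validation_batch),
                 checkpoint = match.arg(checkpoint),
                 seed = as.integer(seed)), class = "training_config")
}

#' Numerically stable softmax cross-entropy loss
#'
#' `l(x, y) = -log( exp(a_y) / sum_c exp(a_c) )` for last-layer outputs
#' (logits) `a` and 0-based target label `y`, evaluated via log-sum-exp.
#'
#' @param logits Numeric vector of length C (last-layer outputs).
#' @param label 0-based true class index.
#' @return The loss value.
#' @examples
#' cross_entropy_loss(rep(0, 46), 0)  # log(46)
#' @export
cross_entropy_loss <- function(logits, label) {
  C <- length(logits)
  if (label < 0 || label >= C || label != floor(label))
    stop("label must be an integer in 0..", C - 1)
  m <- max(logits)
  (m + log(sum(exp(logits - m)))) - logits[label + 1]
}

#' Train the compact reference CNN
#'
#' Minimizes the batch-mean softmax cross-entropy with Adam on preprocessed
#' 180 x 180 images. The architecture is 4 blocks of 3x3 convolution (16,
#' 32, 64, 128 channels) with ReLU and stride-2 max pooling, global average
#' pooling, and a C-way linear output. Per-epoch train/test loss and
#' accuracy are recorded; the accepted weights follow the configured
#' checkpoint rule.
#'
#' @param train,test Lists with `X` (n x 32400 matrix of preprocessed
#'   images) and `y` (integer labels), as from [preprocess_partition()], or
#'   `sans_partition` objects (preprocessed on the fly).
#' @param config A [training_config()].
#' @param n_classes Size of the output layer (defaults to the full 46-model
#'   catalogue so that labels index the catalogue directly).
#' @param verbose Print per-epoch progress.
#' @return Object of class `sans_cnn` with `weights`, `history`,
#'   `best_epoch` and `config`.
#' @export
train_cnn <- function(train, test, config = training_config(),
                      n_classes = nrow(sas_models()), verbose = FALSE) {
  stopifnot(inherits(config, "training_config"))
  if (inherits(train, c("sans_partition", "sans_dataset")))
    train <- preprocess_partition(train)
  if (inherits(test, c("sans_partition", "sans_dataset")))
    test <- preprocess_partition(test)
  if (length(train$y) == 0 || length(test$y) == 0)
    stop("training and test partitions must be nonempty")
  if (length(unique(train$y)) < 2)
    warning("single-class training data: the fit is trivial")
  if (any(train$y < 0 | train$y >= n_classes))
    stop("labels outside 0..", n_classes - 1)
  set.seed(config$seed)
  w0 <- .cnn_init_cpp(as.integer(n_classes))
  fit <- .cnn_train_cpp(w0, train$X, as.integer(train$y),
                        test$X, as.integer(test$y),
                        config$epochs, config$batch_size, config$lr,
                        config$checkpoint == "literal", isTRUE(verbose))
  structure(list(weights = fit$weights,
                 final_weights = fit$final_weights,
                 history = as.data.frame(fit$history),
                 best_epoch = fit$best_epoch,
                 literal_epoch = fit$literal_epoch,
                 n_classes = as.integer(n_classes),
                 config = config), class = "sans_cnn")
}

#' @export
print.sans_cnn <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<sans_cnn> %d classes, %d epochs (checkpoint at %d), final test acc %.3f\n",
    x$n_classes, nrow(h), x$best_epoch, h$test_acc[nrow(h)]))
  invisible(x)
}

.as_design <- function(model, images) {
  if (is.list(images) && !is.null(images$X)) return(images$X)
  if (is.matrix(images) && ncol(images) == 32400) return(images)
  if (is.matrix(images) && all(dim(images) == c(180, 180)))
    return(matrix(as.numeric(images), 1))
  stop("images must be preprocessed 180x180 (single image, n x 32400 ",
       "matrix, or a preprocess_partition() result)")
}

#' Class-probability prediction
#'
#' SoftMax of the last-layer outputs; the predicted label is the positional
#' index (0-based, lowest index on ties) of the highest-weighted node.
#'
#' @param model A `sans_cnn`.
#' @param images Preprocessed input: one 180 x 180 matrix, an n x 32400
#'   matrix, or a [preprocess_partition()] result.
#' @return n x C matrix of probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, images) {
  stopifnot(inherits(model, "sans_cnn"))
  X <- .as_design(model, images)
  if (any(X < 0 | X > 1))
    stop("input images must be preprocessed to [0, 1]")
  .cnn_predict_cpp(model$weights, X)
}

#' Ensemble probability by SoftMax averaging
#'
#' Arithmetic mean of the member networks' SoftMax outputs; the ensemble
#' prediction is the argmax with lowest-index tie-break.
#'
#' @param members List of `sans_cnn` members sharing one catalogue.
#' @param images As in [predict_proba()].
#' @return n x C matrix of averaged probabilities.
#' @export
ensemble_proba <- function(members, images) {
  if (inherits(members, "sans_cnn")) members <- list(members)
  stopifnot(length(members) >= 1)
  C <- unique(vapply(members, function(m) m$n_classes, integer(1)))
  if (length(C) != 1)
    stop("ensemble members disagree on the number of classes")
  probs <- lapply(members, predict_proba, images = images)
  Reduce(`+`, probs) / length(probs)
}

#' Predicted labels from a probability matrix
#'
#' @param probs n x C probability (or score) matrix.
#' @return Integer vector of 0-based predicted labels (lowest index on ties).
#' @export
predict_label <- function(probs) {
  max.col(probs, ties.method = "first") - 1L
}

#' Top-k accuracy
#'
#' Fraction of records whose true label ranks among the k highest scores
#' (ties broken toward the lowest class index).
#'
#' @param probs n x C matrix of class scores.
#' @param labels Integer vector of 0-based true labels.
#' @param k Rank cutoff, 1 <= k <= C.
#' @return The accuracy in [0, 1].
#' @export
topk_accuracy <- function(probs, labels, k = 1) {
  probs <- as.matrix(probs)
  C <- ncol(probs)
  stopifnot(k >= 1, k <= C, nrow(probs) == length(labels))
  hit <- vapply(seq_len(nrow(probs)), function(i) {
    ord <- order(-probs[i, ], seq_len(C))
    (labels[i] + 1L) %in% ord[seq_len(k)]
  }, logical(1))
  mean(hit)
}

#' Per-class precision, recall, F1 and support
#'
#' Precision = TP / (TP + FP); recall = TP / (TP + FN); F1 their harmonic
#' mean. Classes with no predicted positives have undefined precision
#' (reported `NaN`); F1 is 0 whenever precision or recall is 0.
#'
#' @param predictions,labels Integer vectors of 0-based predicted and true
#'   labels.
#' @param n_classes Number of classes C (labels in 0..C-1).
#' @return `data.frame` with one row per class: `label`, `precision`,
#'   `recall`, `f1`, `support`.
#' @export
classification_report <- function(predictions, labels,
                                  n_classes = max(predictions, labels) + 1) {
  stopifnot(length(predictions) == length(labels), length(labels) >= 1)
  cm <- confusion_matrix(predictions, labels, n_classes)
  tp <- diag(cm)
  pred_pos <- colSums(cm)
  real_pos <- rowSums(cm)
  precision <- ifelse(pred_pos > 0, tp / pred_pos, NaN)
  recall <- ifelse(real_pos > 0, tp / real_pos, NaN)
  # classes absent from the labels stay flagged NaN; a supported class with
  # no true positives scores F1 = 0
  f1 <- ifelse(real_pos == 0, NaN,
               ifelse(is.nan(precision) | precision + recall == 0, 0,
                      2 * precision * recall / (precision + recall)))
  data.frame(label = 0:(n_classes - 1), precision = precision,
             recall = recall, f1 = f1, support = as.integer(real_pos))
}

#' Confusion matrix
#'
#' @inheritParams classification_report
#' @return C x C integer matrix `counts[true + 1, predicted + 1]`; row sums
#'   are the class supports and the grand total is the record count.
#' @export
confusion_matrix <- function(predictions, labels,
                             n_classes = max(predictions, labels) + 1) {
  stopifnot(all(predictions >= 0 & predictions < n_classes),
            all(labels >= 0 & labels < n_classes))
  cm <- table(factor(labels, levels = 0:(n_classes - 1)),
              factor(predictions, levels = 0:(n_classes - 1)))
  m <- matrix(as.integer(cm), n_classes, n_classes,
              dimnames = list(true = rownames(cm), predicted = colnames(cm)))
  m
}

#' Model recommendation for a measured 2-D pattern
#'
#' Preprocesses a raw 144 x 256 detector image, averages the ensemble
#' members' SoftMax outputs, and returns the k highest-scoring catalogue
#' models with their scores, the uniform baseline 1/C, and each member's own
#' top-k ranking.
#'
#' @param ensemble List of `sans_cnn` members (or a single one).
#' @param image Raw detector image (non-negative counts, any size; 144 x 256
#'   in the standard pipeline).
#' @param k Number of recommendations.
#' @return Object of class `sans_recommendation`: list with `ranking`
#'   (data.frame of model, label, score), `baseline` (= 1/C), and
#'   `members` (per-member rankings).
#' @export
recommend <- function(ensemble, image, k = 5) {
  if (inherits(ensemble, "sans_cnn")) ensemble <- list(ensemble)
  x <- preprocess_image(image)
  xm <- matrix(as.numeric(x), 1)
  probs <- ensemble_proba(ensemble, xm)
  C <- ncol(probs)
  stopifnot(k >= 1, k <= C)
  cat46 <- sas_models()
  nm <- if (C == nrow(cat46)) cat46$name else as.character(0:(C - 1))
  rank_of <- function(p) {
    ord <- order(-p, seq_along(p))[seq_len(k)]
    data.frame(model = nm[ord], label = ord - 1L, score = p[ord],
               stringsAsFactors = FALSE)
  }
  structure(list(
    ranking = rank_of(probs[1, ]),
    baseline = 1 / C,
    members = lapply(ensemble, function(m)
      rank_of(predict_proba(m, xm)[1, ]))), class = "sans_recommendation")
}

#' @export
print.sans_recommendation <- function(x, ...) {
  cat(sprintf("<sans_recommendation> baseline %.3f\n", x$baseline))
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
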
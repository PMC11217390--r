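# Desk-scale end-to-end learning benchmark: a reduced version of the full
# recommendation-system study that runs on a single CPU in minutes.

#' Desk-scale sampling plan for the learning benchmark
#'
#' Six visually distinct scattering models (sphere, cylinder, dab, broad
#' peak, teubner strey, mass fractal), 25 latin-hypercube points per model x
#' 2 absorption levels x 4 representative instrument configurations = 200
#' images per model, at 1e5 source events per image.
#'
#' @param seed Base seed for the plan.
#' @param n_neutrons Source events per image.
#' @param points_per_model Latin-hypercube points per model.
#' @return A [sampling_plan()].
#' @export
benchmark_plan <- function(seed = 101, n_neutrons = 1e5,
                           points_per_model = 25) {
  sampling_plan(
    models = c("sphere", "cylinder", "dab", "broad peak", "teubner strey",
               "mass fractal"),
    points_per_model = points_per_model,
    absorption = c(0, 0.10),
    configs = c(0, 9, 21, 35),   # both wavelengths, all three distance pairs
    n_neutrons = n_neutrons,
    seed = seed)
}

#' Run the desk-scale recommendation-system benchmark
#'
#' Generates the [benchmark_plan()] dataset, cleans and splits it
#' (0.70/0.20/0.10 stratified), trains a seed-varied ensemble of compact
#' CNNs, and evaluates Top-1/3/5 accuracy on the held-out validation
#' partition, member by member and for the SoftMax-averaging ensemble.
#'
#' @param seed Integer seed driving the whole run (data generation, splits,
#'   member initializations).
#' @param members Number of ensemble members.
#' @param epochs,lr Training schedule for the from-scratch compact CNN.
#' @param n_neutrons,points_per_model Passed to [benchmark_plan()].
#' @param verbose Print progress.
#' @return List with `ensemble` (the trained members), `member_top1`,
#'   `ensemble_top1`, `ensemble_top3`, `ensemble_top5`, `report`
#'   (per-class metrics on validation), `confusion`, `cleaning`, `history`
#'   (per-member training histories) and the partitions' sizes.
#' @export
run_benchmark <- function(seed = 101, members = 3, epochs = 12, lr = 3e-3,
                          n_neutrons = 1e5, points_per_model = 25,
                          verbose = FALSE) {
  plan <- benchmark_plan(seed = seed, n_neutrons = n_neutrons,
                         points_per_model = points_per_model)
  if (verbose) message("generating ", plan$expected_size, " virtual experiments")
  ds <- generate_dataset(plan)
  cl <- clean_dataset(ds)
  sp <- split_dataset(cl$dataset, seed = seed)
  if (verbose) message("partitions: ",
                       paste(vapply(sp, function(p) length(p$target),
                                    integer(1)), collapse = "/"))
  tr <- preprocess_partition(sp$train)
  te <- preprocess_partition(sp$test)
  va <- preprocess_partition(sp$validation)
  ens <- lapply(seq_len(members), function(m) {
    if (verbose) message("training member ", m, "/", members)
    train_cnn(tr, te,
              training_config(epochs = epochs, batch_size = 64, lr = lr,
                              seed = seed + m),
              verbose = verbose)
  })
  member_probs <- lapply(ens, predict_proba, images = va)
  member_top1 <- vapply(member_probs, topk_accuracy, numeric(1),
                        labels = va$y, k = 1)
  pe <- Reduce(`+`, member_probs) / length(member_probs)
  preds <- predict_label(pe)
  list(ensemble = ens,
       member_top1 = member_top1,
       ensemble_top1 = topk_accuracy(pe, va$y, 1),
       ensemble_top3 = topk_accuracy(pe, va$y, 3),
       ensemble_top5 = topk_accuracy(pe, va$y, 5),
       report = classification_report(preds, va$y, ncol(pe)),
       confusion = confusion_matrix(preds, va$y, ncol(pe)),
       cleaning = cl$report,
       history = lapply(ens, function(m) m$history),
       sizes = vapply(sp, function(p) length(p$target), integer(1)),
       validation = va,
       probs = pe)
}
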
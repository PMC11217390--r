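# Pipeline driver: one entry point wiring the stages together from a
# structured config, with JSON reproducibility manifests next to artifacts.
# The command-line wrapper in inst/scripts/sansvex.R is a thin shell over
# run_pipeline().

.KNOWN_KEYS <- list(
  top = c("seed", "paths", "sampling", "cleaning", "split", "training"),
  paths = c("output_dir"),
  sampling = c("models", "points_per_model", "absorption", "configs",
               "n_neutrons"),
  cleaning = c("sd_quantile", "max_quantile"),
  split = c("train", "test", "validation"),
  training = c("epochs", "batch_size", "lr", "members", "checkpoint"))

.check_keys <- function(x, section) {
  unknown <- setdiff(names(x), .KNOWN_KEYS[[section]])
  if (length(unknown))
    stop("unknown config key(s) in ", section, ": ",
         paste(unknown, collapse = ", "))
}

#' Read and validate a pipeline configuration
#'
#' The config is a YAML (or JSON) file with sections `paths`, `sampling`,
#' `cleaning`, `split`, `training` and a global `seed`; unknown keys are
#' rejected. Every field has a default, so a minimal config can be empty.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`), or `NULL` for all
#'   defaults.
#' @param overrides Named list merged over the file values (names like
#'   `"sampling.n_neutrons"`).
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs needs the 'yaml' package; ",
             "use a .json config otherwise")
      yaml::read_yaml(path)
    }
    if (is.null(cfg)) cfg <- list()
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) cfg[[parts]] <- overrides[[key]]
    else cfg[[parts[1]]][[parts[2]]] <- overrides[[key]]
  }
  .check_keys(cfg, "top")
  for (s in c("paths", "sampling", "cleaning", "split", "training"))
    if (!is.null(cfg[[s]])) .check_keys(cfg[[s]], s)
  defaults <- list(
    seed = 1L,
    paths = list(output_dir = "sansvex_out"),
    sampling = list(models = c("sphere", "cylinder", "dab"),
                    points_per_model = 5, absorption = c(0, 0.10),
                    configs = 0:35, n_neutrons = 1e5),
    cleaning = list(sd_quantile = 0.02, max_quantile = 0.99),
    split = list(train = 0.70, test = 0.20, validation = 0.10),
    training = list(epochs = 30, batch_size = 64, lr = 1e-5, members = 3,
                    checkpoint = "best"))
  out <- defaults
  out$seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else defaults$seed
  for (s in c("paths", "sampling", "cleaning", "split", "training"))
    for (k in names(cfg[[s]])) out[[s]][[k]] <- cfg[[s]][[k]]
  structure(out, class = "pipeline_config")
}

.write_manifest <- function(dir, stage, cfg, extra = list()) {
  manifest <- c(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("sansvex")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = .stable_hash(unclass(cfg)),
    catalogue_hash = .stable_hash(sas_models()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

# deterministic content hash without extra dependencies: polynomial rolling
# hash (base 131, modulus 2^45) over the serialized object, double-exact
.stable_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  idx <- seq(1, length(raw), by = max(1, length(raw) %/% 4096))
  h <- 0
  for (b in as.integer(raw[idx])) h <- (h * 131 + b) %% 35184372088832
  paste0(sprintf("%06x", as.integer(h %/% 16777216)),
         sprintf("%06x", as.integer(h %% 16777216)))
}

#' Run one pipeline stage
#'
#' Commands: `generate` (simulate the sweep, write `raw.h5` + CSV), `clean`,
#' `split` (write `train/test/validation.h5`), `preprocess` (write a
#' preprocessed design matrix per partition), `train` (train the ensemble,
#' write checkpoints + JSON sidecars), `evaluate` (Top-k table, per-class
#' metrics CSV, confusion matrix CSV), `recommend` (rank models for one
#' image read from a CSV of counts). Each stage writes a JSON manifest next
#' to its outputs and stops with a clear message when an upstream artifact
#' is missing.
#'
#' @param command One of the stage names above.
#' @param config A `pipeline_config`, or a path passed to
#'   [pipeline_config()].
#' @param overrides Named list of config overrides.
#' @param input For `recommend`: path to a CSV of raw detector counts.
#' @return Stage-dependent result, invisibly.
#' @export
run_pipeline <- function(command = c("generate", "clean", "split",
                                     "preprocess", "train", "evaluate",
                                     "recommend"),
                         config = NULL, overrides = list(), input = NULL) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config, overrides)
  dir <- cfg$paths$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(path, from) {
    if (!file.exists(path))
      stop("missing upstream artifact '", path, "': run the '", from,
           "' stage first")
    path
  }
  res <- switch(command,
    generate = {
      plan <- sampling_plan(cfg$sampling$models, cfg$sampling$points_per_model,
                            cfg$sampling$absorption, cfg$sampling$configs,
                            cfg$sampling$n_neutrons, cfg$seed)
      ds <- generate_dataset(plan)
      write_partition(ds, file.path(dir, "raw.h5"))
      .write_manifest(dir, "generate", cfg,
                      list(n_records = length(ds$target)))
      ds
    },
    clean = {
      raw <- read_partition(need(file.path(dir, "raw.h5"), "generate"))
      ds <- structure(list(data = raw$data, target = raw$target,
                           metadata = raw$metadata), class = "sans_dataset")
      cl <- clean_dataset(ds, cfg$cleaning$sd_quantile,
                          cfg$cleaning$max_quantile)
      write_partition(cl$dataset, file.path(dir, "clean.h5"))
      .write_manifest(dir, "clean", cfg, list(report = cl$report))
      cl
    },
    split = {
      cln <- read_partition(need(file.path(dir, "clean.h5"), "clean"))
      ds <- structure(list(data = cln$data, target = cln$target,
                           metadata = cln$metadata), class = "sans_dataset")
      sp <- split_dataset(ds, unlist(cfg$split), seed = cfg$seed)
      write_splits(sp, dir)
      .write_manifest(dir, "split", cfg,
                      list(sizes = lapply(sp, function(p) length(p$target))))
      sp
    },
    preprocess = {
      for (nm in c("train", "test", "validation")) {
        part <- read_partition(need(file.path(dir, paste0(nm, ".h5")),
                                    "split"))
        pp <- preprocess_partition(part)
        saveRDS(pp, file.path(dir, paste0(nm, "_preprocessed.rds")))
      }
      .write_manifest(dir, "preprocess", cfg)
      invisible(NULL)
    },
    train = {
      tr <- readRDS(need(file.path(dir, "train_preprocessed.rds"),
                         "preprocess"))
      te <- readRDS(need(file.path(dir, "test_preprocessed.rds"),
                         "preprocess"))
      members <- lapply(seq_len(cfg$training$members), function(m) {
        fit <- train_cnn(tr, te, training_config(
          epochs = cfg$training$epochs, batch_size = cfg$training$batch_size,
          lr = cfg$training$lr, checkpoint = cfg$training$checkpoint,
          seed = cfg$seed + m))
        saveRDS(fit, file.path(dir, sprintf("member_%d.rds", m)))
        jsonlite::write_json(
          list(architecture = "compact_cnn_16_32_64_128",
               member = m, seed = cfg$seed + m,
               catalogue_hash = .stable_hash(sas_models()),
               best_epoch = fit$best_epoch,
               history = fit$history,
               config = unclass(fit$config)),
          file.path(dir, sprintf("member_%d.json", m)),
          auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
        fit
      })
      .write_manifest(dir, "train", cfg,
                      list(members = cfg$training$members))
      members
    },
    evaluate = {
      va <- readRDS(need(file.path(dir, "validation_preprocessed.rds"),
                         "preprocess"))
      files <- Sys.glob(file.path(dir, "member_*.rds"))
      if (!length(files))
        stop("missing upstream artifact 'member_*.rds': run 'train' first")
      members <- lapply(files, readRDS)
      probs <- ensemble_proba(members, va)
      preds <- predict_label(probs)
      topk <- data.frame(
        model = c(vapply(seq_along(members), function(m)
          sprintf("member_%d", m), character(1)), "ensemble"),
        top1 = c(vapply(members, function(m)
          topk_accuracy(predict_proba(m, va), va$y, 1), numeric(1)),
          topk_accuracy(probs, va$y, 1)),
        top3 = c(vapply(members, function(m)
          topk_accuracy(predict_proba(m, va), va$y, 3), numeric(1)),
          topk_accuracy(probs, va$y, 3)),
        top5 = c(vapply(members, function(m)
          topk_accuracy(predict_proba(m, va), va$y, 5), numeric(1)),
          topk_accuracy(probs, va$y, 5)))
      rep <- classification_report(preds, va$y, ncol(probs))
      write.csv(rep, file.path(dir, "classification_report.csv"),
                row.names = FALSE)
      write.csv(confusion_matrix(preds, va$y, ncol(probs)),
                file.path(dir, "confusion_matrix.csv"))
      jsonlite::write_json(topk, file.path(dir, "topk_accuracy.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      .write_manifest(dir, "evaluate", cfg)
      list(topk = topk, report = rep)
    },
    recommend = {
      if (is.null(input)) stop("recommend needs 'input': a CSV of counts")
      img <- as.matrix(read.csv(need(input, "an image export"),
                                header = FALSE))
      files <- Sys.glob(file.path(dir, "member_*.rds"))
      if (!length(files))
        stop("missing upstream artifact 'member_*.rds': run 'train' first")
      members <- lapply(files, readRDS)
      rec <- recommend(members, img, k = 5)
      jsonlite::write_json(
        list(ranking = rec$ranking, baseline = rec$baseline),
        file.path(dir, "recommendation.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      .write_manifest(dir, "recommend", cfg)
      rec
    })
  invisible(res)
}
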
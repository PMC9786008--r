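#' Run harness: reproducible train / cross-validation / jackknife runs
#'
#' A run configuration bundles the data source (CSV path or synthetic
#' spec), every model hyperparameter (defaulting to the reference setting
#' `H = 2`, dropout `0.5`, learning rate `0.001`, L2 `0.001`), the
#' evaluation protocol and the seed. Every command writes a manifest
#' sufficient to reproduce the run exactly.
#'
#' @name harness
#' @keywords internal
NULL

#' Build a run configuration
#'
#' @param dataset path to a dataset CSV (`id, smiles, labels...`), or NULL
#'   when `synthetic` is given.
#' @param synthetic a [synthetic_spec()], or NULL.
#' @param split evaluation protocol: `"holdout"` (90/10), `"cv5"` or
#'   `"jackknife"`.
#' @param dim,dim_embed,n_heads,dim_ff,n_iter,dropout,lr,l2 model
#'   hyperparameters (see [adr_model()]).
#' @param epochs,batch_size training schedule.
#' @param train_fraction holdout training fraction (default 0.9).
#' @param threshold label binarization threshold (default 0.5).
#' @param seed integer seed for the whole run.
#' @param outdir output directory (created if missing).
#' @return object of class `run_config`.
#' @export
run_config <- function(dataset = NULL, synthetic = NULL,
                       split = c("holdout", "cv5", "jackknife"),
                       dim = 300, dim_embed = 64, n_heads = 2, dim_ff = 1024,
                       n_iter = 5, dropout = 0.5, lr = 0.001, l2 = 0.001,
                       epochs = 100, batch_size = 32, train_fraction = 0.9,
                       threshold = 0.5, seed = 1, outdir = tempfile("moladr_run_")) {
  split <- match.arg(split)
  if (is.null(dataset) && is.null(synthetic)) {
    stop_config("run_config needs a dataset path or a synthetic spec",
                field = "dataset")
  }
  if (!is.null(dataset) && !file.exists(dataset)) {
    stop_config(sprintf("dataset path does not exist: %s", dataset),
                field = "dataset")
  }
  structure(list(dataset = dataset, synthetic = synthetic, split = split,
                 dim = dim, dim_embed = dim_embed, n_heads = n_heads,
                 dim_ff = dim_ff, n_iter = n_iter, dropout = dropout,
                 lr = lr, l2 = l2, epochs = epochs, batch_size = batch_size,
                 train_fraction = train_fraction, threshold = threshold,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

.load_records <- function(config) {
  if (!is.null(config$dataset)) load_drug_dataset(config$dataset)
  else generate_synthetic(config$synthetic)
}

.new_model <- function(config, n_labels) {
  adr_model(n_labels = n_labels, dim = config$dim,
            dim_embed = config$dim_embed, n_heads = config$n_heads,
            dim_ff = config$dim_ff, n_iter = config$n_iter,
            dropout = config$dropout, lr = config$lr, l2 = config$l2,
            seed = config$seed)
}

.write_manifest <- function(config, path, extra = list()) {
  cfg <- unclass(config)
  cfg$synthetic <- if (!is.null(config$synthetic)) {
    s <- unclass(config$synthetic); s$fragment_pool <- NULL; s
  }
  jsonlite::write_json(c(list(
    package = "moladr",
    version = as.character(utils::packageVersion("moladr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg
  ), extra), path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Train on a holdout split and evaluate
#'
#' Splits the records `train_fraction` / remainder with the configured
#' seed, trains a fresh model on the training part and evaluates on the
#' held-out part. Writes `checkpoint.json`, `metrics.csv`/`metrics.json`
#' and `manifest.json` into `config$outdir`.
#'
#' @param config a `run_config`.
#' @return list with `fit` (an `adr_fit`), `report` (`metrics_report`) and
#'   `paths`.
#' @export
cmd_train <- function(config) {
  if (!inherits(config, "run_config")) stop_config("expected run_config")
  records <- .load_records(config)
  n_labels <- length(records[[1]]$labels)
  sp <- split_train_test(records, config$train_fraction, seed = config$seed)
  model <- .new_model(config, n_labels)
  fit <- train_adr_model(sp$train, model, epochs = config$epochs,
                         batch_size = config$batch_size, seed = config$seed)
  test_df <- data.frame(id = vapply(sp$test, `[[`, character(1), "id"),
                        smiles = vapply(sp$test, `[[`, character(1), "smiles"),
                        stringsAsFactors = FALSE)
  pred <- predict_batch(fit$model, test_df, threshold = config$threshold)
  truth <- label_matrix(sp$test)[rownames(pred$prob), , drop = FALSE]
  report <- evaluate_predictions(truth, pred$prob, threshold = config$threshold)

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ckpt <- file.path(config$outdir, "checkpoint.json")
  save_checkpoint(fit$model, ckpt)
  write_metrics_report(report, file.path(config$outdir, "metrics"))
  manifest <- .write_manifest(config, file.path(config$outdir, "manifest.json"),
                              extra = list(command = "train",
                                           n_train = length(sp$train),
                                           n_test = length(sp$test),
                                           final_loss = fit$loss[length(fit$loss)]))
  list(fit = fit, report = report,
       paths = list(checkpoint = ckpt,
                    metrics = file.path(config$outdir, c("metrics.csv", "metrics.json")),
                    manifest = manifest))
}

#' Five-fold cross-validation with a mean +/- sd summary table
#'
#' @param config a `run_config` with `split = "cv5"`.
#' @param k number of folds (default 5).
#' @return list with `table` (per-fold rows plus `mean` and `sd` rows over
#'   the five metrics), `reports` (per-fold `metrics_report`s) and `paths`.
#' @export
cmd_cv <- function(config, k = 5) {
  if (!inherits(config, "run_config")) stop_config("expected run_config")
  if (config$split != "cv5") stop_config("cmd_cv needs split = 'cv5'", field = "split")
  records <- .load_records(config)
  n_labels <- length(records[[1]]$labels)
  folds <- kfold_split(records, k = k, seed = config$seed)
  reports <- vector("list", k)
  rows <- list()
  for (f in seq_len(k)) {
    model <- .new_model(config, n_labels)
    fit <- train_adr_model(folds[[f]]$train, model, epochs = config$epochs,
                           batch_size = config$batch_size,
                           seed = config$seed + f)
    val <- folds[[f]]$validation
    val_df <- data.frame(id = vapply(val, `[[`, character(1), "id"),
                         smiles = vapply(val, `[[`, character(1), "smiles"),
                         stringsAsFactors = FALSE)
    pred <- predict_batch(fit$model, val_df, threshold = config$threshold)
    truth <- label_matrix(val)[rownames(pred$prob), , drop = FALSE]
    reports[[f]] <- evaluate_predictions(truth, pred$prob,
                                         threshold = config$threshold)
    rows[[f]] <- data.frame(fold = as.character(f),
                            accuracy = reports[[f]]$accuracy,
                            precision = reports[[f]]$precision,
                            recall = reports[[f]]$recall,
                            auc = reports[[f]]$auc,
                            aupr = reports[[f]]$aupr,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "precision", "recall", "auc", "aupr")
  tab <- rbind(tab,
               cbind(data.frame(fold = "mean"),
                     as.data.frame(as.list(colMeans(tab[, metric_cols])))),
               cbind(data.frame(fold = "sd"),
                     as.data.frame(as.list(apply(tab[seq_len(k), metric_cols], 2,
                                                 stats::sd)))))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  tab_path <- file.path(config$outdir, "cv_table.csv")
  utils::write.csv(tab, tab_path, row.names = FALSE)
  manifest <- .write_manifest(config, file.path(config$outdir, "manifest.json"),
                              extra = list(command = "cv", k = k))
  list(table = tab, reports = reports,
       paths = list(table = tab_path, manifest = manifest))
}

#' Jackknife (leave-one-out) evaluation with pooled predictions
#'
#' Trains one model per record on the remaining N-1 records, predicts the
#' held-out record, pools all held-out predictions and evaluates once.
#'
#' @param config a `run_config` with `split = "jackknife"`.
#' @return list with `report` (pooled `metrics_report`), `prob` and `truth`
#'   matrices (one pooled row per record) and `paths`.
#' @export
cmd_jackknife <- function(config) {
  if (!inherits(config, "run_config")) stop_config("expected run_config")
  if (config$split != "jackknife") {
    stop_config("cmd_jackknife needs split = 'jackknife'", field = "split")
  }
  records <- .load_records(config)
  n_labels <- length(records[[1]]$labels)
  pairs <- jackknife_split(records)
  prob <- matrix(NA_real_, length(records), n_labels)
  rownames(prob) <- vapply(records, `[[`, character(1), "id")
  for (i in seq_along(pairs)) {
    model <- .new_model(config, n_labels)
    fit <- train_adr_model(pairs[[i]]$train, model, epochs = config$epochs,
                           batch_size = config$batch_size,
                           seed = config$seed + i)
    p <- model_forward(fit$model, pairs[[i]]$test[[1]], mode = "eval")
    prob[i, ] <- p
  }
  truth <- label_matrix(records)
  report <- evaluate_predictions(truth, prob, threshold = config$threshold)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_metrics_report(report, file.path(config$outdir, "metrics"))
  manifest <- .write_manifest(config, file.path(config$outdir, "manifest.json"),
                              extra = list(command = "jackknife",
                                           n = length(records)))
  list(report = report, prob = prob, truth = truth,
       paths = list(metrics = file.path(config$outdir, c("metrics.csv", "metrics.json")),
                    manifest = manifest))
}

#' Predict ADR labels for a SMILES file from a saved checkpoint
#'
#' @param checkpoint path to a `moladr-model/1` checkpoint.
#' @param smiles_file text file with one SMILES per line (optionally
#'   `smiles<TAB>id`), or a CSV with `id` and `smiles` columns.
#' @param threshold binarization threshold.
#' @param out optional output CSV path.
#' @return data.frame with id, smiles, one probability and one binary
#'   column per label; unparseable rows are flagged in the `error` column
#'   and the run continues.
#' @export
cmd_predict <- function(checkpoint, smiles_file, threshold = 0.5, out = NULL) {
  model <- load_checkpoint(checkpoint)
  if (!file.exists(smiles_file)) {
    stop_io(sprintf("SMILES file not found: %s", smiles_file), path = smiles_file)
  }
  if (grepl("\\.csv$", smiles_file)) {
    df <- utils::read.csv(smiles_file, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df))) {
      stop_validation("CSV input needs 'id' and 'smiles' columns")
    }
  } else {
    lines <- readLines(smiles_file)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    df <- data.frame(
      id = vapply(seq_along(parts), function(i)
        if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("mol%04d", i),
        character(1)),
      smiles = vapply(parts, `[[`, character(1), 1),
      stringsAsFactors = FALSE)
  }
  pred <- predict_batch(model, df, threshold = threshold)
  lab <- colnames(pred$prob) %||% paste0("label_", seq_len(model$n_labels))
  outdf <- data.frame(id = df$id, smiles = df$smiles, error = "",
                      stringsAsFactors = FALSE)
  pm <- matrix(NA_real_, nrow(df), model$n_labels,
               dimnames = list(NULL, paste0("prob_", lab)))
  lm <- matrix(NA_integer_, nrow(df), model$n_labels,
               dimnames = list(NULL, paste0("pred_", lab)))
  ok <- match(rownames(pred$prob), df$id)
  pm[ok, ] <- pred$prob
  lm[ok, ] <- pred$labels
  if (nrow(pred$failed) > 0) {
    outdf$error[match(pred$failed$id, df$id)] <- pred$failed$reason
  }
  outdf <- cbind(outdf, pm, lm)
  if (!is.null(out)) utils::write.csv(outdf, out, row.names = FALSE)
  outdf
}
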
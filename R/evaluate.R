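#' Repeated stratified k-fold cross-validation of the full pipeline
#'
#' For each of `repeats` repetitions the samples are partitioned into `k`
#' stratified folds. Within every fold, class rebalancing, optional
#' hyperparameter search and model fitting happen strictly inside the
#' training portion; the fold's test portion is only ever touched for the
#' final metric report. An audit of the sample ids seen by each fold's
#' training phase is kept so leakage can be checked exhaustively.
#'
#' @param d A [labeled_dataset()]; every class needs at least `k` members.
#' @param k Folds per repeat (default 5).
#' @param repeats Repetitions (default 20).
#' @param hp [hyperparams()] used when no search is requested.
#' @param sampling A [sampling_plan()] applied to each fold's training
#'   portion.
#' @param search Optional [search_spec()]; when supplied, hyperparameters
#'   are re-optimised inside each fold's training portion (expensive). The
#'   default `NULL` uses `hp` everywhere.
#' @param encoder Optional pretrained `tabsense_encoder`.
#' @param threshold Decision threshold for the reports.
#' @param seed Integer seed; fold assignments and fits are deterministic
#'   given it.
#' @return An object of class `cv_result`: `records` (one row per
#'   repeat x fold with the full metric panel), `summary` (mean/sd/min/max
#'   per metric), `audit` (per-fold train/test id lists) and the design
#'   parameters.
#' @export
repeated_kfold <- function(d, k = 5L, repeats = 20L, hp = hyperparams(),
                           sampling = sampling_plan(), search = NULL,
                           encoder = NULL, threshold = 0.5, seed = 1L) {
  stopifnot(inherits(d, "labeled_dataset"), k >= 2L, repeats >= 1L)
  counts <- table(d$labels)
  if (any(counts < k))
    stop("every class needs at least k = ", k, " samples; have ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  metric_keys <- c("accuracy", "auc", "average_precision", "cohen_kappa",
                   "brier_score", "f1", "jaccard", "jaccard_macro", "mcc",
                   "npv", "precision", "sensitivity", "specificity",
                   "neglog2rmsl")
  records <- vector("list", k * repeats)
  audit <- vector("list", k * repeats)
  ri <- 0L
  for (rep_i in seq_len(repeats)) {
    fold <- stratified_folds(d$labels, k, seed + rep_i)
    for (f in seq_len(k)) {
      ri <- ri + 1L
      train_ids <- d$sample_ids[fold != f]
      test_ids <- d$sample_ids[fold == f]
      train <- subset_dataset(d, train_ids)
      test <- subset_dataset(d, test_ids)
      plan <- sampling_plan(sampling$strategy, seed + 7919L * ri)
      train_rs <- resample_training(train, plan)
      fold_hp <- hp
      seen <- train_rs$sample_ids
      if (!is.null(search)) {
        sr <- optimize_hyperparams(train_rs, search, encoder)
        fold_hp <- sr$best_hyperparams
        seen <- union(seen, sr$audit_ids)
      }
      fold_hp <- hyperparams_from_list(
        utils::modifyList(unclass(fold_hp), list(seed = seed + ri)))
      fit <- tabsense_fit(train_rs, fold_hp, encoder = encoder)
      p <- predict(fit, test$features)
      repmet <- metric_suite(test$labels, p, threshold)
      rec <- data.frame(repeat_index = rep_i, fold = f,
                        n_train = nrow(train_rs$features),
                        n_test = nrow(test$features))
      for (mk in metric_keys) rec[[mk]] <- repmet[[mk]]
      records[[ri]] <- rec
      audit[[ri]] <- list(repeat_index = rep_i, fold = f,
                          train_ids = seen, test_ids = test_ids)
    }
  }
  records <- do.call(rbind, records)
  summ <- do.call(rbind, lapply(metric_keys, function(mk) {
    v <- records[[mk]]
    data.frame(metric = mk, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE),
               min = suppressWarnings(min(v, na.rm = TRUE)),
               max = suppressWarnings(max(v, na.rm = TRUE)))
  }))
  structure(list(records = records, summary = summ, audit = audit,
                 k = k, repeats = repeats, seed = as.integer(seed),
                 sampling = sampling$strategy),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold x %d repeats (%d records), sampling = %s\n",
              x$k, x$repeats, nrow(x$records), x$sampling))
  key <- x$summary[x$summary$metric %in% c("auc", "accuracy"), ]
  for (i in seq_len(nrow(key)))
    cat(sprintf("  mean %s: %.4f (sd %.4f)\n", key$metric[i], key$mean[i],
                key$sd[i]))
  invisible(x)
}

#' Write cross-validation results to disk
#'
#' @param cv A `cv_result`.
#' @param csv_path Per-fold records CSV.
#' @param json_path Optional summary JSON.
#' @return `csv_path`, invisibly.
#' @export
write_cv_result <- function(cv, csv_path, json_path = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  utils::write.csv(cv$records, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(k = cv$k, repeats = cv$repeats, seed = cv$seed,
                              sampling = cv$sampling, summary = cv$summary),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(csv_path)
}

#' Evaluate a fitted model on an untouched held-out set
#'
#' Guards against leakage: any overlap between the test sample ids and the
#' ids the model was trained (or early-stopped) on is an error.
#'
#' @param fit A [tabsense_fit()] model.
#' @param test A [labeled_dataset()] with the model's gene list.
#' @return A [metric_suite()] report.
#' @export
evaluate_holdout <- function(fit, test) {
  stopifnot(inherits(fit, "tabsense_fit"), inherits(test, "labeled_dataset"))
  overlap <- intersect(test$sample_ids, fit$training_ids)
  if (length(overlap) > 0L)
    stop("held-out evaluation refused: ", length(overlap),
         " test sample(s) were seen in training (e.g. ",
         paste(utils::head(overlap, 3L), collapse = ", "), ")")
  p <- predict(fit, test$features)
  metric_suite(test$labels, p, fit$decision_threshold)
}

#' Predict sensitivity calls for an unlabeled cohort
#'
#' @param fit A [tabsense_fit()] model.
#' @param cohort Samples x genes matrix normalised with the model's
#'   training statistics.
#' @param threshold Decision threshold; samples with probability exactly at
#'   the threshold are called sensitive.
#' @return An object of class `cohort_prediction`: data frame
#'   (`sample_id`, `probability`, `call`), per-call `counts` and the
#'   threshold.
#' @export
predict_cohort <- function(fit, cohort, threshold = 0.5) {
  stopifnot(inherits(fit, "tabsense_fit"))
  prob <- predict(fit, cohort)
  call <- factor(ifelse(prob >= threshold, "sensitive", "resistant"),
                 levels = c("resistant", "sensitive"))
  df <- data.frame(sample_id = names(prob), probability = unname(prob),
                   call = call, stringsAsFactors = FALSE)
  structure(list(predictions = df,
                 counts = c(sensitive = sum(call == "sensitive"),
                            resistant = sum(call == "resistant")),
                 decision_threshold = threshold),
            class = "cohort_prediction")
}

#' @export
print.cohort_prediction <- function(x, ...) {
  cat(sprintf("cohort_prediction: %d samples -> %d sensitive / %d resistant (threshold %.2f)\n",
              nrow(x$predictions), x$counts[["sensitive"]],
              x$counts[["resistant"]], x$decision_threshold))
  invisible(x)
}

#' Write cohort calls to CSV (one row per sample)
#'
#' The format (`sample_id`, `probability`, `call`) doubles as a ranked
#' class list for downstream enrichment tooling.
#'
#' @param prediction A `cohort_prediction`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(prediction, path) {
  stopifnot(inherits(prediction, "cohort_prediction"))
  df <- prediction$predictions
  df <- df[order(-df$probability), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
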
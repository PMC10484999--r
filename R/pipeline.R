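#' Default pipeline configuration
#'
#' Returns the full configuration template for [run_pipeline()]. Fields:
#' input paths (`expression`, `responses`, optional `unlabeled` and
#' `cohort`), `output_dir`, `drug`, `orientation` of the expression file,
#' the IC50 sensitivity `threshold_nM`, `n_top_genes` for variance-based
#' feature selection, `normalization` (`"train"` fits min-max statistics
#' on training data only; `"global"` on the full annotated matrix),
#' `test_fraction`, `sampling` strategy, `pretrain` settings, `search`
#' settings (`method = "none"` skips searching and uses `hyperparams`),
#' `cv` settings, the decision `threshold` and the master `seed`.
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(expression = NULL, responses = NULL, unlabeled = NULL, cohort = NULL,
       output_dir = "tabsense_output",
       drug = "venetoclax", orientation = "samples_as_rows",
       threshold_nM = 500, n_top_genes = 1000L,
       normalization = "train",
       test_fraction = 0.2,
       sampling = "none",
       pretrain = list(enabled = TRUE, masking_fraction = 0.5,
                       max_epochs = 30L),
       search = list(method = "none", budget = 8L, inner_k = 3L),
       hyperparams = list(),
       cv = list(enabled = FALSE, k = 5L, repeats = 20L),
       threshold = 0.5,
       seed = 1L)
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are an error; missing keys inherit defaults from
#' [default_pipeline_config()]. The configuration round-trips losslessly
#' through YAML.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A configuration list (possibly partial).
#' @export
validate_pipeline_config <- function(config) {
  def <- default_pipeline_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  if (is.null(cfg$expression) || is.null(cfg$responses))
    stop("configuration must name 'expression' and 'responses' input files")
  for (key in c("expression", "responses", "unlabeled", "cohort")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("configured ", key, " file does not exist: ", p)
  }
  stopifnot(cfg$threshold_nM > 0, cfg$n_top_genes >= 1,
            cfg$test_fraction > 0, cfg$test_fraction < 1,
            cfg$normalization %in% c("train", "global"),
            cfg$sampling %in% c("none", "over", "under"),
            cfg$search$method %in% c("none", "hardcoded", "grid", "bayes",
                                     "tpe", "superior"),
            cfg$threshold >= 0, cfg$threshold <= 1)
  cfg
}

#' Run the full sensitivity-prediction pipeline
#'
#' Executes load -> gene selection -> labeling -> train/test split ->
#' normalisation -> sampling -> (pretraining) -> (hyperparameter search)
#' -> fit -> held-out evaluation -> (cross-validation) -> (cohort
#' prediction), writing every artifact plus a manifest (stage status,
#' seeds, content digests) under `config$output_dir`.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   a YAML file path.
#' @return The manifest list, invisibly; artifacts are on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, config = cfg, stages = list(),
                   artifacts = list())
  seed <- as.integer(cfg$seed)

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, cfg$output_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  expr_raw <- stage("load", load_expression(cfg$expression, cfg$orientation))
  responses <- stage("load_responses", utils::read.csv(cfg$responses,
                                                       stringsAsFactors = FALSE))
  genes <- stage("select_genes",
                 select_top_variance_genes(expr_raw,
                                           min(cfg$n_top_genes, ncol(expr_raw))))
  expr_raw <- expr_raw[, genes, drop = FALSE]
  labels <- stage("label", binarize_response(responses, cfg$drug,
                                             rownames(expr_raw),
                                             cfg$threshold_nM))

  split <- stage("split", {
    # split on raw features; normalisation statistics are fit afterwards so
    # "train" mode never sees the held-out samples
    d_raw <- labeled_dataset(unit_scale_passthrough(expr_raw), labels)
    split_train_test(d_raw, cfg$test_fraction, seed = seed)
  })
  norm <- stage("normalize", {
    train_ids <- split$train$sample_ids
    fit_on <- if (cfg$normalization == "train")
      expr_raw[train_ids, , drop = FALSE] else expr_raw
    st <- minmax_normalize(fit_on)$stats
    list(train = labeled_dataset(
           minmax_normalize(expr_raw[train_ids, , drop = FALSE], st)$values,
           labels[train_ids]),
         test = labeled_dataset(
           minmax_normalize(expr_raw[split$test$sample_ids, , drop = FALSE],
                            st)$values,
           labels[split$test$sample_ids]),
         stats = st)
  })
  train <- stage("sample",
                 resample_training(norm$train,
                                   sampling_plan(cfg$sampling, seed + 1L)))

  encoder <- NULL
  if (isTRUE(cfg$pretrain$enabled) && !is.null(cfg$unlabeled)) {
    encoder <- stage("pretrain", {
      unl <- load_expression(cfg$unlabeled, cfg$orientation)
      missing <- setdiff(genes, colnames(unl))
      if (length(missing) > 0L)
        stop("unlabeled matrix lacks selected gene(s): ",
             paste(utils::head(missing, 5L), collapse = ", "))
      unl <- minmax_normalize(unl[, genes, drop = FALSE], norm$stats)$values
      pretrain(unl,
               hyperparams_from_list(utils::modifyList(
                 cfg$hyperparams,
                 list(max_epochs = cfg$pretrain$max_epochs, seed = seed + 2L))),
               cfg$pretrain$masking_fraction)
    })
  }

  base_hp <- hyperparams_from_list(utils::modifyList(cfg$hyperparams,
                                                     list(seed = seed + 3L)))
  hp <- base_hp
  if (cfg$search$method != "none") {
    sr <- stage("search", {
      spec <- search_spec(cfg$search$method, budget = cfg$search$budget,
                          inner_k = cfg$search$inner_k, hardcoded = base_hp,
                          seed = seed + 4L)
      optimize_hyperparams(train, spec, encoder)
    })
    hp <- sr$best_hyperparams
    trace_path <- file.path(cfg$output_dir, "search_trace.csv")
    write_search_trace(sr, trace_path)
    manifest$artifacts$search_trace <- basename(trace_path)
  }

  fit <- stage("fit", {
    inner <- split_train_test(train, 0.2, seed = seed + 5L)
    tabsense_fit(inner$train, hp, encoder = encoder,
                 validation = inner$test)
  })
  model_dir <- file.path(cfg$output_dir, "model")
  save_model(fit, model_dir)
  manifest$artifacts$model <- "model"

  report <- stage("evaluate", evaluate_holdout(fit, norm$test))
  metrics_path <- file.path(cfg$output_dir, "metrics.json")
  metric_report_json(report, metrics_path)
  manifest$artifacts$metrics <- basename(metrics_path)

  if (isTRUE(cfg$cv$enabled)) {
    cv <- stage("cross_validate", {
      full <- labeled_dataset(
        minmax_normalize(expr_raw, norm$stats)$values, labels)
      repeated_kfold(full, k = cfg$cv$k, repeats = cfg$cv$repeats,
                     hp = hp, sampling = sampling_plan(cfg$sampling, seed),
                     encoder = encoder, threshold = cfg$threshold,
                     seed = seed + 6L)
    })
    cv_path <- file.path(cfg$output_dir, "cv_records.csv")
    write_cv_result(cv, cv_path, file.path(cfg$output_dir, "cv_summary.json"))
    manifest$artifacts$cv_records <- basename(cv_path)
    manifest$artifacts$cv_summary <- "cv_summary.json"
  }

  if (!is.null(cfg$cohort)) {
    pred <- stage("predict_cohort", {
      coh <- load_expression(cfg$cohort, cfg$orientation)
      coh <- minmax_normalize(coh[, genes, drop = FALSE], norm$stats)$values
      predict_cohort(fit, coh, cfg$threshold)
    })
    cohort_path <- file.path(cfg$output_dir, "cohort_predictions.csv")
    write_cohort_csv(pred, cohort_path)
    manifest$artifacts$cohort <- basename(cohort_path)
    manifest$cohort_counts <- as.list(pred$counts)
  }

  manifest$model_fingerprint <- fit$fingerprint
  write_manifest(manifest, cfg$output_dir)
  invisible(manifest)
}

# Raw features are only range-checked later; this passthrough rescales each
# gene to [0,1] solely so the split can run on a valid labeled_dataset
# without leaking normalisation statistics (the real statistics are fit on
# the training half afterwards).
unit_scale_passthrough <- function(x) minmax_normalize(x)$values

write_manifest <- function(manifest, dir) {
  for (a in names(manifest$artifacts)) {
    p <- file.path(dir, manifest$artifacts[[a]])
    if (file.exists(p) && !dir.exists(p))
      manifest$artifacts[[a]] <- list(path = manifest$artifacts[[a]],
                                      md5 = unname(tools::md5sum(p)))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  invisible(NULL)
}
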
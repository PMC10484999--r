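#' Train and score a panel of baseline classifiers
#'
#' Fits widely used machine-learning baselines with fixed default settings
#' and a common seed, and evaluates each with the full thirteen-metric
#' suite on the validation set. Available identifiers:
#' `logistic_regression` (ridge-stabilised GLM), `random_forest`,
#' `gradient_boosting` (xgboost), `svm_rbf`, `knn` (k = 5) and
#' `naive_bayes`.
#'
#' @param train,validation [labeled_dataset()] objects sharing a gene list.
#' @param panel Character vector of baseline identifiers; duplicates are
#'   dropped with a warning, unknown identifiers are an error.
#' @param seed Integer seed applied before each model's training.
#' @param threshold Decision threshold for the metric reports.
#' @return Named list of [metric_suite()] reports, one per panel member.
#' @export
fit_baselines <- function(train, validation,
                          panel = c("logistic_regression", "random_forest",
                                    "gradient_boosting", "svm_rbf", "knn",
                                    "naive_bayes"),
                          seed = 1L, threshold = 0.5) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(validation, "labeled_dataset"))
  if (!identical(train$gene_ids, validation$gene_ids))
    stop("train and validation gene lists differ")
  if (length(panel) == 0L) stop("panel must be non-empty")
  known <- c("logistic_regression", "random_forest", "gradient_boosting",
             "svm_rbf", "knn", "naive_bayes")
  bad <- setdiff(panel, known)
  if (length(bad) > 0L)
    stop("unknown baseline identifier(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(panel)) {
    warning("duplicate baseline identifiers removed: ",
            paste(unique(panel[duplicated(panel)]), collapse = ", "))
    panel <- unique(panel)
  }
  Xtr <- train$features
  ytr <- train$labels
  Xva <- validation$features
  out <- lapply(panel, function(id) {
    local_rng(seed)
    prob <- baseline_prob(id, Xtr, ytr, Xva)
    metric_suite(validation$labels, prob, threshold)
  })
  stats::setNames(out, panel)
}

baseline_prob <- function(id, Xtr, ytr, Xva) {
  y01 <- as.integer(ytr == "sensitive")
  switch(id,
    logistic_regression = {
      # small ridge penalty keeps separable high-dimensional fits stable
      fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                            lambda = 1e-3)
      drop(stats::predict(fit, Xva, type = "response"))
    },
    random_forest = {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = 500L)
      stats::predict(fit, Xva, type = "prob")[, "sensitive"]
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(Xtr, label = y01, nthread = 1L)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              max_depth = 4L, eta = 0.1,
                                              nthread = 1L),
                                dtrain, nrounds = 100L)
      stats::predict(fit, xgboost::xgb.DMatrix(Xva, nthread = 1L))
    },
    svm_rbf = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", probability = TRUE)
      attr(stats::predict(fit, Xva, probability = TRUE),
           "probabilities")[, "sensitive"]
    },
    knn = {
      pr <- class::knn(Xtr, Xva, ytr, k = 5L, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "sensitive", win, 1 - win)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      stats::predict(fit, Xva, type = "raw")[, "sensitive"]
    },
    stop("unknown baseline identifier: ", id))
}
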
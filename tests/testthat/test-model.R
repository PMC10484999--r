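test_that("hyperparameter bundles validate ranges and round-trip flat maps", {
  hp <- hyperparams(decision_width = 16, learning_rate = 0.01)
  expect_identical(hp$decision_width, 16L)
  rt <- hyperparams_from_list(unclass(hp))
  expect_identical(rt, hp)
  expect_error(hyperparams(decision_width = 0))
  expect_error(hyperparams(relaxation_gamma = 0.5))
  expect_error(hyperparams_from_list(list(not_a_field = 1)), "not_a_field")
})

test_that("pretraining is seed-deterministic, reduces reconstruction loss, validates input", {
  b <- make_bench(2, n_per_class = 100L, n_genes = 50L, n_informative = 5L)
  X <- b$data$features
  cfg <- quick_hp(seed = 4, max_epochs = 15L)
  e1 <- pretrain(X, cfg)
  e2 <- pretrain(X, cfg)
  expect_identical(e1$fingerprint, e2$fingerprint)
  expect_lt(e1$final_loss, e1$loss_history[1])
  expect_identical(e1$n_features, 50L)

  expect_error(pretrain(X, cfg, masking_fraction = 0), "masking_fraction")
  expect_error(pretrain(X, cfg, masking_fraction = 1), "masking_fraction")
  expect_error(pretrain(X[1, , drop = FALSE], cfg), "2 samples")
  expect_error(pretrain(X * 3, cfg), "normalised")
})

test_that("fitting learns a separable problem and enforces its contracts", {
  # one informative gene, 5-sigma shift: cleanly separable
  b <- make_bench(7, n_per_class = 100L, n_genes = 10L, n_informative = 1L,
                  effect_size = 5)
  fit <- tabsense_fit(b$data, quick_hp(seed = 1, max_epochs = 50L))
  train_acc <- mean((fit$fitted >= 0.5) == (b$data$labels == "sensitive"))
  expect_equal(train_acc, 1.0)

  # probabilities valid and deterministic; permuted columns realigned by name
  p1 <- predict(fit, b$data$features)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict(fit, b$data$features))
  perm <- b$data$features[, sample(ncol(b$data$features))]
  expect_identical(predict(fit, perm), p1)

  extra <- cbind(b$data$features, gX = 0.5)
  expect_error(predict(fit, extra), "gX")
  expect_error(predict(fit, b$data$features[, -1]), "missing")

  single <- labeled_dataset(b$data$features[b$data$labels == "sensitive", ],
                            b$data$labels[b$data$labels == "sensitive"])
  expect_error(tabsense_fit(single, quick_hp()), "single class")

  enc <- pretrain(b$data$features[, 1:5], quick_hp(max_epochs = 5L))
  expect_error(tabsense_fit(b$data, quick_hp(), encoder = enc), "features")
})

test_that("identical seeds give identical fits; S3 methods are coherent", {
  b <- make_bench(5, n_per_class = 40L, n_genes = 20L)
  f1 <- tabsense_fit(b$data, quick_hp(seed = 9, max_epochs = 10L))
  f2 <- tabsense_fit(b$data, quick_hp(seed = 9, max_epochs = 10L))
  expect_identical(f1$fingerprint, f2$fingerprint)
  expect_identical(predict(f1, b$data$features), predict(f2, b$data$features))

  expect_output(print(f1), "attentive tabular")
  expect_s3_class(summary(f1)$training_metrics, "metric_report")
  expect_length(coef(f1), 20L)
  expect_true(all(coef(f1) >= 0))
  expect_length(residuals(f1), 80L)

  # plain-text save/load round-trip preserves predictions
  dir <- tempfile()
  save_model(f1, dir)
  f3 <- load_model(dir)
  expect_equal(predict(f3, b$data$features), predict(f1, b$data$features),
               tolerance = 1e-9)
})

test_that("early stopping on validation restores the best epoch", {
  b <- make_bench(6, n_per_class = 60L, n_genes = 30L)
  sp <- split_train_test(b$data, 0.3, seed = 2)
  fit <- tabsense_fit(sp$train, quick_hp(seed = 2, max_epochs = 60L,
                                         early_stop_patience = 5L),
                      validation = sp$test)
  expect_lte(fit$best_epoch, nrow(fit$history))
  expect_true(is.finite(fit$best_val_score))
  expect_identical(fit$best_val_score,
                   max(fit$history$val_score[seq_len(fit$best_epoch)],
                       na.rm = TRUE))
  # validation ids recorded for the leakage guard
  expect_true(all(sp$test$sample_ids %in% fit$training_ids))
})

test_that("pretraining does not hurt: fine-tuned vs cold-start on paired seeds", {
  deltas <- sapply(1:10, function(s) {
    b <- make_bench(s, n_per_class = 50L, n_genes = 30L, n_informative = 5L,
                    effect_size = 2, n_unlabeled = 80L)
    unl <- minmax_normalize(b$sim$unlabeled, b$stats)$values
    sp <- split_train_test(b$data, 0.3, seed = s)
    enc <- pretrain(unl, quick_hp(seed = s, max_epochs = 10L))
    hp <- quick_hp(seed = s, max_epochs = 25L)
    warm <- tabsense_fit(sp$train, hp, encoder = enc)
    cold <- tabsense_fit(sp$train, hp)
    test_auc(sp$test, warm) - test_auc(sp$test, cold)
  })
  expect_gte(median(deltas), -0.05)
})

test_that("learning collapses to chance when the informative genes are removed", {
  aucs <- sapply(1:10, function(s) {
    b <- make_bench(s, n_per_class = 50L, n_genes = 30L, n_informative = 10L,
                    effect_size = 3)
    keep <- setdiff(b$data$gene_ids, b$sim$truth$informative_gene_ids)
    stripped <- labeled_dataset(b$data$features[, keep], b$data$labels)
    sp <- split_train_test(stripped, 0.3, seed = s)
    fit <- tabsense_fit(sp$train, quick_hp(seed = s, max_epochs = 25L))
    test_auc(sp$test, fit)
  })
  expect_lt(median(aucs), 0.65)
})

test_that("baseline panel trains every member and dominates on separable data", {
  sim <- simulate_pharmacogenomic(200, 200, 30, 10, effect_size = 3,
                                  noise_sd = 1, seed = 7)
  d <- labeled_dataset(minmax_normalize(sim$expression)$values, sim$labels)
  sp <- split_train_test(d, 0.25, seed = 7)
  reports <- fit_baselines(sp$train, sp$test, seed = 7)
  expect_named(reports, c("logistic_regression", "random_forest",
                          "gradient_boosting", "svm_rbf", "knn",
                          "naive_bayes"))
  for (nm in names(reports)) {
    expect_s3_class(reports[[nm]], "metric_report")
    expect_gte(reports[[nm]]$auc, 0.95)
  }

  one <- fit_baselines(sp$train, sp$test, panel = "knn", seed = 1)
  expect_length(one, 1L)
  expect_warning(dup <- fit_baselines(sp$train, sp$test,
                                      panel = c("knn", "knn"), seed = 1),
                 "duplicate")
  expect_length(dup, 1L)
  expect_error(fit_baselines(sp$train, sp$test, panel = "deep_thought"),
               "deep_thought")
})
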
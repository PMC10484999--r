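test_that("confusion counts reproduce the printed worked example and edge cases", {
  # 191 resistant of which 22 called sensitive; 140 sensitive of which 14
  # called resistant
  v <- vectors_from_counts(tp = 126, fp = 22, tn = 169, fn = 14)
  cc <- confusion_counts(v$labels, v$predicted)
  expect_identical(unclass(cc)[c("tp", "fp", "tn", "fn")],
                   list(tp = 126L, fp = 22L, tn = 169L, fn = 14L))

  perfect <- confusion_counts(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5))
  expect_identical(unclass(perfect)[c("tp", "tn", "fp", "fn")],
                   list(tp = 5L, tn = 5L, fp = 0L, fn = 0L))
  inverted <- confusion_counts(rep(c(1, 0), each = 5), rep(c(0, 1), each = 5))
  expect_identical(unclass(inverted)[c("tp", "tn", "fp", "fn")],
                   list(tp = 0L, tn = 0L, fp = 5L, fn = 5L))
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "length")
})

test_that("worked-example metrics match count arithmetic", {
  v <- vectors_from_counts(tp = 126, fp = 22, tn = 169, fn = 14)
  rep <- metric_suite(v$labels, as.numeric(v$predicted))
  expect_equal(rep$accuracy, 295 / 331)
  expect_equal(rep$sensitivity, 126 / 140)
  expect_equal(rep$specificity, 169 / 191)
  expect_equal(rep$precision, 126 / 148)
  expect_equal(rep$npv, 169 / 183)
  expect_equal(rep$f1, 252 / 288)
  expect_equal(rep$jaccard, 126 / 162)
  expect_equal(rep$jaccard_macro, (126 / 162 + 169 / 205) / 2)
})

test_that("Cohen-MCC combination matches closed forms on the worked example", {
  v <- vectors_from_counts(tp = 126, fp = 22, tn = 169, fn = 14)
  km <- cohen_mcc(v$labels, v$predicted)
  # independent closed-form oracle from the raw counts
  tp <- 126; fp <- 22; tn <- 169; fn <- 14; n <- 331
  mcc_o <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa_o <- (po - pe) / (1 - pe)
  expect_equal(km$mcc, mcc_o)
  expect_equal(km$kappa, kappa_o)
  expect_equal(km$combined, (kappa_o + mcc_o) / 2)
  expect_equal(round(km$kappa, 3), 0.779)
  expect_equal(round(km$mcc, 3), 0.780)
  expect_equal(round(km$combined, 3), 0.779)

  perfect <- cohen_mcc(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(perfect$combined, 1)

  # no-association limit on a large balanced sample
  set.seed(123)
  y <- rep(c(0, 1), 5000)
  p <- sample(y)
  null_km <- cohen_mcc(y, p)
  expect_lt(abs(null_km$combined), 0.1)

  # degenerate table -> 0 with flag, min combiner available
  deg <- cohen_mcc(c(1, 1), c(1, 1))
  expect_true(deg$degenerate)
  expect_identical(deg$mcc, 0)
  expect_identical(cohen_mcc(c(1, 0), c(1, 1), combine = "min")$combined, 0)
})

test_that("NegLog2RMSL closed forms, monotonicity and clamp", {
  expect_equal(neglog2_rmsl(c(0, 1, 0, 1), rep(0.5, 4)), 1.0)
  expect_equal(neglog2_rmsl(c(1, 1, 0, 0), c(0.75, 0.75, 0.25, 0.25)), 2.0)
  expect_equal(neglog2_rmsl(c(1, 0), c(1, 0)), -log2(1e-6))
  expect_error(neglog2_rmsl(numeric(0), numeric(0)), "empty")

  # strictly decreasing in RMSL until the clamp
  set.seed(1)
  y <- rep(c(0, 1), 10)
  scores <- sapply(seq(0.45, 0.05, by = -0.05), function(err) {
    neglog2_rmsl(y, abs(y - err))
  })
  expect_true(all(diff(scores) > 0))
})

test_that("thresholded metrics agree with a brute-force set oracle on all labelings n <= 8", {
  set.seed(7)
  for (n in c(2L, 5L, 8L)) {
    p <- runif(n)
    for (code in 0:(2^n - 1)) {
      y <- as.integer(intToBits(code)[1:n])
      rep <- metric_suite(y, p, threshold = 0.5)
      pred <- as.integer(p >= 0.5)
      tp <- sum(y & pred); fp <- sum(!y & pred)
      tn <- sum(!y & !pred); fn <- sum(y & !pred)
      expect_identical(rep$confusion$tp, tp)
      expect_identical(rep$confusion$fp, fp)
      expect_equal(rep$accuracy, (tp + tn) / n)
      expect_equal(rep$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(rep$sensitivity, if (tp + fn == 0) 0 else tp / (tp + fn))
      expect_equal(rep$f1,
                   if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
      expect_equal(rep$jaccard,
                   if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn))
    }
  }
})

test_that("probability metrics: perfect, constant, AUC invariances, pROC cross-check", {
  y <- rep(c(1, 0), each = 10)
  perfect <- metric_suite(y, as.numeric(y))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$average_precision, 1)
  expect_equal(perfect$brier_score, 0)

  # constant 0.5 on a balanced set: brier 0.25; ties classified positive
  const <- metric_suite(y, rep(0.5, 20))
  expect_equal(const$brier_score, 0.25)
  expect_identical(const$confusion$fp, 10L)
  expect_identical(const$confusion$tp, 10L)

  set.seed(11)
  p <- runif(30)
  yy <- rbinom(30, 1, p)
  if (length(unique(yy)) == 1L) yy[1] <- 1 - yy[1]
  m1 <- metric_suite(yy, p)
  # AUC invariant under strictly monotone transforms
  expect_equal(metric_suite(yy, p^3)$auc, m1$auc)
  expect_equal(metric_suite(yy, plogis(5 * p - 2))$auc, m1$auc)
  # independent implementation check
  expect_equal(m1$auc,
               as.numeric(suppressMessages(pROC::auc(
                 yy, p, levels = c(0, 1), direction = "<"))))

  # MCC/kappa symmetry under joint label/prediction inversion
  pred <- as.integer(p >= 0.5)
  a <- cohen_mcc(yy, pred)
  b <- cohen_mcc(1 - yy, 1 - pred)
  expect_equal(a$mcc, b$mcc)
  expect_equal(a$kappa, b$kappa)

  single <- metric_suite(rep(1, 5), runif(5))
  expect_true("auc_undefined" %in% single$flags)
  expect_true(is.na(single$auc))
  expect_false(is.na(single$accuracy))
})

test_that("metric reports serialise to flat JSON with confusion embedded", {
  v <- vectors_from_counts(10, 2, 9, 3)
  rep <- metric_suite(v$labels, as.numeric(v$predicted))
  js <- jsonlite::fromJSON(metric_report_json(rep))
  expect_equal(js$accuracy, rep$accuracy)
  expect_identical(js$tp, 10L)
  expect_identical(js$fn, 3L)
})
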
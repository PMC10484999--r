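test_that("expression loading round-trips both orientations and rejects bad input", {
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(g1 = c(1, 3), g2 = c(2, 4), row.names = c("s1", "s2")),
            tf)
  m <- load_expression(tf)
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(m[["s1", "g1"]], 1)
  expect_identical(m[["s2", "g2"]], 4)

  mt <- load_expression(tf, orientation = "genes_as_rows")
  expect_identical(mt, t(m))

  # gzip round-trip through the writer
  gz <- tempfile(fileext = ".csv.gz")
  con <- gzfile(gz, "w"); writeLines(readLines(tf), con); close(con)
  expect_identical(load_expression(gz), m)

  dup <- tempfile(fileext = ".csv")
  writeLines(c("id,gA,gA", "s1,1,2", "s2,3,4"), dup)
  expect_error(load_expression(dup), "gA")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("id,gA,gB", "s1,1,x", "s2,3,4"), bad)
  expect_error(load_expression(bad), "s1")
})

test_that("variance-based gene selection matches a brute-force oracle", {
  set.seed(42)
  x <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(paste0("s", 1:8), paste0("g", 1:6)))
  x[, "g3"] <- 5 # constant gene

  # brute force: per-gene variance, sorted
  oracle <- names(sort(apply(x, 2, var), decreasing = TRUE))
  expect_identical(select_top_variance_genes(x, 2), oracle[1:2])
  expect_identical(select_top_variance_genes(x, 6), oracle)
  # constant gene ranks last
  expect_identical(utils::tail(select_top_variance_genes(x, 6), 1), "g3")
  expect_warning(all_g <- select_top_variance_genes(x, 99), "exceeds")
  expect_length(all_g, 6L)

  # deterministic lexicographic tie-break for equal variances
  tie <- cbind(a = c(0, 1), b = c(0, 1), c = c(0, 2))
  rownames(tie) <- c("s1", "s2")
  expect_identical(select_top_variance_genes(tie, 3), c("c", "a", "b"))
})

test_that("min-max normalisation obeys endpoints, constants, clipping, idempotence", {
  x <- cbind(g1 = c(0, 5, 10), g2 = c(7, 7, 7))
  rownames(x) <- paste0("s", 1:3)
  nm <- minmax_normalize(x)
  expect_equal(unname(nm$values[, "g1"]), c(0, 0.5, 1))
  expect_equal(unname(nm$values[, "g2"]), c(0, 0, 0))

  # external stats clip out-of-range values
  y <- cbind(g1 = 12, g2 = 3)
  rownames(y) <- "s9"
  expect_equal(unname(minmax_normalize(y, nm$stats)$values[1, "g1"]), 1)

  # idempotence: renormalising with its own stats is the identity
  nm2 <- minmax_normalize(nm$values)
  renorm <- minmax_normalize(nm$values, nm2$stats)$values
  expect_equal(renorm, nm$values, tolerance = 1e-12)

  z <- cbind(g_new = 1)
  rownames(z) <- "s1"
  expect_error(minmax_normalize(z, nm$stats), "g_new")
})

test_that("IC50 binarisation uses a strict 500 nM threshold and is total", {
  resp <- data.frame(sample_id = c("a", "b", "c"), drug = "venetoclax",
                     ic50_nM = c(300, 500, 499.9))
  lab <- binarize_response(resp, "venetoclax")
  expect_identical(as.character(lab), c("sensitive", "resistant", "sensitive"))

  # every positive finite IC50 maps to exactly one class
  ic <- c(1e-6, 1, 499.999, 500, 500.001, 1e9)
  lab2 <- binarize_response(data.frame(sample_id = paste0("s", seq_along(ic)),
                                       drug = "d", ic50_nM = ic), "d")
  expect_false(anyNA(lab2))
  expect_identical(as.character(lab2),
                   ifelse(ic < 500, "sensitive", "resistant"))

  expect_error(binarize_response(resp, "venetoclax", sample_ids = c("a", "zz")),
               "zz")
})

test_that("train/test split partitions samples, stratifies, and is seed-deterministic", {
  b <- make_bench(1, n_per_class = 10L, n_genes = 5L, n_informative = 1L)
  for (seed in c(1, 7, 99)) {
    sp <- split_train_test(b$data, 0.2, seed = seed)
    expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0L)
    expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids),
                    b$data$sample_ids)
  }
  sp1 <- split_train_test(b$data, 0.2, seed = 5)
  sp2 <- split_train_test(b$data, 0.2, seed = 5)
  expect_identical(sp1$test$sample_ids, sp2$test$sample_ids)

  # 50/50 classes, n = 20, stratified 0.2 -> 2 sensitive + 2 resistant
  expect_identical(unname(table(sp1$test$labels)["sensitive"]), 2L)
  expect_identical(unname(table(sp1$test$labels)["resistant"]), 2L)
})

test_that("tripartite resampling balances classes and preserves samples under 'none'", {
  sim <- simulate_pharmacogenomic(3, 10, 8, 2, seed = 3)
  d <- labeled_dataset(minmax_normalize(sim$expression)$values, sim$labels)

  none <- resample_training(d, sampling_plan("none"))
  expect_identical(none$features, d$features)
  expect_identical(none$labels, d$labels)

  over <- resample_training(d, sampling_plan("over", seed = 2))
  expect_identical(unname(table(over$labels)["sensitive"]), 10L)
  expect_identical(unname(table(over$labels)["resistant"]), 10L)
  expect_length(attr(over, "synthetic"), 7L)
  # duplicates only of minority-class originals
  expect_true(all(sub("\\.dup\\d+$", "", attr(over, "synthetic")) %in%
                    d$sample_ids[d$labels == "sensitive"]))

  under <- resample_training(d, sampling_plan("under", seed = 2))
  expect_identical(unname(table(under$labels)["sensitive"]), 3L)
  expect_identical(unname(table(under$labels)["resistant"]), 3L)
  expect_true(all(under$sample_ids %in% d$sample_ids))

  single <- labeled_dataset(d$features[d$labels == "resistant", ],
                            d$labels[d$labels == "resistant"])
  expect_error(resample_training(single, sampling_plan("over")), "both classes")
})
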
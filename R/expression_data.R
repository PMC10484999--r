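#' Load an expression matrix from delimited text
#'
#' Reads a CSV or TSV file (optionally gzip-compressed) holding a numeric
#' expression matrix with one header row and one identifier column, and
#' returns it in the package's internal convention: samples as rows, genes
#' as columns.
#'
#' @param path Path to a CSV/TSV file. The delimiter is inferred from the
#'   file extension (`.tsv`/`.txt` implies tab, otherwise comma). Gzip
#'   compression (`.gz`) is handled transparently.
#' @param orientation Either `"samples_as_rows"` (default) or
#'   `"genes_as_rows"`; the matrix is transposed as needed so the return
#'   value is always samples x genes.
#' @return A numeric matrix with sample ids as rownames and gene ids as
#'   colnames; all values are finite.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(g1 = c(1, 3), g2 = c(2, 4), row.names = c("s1", "s2")), tf)
#' load_expression(tf)
#' @export
load_expression <- function(path, orientation = c("samples_as_rows", "genes_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)(\\.gz)?$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  ids <- as.character(df[[1L]])
  header <- colnames(df)[-1L] # before subsetting: `[.data.frame` dedupes names
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate identifiers in first column: ", paste(unique(dup), collapse = ", "))
  dupc <- header[duplicated(header)]
  if (length(dupc) > 0L)
    stop("duplicate identifiers in header: ", paste(unique(dupc), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  colnames(body) <- header
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0L)
        stop("non-numeric value at row '", ids[bad[1L]], "', column '",
             colnames(body)[j], "': ", v[bad[1L]])
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (anyNA(m) || any(!is.finite(m)))
    stop("matrix contains missing or non-finite values; impute or filter upstream")
  if (orientation == "genes_as_rows") m <- t(m)
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix in the dialect `load_expression` reads
#'
#' @param x Samples x genes numeric matrix with dimnames.
#' @param path Output path; `.tsv` selects tab separation.
#' @param id_column Name for the identifier column header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "sample_id") {
  sep <- if (grepl("\\.(tsv|txt)(\\.gz)?$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select the most variable genes
#'
#' Ranks genes by per-gene variance across samples (descending) and returns
#' the top `k`. Ties are broken lexicographically by gene id so the ranking
#' is deterministic.
#'
#' @param x Samples x genes numeric matrix.
#' @param k Number of genes to keep (`k >= 1`). When `k` exceeds the number
#'   of genes, all genes are returned with a warning.
#' @return Character vector of gene ids, ordered by decreasing variance.
#' @export
select_top_variance_genes <- function(x, k) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (length(k) != 1L || !is.finite(k) || k < 1L) stop("k must be a positive integer")
  k <- as.integer(k)
  v <- apply(x, 2L, stats::var)
  if (k > length(v)) {
    warning("k = ", k, " exceeds the ", length(v), " available genes; returning all")
    k <- length(v)
  }
  ord <- order(-v, colnames(x))
  colnames(x)[ord][seq_len(k)]
}

#' Min-max normalise an expression matrix
#'
#' Rescales each gene to `[0, 1]` via `(x - min) / (max - min)`. When
#' `stats` (per-gene min/max fitted elsewhere, typically on training data)
#' is supplied it is applied instead of freshly computed statistics, and
#' values falling outside `[0, 1]` are clipped. A constant gene maps to 0.
#'
#' @param x Samples x genes numeric matrix.
#' @param stats Optional list with numeric vectors `min` and `max`, named by
#'   gene; every gene of `x` must be present.
#' @return A list with `values` (the normalised matrix) and `stats` (the
#'   per-gene min/max actually used), so the same statistics can be applied
#'   to held-out or unlabeled data.
#' @export
minmax_normalize <- function(x, stats = NULL) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  genes <- colnames(x)
  if (is.null(stats)) {
    mn <- apply(x, 2L, min)
    mx <- apply(x, 2L, max)
  } else {
    missing <- setdiff(genes, names(stats$min))
    if (length(missing) > 0L)
      stop("genes absent from supplied normalisation stats: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    mn <- stats$min[genes]
    mx <- stats$max[genes]
  }
  rng <- mx - mn
  out <- sweep(x, 2L, mn, "-")
  # constant gene: range 0 -> whole column becomes 0, not NaN
  safe <- ifelse(rng > 0, rng, 1)
  out <- sweep(out, 2L, safe, "/")
  out[, rng == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  list(values = out, stats = list(min = stats::setNames(mn, genes),
                                  max = stats::setNames(mx, genes)))
}

#' Binarise IC50 drug response into sensitivity labels
#'
#' Applies the strict rule: a sample is `sensitive` iff its IC50 is below
#' `threshold_nM`; the boundary value itself is `resistant`.
#'
#' @param responses Data frame with columns `sample_id`, `drug`, `ic50_nM`.
#' @param drug Drug name to label for.
#' @param sample_ids Samples requiring a label; defaults to every sample in
#'   the table. Missing IC50s are an error naming the samples.
#' @param threshold_nM Sensitivity cut-off in nM (default 500).
#' @return Factor with levels `c("resistant", "sensitive")`, named by sample.
#' @export
binarize_response <- function(responses, drug, sample_ids = NULL, threshold_nM = 500) {
  stopifnot(all(c("sample_id", "drug", "ic50_nM") %in% colnames(responses)),
            threshold_nM > 0)
  tab <- responses[responses$drug == drug, , drop = FALSE]
  if (anyDuplicated(tab$sample_id))
    stop("duplicate (sample, drug) pairs for drug ", drug)
  if (is.null(sample_ids)) sample_ids <- tab$sample_id
  idx <- match(sample_ids, tab$sample_id)
  if (anyNA(idx))
    stop("no IC50 recorded for drug ", drug, " in samples: ",
         paste(utils::head(sample_ids[is.na(idx)], 5L), collapse = ", "))
  ic50 <- tab$ic50_nM[idx]
  if (any(!is.finite(ic50) | ic50 <= 0)) stop("IC50 values must be positive and finite")
  lab <- factor(ifelse(ic50 < threshold_nM, "sensitive", "resistant"),
                levels = c("resistant", "sensitive"))
  stats::setNames(lab, sample_ids)
}

#' Bundle normalised features and labels into a labeled dataset
#'
#' @param features Samples x genes matrix with every value in `[0, 1]`.
#' @param labels Factor (levels `resistant`, `sensitive`) or character
#'   vector, one per sample, aligned to `rownames(features)` by name when
#'   named.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels) {
  stopifnot(is.matrix(features), !is.null(rownames(features)), !is.null(colnames(features)))
  if (!is.null(names(labels))) labels <- labels[rownames(features)]
  if (length(labels) != nrow(features)) stop("one label per sample required")
  labels <- factor(as.character(labels), levels = c("resistant", "sensitive"))
  if (anyNA(labels)) stop("labels must be 'resistant' or 'sensitive'")
  if (any(features < -1e-12 | features > 1 + 1e-12))
    stop("features must be min-max normalised to [0, 1]")
  structure(list(features = features,
                 labels = stats::setNames(labels, rownames(features)),
                 sample_ids = rownames(features),
                 gene_ids = colnames(features)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", nrow(x$features), "samples x", ncol(x$features), "genes\n")
  print(table(x$labels))
  invisible(x)
}

subset_dataset <- function(d, ids) {
  labeled_dataset(d$features[ids, , drop = FALSE], d$labels[ids])
}

#' Stratified (or simple) train/test split
#'
#' Partitions the samples of a labeled dataset into disjoint train and test
#' sets. Under stratification each class contributes
#' `round(test_fraction * class size)` samples (at least one) to the test
#' set, so test class proportions stay within one sample of the overall
#' proportions.
#'
#' @param d A [labeled_dataset()].
#' @param test_fraction Fraction of samples held out, in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return List with elements `train` and `test` (both `labeled_dataset`).
#' @export
split_train_test <- function(d, test_fraction = 0.2, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(d, "labeled_dataset"),
            test_fraction > 0, test_fraction < 1)
  if (nlevels(droplevels(d$labels)) < 2L) stop("both classes must be present")
  rng <- local_rng(seed)
  ids <- d$sample_ids
  if (stratified) {
    small <- names(which(table(d$labels) < 2L))
    if (length(small) > 0L)
      stop("stratified split needs >= 2 samples per class; too few: ",
           paste(small, collapse = ", "))
    test_ids <- unlist(lapply(levels(d$labels), function(cl) {
      cls <- ids[d$labels == cl]
      n_test <- max(1L, min(length(cls) - 1L, round(test_fraction * length(cls))))
      sample(cls, n_test)
    }), use.names = FALSE)
  } else {
    n_test <- max(1L, min(length(ids) - 1L, round(test_fraction * length(ids))))
    test_ids <- sample(ids, n_test)
  }
  train_ids <- setdiff(ids, test_ids)
  list(train = subset_dataset(d, train_ids), test = subset_dataset(d, test_ids))
}

#' Describe a tripartite sampling plan
#'
#' The three options are `none` (training data passed through unaltered),
#' `over` (minority class grown to the majority count by resampling with
#' replacement) and `under` (majority class reduced to the minority count
#' by random removal).
#'
#' @param strategy One of `"none"`, `"over"`, `"under"`.
#' @param seed Integer seed used by the randomised strategies.
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(strategy = c("none", "over", "under"), seed = 1L) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy, seed = as.integer(seed)), class = "sampling_plan")
}

#' Rebalance training data according to a sampling plan
#'
#' Applies to training data only: held-out test samples must never pass
#' through this operation, so that artificially duplicated samples cannot
#' influence the predictive assessment. Oversampled duplicates get suffixed
#' sample ids (`id.dup1`, ...) and are flagged in the `synthetic` attribute.
#'
#' @param train A [labeled_dataset()] containing both classes.
#' @param plan A [sampling_plan()].
#' @return A `labeled_dataset` with equal class counts under `over`/`under`,
#'   or `train` unchanged under `none`.
#' @export
resample_training <- function(train, plan = sampling_plan()) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(plan, "sampling_plan"))
  counts <- table(train$labels)
  if (any(counts == 0L)) stop("resampling requires both classes in the training data")
  if (plan$strategy == "none") return(train)
  rng <- local_rng(plan$seed)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(names(counts), minority)
  min_ids <- train$sample_ids[train$labels == minority]
  maj_ids <- train$sample_ids[train$labels == majority]
  if (plan$strategy == "under") {
    keep <- c(min_ids, sample(maj_ids, length(min_ids)))
    out <- subset_dataset(train, keep)
    attr(out, "synthetic") <- character(0L)
    return(out)
  }
  extra <- sample(min_ids, length(maj_ids) - length(min_ids), replace = TRUE)
  feats <- rbind(train$features, train$features[extra, , drop = FALSE])
  new_ids <- if (length(extra) > 0L) paste0(extra, ".dup", seq_along(extra)) else character(0L)
  rownames(feats) <- c(train$sample_ids, new_ids)
  labs <- c(as.character(train$labels), rep(minority, length(extra)))
  out <- labeled_dataset(feats, stats::setNames(labs, rownames(feats)))
  attr(out, "synthetic") <- new_ids
  out
}

# Seeded RNG scoped to the calling function: saves and restores .Random.seed
# so library code never perturbs the caller's stream.
local_rng <- function(seed, envir = parent.frame()) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  expr <- if (has_seed) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}
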
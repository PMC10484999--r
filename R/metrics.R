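#' Confusion counts for binary sensitivity predictions
#'
#' Positive class is `sensitive`. Inputs may be factors with levels
#' `c("resistant", "sensitive")`, the strings themselves, or 0/1 vectors
#' (1 = sensitive).
#'
#' @param labels True labels.
#' @param predicted Predicted labels, same length and encoding.
#' @return A list of class `confusion_counts` with integer `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(labels, predicted) {
  y <- as_binary01(labels)
  p <- as_binary01(predicted)
  if (length(y) != length(p)) stop("labels and predictions differ in length")
  structure(list(tp = sum(y == 1 & p == 1),
                 fp = sum(y == 0 & p == 1),
                 tn = sum(y == 0 & p == 0),
                 fn = sum(y == 1 & p == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion (positive = sensitive): tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

as_binary01 <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    bad <- setdiff(unique(x), c("resistant", "sensitive"))
    if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
    return(as.integer(x == "sensitive"))
  }
  if (is.logical(x)) return(as.integer(x))
  if (!all(x %in% c(0, 1))) stop("binary vector must contain only 0/1")
  as.integer(x)
}

#' Negative log2 root-mean-square loss
#'
#' The model-selection score used throughout the package: the root mean
#' square loss between predicted probabilities of the positive class and
#' the 0/1 labels, passed through a negative base-2 logarithm so that
#' *higher is better*. The RMSL is clamped at `eps` before taking the
#' logarithm so a perfect probability vector yields the finite ceiling
#' `-log2(eps)`.
#'
#' @param labels Binary labels (see [confusion_counts()] for encodings).
#' @param probabilities Probabilities of `sensitive`, in `[0, 1]`.
#' @param eps Clamp for the RMSL (default `1e-6`).
#' @return A single number; strictly decreasing in the RMSL until the clamp.
#' @examples
#' neglog2_rmsl(c(0, 1), c(0.5, 0.5)) # RMSL 0.5 -> 1
#' @export
neglog2_rmsl <- function(labels, probabilities, eps = 1e-6) {
  y <- as_binary01(labels)
  p <- as.numeric(probabilities)
  if (length(y) == 0L) stop("empty input")
  if (length(y) != length(p)) stop("labels and probabilities differ in length")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  rmsl <- sqrt(mean((p - y)^2))
  -log2(max(rmsl, eps))
}

#' Combined Cohen's kappa / Matthews correlation score
#'
#' Computes Cohen's kappa and the Matthews correlation coefficient from the
#' 2x2 confusion table and combines them into a single scalar. A degenerate
#' table (any zero marginal) leaves the affected statistic defined as 0 and
#' sets the `degenerate` flag.
#'
#' @param labels,predicted Binary vectors as in [confusion_counts()].
#' @param combine `"mean"` (default, arithmetic mean) or `"min"`.
#' @return List with `kappa`, `mcc`, `combined`, `degenerate`.
#' @export
cohen_mcc <- function(labels, predicted, combine = c("mean", "min")) {
  combine <- match.arg(combine)
  cc <- confusion_counts(labels, predicted)
  km <- kappa_mcc_from_counts(cc)
  comb <- if (combine == "mean") (km$kappa + km$mcc) / 2 else min(km$kappa, km$mcc)
  c(km, list(combined = comb))
}

kappa_mcc_from_counts <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  n <- tp + fp + tn + fn
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  degenerate <- mcc_den == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / mcc_den
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) {
    degenerate <- TRUE
    0
  } else (po - pe) / (1 - pe)
  list(kappa = kappa, mcc = mcc, degenerate = degenerate)
}

# Rank-based (Mann-Whitney) AUC with midrank tie handling.
auc_rank <- function(y, p) {
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Average precision: sum over positives, in decreasing-score order, of
# precision at each positive's rank (ties resolved by stable order).
average_precision <- function(y, p) {
  if (sum(y == 1) == 0L || sum(y == 0) == 0L) return(NA_real_)
  ord <- order(-p, seq_along(p))
  ys <- y[ord]
  cum_tp <- cumsum(ys)
  prec <- cum_tp / seq_along(ys)
  sum(prec[ys == 1]) / sum(ys)
}

#' Thirteen-metric evaluation report
#'
#' Evaluates probabilistic binary predictions with the full panel:
#' accuracy, AUC, average precision, Cohen's kappa, Brier score, F1,
#' Jaccard (positive-class and macro-averaged), MCC, NPV, precision,
#' sensitivity, specificity and NegLog2RMSL, together with the confusion
#' counts at the decision threshold. Samples with probability exactly at
#' the threshold are classified positive (sensitive).
#'
#' @param labels Binary labels (positive = sensitive).
#' @param probabilities Probabilities of sensitive, in `[0, 1]`.
#' @param threshold Decision threshold in `[0, 1]` (default 0.5).
#' @return An object of class `metric_report`: a list of named scalars plus
#'   `confusion` and `flags` (e.g. `auc_undefined` when only one class is
#'   present).
#' @export
metric_suite <- function(labels, probabilities, threshold = 0.5) {
  y <- as_binary01(labels)
  p <- as.numeric(probabilities)
  if (length(y) != length(p)) stop("labels and probabilities differ in length")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  pred <- as.integer(p >= threshold)
  cc <- confusion_counts(y, pred)
  rep <- metrics_from_counts(cc)
  km <- kappa_mcc_from_counts(cc)
  flags <- character(0L)
  if (km$degenerate) flags <- c(flags, "degenerate_confusion")
  auc <- auc_rank(y, p)
  ap <- average_precision(y, p)
  if (is.na(auc)) flags <- c(flags, "auc_undefined")
  structure(c(rep,
              list(auc = auc,
                   average_precision = ap,
                   cohen_kappa = km$kappa,
                   mcc = km$mcc,
                   brier_score = mean((p - y)^2),
                   neglog2rmsl = neglog2_rmsl(y, p),
                   confusion = cc,
                   decision_threshold = threshold,
                   flags = flags)),
            class = "metric_report")
}

# Closed-form thresholded metrics from a confusion table; zero denominators
# yield 0 (documented convention, keeps reports finite).
metrics_from_counts <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  n <- tp + fp + tn + fn
  div <- function(a, b) if (b == 0) 0 else a / b
  prec <- div(tp, tp + fp)
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  npv <- div(tn, tn + fn)
  f1 <- div(2 * tp, 2 * tp + fp + fn)
  jac_pos <- div(tp, tp + fp + fn)
  jac_neg <- div(tn, tn + fp + fn)
  list(accuracy = div(tp + tn, n),
       precision = prec,
       sensitivity = sens,
       specificity = spec,
       npv = npv,
       f1 = f1,
       jaccard = jac_pos,
       jaccard_macro = (jac_pos + jac_neg) / 2)
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  keys <- c("accuracy", "auc", "average_precision", "cohen_kappa", "brier_score",
            "f1", "jaccard", "jaccard_macro", "mcc", "npv", "precision",
            "sensitivity", "specificity", "neglog2rmsl")
  cat("metric_report (threshold =", x$decision_threshold, ")\n")
  for (k in keys) cat(sprintf("  %-18s %s\n", k, formatC(x[[k]], digits = digits, format = "f")))
  print(x$confusion)
  if (length(x$flags) > 0L) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a metric report to flat JSON
#'
#' @param report A [metric_suite()] result.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
metric_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  flat <- report[!names(report) %in% c("confusion", "flags")]
  flat$tp <- report$confusion$tp
  flat$fp <- report$confusion$fp
  flat$tn <- report$confusion$tn
  flat$fn <- report$confusion$fn
  flat$flags <- as.list(report$flags)
  js <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
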
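#' Hyperparameter bundle for the attentive tabular network
#'
#' @param decision_width Hidden width of each decision step's feature
#'   transformer (positive integer).
#' @param attention_width Hidden width of the attentive transformer that
#'   produces per-sample feature masks (positive integer).
#' @param n_decision_steps Number of sequential decision steps.
#' @param relaxation_gamma Prior relaxation factor (>= 1); values near 1
#'   force different steps to attend to different features, larger values
#'   allow feature reuse across steps.
#' @param sparsity_coefficient Weight (>= 0) of the mask-entropy penalty
#'   that encourages sparse feature attention.
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Minibatch size (positive integer).
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation improvement before
#'   training stops (0 disables early stopping).
#' @param seed Integer seed controlling initialisation and minibatch order.
#' @return An object of class `hyperparams` (a validated named list,
#'   serialisable to/from a flat key-value map).
#' @export
hyperparams <- function(decision_width = 8L, attention_width = 8L,
                        n_decision_steps = 3L, relaxation_gamma = 1.3,
                        sparsity_coefficient = 1e-4, learning_rate = 0.02,
                        batch_size = 64L, max_epochs = 100L,
                        early_stop_patience = 20L, seed = 1L) {
  hp <- list(decision_width = as.integer(decision_width),
             attention_width = as.integer(attention_width),
             n_decision_steps = as.integer(n_decision_steps),
             relaxation_gamma = as.numeric(relaxation_gamma),
             sparsity_coefficient = as.numeric(sparsity_coefficient),
             learning_rate = as.numeric(learning_rate),
             batch_size = as.integer(batch_size),
             max_epochs = as.integer(max_epochs),
             early_stop_patience = as.integer(early_stop_patience),
             seed = as.integer(seed))
  with(hp, stopifnot(decision_width >= 1L, attention_width >= 1L,
                     n_decision_steps >= 1L, relaxation_gamma >= 1,
                     sparsity_coefficient >= 0, learning_rate > 0,
                     batch_size >= 1L, max_epochs >= 1L,
                     early_stop_patience >= 0L))
  structure(hp, class = "hyperparams")
}

#' Build hyperparameters from a flat key-value map
#'
#' Unknown keys are an error; omitted keys take their defaults.
#' @param x Named list or vector of hyperparameter values.
#' @return A [hyperparams()] object.
#' @export
hyperparams_from_list <- function(x) {
  x <- as.list(x)
  known <- names(formals(hyperparams))
  bad <- setdiff(names(x), known)
  if (length(bad) > 0L) stop("unknown hyperparameter(s): ", paste(bad, collapse = ", "))
  do.call(hyperparams, x)
}

#' @export
print.hyperparams <- function(x, ...) {
  cat("hyperparams:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

# ---- internal network primitives -----------------------------------------

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

init_params <- function(p, hp, encoder = NULL) {
  S <- hp$n_decision_steps
  d <- hp$decision_width
  na <- hp$attention_width
  rnormal <- function(n, sd = 0.1) stats::rnorm(n, sd = sd)
  steps <- vector("list", S)
  for (s in seq_len(S)) {
    W <- matrix(rnormal(p * d), p, d)
    if (!is.null(encoder)) {
      # warm-start the feature transformer from the pretrained encoder;
      # recycle columns with small jitter if widths differ
      We <- encoder$weights$We
      cols <- rep_len(seq_len(ncol(We)), d)
      W <- We[, cols, drop = FALSE] + matrix(rnormal(p * d, 0.01), p, d)
    }
    steps[[s]] <- list(U = matrix(rnormal(p * na), p, na),
                       bU = numeric(na),
                       V = matrix(rnormal(na * p), na, p),
                       W = W,
                       b = numeric(d))
  }
  list(steps = steps, wo = rnormal(d), bo = 0)
}

# Forward pass; returns probabilities plus the caches needed for backprop.
net_forward <- function(X, params, hp, keep_cache = TRUE) {
  B <- nrow(X); p <- ncol(X)
  S <- hp$n_decision_steps
  prior <- matrix(1, B, p)
  agg <- matrix(0, B, hp$decision_width)
  cache <- if (keep_cache) vector("list", S) else NULL
  masks_sum <- matrix(0, B, p)
  for (s in seq_len(S)) {
    st <- params$steps[[s]]
    A <- relu(sweep(X %*% st$U, 2L, st$bU, "+"))
    Z <- A %*% st$V
    M <- softmax_rows(Z + log(prior + 1e-10))
    Xs <- X * M * p
    H <- relu(sweep(Xs %*% st$W, 2L, st$b, "+"))
    agg <- agg + H
    masks_sum <- masks_sum + M
    if (keep_cache) cache[[s]] <- list(A = A, M = M, Xs = Xs, H = H)
    prior <- pmax(prior * (hp$relaxation_gamma - M), 0)
  }
  logit <- drop(agg %*% params$wo) + params$bo
  list(prob = sigmoid(logit), agg = agg, cache = cache,
       mean_mask = masks_sum / S)
}

# Gradients of BCE + sparsity penalty wrt all parameters. The relaxation
# prior is treated as a constant in the backward pass (forward-only
# recurrence), a standard simplification that keeps the gradient local to
# each decision step.
net_backward <- function(X, y, fw, params, hp) {
  B <- nrow(X); p <- ncol(X)
  S <- hp$n_decision_steps
  lam <- hp$sparsity_coefficient
  dlogit <- (fw$prob - y) / B
  grads <- list(steps = vector("list", S),
                wo = drop(t(fw$agg) %*% dlogit),
                bo = sum(dlogit))
  dagg <- outer(dlogit, params$wo)
  for (s in seq_len(S)) {
    st <- params$steps[[s]]
    ch <- fw$cache[[s]]
    dH <- dagg * (ch$H > 0)
    dXs <- dH %*% t(st$W)
    dM <- dXs * X * p
    if (lam > 0)
      dM <- dM - lam / (S * B) * (log(ch$M + 1e-10) + 1)
    dZ <- ch$M * (dM - rowSums(dM * ch$M))
    dA <- (dZ %*% t(st$V)) * (ch$A > 0)
    grads$steps[[s]] <- list(U = t(X) %*% dA,
                             bU = colSums(dA),
                             V = t(ch$A) %*% dZ,
                             W = t(ch$Xs) %*% dH,
                             b = colSums(dH))
  }
  grads
}

# Minimal Adam over an arbitrarily nested list of numeric arrays.
adam_state <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(step, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- step(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

bce_loss <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(prob) + (1 - y) * log(1 - prob))
}

# ---- pretraining -----------------------------------------------------------

#' Self-supervised pretraining on unlabeled expression data
#'
#' Trains a masked-feature reconstruction autoencoder (hidden width =
#' `decision_width`) on a normalised, unlabeled expression matrix: a random
#' fraction of entries is masked to zero in the input and the network is
#' trained to reconstruct the masked values. The resulting encoder weights
#' warm-start supervised fitting via the `encoder` argument of
#' [tabsense_fit()].
#'
#' @param unlabeled Samples x genes matrix, min-max normalised to `[0, 1]`,
#'   with at least 2 samples.
#' @param config A [hyperparams()] object; `decision_width`,
#'   `learning_rate`, `batch_size`, `max_epochs` and `seed` are used.
#' @param masking_fraction Fraction of entries masked per sample, strictly
#'   in (0, 1). Default 0.5.
#' @return An object of class `tabsense_encoder` carrying the weights, the
#'   gene list, a deterministic content fingerprint, the pretraining config
#'   and the per-epoch reconstruction loss history.
#' @export
pretrain <- function(unlabeled, config = hyperparams(), masking_fraction = 0.5) {
  stopifnot(is.matrix(unlabeled), !is.null(colnames(unlabeled)))
  if (nrow(unlabeled) < 2L) stop("pretraining needs at least 2 samples")
  if (length(masking_fraction) != 1L || !is.finite(masking_fraction) ||
      masking_fraction <= 0 || masking_fraction >= 1)
    stop("masking_fraction must lie strictly in (0, 1)")
  if (any(unlabeled < -1e-9 | unlabeled > 1 + 1e-9))
    stop("unlabeled matrix must be min-max normalised to [0, 1]")
  local_rng(config$seed)
  X <- unlabeled
  n <- nrow(X); p <- ncol(X); d <- config$decision_width
  W <- list(We = matrix(stats::rnorm(p * d, sd = 0.1), p, d), be = numeric(d),
            Wd = matrix(stats::rnorm(d * p, sd = 0.1), d, p), bd = numeric(p))
  st <- adam_state(W)
  bs <- min(config$batch_size, n)
  losses <- numeric(config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, n, by = bs)) {
      rows <- idx[start:min(start + bs - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      mask <- matrix(stats::runif(length(Xb)) < masking_fraction,
                     nrow(Xb), p)
      Xin <- Xb * !mask
      Hpre <- sweep(Xin %*% W$We, 2L, W$be, "+")
      H <- relu(Hpre)
      Xhat <- sweep(H %*% W$Wd, 2L, W$bd, "+")
      nm <- max(sum(mask), 1L)
      resid <- (Xhat - Xb) * mask
      loss <- sum(resid^2) / nm
      dXhat <- 2 * resid / nm
      g <- list(We = t(Xin) %*% ((dXhat %*% t(W$Wd)) * (H > 0)),
                be = colSums((dXhat %*% t(W$Wd)) * (H > 0)),
                Wd = t(H) %*% dXhat,
                bd = colSums(dXhat))
      upd <- adam_update(W, g, st, config$learning_rate)
      W <- upd$params; st <- upd$state
      ep_loss <- ep_loss + loss * length(rows); ep_n <- ep_n + length(rows)
    }
    losses[epoch] <- ep_loss / ep_n
  }
  structure(list(weights = W,
                 n_features = p,
                 gene_ids = colnames(X),
                 masking_fraction = masking_fraction,
                 pretraining_config = config,
                 loss_history = losses,
                 final_loss = losses[length(losses)],
                 fingerprint = weights_fingerprint(W)),
            class = "tabsense_encoder")
}

#' @export
print.tabsense_encoder <- function(x, ...) {
  cat("tabsense_encoder:", x$n_features, "features, width",
      x$pretraining_config$decision_width, "\n")
  cat("  final reconstruction loss:", format(x$final_loss, digits = 5), "\n")
  cat("  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

# Deterministic content digest of a weight list; ascii serialisation keeps
# the digest stable across platforms for identical doubles.
weights_fingerprint <- function(w) {
  digest::digest(signif(rapply(w, identity, how = "unlist"), 12), algo = "md5")
}

# ---- supervised fitting ----------------------------------------------------

#' Fit the attentive tabular sensitivity classifier
#'
#' Trains the sequential-attention tabular network on a labeled dataset:
#' each decision step computes a per-sample softmax attention mask over
#' genes (modulated by a relaxation prior that discourages reusing the same
#' genes across steps, and an entropy penalty that encourages sparse
#' attention), transforms the masked inputs through a ReLU layer, and the
#' aggregated representation feeds a logistic output head. Optimisation is
#' minibatch Adam on binary cross-entropy. When an `encoder` from
#' [pretrain()] is supplied, feature-transformer weights are warm-started
#' from the pretrained reconstruction encoder (semi-supervised transfer).
#'
#' When a `validation` set is given, each epoch is scored by validation
#' NegLog2RMSL and training stops after `early_stop_patience` epochs
#' without improvement, restoring the best weights (set
#' `early_stop_metric = "auc"` to monitor AUC instead).
#'
#' @param train A [labeled_dataset()] with both classes present.
#' @param hp A [hyperparams()] object.
#' @param encoder Optional `tabsense_encoder`; its feature count must match
#'   the training gene list.
#' @param validation Optional [labeled_dataset()] sharing the gene list.
#' @param early_stop_metric `"neglog2rmsl"` (default) or `"auc"`.
#' @return An object of class `tabsense_fit` with `predict`, `print`,
#'   `summary`, `coef`, `plot` and `residuals` methods.
#' @examples
#' sim <- simulate_pharmacogenomic(n_sensitive = 30, n_resistant = 30,
#'                                 n_genes = 20, n_informative = 5,
#'                                 effect_size = 3, seed = 1)
#' d <- labeled_dataset(minmax_normalize(sim$expression)$values, sim$labels)
#' fit <- tabsense_fit(d, hyperparams(max_epochs = 20, seed = 1))
#' head(predict(fit, d$features))
#' @export
tabsense_fit <- function(train, hp = hyperparams(), encoder = NULL,
                         validation = NULL,
                         early_stop_metric = c("neglog2rmsl", "auc")) {
  stopifnot(inherits(train, "labeled_dataset"))
  early_stop_metric <- match.arg(early_stop_metric)
  if (nlevels(droplevels(train$labels)) < 2L)
    stop("training labels contain a single class")
  if (!is.null(encoder)) {
    stopifnot(inherits(encoder, "tabsense_encoder"))
    if (encoder$n_features != length(train$gene_ids))
      stop("encoder was pretrained on ", encoder$n_features,
           " features but the training data has ", length(train$gene_ids))
  }
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "labeled_dataset"))
    if (!identical(validation$gene_ids, train$gene_ids))
      stop("validation gene list differs from training gene list")
  }
  local_rng(hp$seed)
  X <- train$features
  y <- as.integer(train$labels == "sensitive")
  n <- nrow(X); p <- ncol(X)
  params <- init_params(p, hp, encoder)
  st <- adam_state(params)
  bs <- min(hp$batch_size, n)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_score = numeric(0))
  best <- list(score = -Inf, params = params, epoch = 0L)
  patience_left <- hp$early_stop_patience
  for (epoch in seq_len(hp$max_epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = bs)) {
      rows <- idx[start:min(start + bs - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      fw <- net_forward(Xb, params, hp)
      g <- net_backward(Xb, yb, fw, params, hp)
      upd <- adam_update(params, g, st, hp$learning_rate)
      params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + bce_loss(yb, fw$prob) * length(rows)
    }
    val_score <- NA_real_
    if (!is.null(validation)) {
      pv <- net_forward(validation$features, params, hp, keep_cache = FALSE)$prob
      yv <- as.integer(validation$labels == "sensitive")
      val_score <- if (early_stop_metric == "auc") auc_rank(yv, pv)
                   else neglog2_rmsl(yv, pv)
      if (is.finite(val_score) && val_score > best$score + 1e-9) {
        best <- list(score = val_score, params = params, epoch = epoch)
        patience_left <- hp$early_stop_patience
      } else if (hp$early_stop_patience > 0L) {
        patience_left <- patience_left - 1L
        if (patience_left <= 0L) {
          hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                         val_score = val_score))
          break
        }
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                   val_score = val_score))
  }
  if (!is.null(validation) && best$epoch > 0L) params <- best$params
  fw_final <- net_forward(X, params, hp)
  fitted_prob <- fw_final$prob
  structure(list(params = params,
                 hp = hp,
                 gene_ids = train$gene_ids,
                 training_ids = c(train$sample_ids,
                                  if (!is.null(validation)) validation$sample_ids),
                 decision_threshold = 0.5,
                 fitted = stats::setNames(fitted_prob, train$sample_ids),
                 labels = train$labels,
                 feature_importance = stats::setNames(colMeans(fw_final$mean_mask),
                                                      train$gene_ids),
                 history = hist,
                 best_epoch = if (is.null(validation)) nrow(hist) else best$epoch,
                 best_val_score = if (is.null(validation)) NA_real_ else best$score,
                 encoder_fingerprint = if (is.null(encoder)) NA_character_
                                       else encoder$fingerprint,
                 seed = hp$seed,
                 fingerprint = weights_fingerprint(params)),
            class = "tabsense_fit")
}

#' Predict sensitivity probabilities
#'
#' @param object A [tabsense_fit()] model.
#' @param newdata Samples x genes matrix, min-max normalised with the
#'   training statistics. Columns are realigned to the model's gene list by
#'   name; missing or unknown genes are an error listing them.
#' @param type `"prob"` for probabilities of `sensitive` (default) or
#'   `"class"` for thresholded factor calls.
#' @param ... Unused.
#' @return Named numeric vector of probabilities, or a factor of calls.
#' @export
predict.tabsense_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- align_genes(newdata, object$gene_ids)
  prob <- net_forward(X, object$params, object$hp, keep_cache = FALSE)$prob
  prob <- stats::setNames(pmin(pmax(prob, 0), 1), rownames(X))
  if (type == "prob") return(prob)
  factor(ifelse(prob >= object$decision_threshold, "sensitive", "resistant"),
         levels = c("resistant", "sensitive"))
}

align_genes <- function(x, gene_ids) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  extra <- setdiff(colnames(x), gene_ids)
  missing <- setdiff(gene_ids, colnames(x))
  if (length(extra) > 0L)
    stop("unknown gene(s) not in the model: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  if (length(missing) > 0L)
    stop("gene(s) required by the model are missing: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x[, gene_ids, drop = FALSE]
}

#' @export
print.tabsense_fit <- function(x, ...) {
  cat("tabsense_fit: attentive tabular classifier\n")
  cat("  genes:", length(x$gene_ids),
      " training samples:", length(x$training_ids), "\n")
  cat("  steps:", x$hp$n_decision_steps, " width:", x$hp$decision_width,
      " epochs run:", nrow(x$history), " best epoch:", x$best_epoch, "\n")
  if (!is.na(x$best_val_score))
    cat("  best validation score:", format(x$best_val_score, digits = 5), "\n")
  if (!is.na(x$encoder_fingerprint))
    cat("  warm-started from encoder", substr(x$encoder_fingerprint, 1, 8), "\n")
  invisible(x)
}

#' @export
summary.tabsense_fit <- function(object, ...) {
  rep <- metric_suite(object$labels, object$fitted, object$decision_threshold)
  top <- utils::head(sort(object$feature_importance, decreasing = TRUE), 10L)
  out <- list(training_metrics = rep, top_genes = top,
              history = object$history)
  class(out) <- "summary.tabsense_fit"
  out
}

#' @export
print.summary.tabsense_fit <- function(x, ...) {
  cat("Training-set metrics (in-sample, optimistic):\n")
  print(x$training_metrics)
  cat("Top genes by mean attention mass:\n")
  print(round(x$top_genes, 4))
  invisible(x)
}

#' @export
coef.tabsense_fit <- function(object, ...) object$feature_importance

#' @export
residuals.tabsense_fit <- function(object, ...) {
  as.integer(object$labels == "sensitive") - object$fitted
}

#' @export
plot.tabsense_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Training trajectory", ...)
  if (any(is.finite(h$val_score))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_score, type = "l", col = "red", axes = FALSE,
                   xlab = "", ylab = "")
    graphics::axis(4L, col.axis = "red")
    graphics::mtext("validation score", side = 4, line = 2, col = "red")
  }
  invisible(x)
}

#' Save / load a fitted model as a plain-text directory
#'
#' The directory holds a JSON sidecar (gene list, config, seed, metric
#' history, fingerprints, format version) and the weights as delimited
#' text, so models survive text-only archiving.
#'
#' @param object A `tabsense_fit`.
#' @param dir Target directory (created if needed).
#' @return `dir` invisibly (`save_model`); a `tabsense_fit` (`load_model`).
#' @export
save_model <- function(object, dir) {
  stopifnot(inherits(object, "tabsense_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  side <- list(format_version = 1L,
               gene_ids = object$gene_ids,
               training_ids = object$training_ids,
               hp = unclass(object$hp),
               decision_threshold = object$decision_threshold,
               best_epoch = object$best_epoch,
               best_val_score = object$best_val_score,
               seed = object$seed,
               encoder_fingerprint = object$encoder_fingerprint,
               fingerprint = object$fingerprint,
               history = object$history,
               labels = as.character(object$labels),
               fitted = unname(object$fitted),
               feature_importance = unname(object$feature_importance))
  jsonlite::write_json(side, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  flat <- unlist(object$params)
  utils::write.table(data.frame(name = names(flat), value = flat),
                     file.path(dir, "weights.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  wt <- utils::read.table(file.path(dir, "weights.tsv"), sep = "\t", header = TRUE)
  hp <- hyperparams_from_list(side$hp)
  p <- length(side$gene_ids)
  params <- relist_params(stats::setNames(wt$value, wt$name), p, hp)
  fit <- structure(list(params = params, hp = hp,
                        gene_ids = side$gene_ids,
                        training_ids = side$training_ids,
                        decision_threshold = side$decision_threshold,
                        fitted = stats::setNames(side$fitted, side$training_ids[
                          seq_along(side$fitted)]),
                        labels = factor(side$labels,
                                        levels = c("resistant", "sensitive")),
                        feature_importance = stats::setNames(
                          side$feature_importance, side$gene_ids),
                        history = as.data.frame(side$history),
                        best_epoch = side$best_epoch,
                        best_val_score = side$best_val_score,
                        encoder_fingerprint = side$encoder_fingerprint,
                        seed = side$seed,
                        fingerprint = side$fingerprint),
                   class = "tabsense_fit")
  if (!identical(weights_fingerprint(params), side$fingerprint))
    warning("weights fingerprint mismatch after reload (precision loss?)")
  fit
}

relist_params <- function(flat, p, hp) {
  d <- hp$decision_width; na <- hp$attention_width; S <- hp$n_decision_steps
  pos <- 1L
  take <- function(n) {
    out <- flat[pos:(pos + n - 1L)]
    pos <<- pos + n
    unname(out)
  }
  steps <- vector("list", S)
  for (s in seq_len(S)) {
    steps[[s]] <- list(U = matrix(take(p * na), p, na),
                       bU = take(na),
                       V = matrix(take(na * p), na, p),
                       W = matrix(take(p * d), p, d),
                       b = take(d))
  }
  list(steps = steps, wo = take(d), bo = take(1L))
}
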
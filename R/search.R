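#' Specify a hyperparameter search
#'
#' The search space maps [hyperparams()] field names to either a vector of
#' discrete candidate values or a continuous range
#' `list(lower =, upper =, log = TRUE/FALSE)`. Four strategies are
#' available: `hardcoded` (evaluate the pre-defined configuration only),
#' `grid` (exhaustive over an enumerable space, up to the budget),
#' `bayes` (sequential surrogate-based optimisation with a Gaussian-process
#' expected-improvement acquisition) and `tpe` (tree-structured Parzen
#' estimator). `superior` runs all four and keeps the winner by inner
#' cross-validated NegLog2RMSL.
#'
#' @param method One of `"hardcoded"`, `"grid"`, `"bayes"`, `"tpe"`,
#'   `"superior"`.
#' @param space Named list of discrete vectors and/or continuous ranges.
#'   The default explores decision/attention widths, step counts and the
#'   learning rate.
#' @param budget Candidate evaluations per method (>= 1).
#' @param inner_k Stratified folds for inner validation (default 3).
#' @param hardcoded Base [hyperparams()]: the `hardcoded` strategy's
#'   candidate, and the template whose unexplored fields all candidates
#'   inherit.
#' @param seed Integer seed.
#' @return An object of class `search_spec`.
#' @export
search_spec <- function(method = c("superior", "hardcoded", "grid", "bayes", "tpe"),
                        space = default_search_space(),
                        budget = 20L, inner_k = 3L,
                        hardcoded = hyperparams(), seed = 1L) {
  method <- match.arg(method)
  if (length(space) > 0L) {
    bad <- setdiff(names(space), names(formals(hyperparams)))
    if (length(bad) > 0L)
      stop("space refers to unknown hyperparameter(s): ",
           paste(bad, collapse = ", "))
  }
  if (budget < 1L) stop("budget must be >= 1")
  if (length(space) == 0L && method != "hardcoded")
    stop("an empty space is only valid with method = 'hardcoded'")
  structure(list(method = method, space = space, budget = as.integer(budget),
                 inner_k = as.integer(inner_k), hardcoded = hardcoded,
                 seed = as.integer(seed)),
            class = "search_spec")
}

#' Default hyperparameter search space
#' @return Named list usable as the `space` of [search_spec()].
#' @export
default_search_space <- function() {
  list(decision_width = c(8L, 16L, 32L),
       attention_width = c(8L, 16L, 32L),
       n_decision_steps = c(3L, 5L),
       learning_rate = list(lower = 1e-3, upper = 2e-2, log = TRUE))
}

is_range <- function(x) is.list(x) && all(c("lower", "upper") %in% names(x))

# Mean inner-validation NegLog2RMSL over stratified k folds of the
# training split. Only training-derived data ever reaches this function.
inner_cv_score <- function(hp, train, encoder, k, seed) {
  folds <- stratified_folds(train$labels, k, seed)
  scores <- vapply(seq_len(k), function(f) {
    tr <- subset_dataset(train, train$sample_ids[folds != f])
    va <- subset_dataset(train, train$sample_ids[folds == f])
    fit <- tabsense_fit(tr, hp, encoder = encoder, validation = va)
    p <- predict(fit, va$features)
    neglog2_rmsl(va$labels, p)
  }, numeric(1))
  mean(scores)
}

# Stratified fold ids in 1..k, deterministic under seed.
stratified_folds <- function(labels, k, seed) {
  local_rng(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("class '", cl, "' has fewer than k = ", k, " samples")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Candidate parameter list -> full hyperparams, inheriting from the base.
candidate_hp <- function(cand, base) {
  hp <- unclass(base)
  for (k in names(cand)) hp[[k]] <- cand[[k]]
  hyperparams_from_list(hp)
}

# Number of trainable weights in the network for a given configuration:
# the simplicity tie-break of the search.
param_count <- function(hp, n_features) {
  p <- n_features; d <- hp$decision_width; na <- hp$attention_width
  hp$n_decision_steps * (p * na + na + na * p + p * d + d) + d + 1
}

# ---- candidate encoding ----------------------------------------------------

# Draw one random candidate from the space (unit-scale sampling for ranges).
sample_candidate <- function(space) {
  out <- list()
  for (k in names(space)) {
    v <- space[[k]]
    out[[k]] <- if (is_range(v)) decode_range(v, stats::runif(1)) else
      v[[sample.int(length(v), 1L)]]
  }
  out
}

decode_range <- function(v, u) {
  if (isTRUE(v$log)) exp(log(v$lower) + u * (log(v$upper) - log(v$lower)))
  else v$lower + u * (v$upper - v$lower)
}

encode_value <- function(v, x) {
  if (is_range(v)) {
    if (isTRUE(v$log)) (log(x) - log(v$lower)) / (log(v$upper) - log(v$lower))
    else (x - v$lower) / (v$upper - v$lower)
  } else {
    i <- match(x, v)
    if (length(v) == 1L) 0.5 else (i - 1) / (length(v) - 1)
  }
}

encode_candidates <- function(cands, space) {
  t(vapply(cands, function(cand)
    vapply(names(space), function(k) encode_value(space[[k]], cand[[k]]),
           numeric(1)),
    numeric(length(space))))
}

# ---- strategies ------------------------------------------------------------

enumerate_grid <- function(space) {
  if (any(vapply(space, is_range, logical(1))))
    stop("grid search requires an enumerable space (no continuous ranges)")
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

run_strategy <- function(method, train, spec, encoder, seed) {
  # folds keyed to the common spec seed so identical candidates score
  # identically across strategies; the derived seed drives proposals only
  evaluate <- function(cand) {
    hp <- candidate_hp(cand, spec$hardcoded)
    inner_cv_score(hp, train, encoder, spec$inner_k, spec$seed)
  }
  cands <- list(); scores <- numeric(0)
  push <- function(cand) {
    cands[[length(cands) + 1L]] <<- cand
    scores[length(scores) + 1L] <<- evaluate(cand)
  }
  local_rng(seed)
  if (method == "hardcoded") {
    push(list())
  } else if (method == "grid") {
    all_pts <- enumerate_grid(spec$space)
    for (cand in all_pts[seq_len(min(spec$budget, length(all_pts)))]) push(cand)
  } else if (method == "bayes") {
    n_init <- min(spec$budget, max(3L, ceiling(spec$budget / 3)))
    for (i in seq_len(n_init)) push(sample_candidate(spec$space))
    while (length(cands) < spec$budget)
      push(propose_ei(cands, scores, spec$space))
  } else if (method == "tpe") {
    n_init <- min(spec$budget, max(3L, ceiling(spec$budget / 3)))
    for (i in seq_len(n_init)) push(sample_candidate(spec$space))
    while (length(cands) < spec$budget)
      push(propose_tpe(cands, scores, spec$space))
  } else stop("unknown method: ", method)
  list(candidates = cands, scores = scores)
}

# Expected-improvement proposal from a Gaussian-process surrogate on the
# unit hypercube (RBF kernel, fixed length-scale, jitter nugget).
propose_ei <- function(cands, scores, space, n_pool = 50L, xi = 0.01) {
  X <- encode_candidates(cands, space)
  y <- scores
  ok <- is.finite(y)
  if (sum(ok) < 2L) return(sample_candidate(space))
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  mu0 <- mean(y); sd0 <- stats::sd(y)
  if (!is.finite(sd0) || sd0 == 0) return(sample_candidate(space))
  ys <- (y - mu0) / sd0
  l <- 0.3
  k_fun <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-pmax(d2, 0) / (2 * l^2))
  }
  K <- k_fun(X, X) + diag(1e-4, nrow(X))
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(sample_candidate(space))
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  pool <- replicate(n_pool, sample_candidate(space), simplify = FALSE)
  Xp <- encode_candidates(pool, space)
  Ks <- k_fun(Xp, X)
  mu <- drop(Ks %*% alpha)
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  best <- max(ys)
  z <- (mu - best - xi) / s
  ei <- (mu - best - xi) * stats::pnorm(z) + s * stats::dnorm(z)
  pool[[which.max(ei)]]
}

# Tree-structured Parzen estimator proposal: model the densities of the
# top-gamma and remaining candidates per dimension and maximise l(x)/g(x).
propose_tpe <- function(cands, scores, space, n_pool = 20L, gamma = 0.25) {
  ok <- is.finite(scores)
  if (sum(ok) < 4L) return(sample_candidate(space))
  cands <- cands[ok]; scores <- scores[ok]
  n_good <- max(2L, ceiling(gamma * length(scores)))
  ord <- order(-scores)
  good <- cands[ord[seq_len(n_good)]]
  bad <- cands[ord[-seq_len(n_good)]]
  dens <- function(set, k, x) {
    v <- space[[k]]
    vals <- vapply(set, function(c) encode_value(v, c[[k]]), numeric(1))
    if (is_range(v)) {
      bw <- max(1.06 * stats::sd(vals) * length(vals)^(-0.2), 0.05)
      mean(stats::dnorm(x, vals, bw))
    } else {
      # categorical with add-one smoothing over the discrete levels
      lev <- vapply(seq_along(v), function(i) encode_value(v, v[[i]]), numeric(1))
      counts <- vapply(lev, function(lv) sum(abs(vals - lv) < 1e-9), numeric(1))
      p <- (counts + 1) / (length(vals) + length(v))
      p[which.min(abs(lev - x))]
    }
  }
  draw_from_good <- function() {
    base <- good[[sample.int(length(good), 1L)]]
    out <- list()
    for (k in names(space)) {
      v <- space[[k]]
      if (is_range(v)) {
        u <- encode_value(v, base[[k]])
        u <- min(max(u + stats::rnorm(1, sd = 0.1), 0), 1)
        out[[k]] <- decode_range(v, u)
      } else {
        # resample the category from the good-set smoothed frequencies
        lev_vals <- v
        probs <- vapply(seq_along(v), function(i) {
          cnt <- sum(vapply(good, function(c) identical(c[[k]], v[[i]]),
                            logical(1)))
          cnt + 1
        }, numeric(1))
        out[[k]] <- lev_vals[[sample.int(length(v), 1L, prob = probs)]]
      }
    }
    out
  }
  pool <- replicate(n_pool, draw_from_good(), simplify = FALSE)
  ratio <- vapply(pool, function(cand) {
    lg <- vapply(names(space), function(k) {
      x <- encode_value(space[[k]], cand[[k]])
      lg <- dens(good, k, x)
      gg <- dens(bad, k, x)
      log(lg + 1e-12) - log(gg + 1e-12)
    }, numeric(1))
    sum(lg)
  }, numeric(1))
  pool[[which.max(ratio)]]
}

# ---- public operations -----------------------------------------------------

#' Optimise hyperparameters on training data only
#'
#' Runs the strategy named by `spec$method`. Every candidate is scored by
#' stratified inner cross-validation (NegLog2RMSL, higher is better) on the
#' training split; held-out test data can never reach this function, and an
#' audit log of every sample id visible to the search is returned. Ties are
#' broken by preferring fewer model parameters, then by the method order
#' hardcoded, grid, bayes, tpe.
#'
#' @param train A [labeled_dataset()] with both classes.
#' @param spec A [search_spec()].
#' @param encoder Optional pretrained `tabsense_encoder` passed through to
#'   candidate fits.
#' @return An object of class `search_result`: `best_hyperparams`,
#'   `winning_method`, a per-method `table` (best score, evaluations,
#'   error message for failed methods), a per-candidate `trace` data frame
#'   and `audit_ids`.
#' @export
optimize_hyperparams <- function(train, spec, encoder = NULL) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(spec, "search_spec"))
  if (nlevels(droplevels(train$labels)) < 2L)
    stop("training data must contain both classes")
  if (spec$method == "superior") return(superior_search(train, spec, encoder))
  res <- run_strategy(spec$method, train, spec, encoder, spec$seed)
  assemble_result(list(stats::setNames(list(res), spec$method)), train, spec)
}

#' Run all four strategies and keep the best ("superior" search)
#'
#' Executes hardcoded, grid, bayes and tpe sequentially with independent
#' seeds derived from `spec$seed`, then selects the winner by inner
#' cross-validated NegLog2RMSL. A strategy that errors is recorded in the
#' result table and excluded from the argmax; if all fail, the search
#' fails.
#'
#' @inheritParams optimize_hyperparams
#' @return A `search_result` (see [optimize_hyperparams()]).
#' @export
superior_search <- function(train, spec, encoder = NULL) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(spec, "search_spec"))
  methods <- c("hardcoded", "grid", "bayes", "tpe")
  runs <- list()
  for (i in seq_along(methods)) {
    m <- methods[i]
    runs[[m]] <- tryCatch(
      run_strategy(m, train, spec, encoder, spec$seed + 1000L * i),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "strategy_failure"))
  }
  if (all(vapply(runs, inherits, logical(1), "strategy_failure")))
    stop("all search strategies failed")
  assemble_result(list(runs), train, spec)
}

assemble_result <- function(run_sets, train, spec) {
  runs <- run_sets[[1L]]
  p <- length(train$gene_ids)
  rows <- list(); trace <- list()
  for (m in names(runs)) {
    r <- runs[[m]]
    if (inherits(r, "strategy_failure")) {
      rows[[m]] <- data.frame(method = m, score = NA_real_, evaluations = 0L,
                              error = r$message, stringsAsFactors = FALSE)
      next
    }
    hps <- lapply(r$candidates, candidate_hp, base = spec$hardcoded)
    npar <- vapply(hps, param_count, numeric(1), n_features = p)
    ord <- order(-r$scores, npar)
    best_i <- ord[1L]
    rows[[m]] <- data.frame(method = m, score = r$scores[best_i],
                            evaluations = length(r$scores), error = NA_character_,
                            stringsAsFactors = FALSE)
    rows[[m]]$best <- list(hps[[best_i]])
    trace[[m]] <- data.frame(
      method = m, candidate = seq_along(r$scores), score = r$scores,
      params = vapply(hps, function(h)
        as.character(jsonlite::toJSON(unclass(h), auto_unbox = TRUE)),
        character(1)),
      n_parameters = npar, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(rows, function(r) r[, c("method", "score",
                                                       "evaluations", "error")]))
  rownames(tab) <- NULL
  scored <- !is.na(tab$score)
  if (!any(scored)) stop("no strategy produced a score")
  # winner: max score; ties -> fewer parameters, then canonical method order
  best_hps <- stats::setNames(lapply(rows, function(r)
    if (is.null(r$best)) NULL else r$best[[1L]]), names(rows))
  cand_rows <- which(scored)
  npar_best <- vapply(cand_rows, function(i)
    param_count(best_hps[[tab$method[i]]], p), numeric(1))
  method_rank <- match(tab$method[cand_rows],
                       c("hardcoded", "grid", "bayes", "tpe"))
  ord <- order(-tab$score[cand_rows], npar_best, method_rank)
  win <- cand_rows[ord[1L]]
  structure(list(best_hyperparams = best_hps[[tab$method[win]]],
                 winning_method = tab$method[win],
                 table = tab,
                 trace = do.call(rbind, trace),
                 audit_ids = train$sample_ids,
                 seed = spec$seed),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("search_result: winner =", x$winning_method, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write the per-candidate search trace to CSV
#'
#' @param result A `search_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_search_trace <- function(result, path) {
  stopifnot(inherits(result, "search_result"))
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
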
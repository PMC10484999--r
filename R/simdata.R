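#' Simulate a two-class pharmacogenomic dataset with known truth
#'
#' Generates a samples x genes expression matrix for a sensitive and a
#' resistant class, an IC50 response table whose strict `< 500 nM` rule
#' reproduces the intended labels exactly, and an unlabeled pool drawn from
#' the same two-class mixture. Expression is lognormal: per-gene baselines
#' on the log scale plus Gaussian noise, with the informative genes shifted
#' upward by `effect_size * noise_sd` (log scale) in the sensitive class.
#' IC50s are lognormal around 100 nM (sensitive, truncated below 500) and
#' 2000 nM (resistant, truncated above 500).
#'
#' @param n_sensitive,n_resistant Labeled samples per class (>= 1).
#' @param n_genes Total genes; `n_informative` of them carry signal.
#' @param n_informative Number of class-informative genes
#'   (`<= n_genes`).
#' @param effect_size Mean shift between classes in units of `noise_sd`
#'   (0 = no signal).
#' @param noise_sd Log-scale within-class standard deviation (> 0).
#' @param n_unlabeled Unlabeled pool size, drawn from the same mixture with
#'   the labeled class proportions.
#' @param drug Drug name written into the response table.
#' @param seed Integer seed; output is fully reproducible.
#' @return A list with `expression` (labeled samples x genes), `responses`
#'   (data frame `sample_id`, `drug`, `ic50_nM`), `labels` (named factor),
#'   `unlabeled` (matrix), and `truth` (informative gene ids, effect size,
#'   noise, class proportions, seed).
#' @export
simulate_pharmacogenomic <- function(n_sensitive, n_resistant, n_genes,
                                     n_informative, effect_size = 2,
                                     noise_sd = 1, n_unlabeled = 0L,
                                     drug = "venetoclax", seed = 1L) {
  stopifnot(n_sensitive >= 1L, n_resistant >= 1L, n_genes >= 1L,
            n_informative >= 0L, n_informative <= n_genes,
            effect_size >= 0, noise_sd > 0, n_unlabeled >= 0L)
  local_rng(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  informative <- genes[seq_len(n_informative)]
  baseline <- stats::runif(n_genes, 1, 4) # per-gene log-scale baseline
  shift <- numeric(n_genes)
  shift[seq_len(n_informative)] <- effect_size * noise_sd
  draw_class <- function(n, sensitive, prefix, offset = 0L) {
    mu <- baseline + if (sensitive) shift else 0
    logx <- matrix(stats::rnorm(n * n_genes, sd = noise_sd), n, n_genes,
                   byrow = TRUE)
    logx <- sweep(logx, 2L, mu, "+")
    m <- exp(logx)
    rownames(m) <- sprintf("%s%03d", prefix, offset + seq_len(n))
    colnames(m) <- genes
    m
  }
  xs <- draw_class(n_sensitive, TRUE, "S")
  xr <- draw_class(n_resistant, FALSE, "R")
  expr <- rbind(xs, xr)
  labels <- factor(rep(c("sensitive", "resistant"), c(n_sensitive, n_resistant)),
                   levels = c("resistant", "sensitive"))
  names(labels) <- rownames(expr)
  # truncated lognormal IC50s so the strict <500 rule recovers labels exactly
  r_trunc_lnorm <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
    out <- numeric(n)
    need <- seq_len(n)
    while (length(need) > 0L) {
      cand <- stats::rlnorm(length(need), meanlog, sdlog)
      ok <- cand > lower & cand < upper
      out[need[ok]] <- cand[ok]
      need <- need[!ok]
    }
    out
  }
  ic50 <- c(r_trunc_lnorm(n_sensitive, log(100), 0.5, upper = 500),
            r_trunc_lnorm(n_resistant, log(2000), 0.5, lower = 500))
  responses <- data.frame(sample_id = rownames(expr), drug = drug,
                          ic50_nM = ic50, stringsAsFactors = FALSE)
  unlabeled <- NULL
  if (n_unlabeled > 0L) {
    prop_s <- n_sensitive / (n_sensitive + n_resistant)
    n_us <- stats::rbinom(1L, n_unlabeled, prop_s)
    unlabeled <- rbind(draw_class(n_us, TRUE, "U"),
                       draw_class(n_unlabeled - n_us, FALSE, "U", offset = n_us))
  }
  list(expression = expr, responses = responses, labels = labels,
       unlabeled = unlabeled,
       truth = list(informative_gene_ids = informative,
                    effect_size = effect_size, noise_sd = noise_sd,
                    class_proportions = c(sensitive = n_sensitive,
                                          resistant = n_resistant) /
                      (n_sensitive + n_resistant),
                    seed = as.integer(seed)))
}

#' Simulate a noisy dose-response viability curve
#'
#' Viability is generated as `1 - 4PL(dose)` on the inhibitory-effect scale
#' plus Gaussian noise, clipped to `[0, 1.5]` (measurement noise can push
#' viability slightly above 1).
#'
#' @param truth Named list/vector with `bottom`, `top`, `ec50_nM`, `hill`.
#' @param doses Positive concentrations in nM, at least 4 distinct values.
#' @param n_replicates Replicate measurements per dose (>= 1).
#' @param noise_sd Gaussian noise standard deviation (0 = exact curve).
#' @param drug Drug name.
#' @param seed Integer seed.
#' @return A `dose_response_curve` object (see [dose_response_curve()])
#'   with the generating truth attached as attribute `truth`.
#' @export
simulate_dose_response <- function(truth, doses, n_replicates = 3L,
                                   noise_sd = 0.05, drug = "drug",
                                   seed = 1L) {
  truth <- as.list(truth)
  stopifnot(all(c("bottom", "top", "ec50_nM", "hill") %in% names(truth)))
  if (any(doses <= 0)) stop("doses must be positive concentrations")
  local_rng(seed)
  doses <- sort(unique(doses))
  eff <- fourpl_effect(doses, truth$bottom, truth$top, truth$ec50_nM, truth$hill)
  viab <- matrix(rep(1 - eff, each = n_replicates), n_replicates,
                 length(doses))
  if (noise_sd > 0)
    viab <- viab + matrix(stats::rnorm(length(viab), sd = noise_sd),
                          nrow(viab), ncol(viab))
  viab <- pmin(pmax(viab, 0), 1.5)
  out <- dose_response_curve(doses, viab, drug = drug)
  attr(out, "truth") <- truth
  out
}

#' Simulate a drug-combination grid with injected Bliss excess
#'
#' The observed combined effect is the Bliss-independence expectation
#' `e1 + e2 - e1*e2` plus a constant synergy excess `excess_delta` and
#' optional Gaussian noise, clipped into `[0, 1]` (clipping is recorded in
#' the returned truth).
#'
#' @param e1,e2 Single-agent inhibitory effects in `[0, 1]` for drug 1
#'   (rows) and drug 2 (columns).
#' @param excess_delta Injected Bliss excess (synergy > 0).
#' @param noise_sd Gaussian noise on the observed effects.
#' @param seed Integer seed.
#' @return List with `effects_drug1`, `effects_drug2`, `observed` matrix,
#'   and `truth` (delta, noise, whether clipping occurred).
#' @export
simulate_combination_grid <- function(e1, e2, excess_delta = 0,
                                      noise_sd = 0, seed = 1L) {
  if (any(e1 < 0 | e1 > 1) || any(e2 < 0 | e2 > 1))
    stop("single-agent effects must lie in [0, 1]")
  local_rng(seed)
  expected <- outer(e1, e2, function(a, b) a + b - a * b)
  observed <- expected + excess_delta
  if (noise_sd > 0)
    observed <- observed + matrix(stats::rnorm(length(observed), sd = noise_sd),
                                  nrow(observed), ncol(observed))
  clipped <- any(observed < 0 | observed > 1)
  observed <- pmin(pmax(observed, 0), 1)
  list(effects_drug1 = e1, effects_drug2 = e2, observed = observed,
       truth = list(excess_delta = excess_delta, noise_sd = noise_sd,
                    clipped = clipped, seed = as.integer(seed)))
}

#' Write a simulated pharmacogenomic dataset to CSV files
#'
#' Emits the same dialects the loading functions read, for end-to-end and
#' command-line use: expression and unlabeled matrices as CSV with a
#' `sample_id` column and a response CSV (`sample_id`, `drug`, `ic50_nM`).
#'
#' @param sim Result of [simulate_pharmacogenomic()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.csv"),
             responses = file.path(dir, "responses.csv"))
  write_expression(sim$expression, paths[["expression"]])
  utils::write.csv(sim$responses, paths[["responses"]], row.names = FALSE)
  if (!is.null(sim$unlabeled)) {
    paths[["unlabeled"]] <- file.path(dir, "unlabeled.csv")
    write_expression(sim$unlabeled, paths[["unlabeled"]])
  }
  invisible(paths)
}
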
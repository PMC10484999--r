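#' Dose-response curve container
#'
#' Holds replicated viability measurements across increasing drug
#' concentrations. Viability is a fraction of the vehicle control, allowed
#' up to 1.5 to accommodate measurement noise.
#'
#' @param concentrations_nM Strictly increasing positive concentrations; at
#'   least 4 distinct values are required for fitting.
#' @param viability Replicates x concentrations matrix (or a vector for a
#'   single replicate) of fractions in `[0, 1.5]`.
#' @param drug Drug name.
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(concentrations_nM, viability, drug = "drug") {
  if (is.vector(viability)) viability <- matrix(viability, nrow = 1L)
  stopifnot(is.matrix(viability))
  if (any(concentrations_nM <= 0)) stop("concentrations must be positive (nM)")
  if (is.unsorted(concentrations_nM, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (ncol(viability) != length(concentrations_nM))
    stop("viability columns must match the concentration vector")
  if (any(!is.finite(viability)) || any(viability < 0 | viability > 1.5))
    stop("viability values must be finite fractions in [0, 1.5]")
  structure(list(concentrations_nM = as.numeric(concentrations_nM),
                 viability = viability, drug = drug),
            class = "dose_response_curve")
}

#' Read a long-format dose-response CSV
#'
#' Expected columns: `drug`, `concentration_nM`, `replicate`, `viability`.
#'
#' @param path CSV path.
#' @param drug Optional drug to filter on (required when the file holds
#'   several drugs).
#' @return A [dose_response_curve()].
#' @export
read_dose_response <- function(path, drug = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "concentration_nM", "replicate", "viability")
  if (!all(need %in% colnames(df)))
    stop("dose-response CSV needs columns: ", paste(need, collapse = ", "))
  if (is.null(drug)) {
    drugs <- unique(df$drug)
    if (length(drugs) > 1L)
      stop("file holds several drugs (", paste(drugs, collapse = ", "),
           "); pass `drug`")
    drug <- drugs
  }
  df <- df[df$drug == drug, , drop = FALSE]
  doses <- sort(unique(df$concentration_nM))
  reps <- sort(unique(df$replicate))
  v <- matrix(NA_real_, length(reps), length(doses))
  for (i in seq_len(nrow(df)))
    v[match(df$replicate[i], reps), match(df$concentration_nM[i], doses)] <-
      df$viability[i]
  if (anyNA(v)) stop("incomplete replicate x concentration grid for ", drug)
  dose_response_curve(doses, v, drug = drug)
}

# Four-parameter logistic on the inhibitory-effect scale.
fourpl_effect <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / x)^hill)
}

#' Fit a four-parameter logistic dose-response model
#'
#' Fits `effect(x) = bottom + (top - bottom) / (1 + (ec50/x)^hill)` by
#' least squares on the inhibitory-effect scale (`effect = 1 - viability`)
#' using Levenberg-Marquardt with a deterministic multi-start grid over
#' hill slopes and EC50 candidates. Curves with no appreciable response
#' span are flagged degenerate rather than fitted.
#'
#' @param curve A [dose_response_curve()] with >= 4 distinct concentrations.
#' @param min_span Minimum observed effect span below which the curve is
#'   declared degenerate (default 0.1).
#' @return An object of class `fourpl_fit` with fields `bottom`, `top`,
#'   `ec50_nM`, `hill`, `residual_sse`, `converged`, `degenerate`.
#' @examples
#' cur <- simulate_dose_response(list(bottom = 0, top = 1, ec50_nM = 100,
#'                                    hill = 1),
#'                               doses = 10^seq(0, 3.5, length.out = 8),
#'                               n_replicates = 1, noise_sd = 0)
#' fit_4pl(cur)
#' @export
fit_4pl <- function(curve, min_span = 0.1) {
  stopifnot(inherits(curve, "dose_response_curve"))
  x <- curve$concentrations_nM
  if (length(x) < 4L) stop("at least 4 distinct concentrations are required")
  eff <- 1 - colMeans(curve$viability)
  xs <- rep(x, each = nrow(curve$viability))
  ys <- 1 - as.vector(curve$viability)
  span <- max(eff) - min(eff)
  if (span < min_span) {
    return(structure(list(bottom = NA_real_, top = NA_real_,
                          ec50_nM = NA_real_, hill = NA_real_,
                          residual_sse = NA_real_, converged = FALSE,
                          degenerate = TRUE, drug = curve$drug),
                     class = "fourpl_fit"))
  }
  starts <- expand.grid(hill = c(0.5, 1, 2, 4),
                        ec50 = exp(seq(log(min(x)), log(max(x)),
                                       length.out = 5L)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ys ~ bottom + (top - bottom) / (1 + (ec50 / xs)^hill),
        start = list(bottom = min(eff), top = max(eff),
                     ec50 = starts$ec50[i], hill = starts$hill[i]),
        lower = c(bottom = -0.5, top = 0, ec50 = min(x) / 1e3, hill = 0.05),
        upper = c(bottom = 1, top = 1.6, ec50 = max(x) * 1e3, hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(coef = stats::coef(fit), sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_,
                          ec50_nM = NA_real_, hill = NA_real_,
                          residual_sse = NA_real_, converged = FALSE,
                          degenerate = FALSE, drug = curve$drug),
                     class = "fourpl_fit"))
  }
  co <- best$coef
  structure(list(bottom = unname(co["bottom"]), top = unname(co["top"]),
                 ec50_nM = unname(co["ec50"]), hill = unname(co["hill"]),
                 residual_sse = best$sse, converged = TRUE,
                 degenerate = FALSE, drug = curve$drug),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (x$degenerate || !x$converged) {
    cat("fourpl_fit (", x$drug, "): ",
        if (x$degenerate) "degenerate (no response span)" else "did not converge",
        "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("fourpl_fit (%s): bottom=%.3f top=%.3f ec50=%.4g nM hill=%.3f sse=%.4g\n",
              x$drug, x$bottom, x$top, x$ec50_nM, x$hill, x$residual_sse))
  invisible(x)
}

#' Effect concentration (EC-f) from a fitted 4PL curve
#'
#' Closed-form inverse of the four-parameter logistic: the concentration
#' producing `percent_effect`% of the bottom-to-top effect span,
#' `ec50 * (p / (1 - p))^(1 / hill)` with `p = percent_effect / 100`.
#' `effect_concentration(fit, 50)` is exactly the fitted EC50;
#' `effect_concentration(fit, 33)` is the EC33 used for sub-maximal
#' screening doses.
#'
#' @param fit A non-degenerate [fit_4pl()] result.
#' @param percent_effect Strictly between 0 and 100.
#' @return Concentration in nM.
#' @export
effect_concentration <- function(fit, percent_effect) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (fit$degenerate || !fit$converged)
    stop("effect concentrations are undefined for a degenerate fit")
  if (length(percent_effect) != 1L || !is.finite(percent_effect) ||
      percent_effect <= 0 || percent_effect >= 100)
    stop("percent_effect must lie strictly between 0 and 100")
  p <- percent_effect / 100
  fit$ec50_nM * (p / (1 - p))^(1 / fit$hill)
}

#' Bliss independence excess for one combination measurement
#'
#' Scores a drug pair at one dose pair: the expected combined inhibitory
#' effect under Bliss independence is `e1 + e2 - e1*e2`, and the score is
#' `observed - expected`. Positive = synergy, zero = independence,
#' negative = antagonism. All arguments are inhibitory-effect fractions.
#'
#' @param e1,e2 Single-agent inhibitory effects in `[0, 1]`.
#' @param observed Observed combined inhibitory effect in `[0, 1]`.
#' @return The Bliss excess (vectorised over inputs).
#' @export
bliss_score <- function(e1, e2, observed) {
  args <- c(e1, e2, observed)
  if (any(!is.finite(args)) || any(args < 0 | args > 1))
    stop("effects must be inhibitory-effect fractions in [0, 1]")
  observed - (e1 + e2 - e1 * e2)
}

#' Bliss excess over a full combination grid
#'
#' Applies [bliss_score()] elementwise across a dose grid: rows follow
#' drug 1's single-agent effects, columns drug 2's.
#'
#' @param effects_drug1,effects_drug2 Single-agent inhibitory effects.
#' @param observed `length(effects_drug1)` x `length(effects_drug2)` matrix
#'   of observed combined effects.
#' @return A list of class `bliss_grid` with `bliss_excess` (matrix),
#'   `mean_excess` and the inputs.
#' @export
bliss_grid <- function(effects_drug1, effects_drug2, observed) {
  if (!is.matrix(observed) ||
      nrow(observed) != length(effects_drug1) ||
      ncol(observed) != length(effects_drug2))
    stop("observed must be a ", length(effects_drug1), " x ",
         length(effects_drug2), " matrix")
  expected <- outer(effects_drug1, effects_drug2, function(a, b) a + b - a * b)
  e1m <- rep(effects_drug1, times = ncol(observed))
  e2m <- rep(effects_drug2, each = nrow(observed))
  excess <- matrix(bliss_score(e1m, e2m, as.vector(observed)),
                   nrow(observed), ncol(observed))
  structure(list(effects_drug1 = effects_drug1,
                 effects_drug2 = effects_drug2,
                 observed = observed,
                 expected = expected,
                 bliss_excess = excess,
                 mean_excess = mean(excess)),
            class = "bliss_grid")
}

#' @export
print.bliss_grid <- function(x, ...) {
  cat(sprintf("bliss_grid %dx%d: mean excess %.4f (positive = synergy)\n",
              nrow(x$bliss_excess), ncol(x$bliss_excess), x$mean_excess))
  invisible(x)
}

#' Filter a viability-reduction screen for hits
#'
#' Keeps inhibitors whose percent viability reduction versus control meets
#' the cut-off (inclusive), sorted by decreasing reduction.
#'
#' @param viability_reduction Named numeric vector: percent reduction per
#'   inhibitor.
#' @param cutoff_percent Inclusive threshold, default 10.
#' @return Named numeric vector of hits in decreasing order.
#' @export
screen_hits <- function(viability_reduction, cutoff_percent = 10) {
  if (is.null(names(viability_reduction)) ||
      any(!nzchar(names(viability_reduction))))
    stop("viability_reduction must be named by inhibitor")
  if (any(!is.finite(viability_reduction)))
    stop("reductions must be finite percentages")
  hits <- viability_reduction[viability_reduction >= cutoff_percent]
  hits[order(-hits, names(hits))]
}
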
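test_that("Bliss excess matches the independence formula and its invariances", {
  expect_equal(bliss_score(0.5, 0.5, 0.75), 0)
  expect_equal(bliss_score(0.3, 0.4, 0.7), 0.12)
  expect_equal(bliss_score(0.2, 0, 0.2), 0)
  expect_error(bliss_score(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(bliss_score(0.5, 0.5, -0.1), "\\[0, 1\\]")

  # independence lattice: observed = e1 + e2 - e1*e2 scores exactly 0
  e <- seq(0, 1, length.out = 101)
  grid <- expand.grid(e1 = e, e2 = e)
  expected <- grid$e1 + grid$e2 - grid$e1 * grid$e2
  expect_true(all(bliss_score(grid$e1, grid$e2, expected) == 0))
  # expected combined effect stays a valid fraction on the whole lattice
  expect_true(all(expected >= 0 & expected <= 1))

  # adding delta to the observed effect adds exactly delta to the score
  base <- bliss_score(0.3, 0.6, 0.7)
  expect_equal(bliss_score(0.3, 0.6, 0.8) - base, 0.1)
})

test_that("Bliss grids apply the score elementwise and summarise the excess", {
  one <- bliss_grid(0.3, 0.4, matrix(0.7, 1, 1))
  expect_equal(one$bliss_excess[1, 1], bliss_score(0.3, 0.4, 0.7))

  g <- simulate_combination_grid(seq(0.1, 0.6, 0.1), seq(0.1, 0.5, 0.1),
                                 excess_delta = 0.1, noise_sd = 0)
  bg <- bliss_grid(g$effects_drug1, g$effects_drug2, g$observed)
  expect_equal(bg$mean_excess, 0.1, tolerance = 1e-12)
  expect_equal(dim(bg$bliss_excess), c(6L, 5L))

  zero <- simulate_combination_grid(c(0.2, 0.4), c(0.3, 0.5), excess_delta = 0)
  bz <- bliss_grid(zero$effects_drug1, zero$effects_drug2, zero$observed)
  expect_true(all(bz$bliss_excess == 0))

  expect_error(bliss_grid(c(0.1, 0.2), 0.3, matrix(0.5, 1, 1)), "matrix")
})

test_that("combination-grid simulation honours the forward formula and clipping", {
  g <- simulate_combination_grid(0.3, 0.4, excess_delta = 0.12)
  expect_equal(g$observed[1, 1], 0.70)
  clip <- simulate_combination_grid(0.95, 0.95, excess_delta = 0.2)
  expect_equal(clip$observed[1, 1], 1)
  expect_true(clip$truth$clipped)
})

test_that("noiseless 4PL recovery is exact across well-conditioned hill slopes", {
  doses <- 10^seq(0, 3.5, length.out = 8)
  for (hill in c(0.5, 1, 2, 4)) {
    truth <- list(bottom = 0, top = 1, ec50_nM = 100, hill = hill)
    cur <- simulate_dose_response(truth, doses, n_replicates = 1, noise_sd = 0)
    fit <- fit_4pl(cur)
    expect_true(fit$converged)
    expect_lt(abs(fit$ec50_nM - 100) / 100, 0.001)
    expect_lt(abs(fit$hill - hill) / hill, 0.001)
    expect_lt(abs(fit$top - 1), 0.001)
    expect_lt(abs(fit$bottom), 0.001)
  }
})

test_that("noisy 4PL recovery stays within 15% on EC50 (sd 0.05, 3 replicates)", {
  doses <- 10^seq(0, 3.5, length.out = 8)
  truth <- list(bottom = 0, top = 1, ec50_nM = 100, hill = 1)
  cur <- simulate_dose_response(truth, doses, n_replicates = 3,
                                noise_sd = 0.05, seed = 42)
  fit <- fit_4pl(cur)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50_nM - 100) / 100, 0.15)
})

test_that("degenerate and malformed curves are flagged, not fitted", {
  flat <- dose_response_curve(c(1, 10, 100, 1000),
                              matrix(1, 2, 4, byrow = TRUE))
  fit <- fit_4pl(flat)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$ec50_nM))
  expect_error(effect_concentration(fit, 50), "degenerate")

  expect_error(dose_response_curve(c(10, 1, 100, 1000), matrix(1, 1, 4)),
               "increasing")
  expect_error(dose_response_curve(c(-1, 1, 10, 100), matrix(1, 1, 4)),
               "positive")
  expect_error(fit_4pl(dose_response_curve(c(1, 10, 100),
                                           matrix(c(1, 0.5, 0), 1, 3))),
               "4")
})

test_that("effect concentrations invert the fitted curve", {
  doses <- 10^seq(0, 3.5, length.out = 8)
  fit <- fit_4pl(simulate_dose_response(
    list(bottom = 0, top = 1, ec50_nM = 100, hill = 1), doses,
    n_replicates = 1, noise_sd = 0))
  expect_equal(effect_concentration(fit, 50), fit$ec50_nM)
  # closed form: EC33 = ec50 * (0.33/0.67)^(1/hill); near 49.25 nM here
  expect_equal(effect_concentration(fit, 33),
               fit$ec50_nM * (0.33 / 0.67)^(1 / fit$hill))
  expect_equal(effect_concentration(fit, 33), 100 * 33 / 67,
               tolerance = 1e-2)
  # forward-evaluating the 4PL at EC33 gives 33% of the effect span
  ec33 <- effect_concentration(fit, 33)
  eff <- fit$bottom + (fit$top - fit$bottom) /
    (1 + (fit$ec50_nM / ec33)^fit$hill)
  expect_equal((eff - fit$bottom) / (fit$top - fit$bottom), 0.33,
               tolerance = 1e-6)

  fit2 <- fit_4pl(simulate_dose_response(
    list(bottom = 0, top = 1, ec50_nM = 100, hill = 2), doses,
    n_replicates = 1, noise_sd = 0))
  expect_equal(effect_concentration(fit2, 50), fit2$ec50_nM)

  expect_error(effect_concentration(fit, 0), "strictly between")
  expect_error(effect_concentration(fit, 100), "strictly between")
})

test_that("dose-response curves round-trip through the long CSV dialect", {
  truth <- list(bottom = 0.1, top = 0.9, ec50_nM = 50, hill = 1.5)
  cur <- simulate_dose_response(truth, c(1, 10, 100, 1000, 10000),
                                n_replicates = 2, noise_sd = 0.02, seed = 3)
  df <- data.frame(drug = cur$drug,
                   concentration_nM = rep(cur$concentrations_nM,
                                          each = nrow(cur$viability)),
                   replicate = rep(seq_len(nrow(cur$viability)),
                                   times = ncol(cur$viability)),
                   viability = as.vector(cur$viability))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_dose_response(path)
  expect_equal(back$concentrations_nM, cur$concentrations_nM)
  expect_equal(back$viability, cur$viability)

  # midpoint sanity: viability at the EC50 of a full-span noiseless curve
  mid <- simulate_dose_response(list(bottom = 0, top = 1, ec50_nM = 100,
                                     hill = 1),
                                c(1, 10, 100, 1000), n_replicates = 1,
                                noise_sd = 0)
  expect_equal(mid$viability[1, 3], 0.5)
})

test_that("screen-hit filtering is inclusive at the cutoff and sorted", {
  expect_identical(names(screen_hits(c(A = 12, B = 5))), "A")
  expect_identical(names(screen_hits(c(A = 10))), "A")
  hits <- screen_hits(c(a = 15, b = 40, c = 10, d = 9.99))
  expect_identical(names(hits), c("b", "a", "c"))

  # a 378-inhibitor panel entirely below the cutoff yields no hits
  set.seed(1)
  panel <- setNames(runif(378, 0, 9.9), sprintf("inh%03d", 1:378))
  expect_length(screen_hits(panel), 0L)
  expect_error(screen_hits(c(1, 2)), "named")
})
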
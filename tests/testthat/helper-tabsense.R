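# Shared fixture builders; everything is generated in code at test time.

# Fast training configuration for tests: small widths, few epochs.
quick_hp <- function(seed = 1L, max_epochs = 30L, early_stop_patience = 10L,
                     ...) {
  hyperparams(decision_width = 8L, attention_width = 8L, n_decision_steps = 2L,
              max_epochs = max_epochs, batch_size = 32L,
              early_stop_patience = early_stop_patience, seed = seed, ...)
}

# Normalised two-class benchmark dataset with known informative genes.
make_bench <- function(seed = 1L, n_per_class = 75L, n_genes = 50L,
                       n_informative = 10L, effect_size = 3,
                       n_unlabeled = 0L) {
  sim <- simulate_pharmacogenomic(n_per_class, n_per_class, n_genes,
                                  n_informative, effect_size = effect_size,
                                  noise_sd = 1, n_unlabeled = n_unlabeled,
                                  seed = seed)
  nm <- minmax_normalize(sim$expression)
  list(data = labeled_dataset(nm$values, sim$labels), sim = sim,
       stats = nm$stats)
}

# Label/prediction vectors realising given confusion counts
# (positive class = sensitive).
vectors_from_counts <- function(tp, fp, tn, fn) {
  labels <- c(rep(1L, tp + fn), rep(0L, tn + fp))
  predicted <- c(rep(1L, tp), rep(0L, fn), rep(0L, tn), rep(1L, fp))
  list(labels = labels, predicted = predicted)
}

test_auc <- function(d_test, fit) {
  auc <- metric_suite(d_test$labels, predict(fit, d_test$features))$auc
  auc
}
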
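---
title: "Methods: models, metrics and design choices in tabsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, metrics and design choices in tabsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabsense)
```

# Scope

`tabsense` predicts binary drug sensitivity (sensitive vs resistant,
defined by a strict IC50 < 500 nM rule) from gene-expression matrices,
with self-supervised pretraining on unlabeled cohorts, and provides the
dose-response and Bliss-synergy computations used to validate predicted
combination partners. This vignette explains the models, the tunable
parameters, the numerical conventions, and what the synthetic-data tests
do and do not demonstrate.

# The attentive tabular classifier

## Forward model

For normalised features $x \in [0,1]^p$ the network runs $S$ sequential
decision steps. Step $s$ computes a per-sample attention mask over genes,

$$M_s = \mathrm{softmax}\!\big(\mathrm{ReLU}(x U_s + b_{U_s}) V_s + \log P_s\big),$$

where $U_s \in \mathbb{R}^{p \times n_a}$, $V_s \in \mathbb{R}^{n_a \times p}$
form an attentive transformer of width $n_a$ (`attention_width`) and
$P_s$ is a relaxation prior, initialised to 1 and updated
$P_{s+1} = P_s\,(\gamma - M_s)$ with `relaxation_gamma` $\gamma \ge 1$.
Values of $\gamma$ near 1 force different steps to attend to different
genes; larger values allow reuse. The masked input $x \odot M_s \cdot p$
(rescaled by $p$ so magnitudes are comparable to $x$ under a uniform
mask) passes through a ReLU feature transformer of width $d$
(`decision_width`); the step outputs are summed and a logistic head
yields $\Pr(\text{sensitive})$.

The loss is binary cross-entropy plus a sparsity penalty: the mean
entropy of the masks weighted by `sparsity_coefficient`. Minimising mask
entropy pushes each step towards attending to few genes, which is what
makes the aggregated mask mass (`coef()` on a fitted model) usable as a
feature-importance readout.

## Numerical and training conventions

* Optimisation is minibatch Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$).
  All initialisation, shuffling and masking randomness derives from the
  integer `seed` carried in `hyperparams()`, so fits are bit-reproducible
  on a fixed platform; across BLAS/platform classes we promise agreement
  of predictions only to ~1e-6, and tests compare fingerprints within one
  platform.
* The relaxation prior is treated as a constant during backpropagation
  (a forward-only recurrence). This keeps each step's gradient local and
  is the usual simplification for multiplicative prior chains; the
  learning-sanity properties below are unaffected.
* The prior enters the softmax as an additive $\log P$ term, which is the
  exact renormalised product and keeps the softmax Jacobian standard.
* Early stopping monitors validation NegLog2RMSL (the package's
  model-selection score; AUC is available by option) with patience
  `early_stop_patience` (default 20); the best-epoch weights are
  restored. Validation sample ids are recorded as "seen in training" for
  the leakage guard.

## Self-supervised pretraining

`pretrain()` fits a masked-feature reconstruction autoencoder: a random
fraction (`masking_fraction`, default 0.5 — an even corrupt/keep split is
a reasonable default when nothing is known about the feature redundancy
structure) of entries is zeroed and a one-hidden-layer ReLU autoencoder
of width `decision_width` is trained to reconstruct the masked values
(squared error on masked entries only). The encoder weights warm-start
every decision step's feature transformer in `tabsense_fit()` (recycled
with small jitter if widths differ). The intended benefit is the usual
semi-supervised one: representations shaped by the unlabeled pool's
covariance. On the package's synthetic benchmark the measured effect is
neutral-to-positive; the test suite asserts the paired difference
(warm − cold held-out AUC) has median ≥ −0.05 rather than a strict gain,
because with strongly informative genes the supervised signal already
saturates.

# Labels, normalisation and sampling

* **IC50 rule**: sensitive iff IC50 < 500 nM, strict; the boundary value
  is resistant. The rule is total for every positive finite IC50.
* **Min-max normalisation** maps each gene to $[0,1]$. Statistics are fit
  on training data only and applied with clipping to validation, test and
  unlabeled data (`normalization = "train"` in the pipeline). A `"global"`
  mode (statistics from the full annotated matrix) is available for users
  who want the simpler convention; train-only is the default because it
  cannot leak test-range information. A constant gene maps to 0, keeping
  matrices finite.
* **Gene selection** keeps the `k` highest-variance genes (descending),
  with lexicographic gene-id tie-break for determinism. The pipeline
  default is `n_top_genes = 1000`, a conventional order of magnitude for
  expression classifiers; the choice is exposed because no principled
  universal value exists.
* **Tripartite sampling** (`none`, `over`, `under`) applies to training
  data only — the API takes the training split explicitly and test
  samples never pass through it. Oversampling duplicates minority
  samples with replacement (duplicates carry suffixed ids and a
  `synthetic` flag); undersampling discards majority samples at random.
  Duplication rather than interpolation (SMOTE-style) is the default
  because class-count behaviour is identical and duplication introduces
  no synthetic feature vectors.

# Metrics

`metric_suite()` reports thirteen metrics plus confusion counts.
Conventions that matter:

* Positive class is *sensitive*. Probabilities at the decision threshold
  are classified positive (deterministic tie rule; so threshold 0 calls
  everything sensitive and threshold 1 calls only probability-1 samples
  sensitive).
* AUC is the rank (Mann–Whitney) statistic with midrank ties; average
  precision is the stepwise sum of precision at each positive, in
  decreasing-score order.
* Jaccard is reported twice: the positive-class index
  $tp/(tp+fp+fn)$ (`jaccard`) and the macro average over both classes
  (`jaccard_macro`). Both are emitted because reported "Jaccard" values
  in the applied literature are ambiguous between the two.
* **NegLog2RMSL** $= -\log_2 \max(\mathrm{RMSL}, 10^{-6})$ with
  $\mathrm{RMSL} = \sqrt{\tfrac1n \sum (p_i - y_i)^2}$ on probabilities
  vs 0/1 labels. It is strictly decreasing in RMSL until the clamp, and a
  perfect probability vector scores $-\log_2 10^{-6} \approx 19.93$.
  RMSE of probabilities is used as the "root mean square loss"; a
  logit-space variant would be unbounded and need its own clamp.
* **Cohen-MCC**: $\kappa$ and MCC from the 2×2 table, combined by
  arithmetic mean (`combine = "min"` is available for users who want the
  conservative variant). A degenerate table (any zero marginal) defines
  the affected statistic as 0 and sets a flag rather than propagating
  NaN; likewise single-class label vectors flag AUC/AP as undefined while
  the thresholded metrics remain computable.

# Hyperparameter search

Candidates are full `hyperparams()` objects inheriting unexplored fields
from the hardcoded template. Scoring is stratified inner cross-validation
(default 3-fold) on the training split, by mean NegLog2RMSL. The four
strategies:

* `hardcoded` evaluates the pre-defined configuration once.
* `grid` enumerates a discrete space exhaustively (up to the budget) —
  continuous ranges are rejected.
* `bayes` is sequential surrogate-based optimisation: a Gaussian-process
  surrogate (RBF kernel, fixed length-scale 0.3 on the unit-scaled space,
  jitter nugget) with expected-improvement acquisition over a random
  candidate pool, after a random initial design of one third of the
  budget.
* `tpe` is a per-dimension tree-structured Parzen estimator: the top 25%
  of candidates define the "good" density (Gaussian KDE for continuous
  dimensions, add-one-smoothed frequencies for discrete ones) and
  proposals maximise the good/bad density ratio.

`superior` runs all four sequentially with derived seeds and keeps the
winner. Inner-validation folds are keyed to the common spec seed, so the
same candidate scores identically under every strategy and the winner is
a fair argmax; ties are broken by preferring fewer trainable parameters,
then the fixed order hardcoded → grid → bayes → tpe (simplicity first).
Per-method internal scores are compared directly rather than re-evaluated
on a common extra validation set; with shared folds the scores are
already commensurable. A strategy that errors is recorded in the result
table and excluded from the argmax. The default space (widths
{8, 16, 32}, steps {3, 5}, learning rate log-uniform on
[10⁻³, 2·10⁻²], budget 20) is a pragmatic default, not a claim about any
particular study's ranges.

Leakage is controlled structurally: the search interface only accepts the
training split, and every result carries an audit of the sample ids it
saw, which the tests verify never intersects held-out ids.

# Cross-validation design

`repeated_kfold()` uses stratified folds (robust to class imbalance);
within each fold, sampling, optional search and fitting happen strictly
inside the training portion. By default one fixed configuration is used
across folds and search is off, because nesting a full search inside
every one of k × repeats folds multiplies cost ~budget-fold; per-fold
search remains available via the `search` argument. Records are one row
per repeat × fold; the per-fold train/test id audit is retained in the
result so partition and leakage properties can be checked exhaustively.

# Dose-response and synergy

The four-parameter logistic is fit on the inhibitory-effect scale,
$\text{effect} = 1 - \text{viability}$ (viability as a fraction of the
vehicle control):

$$\text{effect}(x) = \text{bottom} + \frac{\text{top} - \text{bottom}}
{1 + (\mathrm{EC}_{50}/x)^{\text{hill}}}.$$

Fitting is Levenberg–Marquardt least squares with a deterministic
multi-start grid (hill ∈ {0.5, 1, 2, 4} × five log-spaced EC50 starts
across the dose range), keeping the lowest-SSE convergent fit. At least
4 distinct concentrations are required. A curve whose observed effect
span is below `min_span` (default 0.1) is flagged *degenerate* — its
EC50 is unidentifiable and no parameters are reported — and a fit that
never converges is flagged as a failure rather than silently returning
starting values.

Effect concentrations invert the fitted curve in closed form:
$\mathrm{EC}_f = \mathrm{EC}_{50} \cdot (p/(1-p))^{1/\text{hill}}$ for
effect fraction $p = f/100$ of the bottom→top span; EC50 is recovered
exactly at $f = 50$ for every non-degenerate fit, independent of hill.

Bliss independence treats the two drugs' inhibitory-effect fractions as
independent probabilities: expected combined effect
$e_1 + e_2 - e_1 e_2$ (always within [0,1] for valid inputs), and the
score is observed − expected, so adding δ to the observed effect adds
exactly δ to the score. Effects are fractions throughout; percentages
are converted at the I/O boundary. Screen-hit filtering is inclusive at
the cutoff (default 10%), since boundary semantics are otherwise
arbitrary. A combination-index statistic is deliberately not provided:
there is no single standard formula, and silently picking one would
invite misreading; Loewe/ZIP/HSA models are likewise out of scope.

# The synthetic-data generator

`simulate_pharmacogenomic()` emulates a two-class pharmacogenomic study:
log-normal expression (per-gene log-scale baselines uniform on [1, 4],
within-class noise `noise_sd`), with `n_informative` genes shifted by
`effect_size · noise_sd` on the log scale in the sensitive class, an
IC50 table drawn from truncated log-normals (sensitive around 100 nM
truncated below 500; resistant around 2000 nM truncated above 500) so
the strict < 500 nM rule reproduces the intended labels exactly, and an
unlabeled pool from the same mixture. Log-normal marginals were chosen
over Gaussian to match expression positivity and heavy right tails; the
IC50 truncation is a deliberate simplification vs real pharmacology that
buys deterministic ground-truth labels.

What the generator does **not** emulate: gene–gene correlation structure,
batch effects, platform differences, dropout, label noise near the IC50
boundary, or class-dependent library sizes. Passing tests on this
generator therefore demonstrate that the pipeline's machinery is correct
(learns real signal, stays at chance without it, never leaks test data),
not that any particular accuracy will transfer to real cohorts.

`simulate_dose_response()` and `simulate_combination_grid()` provide the
synergy arm's ground truth analogously (forward 4PL plus Gaussian noise
clipped to [0, 1.5]; Bliss expectation plus injected excess clipped to
[0, 1] with clipping recorded).

# Problem sizes used in the test and acceptance runs

The package's own verification runs use desk-scale simulations chosen to
exercise every code path while keeping the full suite in minutes on one
CPU: the learning benchmark is 300 samples × 100 genes with 10
informative genes at a 3σ effect (held-out AUC median over 10 seeds, with
a label-shuffled null), cross-validation is the full 5-fold × 20-repeat
design (100 fits at reduced epochs), and search/leakage checks use
smaller grids with 2-fold inner validation. These sizes are the package's
reference conditions; users fitting real cohorts should expect to raise
`max_epochs` (default 100) and the search budget.

# Known limitations

* The classifier is a compact attentive network, not a large-scale deep
  model; on very wide matrices (tens of thousands of genes) variance-based
  selection down to ~10³ genes is assumed first.
* Bitwise reproducibility is per platform/BLAS class.
* `fit_4pl()` assumes a monotone dose-effect relationship; biphasic
  curves will fit poorly and should be caught by inspecting
  `residual_sse`.
* Cohort predictions are only as calibrated as the decision threshold;
  no recalibration (Platt/isotonic) is provided.
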
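---
title: "Federated multi-channel prognosis modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated multi-channel prognosis modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospitals that would like to pool their electronic health records for
prognosis modelling usually cannot: raw patient data may not leave the
institution, the sets of laboratory tests and vital signs each institution
records overlap only partially, and the institutions often care about
different prediction targets (a COVID-19 ward predicts remaining length of
stay, a nephrology department predicts mortality risk). `fedprog` implements
a federated representation-learning architecture for exactly this setting:

* **Per-feature sequential channels.** Every dynamic clinical feature `x` has
  its own gated recurrent unit with scalar input and hidden size `h`; the
  channel's final hidden state `f_x` is that feature's embedding. Because a
  channel sees only one feature, institutions that record the feature can
  train the channel *jointly* regardless of what else they record.
* **Demographic embedding.** Static covariates (age, gender) are mapped into
  the same `h`-dimensional space by a linear embedding, followed by a GELU
  activation and dropout 0.1 (training mode only) in the full model.
* **Masked attention recalibration.** The canonical feature rows are stacked
  into a matrix `F` (zero placeholder rows, with a `recorded_row_mask`, for
  features an institution does not record, so all institutions share one row
  indexing). Each row `i` owns private projections producing a query from the
  patient context `f̄` (the mean of recorded rows), and a key and value from
  the row itself. Scores of unrecorded rows are replaced by −10⁹ before the
  softmax, so their attention weight vanishes and recorded rows renormalize
  as if the unrecorded ones were absent. The health-status representation is
  `s = Σ αᵢ vᵢ`.
* **Private task heads.** A logistic head for terminal mortality (mean binary
  cross-entropy over patients) and a linear head for remaining length of stay,
  supervised *at every record* of the stay. The representation fed to the
  regression head at record `t` is built from the sequence prefix up to `t`
  (for a recurrent channel this is simply its intermediate hidden state), so
  remaining-days predictions are causal.

Two federation protocols are implemented behind a switch, because both appear
in practice and they are genuinely different algorithms:

* `fedavg` — each round every site runs `local_epochs` epochs of AdamW on its
  own loss, then the server replaces every shared parameter by the
  count-weighted mean over the sites that hold it.
* `accum` — each round every site sends the gradient of one mini-batch
  evaluated at the current synchronized snapshot, with parameters of features
  it does not record *frozen and masked* (absent from the message); the server
  accumulates the shared-key gradients and takes a single optimizer step,
  while sites step their private keys locally.

Sharing rule: a feature's channel is shared iff at least two institutions
record the feature; the demographic embedding is shared when the demographic
schema is common; the recalibration projections and the heads are always
private — they encode which features matter for a site's own task.

## Privacy pattern

No message a site emits can contain patient-level data. Standardization uses
pooled moments: each site shares per-feature `(count, sum, sum of squares)`
triples over its *training* split, the triples are merged by count weighting
(population variance, so the merge is exact and order-independent), and every
site applies the same z-score transform to shared features; private features
use local moments. Parameter and gradient exchange objects are validated
against a schema that admits only keyed numeric parameter arrays plus a sample
count. Cryptographic protection of the transport (secure aggregation,
differential privacy, encryption) is out of scope.

## The synthetic federation

No real multi-hospital EHR collection can ship with a package, so the
generator builds one with the structural properties that matter:

* a latent patient risk state `z_t` (dimension 3) following a Gaussian random
  walk (`z_1 ~ N(0, I)`, step s.d. 0.35) over a visit sequence of length
  4–12;
* each dynamic feature is a fixed random linear readout of `z_t` plus
  Gaussian observation noise, with the readout attached to the *feature name*
  so the same feature carries the same signal at every site recording it —
  this is what makes cross-site channel sharing genuinely informative;
* terminal mortality `~ Bernoulli(sigmoid(intercept + w·z_T + 0.3·age_std +
  0.1·(gender−½)))`, the intercept calibrated by bisection on a fixed-seed
  Monte Carlo sample (n = 10 000) to a 15% base rate;
* remaining length of stay decreasing by exactly one day per record index to
  a terminal remainder `max(0, round(6 − 2·w·z_T))` that shortens with risk
  (a per-step noisy stay target cannot both be rounded and decrement exactly
  with the record gap; we keep the exact decrement, which is what the data
  model promises downstream);
* observations dropped i.i.d. at rate 0.3; demographics age ~ U(18, 95),
  gender ~ Bernoulli(½).

The default study configuration mirrors a three-institution federation with
cohort-size asymmetry (400 / 1500 / 600 patients), a feature Venn of 8
all-shared + 4 per pairwise intersection + 4 private features per site (32
dynamic features), and a task split where sites 1–2 predict mortality and
length of stay while site 3 predicts mortality only.

The observation noise s.d. defaults to 1.0 — per-observation signal-to-noise
around one per feature, comparable to real clinical laboratory measurements,
so no single feature identifies the latent state and channel quality matters.
What the
generator does *not* emulate: realistic clinical marginal distributions,
informative (non-random) missingness, treatment feedback processes. Passing
tests therefore demonstrate correctness of the machinery and the *direction*
of the collaboration effect under a shared latent signal, not clinical
performance on real data.

## Numerical and design choices

* **Gate convention.** `h_t = (1−z_t)⊙h_{t−1} + z_t⊙c_t` with candidate
  `c_t = tanh(W_h x_t + U_h(r_t⊙h_{t−1}) + b_h)`; initial state 0. With all
  parameters zero the hidden state stays exactly zero.
* **Demographic embedding orientation.** The embedding is stored `h × m` so
  `f = W_base · base` lands in the channel hidden space (the two shape
  conventions in circulation cannot both hold literally; one orientation is
  fixed and documented).
* **Context vector.** `f̄` is the mean over *recorded* rows, including the
  demographic row (it is always recorded). Mean pooling is the minimal
  permutation-invariant context; excluding unrecorded placeholder rows keeps
  the context independent of how many features a site does not record.
* **Mask value.** −10⁹. After max-subtraction the masked exponentials
  underflow to exactly 0 in double precision, so masked rows carry weight 0
  and contribute nothing to `s` (their value vectors are also exactly 0
  because placeholder rows are zero).
* **Loss conventions.** Mean BCE over patients; mean squared error over
  (patient, time) records for length of stay. Both are the standard
  non-negative forms. Predicted probabilities are clamped to
  `[10⁻⁷, 1−10⁻⁷]`.
* **Regression target scaling.** The remaining-LOS target is standardized
  with the same pooled count/sum/sumsq pattern used for features (one scale
  for the whole federation), and predictions are mapped back to days for
  reporting. Without this the squared-error term is one to two orders of
  magnitude larger than the cross-entropy term and dominates every shared
  gradient; with it the two tasks train at commensurate scales.
* **Optimizer.** AdamW (decoupled weight decay 0.01), learning rate 0.001,
  plain Adam behind a flag. Per-key step counts keep bias correction correct
  for parameters that are frozen in some rounds.
* **Standardization split.** Moments are computed on each site's training
  split only, so validation/test information never leaks into preprocessing.
* **Degenerate inputs.** A feature with zero pooled count or pooled s.d.
  below 10⁻⁸ passes through standardization unchanged; a validation split
  whose bootstrap or metric is undefined (single class) falls back to the
  negative loss as the early-stopping criterion.
* **Seeding.** One master seed fans out through a deterministic string-tagged
  child-seed function to initialization, splits, batch shuffles and dropout
  masks. Streams are mode-independent, which makes `federated` with one site
  bit-identical to `isolated` — a degeneracy the test suite asserts.
* **Early stopping.** Per-site patience of 10 epochs on validation AUPRC
  (classification sites) or negative MSE (regression-only sites); each site's
  returned model is its best-validation snapshot.
* **Local fine-tuning.** After federation each site may train all of its
  parameters locally for `finetune_epochs` further epochs (default 0) — the
  personalization step for sites whose tasks differ from the federation
  majority.

## The collaboration-benefit experiment

`collaboration_benefit()` trains, per seed, the default three-site federation
under the Algorithm-style gradient-accumulation protocol, the smallest site
alone (`isolated`), and a pooled-data oracle (`centralized`), and reports the
smallest site's test AUPRC under each. The three regimes are tightly paired:
same cohorts, same splits, same parameter initialization, same shuffle and
dropout streams, so differences reflect the protocol rather than run-to-run
noise.

The experiment's problem sizes are the package's desk-scale choices: hidden
dimension 8, batch 256, learning rate 0.003, a fixed budget of 26 epochs with
best-validation snapshot selection (no early abort) — chosen so ten
replicates complete on a laptop-class single core in minutes while the
learning curves have clearly flattened. The larger learning rate matters at
this scale: at 0.001 a minority of replicates never escape the initial
plateau within the budget, and an early-abort rule then freezes them at a
near-random snapshot; with the fixed budget the best-validation snapshot
still guards against overfitting. The default hidden size and learning rate
elsewhere remain 32 and 0.001.

## Known limitations

* Single-layer, unidirectional channels only; no temporal attention and no
  multi-head attention.
* All clients participate in every round; client sampling and dropout
  tolerance are not modelled.
* The bootstrap mean±std reflects test-set resampling only, not training
  reruns; the paired comparison test is a t-test on replicate vectors.
* No transport layer: the federation is simulated in-process, with message
  schema validation standing in for the privacy claim at the protocol level.
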
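# fedprog

Privacy-preserving federated representation learning for clinical prognosis
across institutions that record **different feature sets** and pursue
**different prediction tasks**.

## The problem

Several hospitals want a better in-hospital mortality and remaining
length-of-stay (LOS) model than any of them can train alone, but raw patient
records cannot leave the institutions, their recorded laboratory/vital-sign
panels overlap only partially, and not every site has every label. `fedprog`
implements a federated architecture built for exactly this setting:

* **Per-feature recurrent channels.** Each dynamic feature *x* is embedded by
  its own gated recurrent unit over the patient's standardized value sequence,
  `f_x = GRU_x(r_{x,1}, …, r_{x,T})`; demographics enter through a linear
  embedding `f_{x+1} = W_base · base` into the same hidden space. Channels for
  features recorded by two or more sites are trained **collaboratively**;
  channels for single-site features stay **private**.
* **Masked attention recalibration** (always private). Per canonical feature
  row *i*: `q_i = W_i^q f̄`, `k_i = W_i^k f_i`, `v_i = W_i^v f_i`,
  `ζ_i = q_i·k_i` for recorded rows and a large negative mask (−10⁹) for
  unrecorded ones, `α = softmax(ζ)`, and the health-status representation
  `s = Σ_i α_i v_i`. Unrecorded features receive vanishing weight; recorded
  ones renormalize as if the others were absent.
* **Private task heads.** `ŷ_cla = σ(W_cla·s + b_cla)` with mean binary
  cross-entropy over patients; `ŷ_reg = W_reg·s + b_reg` with mean squared
  error over every record of the stay (remaining days, causally predicted
  from the sequence prefix).
* **Two federation protocols.** `fedavg`: per round, local epochs followed by
  the count-weighted average `w ← Σ_n (M_n/M) w_n` of shared keys over the
  sites that hold them. `accum`: per round, each site contributes one
  mini-batch gradient evaluated at the synchronized snapshot with unused
  parameters frozen and masked, the server accumulates `G ← G + ∇l` and takes
  one AdamW step.
* **Moment-sharing standardization.** Sites exchange only per-feature
  `(count, sum, sum of squares)` triples computed on their training splits;
  the pooled z-score transform is exact regardless of how values are
  partitioned. No message in the protocol can carry patient-level data, and a
  schema validator enforces it.

Because real multi-hospital EHR collections cannot ship with a package, a
first-class synthetic cohort generator builds federations with the structural
heterogeneity that matters — a latent patient risk process read out by
partially overlapping feature panels, imbalanced mortality, per-record LOS
targets, and missingness — so every stage is testable offline.

## Worked example

```r
library(fedprog)

# a three-site federation: 400 / 1500 / 600 patients, 32 dynamic features in
# a Venn structure (8 shared by all, 4 per pairwise overlap, 4 private each);
# sites 1-2 predict mortality + LOS, site 3 mortality only
co  <- generate_cohorts(default_study_config(seed = 11))

# desk-scale training protocol (see the methods vignette): hidden size 8,
# gradient-accumulation federation, a fixed 30-epoch budget with
# best-validation snapshot selection
cfg <- fed_config(mode = "federated", fed_mode = "accum", lr = 3e-3,
                  epochs = 30, patience = 30, batch_size = 256, h = 8,
                  seed = 11)
fit <- train_federated(co$datasets, co$manifest, cfg)

ev <- evaluate_sites(fit)          # held-out test split per site
report <- bootstrap_report(scores   = ev$site2$p_mort,
                           labels   = ev$site2$y_mort,
                           los_pred = ev$site2$los_pred,
                           los_true = ev$site2$los_true,
                           B = 10, seed = 1)
report
#> <eval_report> B = 10
#>   auroc   91.94 (bootstrap  92.82 +/- 1.33)
#>   auprc   68.72 (bootstrap  71.54 +/- 4.86)
#>   mse     15.75 (bootstrap  15.56 +/- 0.53)
#>   rmse     3.97 (bootstrap   3.94 +/- 0.07)
#>   mae      3.12 (bootstrap   3.11 +/- 0.05)
```

Classification metrics are ×100 for readability; the mortality outcome is
imbalanced (15% base rate), which is why AUPRC is the headline number. The
LOS errors are in days (per record of the stay).

The same pipeline is scriptable from a shell:

```sh
Rscript inst/exec/fedprog simulate --out cohort --seed 42
Rscript inst/exec/fedprog train --data cohort/site1 cohort/site2 cohort/site3 \
        --mode federated --fed-mode accum --out run --seed 1
Rscript inst/exec/fedprog evaluate --checkpoint run/checkpoint.json \
        --data cohort/site1 cohort/site2 cohort/site3 --bootstrap 10 --seed 1 \
        --out eval --export-attention
```

`evaluate --export-attention` writes the per-patient attention weights
(`patient_id, feature, weight`) — the model's account of which recorded
features drove each patient's representation.

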
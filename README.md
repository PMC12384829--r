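# pdcognet

Explainable neural-network prediction of 3-year cognitive decline in
Parkinson's disease (PD), as a tested, reusable R pipeline.

## What it does, and for whom

Clinicians and methodologists studying PD progression want to know, from
baseline data a clinic already collects — cognitive screening (MoCA) and
domain tests, MDS-UPDRS motor scores, neuropsychiatric questionnaires,
DAT-imaging uptake summaries, genetic markers — which patients will be
cognitively impaired three years later, and *which variables drive that
prediction*. `pdcognet` implements the full analysis:

* **Synthetic cohort generator** — 618 subjects × 166 baseline variables
  in 20 correlated blocks (one latent factor per block), calibrated to a
  follow-up impairment prevalence of ≈ 31% (MoCA < 26), with four planted
  informative groups (MoCA, HVLT-R, MDS-UPDRS III, STAI) as ground truth.
  Real cohorts of this kind are access-controlled; every downstream stage
  is testable without any download.
* **Preprocessing** — iterative random-forest imputation (missForest
  style, via `ranger`), z-scoring, and group-wise PCA keeping components
  with eigenvalue ≥ 1.5 in groups of more than 5 variables (166 → ~21
  features on the default cohort).
* **Classifier** — a feed-forward network (7 leaky-ReLU hidden units, 2
  softmax outputs) written from the formulas, trained with the focal
  cross-entropy loss

  FL(p_t) = −α_t (1 − p_t)^γ log(p_t),  α = (0.5, 2.0), γ = 1.5,

  Adam, batch 8, ≤ 50 epochs, early stopping; analytic backpropagation
  verified against finite differences.
* **Evaluation** — stratified 5-fold cross-validation, best-fold
  selection by Impaired-class recall, per-class recall/precision/F1,
  accuracy, ROC/AUC (trapezoid = rank statistic), and misclassification
  by longitudinal trajectory class.
* **Explainability** — sampled Shapley attributions (with an exact
  enumeration oracle), group-wise masking ΔRecall, and brute-force
  combinatorial masking of all 21,699 group subsets of size 1–5.

See `vignettes/pdcognet-methods.Rmd` for the model, its assumptions, and
every numerical convention.

## Worked example

```r
library(pdcognet)

run <- run_pipeline(pipeline_config(
  out_dir = "pd-run",
  cohort  = cohort_spec(seed = 20250930L),  # default study conditions
  seed    = 20250930L
))
#> stage=generate n=618 vars=166 missing=5133
#> stage=preprocess features_in=166 features_out=21
#> stage=cv k=5 best_fold=5 best_recall=0.872
#> stage=evaluate recall=0.913 accuracy=0.683 auc=0.829
#> stage=shap permutations=200 top=STAI_PC1
#> stage=mask most_critical=STAI delta=-0.103
#> stage=combo subsets=21699 worst_recall=0.682

head(run$mask, 4)
#>       group baseline_recall masked_recall delta_recall
#> 1      STAI       0.9128205     0.8102564  -0.10256410
#> 2    HVLT_R       0.9128205     0.8410256  -0.07179487
#> 3      MOCA       0.9128205     0.8512821  -0.06153846
#> 4 UPDRS_III       0.9128205     0.8717949  -0.04102564
```

Reading this: the 166 raw variables collapse to 21 PCA features; the
best cross-validation fold reaches held-out Impaired recall 0.872; the
selected model, evaluated on the full cohort, flags 91.3% of subjects who
will be impaired at follow-up (AUC 0.83). Masking the anxiety block
(STAI) costs the most sensitivity (ΔRecall −0.10), followed by verbal
memory, baseline MoCA, and motor severity — exactly the four groups the
generator planted, recovered without the model being told. The worst
5-group subset drops recall to 0.682. `run$metrics` also carries the
aggregated held-out confusion counts, the honest out-of-sample estimate
next to the in-sample full-dataset figures.

The worked-example metrics module reproduces, from a published
misclassification table alone (per-trajectory totals 371/92/100/55,
errors 84/3/15/36), the full downstream accounting: confusion matrix
(TP 174, FN 18, TN 306, FP 120), Impaired recall 174/192 = 0.906,
precision 0.592, accuracy 0.777, macro recall 0.812, conversion detection
85% — see `metrics_from_confusion()`.

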
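# fewshotDx

Prior-informed few-shot diagnostic classification for small transcriptomic
cohorts.

Rare-disease and single-study cohorts — a few dozen microarray or RNA-seq
samples per class — are too small for conventional deep classifiers and
often too noisy for single-gene markers. fewshotDx implements a diagnostic
pipeline built for exactly this regime, combining a frozen pathway-aligned
latent prior, biomarker-guided channel gating, and a Relation Network
style few-shot comparator, together with the upstream consensus
feature-selection workflow and downstream calibration, explanation and
decision-curve analysis.

## The method

**Projection onto a frozen prior.** Log2 expression `X` (genes × samples,
z-scored per gene with training-derived parameters) is projected onto the
latent variables (LVs) of a fixed PLIER/MultiPLIER-style loading matrix
`Z` by ridge regression:

    B = (ZᵀZ + λI)⁻¹ ZᵀX,  λ ≥ 0 (default 1)

`Z` is never fine-tuned, preserving its pathway/cell-type alignment.

**Hub-gene channel gating.** A consensus biomarker set G*′ re-weights the
latent channels through the prior's own loadings:

    αℓ = mean over g ∈ G*′ of |Z_gℓ|,   B̃ = diag(α̂) B

with α̂ = α/max(α) (or α/‖α‖₁).

**Few-shot relation scoring.** A shared 2-layer encoder (L → 128 → 64,
ReLU, dropout 0.3) embeds gated activities; query–support similarity is
the Hadamard product m_{q,s} = h_q ⊙ h_s; and a permutation-invariant
Deep-Sets head scores each class:

    r_{q,c} = ρ_ψ( Σ_{s∈S_c} φ(m_{q,s}) )

Training is episodic (2-way 5-shot, 5 queries/class, temperature-scaled
cross-entropy, Adam, early stopping on validation AUC). The raw
diagnostic score is the binary log-odds s(x) = r_{q,1} − r_{q,0},
calibrated to a probability by Platt scaling or isotonic regression
(whichever wins by cross-validated Brier score), explained by
complete-permutation Shapley attribution over LVs, aggregated to an
additive 0–100 point gene scorecard, and assessed by ROC/AUC and
decision-curve analysis. The forward and backward passes of the network
are implemented directly in R and gradient-checked in the test suite.

**Consensus feature selection.** The biomarker panel itself comes from
intersecting LASSO (cross-validated L1 logistic regression), SVM-RFE
(recursive elimination by squared linear-SVM weights) and random-forest
importance (out-of-bag error, mean-decrease-Gini and permutation
importance recomputed from the fitted trees' structures), followed by a
per-gene AUC > 0.7 screen.

A seeded synthetic-cohort generator with planted latent disease signal
makes every stage testable fully offline.

## Worked example

```r
library(fewshotDx)

# 1. simulate a cohort with a planted latent disease signal
cfg <- synthetic_config(n_per_class = 60, effect_size = 1.5, seed = 7)
ds  <- make_dataset(cfg)
ds$true_hub_genes
#> [1] "G0001" "G0012" "G0013" "G0074"

# 2. hold out 20 samples per class, train on the rest
set.seed(99)
test  <- c(sample(which(ds$labels == 0), 20), sample(which(ds$labels == 1), 20))
train <- setdiff(seq_along(ds$labels), test)
model <- fewshot_train(ds$expression[, train], ds$labels[train],
                       ds$loadings, ds$true_hub_genes,
                       train_config(seed = 11))
model
#> fewshot_model: 1000 genes -> 50 LVs -> d=64 embedding
#>   hub genes: G0001, G0012, G0013, G0074
#>   best validation AUC 0.960 at checkpoint 13 (23 logged)

# 3. score the held-out samples
pred <- predict(model, ds$expression[, test], seed = 3)
head(pred, 3)
#>   sample_id        r0         r1      score class
#> 1      S048 1.6811485 -0.5886578 -2.2698063     0
#> 2      S033 1.2110843  0.1484751 -1.0626092     0
#> 3      S044 0.7179888  0.1138052 -0.6041836     0
roc_auc(pred$score, ds$labels[test])$auc
#> [1] 0.985

# 4. calibrate and inspect clinical utility
cal <- fit_calibration(predict(model, ds$expression[, train], seed = 5)$score,
                       ds$labels[train], seed = 10)
cal
#> calibration_map: platt (CV Brier platt=0.1119 isotonic=0.1227, 5 folds)
probs <- predict(cal, pred$score)
decision_curve(probs, ds$labels[test], grid = c(0.2, 0.4, 0.6))
#>   threshold nb_model     nb_all nb_none
#> 1       0.2   0.4375  0.3750000       0
#> 2       0.4   0.4750  0.1666667       0
#> 3       0.6   0.3000 -0.2500000       0

# 5. explain one reference case sample
acts <- model$reference$activities
sh <- shap_attribution(model, acts[, 41], acts, n_permutations = 32, seed = 2)
round(sort(sh$attributions, decreasing = TRUE)[1:3], 3)
#> LV004 LV001 LV050
#> 3.625 2.977 1.276
```

The held-out AUC of 0.985 says the comparator separates the two classes
almost perfectly on this clearly separable synthetic cohort; the
net-benefit column dominating both treat-all and treat-none across the
threshold grid says the calibrated probabilities would be clinically
usable at any of those risk cutoffs; and the top attributed LVs are among
the planted disease LVs (`LV001`–`LV005`), i.e. the explanation points at
the right pathways.

A thin command-line wrapper over the same functions ships in
`inst/exec/fewshotdx` (subcommands `simulate`, `project`, `gate`,
`select-features`, `train`, `predict`, `evaluate`).

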
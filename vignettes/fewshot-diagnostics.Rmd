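---
title: "Prior-informed few-shot diagnosis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-informed few-shot diagnosis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fewshotDx)
```

## The problem

Transcriptomic diagnosis of rare or small-cohort conditions — the motivating
case is distinguishing alopecia areata, an autoimmune, cytotoxic-T-cell-driven
hair-loss disease, from healthy scalp using tens of microarray samples — sits
in the regime where conventional classifiers overfit. fewshotDx addresses this
with three ideas that are common individually but rarely combined:

1. **A frozen biological prior.** Expression is not fed to the network raw.
   It is projected onto latent variables (LVs) from a PLIER/MultiPLIER-style
   loading matrix learned once on a large compendium and *never* updated here.
   The network therefore sees a few hundred pathway- and cell-type-aligned
   activities instead of ~20k genes, which both regularizes and keeps every
   downstream attribution interpretable at the pathway level.
2. **Hub-gene channel gating.** A consensus biomarker panel (e.g. GZMA,
   IL2RB, IL2RG, EOMES for the motivating disease) re-weights the latent
   channels through the prior's own loadings, emphasizing disease-relevant
   LVs without discarding the rest of the space.
3. **Few-shot set-to-set comparison.** Instead of a per-sample decision
   boundary, a Relation Network style comparator scores a query against
   *sets* of labeled reference samples, trained episodically so the task it
   sees at inference (compare against K references per class) is exactly the
   task it saw during training.

## The model, stage by stage

### Projection

With $X$ the genes $\times$ samples log2 expression matrix (genes z-scored;
see below) and $Z$ the genes $\times$ LVs prior, LV activities solve the
ridge problem

$$B = (Z^\top Z + \lambda I)^{-1} Z^\top X .$$

$\lambda$ (default 1.0) is not critical: the package's test suite checks
that held-out benchmark AUC moves by less than 0.02 across
$\lambda \in \{0.1, 1, 10\}$, which is what one expects when the Gram matrix
$Z^\top Z$ is well-conditioned. $\lambda = 0$ is allowed when the Gram
matrix is invertible; otherwise the error message advises a positive
penalty.

**Scaling choice.** Whether projection should consume raw log2 values or
per-gene standardized values is genuinely open; we standardize (training-set
derived mean and SD per gene, population $1/n$ convention) because it puts
microarray cohorts and synthetic cohorts on a common scale and matches
common practice when projecting new data onto a fixed basis. Standardization
parameters are stored in the model and re-applied verbatim to queries, so no
information flows from query samples into the preprocessing. Genes with zero
training variance are dropped with a warning and recorded.

### Gating

For hub set $G^{*\prime}$, the gate is
$\alpha_\ell = |G^{*\prime}|^{-1} \sum_{g \in G^{*\prime}} |Z_{g\ell}|$,
normalized by its maximum (default) or its $\ell_1$ norm, and applied as
$\tilde B = \mathrm{diag}(\hat\alpha) B$. Max normalization is the primary
formula and keeps every weight in $[0, 1]$ (so gating is a row-wise
contraction); $\ell_1$ is exposed as the documented alternative. Which of
the two the original experiments used is not knowable from the method
description; results in the test suite use max. The gate depends only on
$Z$ and the hub set, is computed once at training time, and is stored with
the model — it is never re-derived from data at inference.

### Encoder, similarity, relation head

The shared encoder $f_\theta : \mathbb{R}^L \to \mathbb{R}^d$ is a 2-layer
fully connected network, $L \to 128$ (ReLU, dropout 0.3) $\to 64$ (ReLU),
with the 64-unit layer as the embedding ($d = 64$). The description of the
architecture fixes the widths but not $d$; identifying the embedding with
the last hidden layer is our reading. Query–support similarity is the
Hadamard product $m_{q,s} = h_q \odot h_s$, and class scores come from a
Deep-Sets head

$$r_{q,c} = \rho_\psi\!\Big(\sum_{s \in S_c} \phi(m_{q,s})\Big),$$

with $\phi$ a $64 \to 64 \to 64$ perceptron and $\rho_\psi$ a
$64 \to 32 \to 1$ perceptron (both ReLU-hidden, linear output; widths are
our choice, attention-based aggregators are deliberately out of scope). Sum
aggregation is the default; mean aggregation is available because it is
invariant to support-set size and duplication, which matters if inference
support sizes differ from the training shot count.

Forward and backward passes are implemented directly in R as matrix
algebra. This is deliberate: the network is small (a few tens of thousands
of parameters), episodes are tiny, and an explicit implementation keeps the
package dependency-light and the computation auditable. The analytic
gradient is verified against central finite differences in the test suite
(agreement to ~1e-10 on random episodes).

### Episodic training

Episodes are 2-way 5-shot with 5 queries per class, drawn without
replacement, support and query disjoint. The loss is the temperature-scaled
cross-entropy on query predictions; we use the *mean* over queries rather
than the sum so the loss magnitude does not depend on the query count (a
pure gradient rescaling, absorbed by the learning rate). One episode is one
Adam step (learning rate 1e-3, weight decay 1e-4 on weight matrices,
dropout 0.3 in the encoder), up to 1000 episodes.

Early stopping monitors validation AUC every 10 episodes; "stagnation for
10" is read as **10 consecutive validation checkpoints** without
improvement — the phrase is ambiguous between episodes and checks, and
checkpoint-granularity is the interpretation that makes patience
independent of the evaluation cadence. The best-AUC checkpoint's weights
are returned.

### Inference and the raw score

A query is standardized, projected, gated, encoded (evaluation mode,
deterministic) and scored against a labeled reference. The default strategy
(`kshot_ensemble`) averages relation scores over 20 seeded draws of K
supports per class, so the aggregator sees the support-set size it was
trained with; `full_set` scores against every reference sample at once,
honoring the literal "support reference set" reading. The two agree on hard
labels for $\ge 95\%$ of held-out synthetic queries in the test suite.

The raw diagnostic score is $s(x) = r_{q,1} - r_{q,0}$. For a two-score
softmax head at $\tau = 1$ this *is* the binary log-odds, which is what a
"raw output logit" should mean for this architecture.

### Calibration, scorecard, decision curves

Platt scaling and isotonic regression are both fitted to $(s(x), y)$;
5-fold seeded stratified cross-validation picks the lower-Brier method
(ties to Platt, the simpler map; isotonic falls back to Platt with a
warning when scores are degenerate). Isotonic predictions interpolate
linearly between knots, which preserves monotonicity.

Attributions of $s(x)$ over the gated LV inputs use complete-permutation
Shapley estimation with background-mean imputation and antithetic ordering
draws. This variant was chosen over faster approximations because each
permutation telescopes from the background to the sample, making the
efficiency identity $base + \sum_\ell \phi_\ell = s(x)$ hold exactly — the
additivity the scorecard depends on, enforced at 1e-6 in the tests.

Gene-level aggregation shares each LV's attribution among hub genes
proportionally to $|Z_{g\ell}|$; "via the loadings" does not pin down a
formula, and proportional-to-absolute-loading is the simplest share that is
non-negative, sums to one per LV, and respects the prior. LVs with no hub
loading pool into an explicit "other" term so additivity survives
aggregation. The 0–100 point scale anchors the anchor cohort's range of
summed positive gene contributions linearly; new samples outside the range
clip with a flag.

Decision-curve analysis uses
$NB(p_t) = TP/n - (FP/n)\, p_t/(1 - p_t)$ on a default grid of 99
thresholds (0.01–0.99), against treat-all and treat-none.

## Consensus feature selection

The upstream biomarker panel comes from intersecting three selectors run on
a candidate feature table:

- **LASSO**: the L1-penalized binomial deviance along a coordinate-descent
  path; 10-fold seeded CV chooses the penalty, `lambda.min` by default
  (`lambda.1se` available — the original rule is not stated, so both are).
- **SVM-RFE**: linear soft-margin SVM refitted each round, features ranked
  by $w_j^2$, lowest-ranked removed (one per round by default), subset
  chosen by cross-validated accuracy with ties going to the smaller subset.
  $C$ and the per-round elimination count are exposed since no canonical
  values exist.
- **Random forest**: 500 Gini-split trees. Out-of-bag error, mean decrease
  in impurity and permutation importance are recomputed from the fitted
  trees' structures rather than read from the library's report — the test
  suite confirms the recomputation matches the library's own numbers to
  ~1e-14, which validates both routes. MDI is reported on two scales: the
  per-node *fraction*-weighted average (at most ~0.5 per tree) and the
  conventional count-weighted report scale (`mean_decrease_gini`, $= n
  \times$ the former). The default absolute selection threshold of 3
  applies to the report scale, where that conventional cutoff lives; it is
  cohort-size dependent, which is why a fraction-of-max alternative is
  offered.

Solvers (glmnet, e1071, randomForest) are delegated; the orchestration —
the RFE loop, the importance formulas, the intersection — is the package's
own code.

The per-gene AUC screen reports the direction-specific AUC (the larger of
the two orientations, with its direction) and passes a gene only on a
*strict* inequality against the 0.7 threshold.

## The synthetic cohort generator

`make_dataset()` draws per-sample LV activities as standard Gaussians,
shifts the first `n_disease_lvs` (default 5) by `effect_size` (default 1.5
activity-SD units) in case samples, and emits $X = ZB + \varepsilon$ with
unit Gaussian gene noise. The loading matrix is block-sparse and
non-negative (20 genes per LV, 2-gene overlap between adjacent blocks,
magnitudes $|N(0,1)|$ rescaled to mean 0.5). Hub genes are the 4
top-loading genes of the disease LVs, mirroring a four-gene validated
panel. These defaults describe a clearly separable cohort of realistic
dimension (1000 genes, 50 LVs, 40/class) for a condition with a coherent
multi-pathway immune signature.

What the generator does **not** emulate: microarray heteroskedasticity,
probe-level artifacts, batch effects, correlated noise, class imbalance,
or single-cell counts. Passing tests on this generator therefore
demonstrate that the pipeline's machinery is correct and that the method
recovers planted signal of the assumed form — not that it attains any
particular accuracy on real cohorts.

## Problem sizes and numerical choices in the shipped tests

- End-to-end benchmark: 1000 genes, 50 LVs, 60 samples/class generated
  (40/class to the trainer, which holds out a stratified quarter for early
  stopping; 20/class held out for evaluation), default 2-way 5-shot
  training. Effect-size sweep at $\delta \in \{0, 0.5, 1.0, 1.5\}$.
- Planted-selection benchmark: 2 informative features (class shift 3
  noise-SDs, single-feature AUC $\approx 0.98$ — "clearly separable") among
  18 noise features, $n = 100$, 10 fixed seeds.
- Shapley estimates in tests use 2–4 antithetic permutations (additivity is
  exact per permutation, so tiny permutation counts still verify it); the
  default for interpretation is 128.
- Ridge projections are validated against dense `solve()` on 50 random
  instances ($G \le 20$, $L \le 8$) at 1e-8.
- Relation scores sum each support set in a canonical (lexicographic)
  element order, which makes permutation invariance hold *bit-identically*
  rather than to rounding.
- ReLU derivative at 0 is taken as 0; dropout uses inverted scaling
  ($\times 1/(1-p)$ at train time); weight init is uniform fan-in scaled,
  drawn from the run seed, so runs are reproducible end to end.

## Known limitations

- Two classes only; N-way episodes, attention aggregators and
  convolutional encoders are out of scope by design.
- Gene symbols are matched case-sensitively with no alias resolution; feed
  matrices keyed on a common symbol standard.
- The absolute MDI threshold is cohort-scale dependent (see above).
- The point scale of the scorecard is anchored to the cohort it was built
  on; transferring it to a differently-scaled cohort requires re-anchoring.
- Episodic training on very small cohorts (fewer than ~10 samples per
  class) cannot form valid episodes with the default shot/query counts;
  reduce `k_shot`/`queries_per_class` accordingly.
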
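---
title: "Methods: boosted-tree liquid-biopsy classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boosted-tree liquid-biopsy classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidcascade)
```

This vignette documents the models, estimators and design decisions behind
`liquidcascade`, in the spirit of a statistical-methods appendix. The
pipeline classifies blood samples by combining plasma protein biomarker
concentrations, a cfDNA mutation summary (the omega score) and clinical
covariates, first into cancer/normal and then into one of several cancer
types via a chain of binary classifiers.

## The omega score

Per sample, cfDNA sequencing yields `w` wells; each well contributes a UID
(unique molecular identifier) count and two p-values locating the well's
mutant allele frequency in cancer and normal reference distributions. The
score is the UID-weighted sum of log-ratios,

$$\Omega=\sum_{i=1}^{w} w_i \ln\frac{p_i^C}{p_i^N},\qquad
  w_i=\frac{\mathrm{UIDs}_i}{\sum_j \mathrm{UIDs}_j},$$

with the natural logarithm. Two conventions are worth stating because the
formula alone does not fix them: the sum runs over **all** wells, and the
score is undefined (an error) for any p-value outside $(0,1]$. The score is
invariant to rescaling all UID counts, and additive over well partitions
when weights are kept global — both properties are tested. How the per-well
p-values are derived from MAF distributions is upstream of this package; we
consume them as given.

## Feature reduction: correlation + mutual information

Redundant features are removed in two steps on the **training split only**
(computing them on the full cohort would leak test information into the
model):

1. All feature pairs with $|r| > 0.5$ (strictly greater; Pearson, pairwise
   complete observations) are collected and sorted by $|r|$ descending,
   ties lexicographic — a canonical order that makes the procedure
   invariant to input column order.
2. Walking that list, if neither member has been dropped yet, the member
   with the **lower** mutual information with the class label is dropped.
   The skip-if-already-dropped rule handles correlation chains; at most one
   member of any pair is ever removed.

Mutual information $I(X;Y)=H(X)-H(X|Y)$ is estimated by the plug-in
(maximum-likelihood) estimator on a discretized joint table, in nats.
Continuous features are discretized by equal-frequency binning with
`n_bins = 10` by default: equal-frequency rather than equal-width because
biomarker concentrations are heavily right-skewed, and 10 bins as a
standard bias/variance compromise at cohort sizes in the hundreds-to-
thousands. Features with at most `n_bins` distinct values are used as
categories directly, which makes the estimator *exactly* equal to the
brute-force double sum on discrete data — the test suite exploits this with
an independent oracle. Estimates are clamped at zero; MI ties keep the
feature earlier in canonical column order. Which binning (if any) the
original development used is not recoverable; the binned plug-in estimator
is the simplest faithful and exactly-testable choice.

## Feature selection: iterative gain importance

A gradient-boosted tree classifier (binary log-loss objective; the
monitored evaluation metric is the misclassification error rate
$(FP+FN)/N$ — boosting needs a differentiable objective, so the error rate
is a metric, not the loss) is fitted `n_rounds = 5` times on shrinking
feature sets. With $n$ reduced features, the subset size is
$\lfloor n/5\rfloor$; round 1 uses all $n$, and between rounds the
subset-size **lowest-gain** features are removed, giving e.g.
40/32/24/16/8. Removing low-gain (rather than high-gain) features is the
only reading under which features selected early can keep reappearing in
later rounds. Gain importance is the per-feature total split gain,
reported as its share of the total; zero-importance features rank below
all positive-gain features with ties broken by canonical column order. The
final selection is the union of the per-round top-10 lists, deduplicated
in first-occurrence order; a round with fewer features than `top_k`
reports them all.

## Ensemble training

The classifier is a leaf-wise histogram gradient-boosted decision-tree
model, consumed strictly through a fit / predict-probability / gain
contract (the package does not re-implement the boosting objective). It is
backed by xgboost with `tree_method = "hist"` and
`grow_policy = "lossguide"`, which grows trees leaf-wise under a
`num_leaves` cap — the histogram/leaf-wise algorithm family of LightGBM.
Threads are pinned to 1 by default so fits are bit-reproducible.

Tuning is random search: `n_iterations = 60` draws by default, with
`n_estimators` from $\{50,100,\dots,500\}$, `num_leaves` from a 50-point
grid spanning 5–500, and `learning_rate` uniform on $(0,1)$. Each draw is
scored by mean balanced accuracy over an inner stratified 5-fold CV (the
outer evaluation uses its own held-out split, so the inner fold count only
trades variance against cost; 5 is conventional). Ties go to the first
sampled configuration.

The tuned configuration is trained with stratified tenfold CV. Each fold
model's balanced accuracy on its held-out fold becomes its ensemble
weight; prediction is **soft voting**,
$s=\sum_i w_i p_i/\sum_i w_i$, thresholded at 0.5 with the boundary
classified positive. Averaging probabilities rather than hard votes was a
genuinely open choice ("average and round" reads either way); probabilities
preserve an AUC-capable score and are the package default. Weights are
normalized by their sum, so rescaling them all leaves predictions
unchanged.

## The typing cascade

Type classification is a chain of binary problems: stage 0 is
cancer-vs-normal on the full cohort; stage $t\ge 1$ separates the $t$-th
type in `class_order` from the remaining types, with normals and
previously claimed types removed. Each stage re-runs the *entire*
reduction/selection/tuning/ensembling pipeline on its own 90/10 split with
derived seed `seed + stage`, so stages are independently reproducible and
their feature panels may differ. At prediction time a sample rejected by
the detection stage is Normal; otherwise the first typing stage that votes
positive assigns its type, and a sample rejected by every typing stage
receives the **last** class in `class_order` — the final binary stage's
negative side — making the decision total. The stage order is a config
parameter (default: first-appearance order of the cohort's types); with
$k$ types there are always $k$ stage datasets and $k$ fitted stages.
Typing-stage splits are drawn independently rather than reusing the
detection split's test samples; nothing in the procedure requires the
splits to be coupled, and independent splits keep each stage
self-contained.

## Evaluation

All metrics derive from the binary confusion matrix: accuracy, precision,
recall/TPR, specificity/TNR, FPR, F1, balanced accuracy
$(TPR+TNR)/2$ and error rate $1-\mathrm{accuracy}$. A metric with a zero
denominator is reported as *undefined* (`NA`), never coerced to zero —
real cohorts never hit these cases but degenerate tests do, and silently
reporting 0 would corrupt macro-averages. AUC is the trapezoidal area
under the ROC curve with tied scores grouped, computed via midranks
(exactly the Mann–Whitney concordance probability). Cross-stage summaries
are unweighted macro-averages that skip undefined entries; macro (rather
than pooled) averaging matches per-stage reporting and keeps small late
stages visible.

## Cost model

Only biomarker assays carry cost and time: the six routinely assayed
markers (AFP, CA 19-9, CA 125, CEA, Prolactin, CA 15-3) at \$2 per test,
other biomarkers at \$5.50, and 2.5 h per biomarker. The omega score and
clinical covariates are free — the only convention consistent with a
12-biomarker panel costing \$62.50 and 30 h. Cost is additive over
disjoint panels and order-invariant.

## The synthetic cohort generator

The generator exists so the whole pipeline is testable end to end without
the restricted clinical cohort it emulates. Its defaults are fixed study
conditions, not tuning knobs:

* **Class structure**: 812 normals and 1005 cancers over seven types.
  Per-type counts are not printed in the source material; the defaults
  allocate 388/209/113/104/93/54/44 to Colorectal/Breast/Upper
  GI/Lung/Pancreas/Ovarian/Liver — a realistic, strongly imbalanced
  allocation summing to 1005.
* **Biomarkers**: log-normal baselines (concentrations are non-negative
  and right-skewed), `noise_sd = 0.5` on the log scale, with informative
  features shifted on the log scale by their effect size × SD for the
  affected class. Defaults give all cancer classes shared inflammatory
  markers (IL-8, IL-6, OPN, …) plus type-specific markers (CA-125/HE4 for
  ovarian, AFP for liver, CEA for colorectal, …).
* **Correlated pairs** are induced by shared Gaussian latent factors on
  the log scale *before* effects are added, so a pair may have one
  informative member and one redundant member — giving the reduction step
  a well-defined right answer. The realized raw-scale Pearson r is
  attenuated below the latent $\rho$ by the log-normal transform and by
  class-shift variance on the informative member (for $\sigma=0.5$ and
  $\rho=0.9$, roughly $r\approx0.89$ within class); default pair
  correlations (0.70–0.80) were chosen from this attenuation calculation
  so realized correlations stay clearly above the 0.5 threshold. A config
  error rejects a feature in two pairs, or a pair whose members carry
  *different* nonzero effects (the ground truth for the reduction test
  would be ambiguous).
* **Omega score**: per sample, 4 wells with UID counts uniform on 50–150;
  normal p-values are uniform, and the cancer p-value is $u^{e^{s}}$ for
  uniform $u$ and class shift $s$, so $E[\Omega] = 1-e^{s}$ in closed form
  (0 at the null, negative for cancers with $s>0$) — used as an analytic
  oracle in the tests.
* **Demographics**: ages from truncated normals (normals 17–88, mean 49;
  cancers 22–93, mean 63); sex and race from per-class categorical
  distributions mirroring the cohort's demographics, stored as integer
  codes with persisted level tables (a covariate stays one feature, which
  keeps importance rankings one-row-per-covariate).

What the generator does **not** emulate: real biomarker units and
reference ranges, inter-assay variance, heavy-tailed outliers, missingness
patterns, or correlations between clinical covariates and biomarkers.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and recovers planted structure — not that the headline accuracies
on the real cohort would be reproduced; those depend on signal strength
the generator only stylizes.

## Numerical and degenerate-input choices

* Per-class test counts round half **away from zero**
  (`round(0.1 · 1005) = 101`, `round(0.1 · 812) = 81`); R's default
  banker's rounding would give 100.
* Constant features yield undefined correlation entries (flagged `NA`),
  never exceptions; they simply cannot form pairs.
* Missing values propagate as `NA` into the learner, which routes them
  natively at each split; no imputation.
* A single-class target is an error everywhere a classifier is fitted.
* Scores exactly at the decision threshold classify positive.
* All RNG flows through per-call seeds with save/restore of the caller's
  RNG state; the learner runs single-threaded by default.

## Problem sizes used in the shipped checks

The package's own validation runs on deliberately compact instances: the
parameter-recovery study uses 2000-sample cohorts (40 biomarkers, five
2-SD informative features, three redundant pairs at latent ρ = 0.85) over
20 seeds; the end-to-end acceptance run uses the full 1817-sample default
cohort with 10 random-search iterations for detection and 5 per cascade
stage. These sizes give stable statistics while keeping a full validation
run in the tens of seconds on one CPU.

## Known limitations

* The boosting internals are delegated, so gain values are reported as
  normalized shares; rankings are identical to raw total gain.
* No probability calibration across cascade stages; stage scores are not
  comparable as probabilities.
* No confidence intervals on metrics, and no SMOTE-style rebalancing —
  imbalance is handled only through balanced-accuracy weighting and
  stratification.
* The cascade's stage order affects its per-stage difficulty; the default
  order is a convention, not an optimized choice.
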
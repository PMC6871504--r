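---
title: "Methylation subtype discovery with methylMCFS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation subtype discovery with methylMCFS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylMCFS)
```

# The problem

DNA methylation profiles distinguish tumour subtypes that histology alone
cannot. The workflow this package implements addresses a three-stage
question asked of a probe × sample matrix of beta values with a class label
per sample: *which CpG probes carry subtype information, how few of them
suffice for accurate classification, and what biology do they point at?*
The motivating setting is multiclass and unbalanced (three subtypes of
IDH-mutant glioma with roughly 78/46/80 training samples), which shapes
several choices below: class-balanced accuracy inside the ranking,
stratified cross-validation, and per-class accuracies alongside the
multiclass MCC.

# Stage 1: Monte-Carlo feature selection

`mcfs_rank()` grows one binary decision tree per combination of `t` random
feature subsets and `m` bootstrap sample sets, and scores each feature `f`
by its relative importance

$$RI_f \;=\; \sum_{\tau=1}^{m\,t} (wAcc)^u \; IG\!\left(n_f(\tau)\right)
\left(\frac{\text{no. in } n_f(\tau)}{\text{no. in }\tau}\right)^{v},$$

summed over the nodes $n_f(\tau)$ that split on $f$ in tree $\tau$. The
intuition: a feature is important if it is chosen often, splits
high-information nodes near the root (large sample fraction), and does so
in trees that generalize (large $wAcc$).

Assumptions and conventions:

* **Trees.** Binary, entropy (base-2) split criterion — so the $IG$ in the
  score is exactly the quantity the tree maximised — with no depth limit,
  a minimum of 2 samples to split, and thresholds at midpoints between
  adjacent sorted values. Split ties go to the smallest feature index,
  then the smallest threshold; leaf-vote ties to the first class level.
  These tie-breaks make the whole ranking a pure function of the seed.
* **wAcc** is the unweighted mean of per-class recalls, computed on the
  bootstrap draw's *out-of-bag* samples. In-bag accuracy of a fully grown
  tree is ~1 by construction and would flatten the weighting; out-of-bag
  evaluation reuses the bootstrap the method already prescribes. Classes
  with no out-of-bag representative are dropped from that tree's mean; a
  bootstrap draw with an empty out-of-bag set is redrawn (and counted in a
  message).
* **"no. in τ"** counts the bootstrap *multiset* (80 samples drawn with
  replacement count as 80), so the root fraction is always 1.

Tunable parameters (defaults):

| parameter | default | why |
|---|---|---|
| `t` | 100 | desk-scale Monte-Carlo budget; published MCFS analyses often use thousands of subsets, and the ranking sharpens with `t` |
| `m` | 5 | bootstrap repetitions per subset; 500 trees total at the defaults |
| `subset_size` | `max(5, ceil(0.05 p))` | the "relatively small subset" convention of the original MCFS method; the source study does not state a value |
| `u`, `v` | 1 | the study's stated weighting exponents |

`filter_positive_ri()` then drops features never chosen for any split:
RI = 0 means the ensemble found no discriminative use for the probe, and
only the positive-RI list (19,692 of 42,383 probes in the motivating
study) enters selection.

# Stage 2: incremental feature selection

`run_ifs()` evaluates the ranked list in nested prefixes of 10
(`make_prefix_sizes()`), scoring each prefix by stratified 10-fold
cross-validation and pooling all held-out predictions into one confusion
matrix. Pooling (rather than averaging per-fold metrics) matches how a
single per-class accuracy and a single MCC per prefix are conventionally
reported, and keeps small folds from producing degenerate per-fold MCCs.
Fold assignment balances both per-class counts and total fold sizes to
within one sample, and is deterministic given the seed; classifier fit
seeds are derived from the CV seed, prefix size and fold index.

The multiclass MCC is Gorodkin's $R_K$,

$$R_K = \frac{c\,s-\sum_k p_k t_k}
{\sqrt{\left(s^2-\sum_k p_k^2\right)\left(s^2-\sum_k t_k^2\right)}},$$

defined as 0 when either denominator factor vanishes (e.g. every sample
predicted into one class), and reducing exactly to the binary Matthews
coefficient for two classes.

Classifiers are pluggable adapters (`register_classifier()`), each a
`fit`/`predict` pair that must pass a conformance contract
(`validate_classifier_adapter()`): factor predictions over the training
levels, determinism under a fixed seed. Two adapters ship with the
package:

* **`svm_ovr_linear`** — a linear SVM with the one-vs-rest multiclass
  strategy, C = 1, and per-feature min–max scaling to [0, 1] *fitted on
  the training folds only* (constant features map to 0). No suitable SVM
  library is available in the target environment, so the primal
  L2-regularized squared-hinge objective is minimised directly with BFGS;
  the problem is smooth and strictly convex, so the fit is deterministic
  without any RNG. Prediction takes the maximal decision value, ties going
  to the alphabetically first class.
* **`random_forest`** — 100 bagged entropy trees with per-node feature
  subsampling (`mtry = floor(sqrt(p))`) and majority vote, built on the
  same tree grower as the MCFS stage.

A rule-induction learner (RIPPER-style) is deliberately *not* shipped: it
is a large subsystem orthogonal to the workflow, and the adapter registry
accepts external implementations.

`select_optimum()` takes the prefix with maximal MCC (smallest k on ties);
`select_compact()` takes the smallest prefix within `tol` (default 0.01)
of that maximum — the "nearly as good but far smaller" signature, sized to
cover the motivating study's 0.007 MCC gap between its 750- and 20-probe
sets. `evaluate_holdout()` refits on the full training set and scores an
independent test set once, mirroring how generalization is usually
demonstrated for such signatures.

# Stage 3: enrichment

`probes_to_genes()` maps probes to the union of their annotated gene
symbols; intergenic probes (and probes missing from the annotation)
contribute nothing and are counted. `enrich()` tests each term with the
hypergeometric upper tail $P(X \ge k)$ (via R's `phyper`, the standard
route) and adjusts with Benjamini–Hochberg. Conventions:

* **Universe** — genes mapped from *all* probes of the analyzed matrix by
  default (`universe = "platform"`), the conservative conventional choice;
  `"positive-ri"` restricts it to ranked probes. The source procedure does
  not state its universe, so both are provided.
* Term gene sets are intersected with the universe before counting; terms
  with fewer than `min_term_size = 2` universe genes are excluded —
  singleton terms are mostly annotation noise.
* The multiple-testing family is all terms tested in one call, so GO and
  KEGG collections supplied in one GMT are adjusted jointly, separately if
  run separately.
* Only over-representation (upper tail) is tested; the adjustment is BH —
  the usual reading of "adjusted to obtain their FDR".

# The synthetic world

`generate_dataset()` exists so that every stage has a ground truth.
It draws beta values from Beta distributions parameterized by mean and
concentration $s$ — shapes $(\mu s, (1-\mu)s)$ — which respects the
bounded, skewed distribution of methylation fractions; $s = 30$ gives a
within-class spread of about 0.08 sd at $\mu = 0.5$, a realistic
array-scale noise level. Noise probes share one mean
$\mu \sim U(0.2, 0.8)$ across classes; each planted probe gets
class-specific means $\mu$, $\mu+\delta$, $\mu-\delta$ (clipped to
(0.05, 0.95)), with the class order randomized per probe so no class is
uniformly hyper-methylated. Defaults mirror the motivating study's stated
world: classes 78/46/80, 42,383 probes, a 20-probe signature; the
recovery experiments in the test suite use the smaller stated
configuration (30/20/30 samples, 500 probes, $\delta = 0.25$, $s = 30$)
to fit desk-scale budgets.

Each planted probe maps to a distinct planted gene; noise probes are
intergenic with probability 0.25 (around the 450K's intergenic fraction)
or map to one or occasionally two filler genes, exercising the empty- and
multi-annotation code paths. The term map contains the planted term (the
planted genes exactly, by default, so enrichment recovery has a known
optimum) plus ≥ 20 random filler terms.

What the generator does **not** emulate — so a green recovery test does
not establish robustness to it: spatial correlation along the genome,
probe-type chemistry differences, batch effects, bimodal
(methylated/unmethylated) marginal mixtures, or label noise. It is a
clean-signal world for verifying the machinery, not a simulator of array
artefacts.

# Numerical and degenerate-input choices

* Beta values are validated to [0, 1] at load; missing values are rejected
  by default, and `drop_incomplete_probes` removes affected probes rather
  than imputing — imputation would silently move RI scores. Input values
  are treated as final (no re-normalization or M-value transform).
* All writers emit 6-decimal fixed-point reals, and every ordering
  (ranking ties by ascending probe id, enrichment rows by FDR/p/term id)
  is deterministic, so artifacts are byte-stable across runs of the same
  seed; the pipeline derives fixed per-stage seeds from one master seed.
* Splits need a strictly positive information gain (tolerance 1e-12);
  otherwise the node becomes a leaf.
* $R_K$ and wAcc edge cases: degenerate margins give MCC = 0 by
  definition; classes absent from an evaluation set are excluded from
  wAcc and reported as `NA` per-class accuracy.
* `hypergeom_upper_tail(k = 0, ...)` is exactly 1.

# Known limitations

* **Selection bias in the IFS curve.** The ranking is computed on the same
  samples the cross-validation then scores, so IFS metrics are optimistic
  — this is inherent to the workflow as published, and is why
  `evaluate_holdout()` exists. The effect is plainly visible under a
  label-permutation null: re-ranking on permuted labels and
  cross-validating on the same samples still yields max MCC around 0.4 at
  the 80-sample scale, while a *fixed* ranking scored against permuted
  labels collapses to ~0 as it should. The package's null checks therefore
  permute at the stage being tested: re-ranking for ranking recovery,
  fixed ranking for classifier evaluation.
* MCFS defaults (`t = 100`, `m = 5`) are a desk-scale budget; production
  runs on tens of thousands of probes should raise `t` substantially.
* The linear SVM is the primal squared-hinge variant, not an SMO dual
  solver with logistic calibration; decision values, not probabilities,
  drive prediction.
* Cross-validation is a single stratified split per seed, not repeated;
  hyperparameters are fixed (no nested tuning), matching the
  default-parameter usage the workflow prescribes.
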
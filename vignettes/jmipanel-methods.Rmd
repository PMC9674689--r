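---
title: "Methods: moderated DEG filtering and joint-mutual-information panel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated DEG filtering and joint-mutual-information panel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jmipanel)
```

## The problem and the model

Bulk transcriptomic case–control cohorts routinely yield thousands of
differentially expressed genes (DEGs), far more than a usable diagnostic
panel, and many of them near-duplicates of one another (co-regulated family
members, transcripts of the same pathway). `jmipanel` implements a
two-stage filter for distilling such a cohort into a small, minimally
redundant gene panel, plus the downstream checks one would run on the
resulting panel.

**Stage 1 — moderated differential expression.** For each gene on the
log2 scale, a two-group linear model reduces to `logFC = mean(tumor) −
mean(normal)` with pooled within-group variance `s²` on `d = n₁ + n₂ − 2`
degrees of freedom. Per-gene variances are unstable when samples are few,
so they are shrunk by empirical Bayes: assuming `s² ~ s₀²·F(d, d₀)`, the
prior `(d₀, s₀²)` is fitted by method of moments on `log s²` (matching its
mean and variance through digamma/trigamma identities, with a Newton
inverse of the trigamma function), and each gene's posterior variance is
`s̃² = (d₀·s₀² + d·s²)/(d₀ + d)`. The moderated t-statistic
`logFC / √(s̃²(1/n₁ + 1/n₂))` has `d + d₀` degrees of freedom; p-values are
Benjamini–Hochberg adjusted and the DEG rule is the conventional
`|logFC| > 1 & adj.P < 0.05`, both inequalities strict. Two documented
limits anchor the implementation: `d₀ = 0` recovers the ordinary pooled t
exactly, and when all log-variances are no more dispersed than chi-square
sampling noise allows, `d₀ = ∞` and every posterior variance collapses to
the common value. No trend or robust variant of the variance prior is
offered; genes with zero variance and zero logFC get `p = 1` rather than
0/0.

**Stage 2 — greedy information-theoretic selection.** Expression is
discretized per gene into `B` equal-frequency bins (default `B = 4`; ranks
split into contiguous blocks, ties broken by original position so the
result is deterministic; a constant gene collapses to one bin rather than
fabricating information from tie order). All information quantities are
plug-in estimates in bits. With `S` the selected set and `C` the class,
each greedy step maximizes one of

* mRMR: `α(fᵢ) = I(fᵢ;C) − (1/|S|) Σ_{f_s∈S} I(fᵢ;f_s)`,
* JMI: `α(fᵢ) = Σ_{f_s∈S} I(fᵢ,f_s;C)`,

where `I(fᵢ,f_s;C)` is the information the *pair* carries about the class —
the quantity that sees synergy (the XOR configuration is worth a full bit
jointly while both marginals are zero) and that assigns a duplicate of an
already-selected gene no more credit than the original earned alone. Both
criteria have an empty sum at step 1, so the first feature is
`argmax I(f;C)` under either — the universal convention in this literature;
the procedure is otherwise indeterminate at step 1. Ties at any step break
by ascending gene id in C-locale order, making selection a pure function of
`(matrix, labels, k, criterion, n_bins)`.

The panel size `k` is a user parameter with no default: published analyses
of this kind report a panel size without stating a stopping rule, and we
decline to invent one silently. Callers wanting automation can inspect the
returned trace (`steps$score`) and stop at a score plateau of their
choosing.

## Downstream evaluation

* **ROC/AUC** by the rank (Mann–Whitney) statistic, ties half-counted.
  Orientation is fixed tumor-positive; a down-regulated marker therefore
  scores below 0.5, and the orientation-free `max(AUC, 1−AUC)` is reported
  alongside, because common ROC tools silently auto-orient and the two
  conventions are easily conflated.
* **Cluster purity** replaces t-SNE/heatmap visual inspection with a
  deterministic number: genes standardized, samples clustered by
  average-linkage on Euclidean distance, tree cut at 2, purity = best
  label-to-cluster agreement (∈ [0.5, 1]).
* **Stage trend**: a gene is flagged when its four stage means (known-stage
  tumor samples only) are monotone non-decreasing or non-increasing across
  I→IV. No formal trend test is attached, since monotone consistency is the
  claim actually being screened for.
* **Survival**: expression is median-split (strictly above the median is
  "high"; median ties go low, so a constant gene yields one group and no
  test), Kaplan–Meier product-limit curves are fitted per group, and a
  standard 1-df log-rank test compares them. The median cut-point is chosen
  for determinism and interpretability; maximally selected rank statistics
  would inflate the apparent separation unless corrected.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws Gaussian log2 expression: per-gene baselines
uniform on [4, 12] log2 units, noise SD 1 by default — the scale on which
log-normalized bulk RNA-seq genes typically live. Planted structure:

* informative genes with tumor means shifted ±`effect_size` (default 2
  log2 units, a clear DEG; signs alternate so the panel mixes up- and
  down-regulated markers, as real signatures do);
* redundant duplicates built as `ρ·z_parent + √(1−ρ²)·ε` on the
  standardized parent and rescaled (default ρ = 0.95), so duplicates carry
  an attenuated class effect and *pass* the DEG filter — exactly the
  redundancy the JMI stage must survive;
* via `attach_stage_and_survival()`: stages I–IV multinomial with
  probabilities 0.138/0.324/0.438/0.100 (a realistic stomach-cancer stage
  mix), an additive `stage_delta·(stage−1)` increment on designated genes
  (population stage means strictly increasing by construction), and
  exponential survival with log-hazard `log_hr` (default `log 2`) per SD of
  the planted survival genes' expression, median 500 days at baseline,
  independent uniform censoring on [0, 2000] days (roughly the ~60%
  censoring of a typical cohort).

It does **not** emulate count-level noise (no negative-binomial layer),
batch effects, correlated null structure beyond the planted duplicates, or
probe-level artifacts. A green test therefore establishes that the
algorithms do what their definitions say on data satisfying their own
assumptions — not that any particular biological cohort will yield any
particular panel.

## Numerical choices

* Information in bits (log base 2); rankings are base-invariant.
* Plug-in estimation, no Miller–Madow or k-NN correction: the criteria
  compare features at equal sample size, where plug-in bias largely
  cancels, and plug-in is exactly testable against a counting oracle.
* `trigamma` inversion by Newton iteration from `0.5 + 1/x`, tolerance
  1e−10 relative.
* BH adjustment as the explicit step-up cumulative minimum, capped at 1.
* Strict inequalities at both DEG thresholds; a gene at `|logFC| = 1` or
  `adj.P = 0.05` exactly does not pass.
* All ties everywhere (binning, selection) resolve by stable or
  lexicographic rules, so every result is bit-reproducible across
  platforms; the pipeline writes no timestamps into result files for the
  same reason.

## Known limitations

* The DEG stage handles a single two-group contrast; no covariates,
  multi-factor designs, or precision weights.
* Discretization at `B = 4` is a package default, not a recovered setting
  of any published analysis (which left its estimator unstated); with very
  few samples per class, fewer bins may be warranted.
* Greedy forward selection is not globally optimal for either criterion;
  the audit trail (`candidate_scores`) verifies per-step optimality only.
* `cluster_purity` with two highly unbalanced classes has a high trivial
  baseline (the majority-class fraction); compare against that baseline,
  not 0.5.
* The log-rank test is asymptotic chi-square(1); at very small group sizes
  its null calibration degrades, as for any log-rank implementation.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(n_genes = 1000, n_tumor = 200, n_normal = 200,
                      n_informative = 5, n_redundant_per = 2,
                      effect_size = 2, redundancy_rho = 0.95,
                      noise_sd = 1, seed = 7)
tab  <- deg_table(co$matrix, co$annotations$class)   # moderated DE
degs <- filter_degs(tab)                             # |logFC|>1 & adj.P<.05
tr   <- greedy_select(co$matrix[degs, ], co$annotations$class,
                      k = 5, criterion = "jmi")
tr$steps
ev <- evaluate_panel(co$matrix, co$annotations, tr$steps$gene)
ev$per_gene[, c("gene", "auc", "auc_oriented")]
ev$purity
```

The same flow is available as one call through `run_pipeline()` /
`pipeline_config()` or the `jmipanel` command-line script (subcommands
`simulate`, `deg`, `select`, `evaluate`, `run`).
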
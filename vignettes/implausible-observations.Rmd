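---
title: "Detecting implausible EHR observations by sparse-cluster flagging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting implausible EHR observations by sparse-cluster flagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iodetect)
```

## The problem

Electronic health records accumulate laboratory results and vital signs at a
scale where manual plausibility review is impossible, yet single implausible
entries — a negative hemoglobin A1c, a troponin of 41 ng/mL created by a unit
error — can distort any secondary analysis. Rule-based screening needs
curated cutoffs for every observation type at every institution, which does
not scale. `iodetect` implements an unsupervised alternative built on two
linked assumptions:

1. absent systematic error, implausible values are *sparse* in large
   observation sets; and
2. if the values are clustered well, implausible values end up in clusters
   with very small populations.

The detector therefore never needs a reference range. Curated ranges (the
*silver standard*) are used only afterwards, to score the detector.

## The procedure

For one observation type with values $x(1), \dots, x(N)$:

1. **Shuffle** the rows (seeded) to destroy incidental ordering.
2. **Partition** into folds of $n$ consecutive points (the last fold keeps
   the remainder). Folds are processed independently, which is also the
   parallelization unit on a cluster or database server.
3. **Transform** each fold: center, scale to unit sample standard deviation,
   and cube. Cubing preserves sign and rank but stretches both tails, so
   tail points separate from the body before clustering.
4. **Approximate the cluster number** $k$ by iterative subsampling: fit
   univariate Gaussian mixtures (equal- and unequal-variance) for
   $k = 1 \dots k_{\max}$ on subsamples of the fold, select each subsample's
   $k$ by BIC, and take the rounded mean.
5. **Cluster** with hybrid hierarchical K-means (HK-means): Ward-linkage
   agglomerative clustering is cut at $k$ groups, the group means initialize
   K-means, and Lloyd iterations
   $$C(i) := \arg\min_k \lVert x(i) - \mu(k)\rVert^2, \qquad
     \mu(k) := \frac{\sum_i I\{C(i)=k\}\, x(i)}{\sum_i I\{C(i)=k\}}$$
   run until the assignments stop changing. Hierarchical initialization
   removes the dependence on random centroid seeds, so the whole pipeline is
   a pure function of the data and one integer seed.
6. **Flag** every point whose cluster population $p_k$ satisfies
   $p_k \le \lfloor \alpha\, n_{\text{fold}} \rfloor$, where $\alpha$ is the
   sparsity ratio. With the default coupling $n_{\text{fold}} = 1/\alpha$
   the threshold is exactly 1: only singleton clusters are implausible.

The canonical $\alpha$ grid is `default_alphas()`: 1/500 (most liberal) to
1/10,000 (most stringent). Smaller $\alpha$ means a larger fold and a harder
condition for flagging, hence higher specificity and lower sensitivity.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1/5000 | population fraction at or below which a cluster is implausible; 1/4000–1/6000 balances true and false positives in large repositories |
| `fold_size` | `round(1/alpha)` | points per fold; independently settable because the flag rule is a fraction |
| `k_max` | 10 | cap for the cluster-number search |
| `transform` | `scale_cube` | set `none` to cluster raw values |
| `subsample_size`, `n_subsamples` | 500, 10 | the subsampling schedule of the cluster-number approximation |
| `hclust_cap` | 2000 | above this fold size, hierarchical initialization runs on a seeded subsample (Ward linkage is quadratic in memory); all points still enter the K-means refinement |
| `seed` | 1 | drives the shuffle; every fold derives its own sub-seed from it |

## Design choices where the design was open

* **"Scale" means z-scoring.** Min–max scaling followed by cubing would
  compress the lower tail asymmetrically; centering first lets the cube
  emphasize both tails symmetrically.
* **Per-fold transformation.** The transform is applied within each fold,
  not globally, keeping folds self-contained (and parallelizable). The cost
  is that a flag can depend weakly on fold composition; the shuffle makes
  folds exchangeable so this averages out.
* **Cluster-number approximation.** The approximation criterion is BIC on
  1-D Gaussian-mixture fits over subsamples — cheap, deterministic given the
  seed, and scale-equivariant (affine maps shift all BIC values equally).
  Any criterion with those properties could be substituted.
* **Flag rule inequality is non-strict** (`p_k <= threshold`), and the
  threshold uses `floor(alpha * fold_length + 1e-9)`: the epsilon absorbs
  IEEE artefacts such as `(1/3000)*3000 < 1`, which would otherwise zero the
  threshold at exactly the canonical settings.
* **Ties and degeneracies.** Nearest-centroid ties go to the lowest cluster
  index; clusters emptied during refinement are dropped (reducing `k`)
  rather than reseeded; a zero-variance fold transforms to all zeros and
  yields a single cluster, so nothing is flagged; folds of one point are
  passed through unflagged with a warning.
* **Short final folds** are still processed when they hold at least two
  points, with the flag threshold computed from their own length.
* **Baselines are global.** The SD and Mahalanobis baselines use the full
  series mean and SD, not per-fold statistics, because that is how those
  rules are conventionally applied; in 1-D they are the same rule with
  different cutoffs (6 SD versus the critical distance 3.717526, the square
  root of 13.82, both kept as stated constants rather than recomputed
  quantiles).
* **Paired detector comparison.** False positives of two detectors on the
  truly plausible rows are compared with an exact two-sided binomial test on
  the discordant rows (null 1/2) — the exact McNemar construction. The
  choice of this particular test is a package decision.
* **Undefined sensitivity** (no truly implausible rows) is reported as `NA`,
  never 0 or 1, so zero-positive observation types drop out of sensitivity
  summaries instead of biasing them.

## What the synthetic generator emulates — and what it does not

`generator_config()` defaults sketch a cardiac-troponin-like analyte:

* a lognormal plausible body, `meanlog = log(0.13)`, `sdlog = 0.5` —
  non-negative, right-skewed, median inside the clinical normal range
  0.04–0.39 ng/mL — rejection-sampled into the plausibility interval
  `[0, 20]`;
* contaminants at rate 0.000576 (0.0576%, a realistic average implausibility
  prevalence) placed in the upper tail at uniform multiples 2–50 times the
  violated bound — separable but not trivially infinite. When a bound is 0,
  a pure multiple degenerates, so magnitudes below a zero lower bound are
  2–50 interval-widths instead;
* an optional systematic unit-error mode multiplying a fraction of rows by
  100 (0.41 reported as 41), which deliberately breaks the sparsity
  assumption.

Truth labels are computed from the silver-standard rule itself, so label and
standard cannot disagree by construction. The generator does **not** emulate
patient-level repeated measures, batch effects, digit-preference rounding,
unit mixtures within the plausible range, or near-boundary implausibles.
Passing the synthetic benchmark therefore shows that the method separates
sparse, well-separated tail contamination — the regime the method assumes —
not that it would detect subtle in-range errors in real data.

Benchmark sizes used throughout the test suite were chosen as ordinary
desk-scale analogues: series of 100,000 points with 10 replicate seeds for
the specificity/sensitivity checks, and 3 replicates across the full
eight-ratio grid for the specificity trend.

## Known limitations

* HK-means is a heuristic. Ward initialization followed by Lloyd iterations
  can converge to a local minimum of the within-cluster sum of squares; on
  small smooth 1-D instances it misses the dynamic-programming optimum in
  roughly 6% of random cases (identically to `stats::kmeans` started from
  the same centroids). On the separated body-plus-outlier geometry the
  detector actually targets, we observe no misses. Consumers needing
  certified-optimal 1-D partitions should use a dynamic-programming solver;
  the point here is fidelity to the screening procedure, whose performance
  the benchmarks measure directly.
* One observation type, one dimension. Multivariate extensions (clustering
  jointly with demographics or comorbidity) are out of scope.
* The detector flags *sparse* clusters; systematic errors (the unit-error
  scenario) produce populous implausible clusters that it will not flag —
  by design it then still produces no false positives, but sensitivity
  collapses. Screening output is meant to augment, not replace, human
  review.
* Units are carried as-is and never normalized; mixed-unit LOINC codes are
  the main known source of systematic error.
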
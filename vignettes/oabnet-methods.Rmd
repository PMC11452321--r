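---
title: "Methods: dynamic network analysis of OABSS trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic network analysis of OABSS trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oabnet)
```

## Scope and model

`oabnet` analyses cohorts scored with the four-item overactive bladder
symptom score (OABSS) at five fixed visits (T0, T6, T12, T18, T24 months).
The analysis has four layers:

1. **Trajectory clustering.** Each patient is the vector of total scores
   across the five visits. Totals are standardized per visit and clustered:
   Ward's minimum-variance linkage on Euclidean distances gives a merge
   tree; the K-means objective
   $J(k) = \sum_{i=1}^{k}\sum_{x \in C_i}\lVert x - \mu_i\rVert^2$
   evaluated over a candidate range gives the elbow; K-means at the elbow k
   gives the final labels.
2. **PCA embedding** of the same matrix (two components) for inspection.
3. **Per-visit similarity networks.** Nodes are patients; an edge joins a
   pair whose Pearson correlation exceeds a threshold, with length
   $(1/r - 1)\times 1000$.
4. **Dynamic statistics.** Per cluster and visit: average degree centrality
   $\frac{1}{|C|}\sum_{v\in C} \frac{\deg(v,t)}{|V|-1}$ and induced-subgraph
   edge density $|E(C)| / \binom{|C|}{2}$. Adjacency/Laplacian matrices and
   eigenvector centrality are provided as supporting graph algebra.

Assumptions inherited from the study design: complete cases only (all five
visits present — the package validates rather than imputes), integer item
scores within the instrument bounds, and a cohort small enough (~100) that
dense correlation matrices and exact linkage are trivial.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `standardize` | `TRUE` | — | cluster/PCA on per-visit z-scores (population SD, divisor n, matching the conventional scaler). The raw-feature variant is kept behind `standardize = FALSE` because both conventions are defensible for bounded scores and the choice visibly moves the embedding. |
| `k_range` | `1:8` | clusters | elbow candidates; must be consecutive so the second difference is defined. |
| `seed` | 42 | — | root seed for k-means++ draws and simulation; every stage of a pipeline run derives from it. |
| `r_min` | 0.7 | correlation | edge inclusion threshold. A threshold is unavoidable (otherwise every graph is complete) but no canonical value exists; 0.7 keeps item-vector graphs clearly non-complete while leaving clusters connected. Trajectory outputs always record the `r_min` and `mode` used. |
| `mode` | `components_at_t` | — | similarity basis, see below. |
| `noise_cor` | preset-dependent | — | shared within-visit noise loading of the generator (see calibration). |

## The similarity-basis decision

A per-visit graph needs a per-visit similarity, yet a correlation "across
all time points" is visit-invariant — the two readings cannot both hold, so
the basis is explicit configuration:

- `components_at_t` (default): correlate the two patients' four item scores
  at that visit. Gives genuinely time-varying networks, which is the point
  of a dynamic analysis. Caveat, stated plainly: a Pearson correlation of
  two 4-vectors of small integers is coarse — values near ±1 are common and
  exact ties at `r == r_min` are excluded (strict inequality) for
  determinism.
- `trajectory_up_to_t`: correlate total-score trajectories over visits
  ≤ t — the literal cumulative reading. At T0 a single total is not a
  vector, so T0 falls back to `components_at_t` with a warning.

Negative and zero correlations never form edges: the length transform
diverges at 0 and is negative below it; such pairs (and pairs involving a
constant vector, where r is undefined) are excluded and counted.

## Elbow formalization

"Where the SSE decrease slows down" is made testable as the interior
candidate maximizing the discrete second difference
$J(k-1) - 2J(k) + J(k+1)$; ties go to the smaller k. The SSE curve is
guaranteed non-increasing because each k is fitted from 10 k-means++
restarts *plus* a warm start built from the previous solution (its
centroids plus the worst-fitted point), whose Lloyd refinement can only
lower J relative to k−1. K-means labels are permutation-arbitrary, so
labels are canonicalized: clusters ordered by descending size, ties by
lowest member index. Cluster/color correspondences in any published figure
are presentation, not inference, and are deliberately not encoded.

## What the synthetic generator emulates

The clinical data are not deposited, so the generator is the package's
study stand-in. A score is
`baseline + separation × cluster_offset + delta(cluster, visit) + noise`,
rounded half-away-from-zero and clipped to the item bounds. The noise for
item c is `sd_c (ρ u + sqrt(1−ρ²) v_c)` with `u` shared within a
patient-visit: ρ models the clinical fact that a bad day is bad across
items, and it is what lets the total-score change SD exceed the
independent-item sum.

Two presets:

- **`table1_calibrated`** (n = 101, planted sizes 34/47/20): per-item mean
  changes equal the published change table at every follow-up; per-item
  noise SD is the published change SD divided by √2 (a change is the
  difference of two equally noisy visits); ρ ≈ 0.70 is solved in closed
  form so the implied total change SD matches the published ≈ 2.03.
  Baselines (1.1, 1.4, 2.9, 2.6) sit mid-range so rounding/clipping bias on
  the calibrated means stays within 0.1 score units (property-tested at
  n = 20000). The published abstract-level figure of −2.82 ± 3.03 at 24
  months contradicts the change table's −0.83 ± 1.94; the table is taken as
  authoritative and the other figure is not targeted. The table's T6 and
  T12 rows are digit-identical — possibly a transcription artifact — and
  the generator reproduces whatever its draws yield rather than forcing
  equality.
- **`study_sizes`** (n = 101, sizes 34/47/20): three qualitative response
  shapes — stable responder, improve-then-regress, and a smaller severe
  cluster improving sharply after T6 — with baseline offsets chosen so the
  three total-score centroids are **near-equidistant** in 5-space. An
  earlier draft placed them on a severity gradient; the planted structure
  was then genuinely two-ended and the elbow (correctly) said k = 2. The
  exact delta values are artifact choices; the shapes and the
  three-foldness are the scenario.

What the generator does *not* emulate: dropout/censoring, covariates (age,
hormones), item-level floor effects beyond clipping, visit-to-visit serial
correlation within patients (noise is independent across visits given the
cluster trajectory), and any real-data deviation from Gaussian-plus-rounding
noise. Passing tests therefore demonstrate that the pipeline recovers
structure *of this kind*; they are not evidence about the undeposited
clinical cohort.

## Numerical choices

- Standardization uses the population SD; constant columns map to zeros
  with a warning instead of erroring, so degenerate synthetic configs still
  flow through.
- PCA eigenvector signs are pinned (largest-|loading| positive) for
  reproducible plots and regression tests.
- Ward linkage uses the `ward.D2` criterion, the correct form for
  unsquared Euclidean distances.
- Eigenvector centrality is computed by power iteration on `A + I`
  (tolerance 1e-10, ≤ 1000 iterations): the unit shift leaves eigenvectors
  unchanged but prevents oscillation on bipartite graphs. It is defined on
  the largest connected component with zeros elsewhere, L2-normalized, and
  checked against `Ax = λx`.
- Severity bands are reported exactly as published — mild < 5, moderate
  6–11, severe ≥ 12 — which leaves a total of 5 unassigned; it is labeled
  `"unclassified"` rather than silently binned.
- Change summaries use the sample SD (n−1), the convention for cohort
  tables; the generator calibration accounts for this.

## Problem sizes

The test and acceptance workloads run at the study's own scale: cohorts of
101 patients, 5 visits, candidate k up to 8, 20-seed recovery sweeps, and
100-instance oracle comparisons on graphs of up to 12 nodes. The full suite
completes in well under a minute.

## Known limitations

- Item-vector correlations on 4 small integers are coarse; `r_min`
  sensitivity should be inspected (the monotonicity property — raising
  `r_min` never adds edges — makes this cheap).
- The elbow's second difference needs at least three candidates and is
  undefined at the range ends; genuinely elbow-free data will still return
  an argmax.
- Eigenvector centrality is reported per graph but intentionally not part
  of the headline trajectory, which uses degree centrality and edge
  density only.
- With `k` fixed and clusters well separated, Ward-cut and K-means labels
  coincide; on weakly structured data they can differ, and both are
  exposed (`ward_labels` vs `labels`) rather than reconciled.
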
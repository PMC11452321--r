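# oabnet

Dynamic network analysis of longitudinal overactive bladder symptom scores.

## The problem

Overactive bladder (OAB) syndrome is a chronic urinary condition whose
treatment response varies strongly between patients and over time. A common
way to follow a treated cohort is the four-item OAB symptom score (OABSS):
Q1 daytime frequency (0–2), Q2 nighttime frequency (0–3), Q3 urgency (0–5),
Q4 urgency incontinence (0–5), total 0–15, measured at baseline (T0) and at
6, 12, 18 and 24 months (T6–T24). Group-mean change tables hide the
heterogeneity: some patients respond durably, some regress, some respond
late.

`oabnet` treats the cohort as a **dynamic network**. Patients are nodes; at
each timepoint an edge joins two patients whose symptom profiles are
strongly correlated, and per-cluster network statistics tracked across the
five snapshots expose how response subgroups form, tighten and dissolve
during follow-up. It is aimed at biostatisticians analysing small
longitudinal questionnaire cohorts.

## The method

1. **Clustering.** Patients are represented by their total-score
   trajectories `x_i ∈ R^5`, standardized per timepoint (population SD).
   Euclidean distances feed Ward's minimum-variance linkage; the number of
   clusters k is chosen by the elbow of the K-means objective
   `J(k) = Σ_k Σ_{x ∈ C_i} ‖x − μ_i‖²`, formalized as the interior k
   maximizing the discrete second difference
   `J(k−1) − 2J(k) + J(k+1)`; K-means (Lloyd, k-means++ seeding, best of 10
   restarts) produces the final labels, relabeled by descending cluster
   size.
2. **Embedding.** Two-component PCA of the same matrix for visualization.
3. **Networks.** At each timepoint t, the Pearson correlation r of two
   patients' item vectors (Q1..Q4 at t) defines an edge when `r > r_min`
   (default 0.7), with edge length `(1/r − 1) × 1000` — 0 for perfectly
   correlated patients, growing without bound as r → 0.
4. **Dynamics.** For each cluster C and snapshot G_t = (V, E_t):
   average degree centrality `(1/|C|) Σ_{v∈C} deg(v,t)/(|V|−1)` (all
   incident edges count) and induced-subgraph edge density
   `|E(C)| / (|C|(|C|−1)/2)`. The adjacency matrix A, Laplacian L = D − A
   and eigenvector centrality (`Ax = λx`, power iteration) are exposed as
   supporting machinery.
5. **Summaries.** Mean ± SD change from baseline per item and total, and
   severity banding (mild < 5, moderate 6–11, severe ≥ 12; a total of
   exactly 5 is reported as "unclassified" because the published bands skip
   it).

Because the clinical source data are not public, the package ships a
calibrated synthetic cohort generator (planted response clusters, bounded
integer scores, change distributions matched to the published cohort's
summary table) so the entire pipeline is testable end to end.

## Worked example

```r
library(oabnet)

cohort <- generate_cohort(preset_config("study_sizes", seed = 42))
scores <- standardize_scores(extract_totals(cohort))
model  <- fit_clusters(scores, k_range = 1:8, seed = 42)
model
#> K-means cluster model: k = 3, J = 63.8281
#>   sizes: cluster 0: 47, cluster 1: 34, cluster 2: 20
```

The elbow lands on k = 3 and K-means recovers the three planted response
groups (47/34/20 patients) exactly. Following the clusters through the
five similarity networks:

```r
graphs  <- build_graphs(cohort, r_min = 0.7, clusters = model$labels)
metrics <- centrality_trajectory(graphs, model)
head(as.data.frame(metrics)[, 1:4], 6)
#>   timepoint cluster avg_degree_centrality edge_density
#> 1        T0       0             0.8870213    0.8760407
#> 2        T0       1             0.8967647    0.8930481
#> 3        T0       2             0.9310000    1.0000000
#> 4        T6       0             0.6280851    0.7696577
#> 5        T6       1             0.2582353    0.1354724
#> 6        T6       2             0.7120000    0.9684211
```

At baseline all clusters are densely interconnected (everyone is
symptomatic in similar ways); by T6 cluster 1's centrality has collapsed
from 0.90 to 0.26 — its members' profiles have decorrelated from the rest
of the cohort as they respond. `plot_trajectory(metrics)` draws the
per-cluster curves; `plot_embedding(pca_2d(scores), model$labels)` shows
the PCA plane.

The calibrated preset reproduces the published change-from-baseline table:

```r
change_summary(generate_cohort(preset_config("table1_calibrated", seed = 42)))
#> Change from baseline (mean ± SD), n = 101
#>     ...
#> T6  total -1.4257 ± 2.3339
#> T24 total -0.7624 ± 2.1267
```

(population targets −1.63 and −0.83; a 101-patient draw has a standard
error of ≈ 0.2 on these means).

A command-line wrapper with `simulate` / `cluster` / `embed` / `network` /
`dynamics` / `summarize` / `run-all` subcommands lives in
`inst/scripts/oabnet-run.R`:

```sh
Rscript inst/scripts/oabnet-run.R run-all --preset study_sizes --seed 42 --outdir run1
```

It writes the cohort, assignments, SSE curve, embedding, five GraphML
networks, the trajectory table, the change summary, figures and a JSON
manifest.

## Layout

- `R/` — generator, preprocessing, clustering, embedding, networks,
  metrics, summaries, pipeline.
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles.
- `vignettes/oabnet-methods.Rmd` — model, assumptions, calibration and
  design notes.
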
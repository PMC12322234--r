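---
title: "Pathway-centric ratio clustering of targeted metabolomics panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-centric ratio clustering of targeted metabolomics panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Targeted LC-MS/MS panels measure absolute concentrations of a few dozen
central-carbon and amino-acid metabolites across a panel of cell lines.
Clustering cell lines directly on those concentrations tends to produce
groups that are hard to interpret: a metabolite's level confounds pathway
flux with downstream blockage, and strong metabolite–metabolite structure
lives at the reaction level rather than at the whole-profile level.

`metaboratio` implements a pathway-centric alternative. Each pathway is
anchored to one *precursor* (denominator) metabolite — glucose for
glycolysis and the pentose phosphate pathway, pyruvate for the TCA cycle,
glutamine, serine, proline and methionine for their amino-acid pathways —
and every other pathway member becomes a *ratio feature*

\[
r_{ij} = \log_{10} x_{i,\mathrm{num}(j)} - \log_{10} x_{i,\mathrm{den}(j)},
\]

the log of the product-to-precursor concentration ratio in cell line $i$.
Ratios of proximal metabolites track reaction equilibria, so clusters of
cell lines in ratio space are clusters of *pathway behaviour*. A second
benefit is purely technical: any per-sample global shift on the log scale
(cell amount, extraction efficiency) cancels exactly in every feature.

## Batch correction with RUV-III

Panels of this size are acquired over several batches, with a few anchor
cell lines re-measured in every batch. On the log10 scale we model the
observed matrix $Y$ (samples × metabolites) as biology plus unwanted
variation $W\alpha$ and remove the latter with RUV-III:

1. residualize on replicate-group means, $Y_0 = (I - M(M^\top M)^{-1}M^\top)Y$,
   where $M$ is the samples × replicate-groups membership matrix — anything
   shared by replicates of a cell line (its biology) is protected;
2. estimate unwanted directions as the top-$k$ left singular vectors $U_k$
   of $Y_0$ and their metabolite loadings $\alpha = U_k^\top Y$;
3. score all samples through the control metabolites,
   $W = Y_c\,\alpha_c^\top(\alpha_c\alpha_c^\top)^{-1}$;
4. subtract: $Y_{\mathrm{corr}} = Y - W\alpha$.

Defaults: $k = 9$ unwanted factors and *all* metabolites as negative
controls — the standard choice for targeted panels without spike-in
controls, where no metabolite is known a priori to be biology-free.
$k$ is exposed as a parameter (`ruv_k`); it must satisfy
$k \le n_{\mathrm{samples}} - n_{\mathrm{groups}}$ and $k \le$ the number of
controls, and $k = 0$ is the identity. The correction quality gate
(`replicate_cohesion()`) re-clusters the corrected samples and warns if any
cross-batch replicate set splits across clusters.

Two ordering decisions are deliberate. Log10 first, then RUV-III: additive
unwanted variation on the log scale is the standard RUV assumption.
Replicates are corrected as individual samples and averaged per cell line
only *afterwards* (`aggregate_replicates()`): correction needs the
replicate structure, clustering operates on cell lines.

## Consensus clustering and choosing k

Cell lines are clustered on the feature-z-scored ratio matrix with K-means
under the `1 - Pearson correlation` distance. Internally this is plain
Lloyd iteration on row-standardized data (each profile centered and scaled
to unit norm), where squared Euclidean distance equals $2(1-r)$ — the
correspondence is exact, centroids are well defined, and they are
re-standardized after every update so they stay on the correlation sphere.
Initialization is k-means++, an emptied cluster is re-seeded at the
worst-fitted point, and iteration stops when assignments stabilize
(cap 300 sweeps).

A single K-means run depends on its initialization, so the procedure is
repeated (default `n_reps = 1000`, seed stream `seed, seed+1, ...`) and the
*co-association matrix* $C_{ij}$ — the fraction of runs in which $i$ and
$j$ share a cluster — is summarized into a consensus partition by
average-linkage hierarchical clustering of $1 - C$, cut at $k$.

The number of clusters is chosen by three standard heuristics, each
computed from best-of-10-restarts fits over `k_range` (default 2–8, with
k = 1 probed as the null):

* **gap statistic** — $\mathrm{Gap}(k) = \overline{\log W_k^{\mathrm{ref}}} -
  \log W_k$ against B = 50 reference datasets drawn uniformly over each
  feature's observed range (the simple uniform variant, not the
  PCA-rotated one — adequate at this scale and much cheaper); chosen k is
  the smallest with $\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$;
* **elbow** — the k whose (k, WSS) point lies farthest from the chord
  joining the curve's endpoints, ties to the smaller k;
* **silhouette** — argmax of the mean width
  $s(i) = (b(i)-a(i))/\max(a(i),b(i))$, singletons scored 0.

`combine_k_choices()` takes the majority; a three-way disagreement defers
to the silhouette (the only one of the three that directly measures
separation of the realized partition). The gap and K-means machinery also
accept `distance = "euclidean"` for data where the correlation geometry is
degenerate — with two features, row standardization collapses every
profile onto two antipodal points, so low-dimensional point clouds (as in
the calibration checks on Gaussian blobs) are clustered in plain Euclidean
space instead.

## Cluster contrasts

`contrast_clusters()` compares two clusters feature by feature with the
unpaired, equal-variance Student's t-test (Welch behind a flag), on the
*unscaled* ratio matrix so the reported means are interpretable log10
ratios. The false discovery rate across the features of one contrast — the
family is one contrast's worth of features, mirroring per-panel correction
practice; the family scope is a choice the user can change by passing a
different feature set — is controlled at `q* = 0.05` by the
Benjamini–Krieger–Yekutieli two-stage step-up: stage 1 is
Benjamini–Hochberg at $q^*/(1+q^*)$, its rejection count estimates the
number of true nulls $\hat m_0 = m - r_1$, and stage 2 re-runs the step-up
with the slope inflated by $m/\hat m_0$. Reported q-values are the stage-2
step-up adjustment scaled by $(1+q^*)$, so `reject <=> q <= q*`; like the
procedure itself they depend on the chosen level. Features constant in
both groups are reported with $t = 0, p = 1$ rather than silently dropped.

## Screen mining

Loss-of-function (DEMETER / Project Score shaped fitness scores) and drug
sensitivity (PRISM / GDSC2 shaped AUCs) tables are mined for targets
differentially lethal between two clusters. After filtering to clustered
cell lines and to targets with a pathway annotation (a static
user-supplied target→pathway file; no live database queries, so results
are version-stable), each target's scores are z-scored across the full
filtered cell-line set and the differential score is the mean z in cluster
A minus cluster B. Under the lower-is-more-sensitive convention the most
A-vulnerable targets rank first; ties break lexicographically so lists are
deterministic. Pathways are then consolidated across databases: per
database, the count of a pathway's targets inside the top-20 list divided
by 20, summed over databases. This consolidation score is this package's
own definition (the operation is commonly described but rarely specified);
it is deliberately simple and is pluggable via the `n` and top-list inputs.

## The synthetic study generator

`generate_panel()` draws a full study with known truth so every stage is
testable without any download. Log10 abundance of metabolite $j$ in sample
$i$ of cell line $c$:

\[
x_{ij} = \mu_{0j} + \textstyle\sum_{p:\, j \in \mathrm{members}(p)}
\delta_{\mathrm{cluster}(c), p} + b_{\mathrm{batch}(i), j} + s_i +
\varepsilon_{ij},
\]

with defaults chosen to mirror a realistic mid-sized targeted study:
5 clusters × 12 cell lines, 50-metabolite panel (the seven example
pathways plus nine free amino acids), triplicates, 6 batches with 3 anchor
cell lines present in every batch, baseline $\mu_{0j} \sim N(1.0, 0.4^2)$
(log10 pmol-scale), batch effects $b \sim N(0, 0.3^2)$ per (batch,
metabolite), per-sample global scaling $s_i \sim N(0, 0.3^2)$ applied to
all metabolites, technical noise $\sigma_e = 0.08$, and cluster shifts of
magnitude $\delta = 0.5$ log10 units. Effects are additive on the log
scale (multiplicative on concentrations). Crucially, $\delta$ is applied
to pathway *members only*, never to precursors, so planted "pathway
activity" is by construction a product-to-precursor ratio shift; a
metabolite listed in several pathways receives the sum of their shifts.
The default $\delta$ pattern gives each cluster one raised and one lowered
pathway, with clusters 3 and 4 taking opposite signs on the TCA cycle —
the pair the worked examples contrast. Each cluster's screen vulnerability
is its raised pathway. All draws run off one integer seed through unit
normals scaled by the requested sd, so changing one sd leaves every other
draw identical — which is what makes the ratio-cancellation invariance
testable seed-for-seed.

What the generator does **not** emulate: per-cell-line biological
individuality within a cluster (profiles differ only through noise and
nuisance), LC-MS peak integration artifacts, missingness and
limit-of-detection censoring beyond the half-minimum hook, correlated
metabolite noise, media composition effects, and isotope tracing. Passing
tests therefore demonstrate that the machinery recovers structure *of the
planted kind*; they do not certify behaviour on real panels where cluster
signal competes with within-cluster biology.

One consequence deserves emphasis. Because the planted signal sits on
member-metabolite abundances and RUV-III removes the batch nuisance while
the correlation distance ignores per-sample shifts, clustering the
*corrected abundances* recovers the planted clusters just as well as the
ratio route in this synthetic world. The ratio transform's advantages here
are exact invariance to per-sample scaling and direct pathway
interpretability of features and contrasts — not raw recovery power. On
real panels, where abundance-space structure is dominated by biology that
does not organize along pathways, the two routes genuinely diverge; that
divergence is outside what this generator can show.

## Numerical choices and determinism

* Non-positive or missing raw concentrations are a hard error by default;
  `impute_lod = TRUE` applies the per-metabolite half-minimum rule before
  the log — standard LOD practice, but opt-in because silent imputation
  can hide acquisition problems.
* Zero-variance ratio features are dropped (with a warning) before
  z-scoring; zero-variance samples are an error in the correlation
  distance, since their profile correlation is undefined.
* Pearson correlations with an undefined value (zero variance) are
  reported as `NA`, never as 0, so downstream counts of negative/positive
  correlations are not diluted.
* Every stochastic entry point takes a seed and derives per-repetition
  seeds (`seed + r`, kept inside 32-bit range); RNG state is restored on
  exit, so library calls never perturb a caller's stream. Identical
  configurations and seeds give byte-identical output files; the pipeline
  manifest records the seed and a hash of the analysis-defining
  configuration (the output directory is excluded from the hash).
* Ties: elbow ties go to the smaller k; top-target ties break by target id;
  consolidation-score ties break alphabetically; a three-way k-selection
  disagreement defers to the silhouette.

The package's own test suite exercises the full study conditions at desk
scale: 20 generator seeds with 200 consensus repetitions and 50 gap
references for cluster recovery, 1000 simulated families for FDR
calibration, and 20 seeds for screen mining — sizes chosen so the whole
suite runs in a few minutes on one CPU while keeping Monte-Carlo error
well below the asserted margins.

## A complete run

```{r}
library(metaboratio)

cfg <- synthetic_config(seed = 1)
study <- write_synthetic_study(cfg, "study")

res <- run_pipeline(pipeline_config(
  abundance = study$abundance, metadata = study$metadata,
  pathways = study$pathways, out_dir = "out",
  screens = study$screens, kegg_map = study$kegg_map,
  ruv_k = 9, k = "auto", n_reps = 1000, contrast = c(4, 3), seed = 1))

res$clusters                        # consensus partition + diagnostics
autoplot(res$clusters$diagnostics)  # WSS / gap / silhouette curves
autoplot(res$clusters)              # co-association heatmap
plot_ratio_heatmap(res$ratios_scaled, res$clusters)
dplyr::filter(tidy(res$contrast), reject)
res$screens$pathway_scores
```
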
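---
title: "Weighted physical-distance efficiency of structural brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted physical-distance efficiency of structural brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neteff)
```

## The model

neteff analyzes structural brain networks built from diffusion
tractography. A subject's network is a pair of symmetric matrices over a
cortical parcellation (78 regions by default): a strength matrix $W$, where
$w_{ij}$ is the tract count between regions $i$ and $j$ divided by the mean
of their surface sizes, and a length matrix $L$ of mean fiber lengths in
mm. A zero strength means the connection is absent; self-connections are
discarded.

Communication efficiency between two nodes is taken to be inversely
proportional to the shortest *physical* path length between them — the
smallest sum of fiber lengths over all connecting paths, not the hop count
and not the Euclidean distance. Because connection strength plausibly
tracks conduction capacity, the primary analysis uses the weighted
distance, in which each edge contributes $l_e / w_e$: strong connections
shorten the effective path. Strengths are first rescaled by the subject's
maximum so that $w \in [0, 1]$, which bounds the weighted local terms and
removes the arbitrary scale of tract counts.

From the all-pairs distance matrix $d^w$ the package computes, per node:

* **nodal global efficiency**
  $E^{glob}_i = \frac{1}{N-1}\sum_{j \ne i} 1 / d^w_{ij}$, with
  $1/\infty := 0$ for unreachable partners;
* **nodal local efficiency**
  $E^{loc}_i = \frac{1}{N_{G_i}(N_{G_i}-1)}
  \sum_{j \ne k \in G_i}\left((d^w_{jk})^{-1} w_{ij} w_{ik}\right)^{1/3}$,
  where $G_i$ is the subgraph of $i$'s neighbors ($w_{ij} > 0$; no
  threshold) and paths are restricted to edges among those neighbors. A
  node with fewer than two neighbors scores zero.

Whole-network summaries (`network_efficiency()`) are the mean over ordered
pairs of $1/d_{ij}$ and the mean over nodes of each neighborhood subgraph's
efficiency.

### Normalization by the ideal network

Raw efficiencies are normalized against the ideal fully connected network:
the complete graph on the same nodes with every weight at the
post-rescaling maximum of 1 and every length at the subject's minimum
observed edge length $l_{\min}$; for local efficiency the same construction
is applied to each neighborhood subgraph. Every edge length $l_e/w_e$ is at
least $l_{\min}$, so raw values never exceed the ideal and normalized
efficiencies lie in $[0, 1]$; in the unweighted case the construction
reduces to the classical fully connected reference. The exact weighted
ideal is a design choice — the reference literature names the fully
connected network without defining its weighted edges — and this
construction was chosen because it guarantees the unit interval.

Two further conventions: unreachable pairs contribute zero rather than
raising an error (so sparse subjects remain analyzable), and local-path
restriction to the neighborhood subgraph follows the subgraph-efficiency
reading of the local measure. Both are switchable in principle but are the
defaults throughout. All equality tests in the package use an absolute
tolerance of 1e-9, appropriate for double-precision path sums over at most
78 nodes.

### Distances

Shortest paths are computed exactly by Floyd–Warshall (non-negative edge
lengths; absent edges are $+\infty$), with a compiled core because nodal
local efficiency needs a separate all-pairs solve inside every node's
neighborhood subgraph — roughly $N$ solves per subject — and cohort-level
Monte-Carlo work multiplies that by thousands. The test suite cross-checks
the distances against an independent Dijkstra implementation and, on small
graphs, against exhaustive enumeration of all simple paths.

## Regional statistics

For each region and each efficiency measure, ordinary least squares models
relate normalized efficiency to the covariates of the study design:

* `icv`: efficiency ~ ICV + age + TBV, testing the ICV slope. ICV
  (intra-cranial volume) indexes maximum brain size attained during
  development; TBV (current total brain volume) is controlled so the ICV
  coefficient isolates the developmental-peak component.
* `group`: efficiency ~ group + age, testing the group difference. Group
  is coded control = 0, ASD = 1, so a negative t means lower efficiency in
  ASD.
* `icv_x_group`: efficiency ~ ICV * group + age + TBV, testing the
  interaction; all main effects and covariates are retained for
  hierarchical well-formedness.

Two-sided p-values use the t distribution with residual degrees of
freedom. Benjamini–Hochberg FDR correction is applied across the 78
regions separately per contrast and per measure (matching one brain map at
a time), at q = 0.05. Pattern agreement between two regional t-maps is
measured by cosine similarity.

## The synthetic cohort generator

No imaging data ship with the package; `generate_cohort()` stands in for a
44-subject study (22 ASD, 22 control adult males). It emulates the region
level of a tractography study, not the imaging upstream:

* **Geometry.** 39 centroids per hemisphere on an ellipsoidal shell with
  brain-like semi-axes (60, 82, 65 mm), placed greedily with a minimum
  mutual separation of 14 mm (parcellations tile the surface), mirrored
  across the midsagittal plane. Region sizes are log-normal around 250.
* **Lengths.** Fiber length is `tortuosity (1.3) x Euclidean distance`,
  scaled by `(ICV / ICV_mean)^(1/3)` — a linear dimension scales as the
  cube root of volume, so pure size scaling is isometric and cancels in
  the normalized efficiencies. Inter-hemispheric routes add a fixed 60 mm
  callosal detour.
* **Weights.** Expected log tract count decays with the ICV-normalized
  fiber length at scale 30 mm. Homotopic (mirror-image) pairs instead get
  a strong bundle count (400), emulating the callosal connections that
  carry inter-hemispheric shortest paths; the bundle strength is kept
  below the strongest short-range edges so the weight-rescaling anchor is
  never an effect-modulated edge. Edge existence is decided from the
  effect-free expected counts (below one streamline = anatomically
  absent), so adjacency never varies with ICV or group.
* **Effects.** Long-range edges — above the 75th percentile of Euclidean
  distance, plus the whole inter-hemispheric cut — have their log-weights
  reduced by `icv_longrange_slope x (ICV - ICV_mean)` and, in ASD, by
  `log(1 - group_weight_deficit)`. Both penalties are graded by fiber
  length (longer connections carry proportionally greater conduction-delay
  cost), and the favorable small-brain side saturates at a doubling. The
  inter-hemispheric cut is included because a percentile threshold alone
  can be routed around through short medial crossings, leaving global
  efficiency untouched by construction.
* **Noise.** Weight noise is log-normal and length noise Gaussian, both
  scaled by a Poisson-type `1/sqrt(expected count)` factor around a
  reference count of 100: quantities estimated from many streamlines
  (strong, short connections — which also set the rescaling maximum and
  the ideal length scale) are measured precisely, sparse long-range ones
  noisily.
* **Covariates.** ICV is Normal(1.5e6, 1.2e5) mm^3 (ASD shifted +4e4, a
  modest adult remnant of early overgrowth), age Uniform(20, 50) years,
  TBV = 0.75 ICV + Normal(0, 4.5e4) (ICV–TBV correlation near 0.9, as in
  adults). Every draw flows from the master seed through a fixed
  per-subject substream, so single subjects reproduce independently of
  cohort size.

Effect-size defaults (`icv_longrange_slope = -5e-6` per mm^3, about 0.6
log-units of long-range weight per ICV standard deviation, and
`group_weight_deficit = 0.3`) are illustrative of a clearly detectable
effect at n = 44; quantitative effect sizes of this kind are not known, so
the defaults are not calibrated to any real dataset. `null_config()`
switches every effect off, which makes ICV and group exactly inert for
normalized efficiency and gives the null cohorts used for false-positive
calibration.

### What the generator does and does not emulate

It reproduces the tabular shape, the distance-dependence, the
interhemispheric bundle structure, and known-direction ICV/group effects
with realistic covariate correlations. It does not emulate streamline-level
tractography biases, hub/module topology beyond the homotopic bundles,
age effects, or any vertex-level structure. Passing recovery tests
therefore shows that the pipeline detects effects of this kind at this
design size — not that any particular real dataset contains them.

### Known limitations

* Because the group deficit acts multiplicatively on weights while the
  models are linear in efficiency units, strong planted effects can induce
  a genuine (small) ICV-by-group interaction in some cohorts even though
  the generator applies identical ICV slopes to both groups; the
  interaction null is exact only when effects are off.
* The weighted local-efficiency denominator follows the printed form
  $N_{G_i}(N_{G_i}-1)$; the measure is consequently not monotone under
  adding weak neighbors.
* Normalized efficiency depends on two per-subject anchor statistics (the
  maximum strength and the minimum edge length); with heavy edgewise
  noise these anchors dominate between-subject variance, which is why the
  generator's noise model is precision-weighted.

## Problem sizes used in the tests

The suite validates distances and both efficiency measures against
exhaustive simple-path enumeration on 500 random graphs of up to 8 nodes,
checks monotonicity on 200 perturbed graph pairs, runs the full pipeline
on 50 seeded 44-subject cohorts for direction/similarity recovery, and
calibrates FDR on 200 null cohorts; these sizes give stable Monte-Carlo
estimates while keeping the default test run comfortably interactive.

## A worked run

```{r, eval = FALSE}
out_dir <- tempfile("neteff-run-")
manifest <- run_pipeline(config = generator_config(seed = 1),
                         output_dir = out_dir)
summarize_run(manifest)
```

The run writes six per-region CSV maps (two measures x three contrasts), a
cosine-similarity report, and a JSON manifest with file hashes; identical
config and seed give byte-identical outputs.
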
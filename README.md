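# neteff

Weighted physical-distance efficiency analysis of structural brain
networks, for researchers relating region-level diffusion-tractography
connectomes to subject covariates such as intra-cranial volume (ICV) and
diagnostic group.

## What it computes

A subject's connectome is a pair of symmetric matrices over a cortical
parcellation (78 regions by default): connection strengths
`w_ij = tract count / mean(region sizes)` and mean fiber lengths `l_ij`
(mm). Distances between regions are shortest *travel* distances — the
smallest sum of edge contributions over all paths — using the weighted
edge length `l_e / w_e`, so strong connections shorten effective paths
(strengths are rescaled to a unit maximum per subject first). From the
all-pairs distances `d^w` the package computes, per region *i*:

- nodal global efficiency
  `E_i = (1/(N-1)) * sum_{j != i} 1 / d^w_ij`, with `1/Inf := 0`;
- nodal local efficiency
  `E_i = (1/(N_Gi (N_Gi - 1))) * sum_{j != k in G_i} ((d^w_jk)^-1 w_ij w_ik)^(1/3)`,
  over the subgraph `G_i` of *i*'s neighbors, paths restricted to that
  subgraph.

Both are normalized against the ideal fully connected network (every pair
directly connected at maximal weight and the subject's minimum edge
length), so values lie in [0, 1]. Per-region ordinary least squares then
tests three contrasts per measure — ICV (controlling age and total brain
volume), group (controlling age; ASD coded so negative t = lower
efficiency in ASD), and the ICV-by-group interaction — with
Benjamini–Hochberg FDR across regions, and regional t-maps are compared by
cosine similarity. A seeded synthetic cohort generator
(`generate_cohort()`) stands in for imaging data, planting known
distance-dependent wiring, callosal bundle structure, and ICV/group
effects on long-range connectivity.

## Worked example

```r
library(neteff)
manifest <- run_pipeline(config = generator_config(seed = 1),
                         output_dir = "neteff_run")
summarize_run(manifest)
#> neteff run (synthetic mode, seed 1, q <= 0.05)
#>   nodal_local_icv              significant: 55/78 negative, 0/78 positive
#>   nodal_local_group            significant: 0/78 negative, 0/78 positive
#>   nodal_local_icv_x_group      significant: 0/78 negative, 0/78 positive
#>   nodal_global_icv             significant: 11/78 negative, 0/78 positive
#>   nodal_global_group           significant: 0/78 negative, 0/78 positive
#>   nodal_global_icv_x_group     significant: 0/78 negative, 0/78 positive
#>   cosine(t_icv, t_group) [nodal_local] = 0.9221
#>   cosine(t_icv, t_group) [nodal_global] = 0.9585
```

Reading this: larger ICV predicts significantly lower nodal local
efficiency in 55 of 78 regions (and lower global efficiency in 11), no
region shows a significant increase, the ICV-by-group interaction is null
everywhere, and the ICV and group t-maps share their spatial pattern
(cosine ≈ 0.92–0.96). The run directory holds the six per-region CSV maps
(`region_id,name,beta,t,p,q,significant`), `similarity.csv`, and a
`manifest.json` with file hashes; identical config and seed reproduce the
files byte for byte.

Individual stages are exposed as data-frame-first functions that chain
with the pipe: `read_connectome_pair()` / `build_connectome()`,
`compute_efficiency()`, `fit_region_models()` (with `tidy()`, `glance()`,
`autoplot()` methods), `fdr_adjust()`, `cosine_similarity()`,
`calibrate_fdr()`. A thin command-line wrapper lives at
`inst/cli/neteff.R` (subcommands `generate`, `compute`, `fit`, `run`,
`calibrate`).

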
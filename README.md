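# wmnet — white-matter structural connectome analysis

`wmnet` is an R package for graph-theoretic analysis of diffusion-tensor
white-matter networks, the kind of analysis used to compare structural brain
connectivity between a patient group and healthy controls. It covers the
whole chain:

1. **Tractography** — deterministic FACT fiber tracking on tensor volumes,
   terminating when fractional anisotropy drops below 0.2 or the turning
   angle exceeds 45°;
2. **Network construction** — mapping streamline endpoints onto a 90-region
   (AAL) parcellation and weighting each edge by the mean FA of its
   connecting streamlines, yielding a weighted, undirected, symmetric
   90 × 90 matrix per subject;
3. **Graph metrics** — repeated thresholding over a sparsity grid
   S ∈ [0.10, 0.34] (step 0.01), computing clustering coefficient (Cp),
   characteristic path length (Lp), global/local efficiency, nodal degree,
   nodal efficiency and betweenness at every threshold, normalizing Cp and
   Lp against 100 degree-preserving random networks
   (γ = Cp/C<sub>random</sub>, λ = Lp/L<sub>random</sub>,
   σ = γ/λ), and summarizing every curve by its area under the curve (AUC);
4. **Group inference** — covariate-adjusted (age, gender, SAS, SDS)
   permutation tests on the AUCs (Freedman–Lane residualization, 10,000
   permutations, two-tailed), Benjamini–Hochberg FDR across nodes,
   identification of *overlap nodes* (significant in betweenness AND degree
   AND efficiency with a consistent direction), partial correlation of
   overlap-node betweenness with clinical variables, and a demographics
   table (t-tests / chi-squared);
5. **Synthetic data** — tensor phantoms with labeled end-caps for testing
   the tractography, and two-group connectome cohorts (default 70 + 45
   subjects) with a spatially structured small-world backbone, planted
   nodal effects, and clinical covariate tables, so the full pipeline runs
   and is testable with no imaging download.

A network is *small-world* when σ = γ/λ > 1 with γ > 1 and λ ≈ 1; the
default synthetic cohort exhibits this across the whole sparsity grid, as
real white-matter networks do.

## Worked example

Simulate a two-group cohort with five planted nodes (three increased, two
decreased in group A), run the nodal analysis, and recover them:

```r
library(wmnet)

spec <- cohort_spec(n_group_a = 20, n_group_b = 15,
                    effect_nodes_up = c(3, 7, 20), effect_nodes_down = c(50, 81),
                    effect_size = 1.5, seed = 42)
cohort <- gen_cohort(spec)
cohort$matrices[[1]]
#> connectivity_matrix: 90 nodes, 2002 edges (density 0.500), weights [0.353, 1.000]

# small-world parameters of one subject at sparsity 0.10
a  <- threshold_by_sparsity(cohort$matrices[[1]], 0.10)
sw <- small_world(a, n_rand = 100, seed = 1)
str(sw[c("Cp", "Lp", "gamma", "lambda", "sigma")])
#> List of 5
#>  $ Cp    : num 0.54
#>  $ Lp    : num 3.07
#>  $ gamma : num 4.1
#>  $ lambda: num 1.33
#>  $ sigma : num 3.07

# nodal AUCs over the sparsity grid, then covariate-adjusted permutation tests
aucs <- cohort_aucs(cohort$matrices, n_rand = 0, nodal_only = TRUE, seed = 5)
inf  <- analyze_cohort(aucs, cohort$cohort, n_perm = 1000, seed = 9)
inf
#> wm_inference: 2 global metrics, 270 nodal tests, 1000 permutations
#> overlap nodes (significant in all three nodal metrics): SFGdor.L[A>B],
#>   MFG.L[A>B], SMA.R[A>B], SOG.R[A<B], STG.L[A<B]
```

The five reported overlap nodes are exactly the planted ones — indices 3
(SFGdor.L), 7 (MFG.L) and 20 (SMA.R) increased, 50 (SOG.R) and 81 (STG.L)
decreased — each significant in all three nodal metrics after FDR
correction, with the correct direction. `sigma = 3.07 > 1` with
`gamma = 4.1 > 1` and `lambda = 1.33` shows the small-world topology of the
synthetic networks. The demographics table prints group means ± SD with the
appropriate test per variable:

```r
head(inf$demographics)
#>   variable  test       group_a      group_b  statistic            p
#> 1      age     t  21.95 ± 2.00 21.71 ± 1.56 0.39831705 6.929620e-01
#> 2   gender chisq          2/18         2/13 0.09408602 7.590455e-01
#> 3      SAS     t  40.60 ± 8.52 33.77 ± 7.43 2.47402081 1.867591e-02
#> 4      SDS     t  51.01 ± 6.10 36.30 ± 7.75 6.29109847 4.106314e-07
#> 5 duration  none 71.92 ± 36.94            /         NA           NA
#> 6      CCS  none  13.08 ± 2.03            /         NA           NA
```

A whole run — simulate, per-subject metric curves with null normalization,
group analysis, TSV/JSON outputs with a reproducibility manifest — is one
call:

```r
cfg <- run_config(cohort = list(n_group_a = 10, n_group_b = 10),
                  n_rand = 100, n_perm = 10000, seed = 7, out_dir = "run1")
res <- full_run(cfg)
```

Tractography works the same way from tensor volumes (NIfTI in/out via
`read_phantom_nifti()` / `write_phantom_nifti()`):

```r
ph <- gen_tensor_phantom(phantom_spec(
  grid_shape = c(25, 15, 9),
  bundles = list(list(path = cbind(seq(3, 22), 8, 5), radius = 2, fa_target = 0.8))))
tracks <- fact_track(ph$tensors)
build_connectome(tracks, ph$labels)
#> connectivity_matrix: 2 nodes, 1 edges (density 1.000), weights [0.800, 0.800]
```

## Package layout

| path | contents |
|---|---|
| `R/synthetic-data.R` | phantom and cohort generators, covariate models |
| `R/tractography.R` | FA, principal directions, FACT tracking |
| `R/connectome.R` | endpoint mapping, FA-weighted matrices, TSV I/O |
| `R/graph-metrics.R` | thresholding, metrics, null models, AUCs |
| `R/group-inference.R` | permutation tests, FDR, overlap nodes, correlations |
| `R/pipeline.R` | cohort-level orchestration, YAML configs, `full_run()` |
| `vignettes/wmnet-methods.Rmd` | the models, parameters and design choices |
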
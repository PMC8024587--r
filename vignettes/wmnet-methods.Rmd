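---
title: "White-matter connectome analysis with wmnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White-matter connectome analysis with wmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wmnet` implements a complete graph-theoretic analysis chain for diffusion-tensor
white-matter networks: deterministic fiber tracking on tensor volumes,
construction of FA-weighted 90-region connectivity matrices, sparsity-thresholded
global and nodal network metrics normalized against degree-preserving random
networks, AUC summarization over a sparsity grid, and covariate-adjusted
permutation inference between two groups. This vignette explains the models
behind each stage, the tunable parameters and their defaults, the behavior of
the synthetic-data generator, and the numerical decisions taken where the
methodology left genuine freedom.

## 1. Tractography model

The tracking stage implements Fiber Assignment by Continuous Tracking (FACT)
on a voxel grid of diffusion tensors. Each voxel's tensor is decomposed into
eigenvalues; fractional anisotropy is

$$\mathrm{FA} = \sqrt{\tfrac{3}{2}}\,
  \frac{\sqrt{\sum_i (\lambda_i - \bar\lambda)^2}}{\sqrt{\sum_i \lambda_i^2}},$$

with eigenvalues clamped at zero first and FA defined as 0 for an all-zero
tensor. Propagation is voxel-to-voxel: from the current position the ray
advances along the current voxel's principal eigenvector to the exit face,
enters the neighbor, and adopts that neighbor's principal direction after
sign alignment with the incoming direction. Propagation terminates when

* the next voxel's FA falls below `fa_min` (default **0.2**),
* the angle between successive principal directions exceeds
  `angle_max_deg` (default **45°**),
* the leading eigenvalue is degenerate (top two eigenvalues tied within
  `1e-9`), or
* the ray leaves the volume.

Both termination thresholds are the standard deterministic-tractography
values for adult white matter: FA below about 0.2 is gray matter or CSF, and
turns sharper than 45° between adjacent voxels are more likely noise or
crossing fibers than a true fascicle. Two half-tracks are grown from every
seed in opposite directions and concatenated.

Decisions the method itself does not fix, exposed as arguments:

* **Seeding** — one seed at the center of every voxel with FA ≥ `fa_min`
  (whole-volume seeding); a custom seed matrix can be supplied.
* **Angle definition** — measured between principal directions of
  consecutive voxels, not between chord segments, matching the original
  FACT formulation.
* **Minimum length** — streamlines visiting fewer than `min_points = 3`
  voxels are discarded.
* **Exit-face geometry** — ray–box intersection in world coordinates; a ray
  hitting a voxel edge or corner is advanced across the axis with the
  largest direction component, and the few zero-length steps needed to pass
  exactly through a corner are permitted (a ray stuck for more than three
  such steps is terminated). This makes tracking fully deterministic.

Voxel indices are 1-based throughout (the R convention); world coordinates
come from the affine applied to voxel centers.

## 2. Network construction

Nodes are the 90 cortical and subcortical regions of the AAL atlas (the
region table ships as plain text; no atlas volume is redistributed). A
streamline connects regions $i \ne j$ when its two *terminal* voxels are
labeled $i$ and $j$; pass-through contact does not create edges, and
streamlines ending in unlabeled tissue or with both ends in one region are
dropped. The edge weight is the mean, over connecting streamlines, of each
streamline's mean FA sampled at its visited voxels — the simplest reading of
"mean FA of the connected streamlines". The result is a weighted, undirected,
symmetric 90 × 90 matrix per subject with zero diagonal.

`min_count` (default 1) optionally suppresses edges supported by fewer
streamlines; the default applies no count filter.

## 3. Graph metrics over the sparsity grid

Because streamline counts and FA distributions differ across subjects, raw
matrices are equated by **connection sparsity**: at sparsity $S$, exactly
$\mathrm{round}(S \cdot N(N-1)/2)$ strongest-weight edges are kept. Ties at
the cut are broken by descending weight then ascending $(i,j)$ order, so
thresholding is deterministic. The analysis grid is $S \in [0.10, 0.34]$ in
steps of 0.01 (25 points): dense enough that the weakest networks remain
connected and sparse enough that graphs do not approach completeness.

The default analysis mode is **binary** (thresholded entries set to 1),
following the conventional conversion of the connectivity matrix into an
undirected binary network. Because nodal degree is sometimes defined as the
sum of incident weights, a full **weighted** mode is also provided: strength
for degree, edge lengths $1/w$ for paths, Onnela cube-root triangle
intensity for clustering, and weight-multiset-preserving rewiring for the
nulls. The two definitions disagree in general; the binary default is used
everywhere unless the caller opts in.

Metrics at each threshold:

* $C_p$ — mean Watts–Strogatz clustering ($C_i = 2t_i/(k_i(k_i-1))$, nodes
  with degree < 2 contribute 0);
* $L_p$ — characteristic path length over finite distances; a disconnected
  graph is flagged and warned about rather than silently averaged;
* $E_{glob}$ — mean inverse distance over ordered pairs, unreachable pairs
  contributing 0 (well-defined on disconnected graphs);
* $E_{loc}$ — mean over nodes of the global efficiency of the
  neighbor-induced subgraph (degree < 2 contributes 0);
* nodal degree, nodal efficiency (mean inverse distance from a node), and
  unnormalized Freeman betweenness with proportional sharing over
  equal-length shortest paths.

**Normalization.** $\gamma = C_p / \langle C_p^{rand}\rangle$ and
$\lambda = L_p / \langle L_p^{rand}\rangle$ are computed against **100
matched random networks** produced by Maslov–Sneppen double-edge swaps
(default $10\times$ the edge count), which preserve the exact degree
sequence. Small-worldness is $\sigma = \gamma/\lambda$; a small-world
network has $\gamma > 1$, $\lambda \approx 1$, $\sigma > 1$. Per-null seeds
are derived from a master seed by a counter, so every normalized quantity is
exactly reproducible.

**AUC.** Each metric's curve over the grid is summarized by its trapezoidal
area under the curve. The trapezoid rule was chosen over a step sum because
it is the standard quadrature for a curve sampled on a uniform grid and is
exact for the (approximately piecewise-linear) metric curves; endpoints are
inclusive.

Distances, betweenness and rewiring are delegated to `igraph`; the
definitional conventions above (degree-<2 nodes, unreachable pairs,
tie-breaks, neighbor-induced subgraphs) are enforced by this package, and
the test suite checks every metric against independent brute-force
enumeration (Floyd–Warshall distances, exhaustive triangle and path
counting) on dozens of small random graphs at tolerance $10^{-9}$.

## 4. Group inference

Group differences are tested on the AUCs with **covariate-adjusted
permutation tests** in the Freedman–Lane style: the outcome is residualized
once on an intercept plus covariates (age, gender, SAS and SDS by default),
the pooled-variance two-sample $t$ statistic of the residuals is computed,
and group labels are permuted (default **10,000** times). The two-tailed
p-value uses the add-one estimator $(b+1)/(m+1)$, which cannot reach zero
and is slightly conservative. Constant covariate columns are dropped with a
warning rather than allowed to break the design.

Multiple comparisons across the 90 nodes are controlled by
**Benjamini–Hochberg FDR at 0.05 within each nodal metric separately**
(90 tests per family). The family definition is genuinely ambiguous —
pooling all 270 nodal tests is defensible too — so `fdr_family = "pooled"`
is available; per-metric correction is the default because each metric
answers a distinct question about the node.

**Overlap nodes** are nodes significant in nodal betweenness AND degree AND
efficiency with a consistent direction of difference; nodes significant
everywhere but with conflicting directions are excluded with a warning.
Brain-behavior association is then assessed by **partial correlation**
(Pearson on covariate-residualized vectors, $t$ on $n-2-k$ degrees of
freedom) between the overlap nodes' betweenness AUC and the clinical
variables (duration, CCS) within the patient group, FDR-corrected across the
tested pairs. Demographics are compared with pooled-variance two-tailed
t-tests for continuous variables and a chi-squared test without continuity
correction for gender (the uncorrected statistic equals the textbook
$\sum (O-E)^2/E$; Yates correction is available via an argument).

## 5. The synthetic-data generator

The generator exists so that the full chain can run, and be tested, with no
imaging data. It emulates the *statistical structure* of a two-group
structural-connectome study, not the anatomy of any real brain.

**Tensor phantoms.** Fiber bundles are tubes of radius ≥ 1 voxel around
polyline paths; in-bundle voxels carry an axially symmetric tensor with the
path tangent as principal eigenvector and a prescribed FA (mean diffusivity
fixed at $0.7 \times 10^{-3}$ mm²/s, a typical white-matter value). The
background is near-isotropic with FA < 0.2, so tracking can never leave a
bundle. Bundle end-caps receive distinct region labels. Phantoms are
tensor-level by design: raw diffusion-weighted signals, gradient tables and
k-space are out of scope.

**Connectome cohorts.** All subjects share a spatial backbone: 90 nodes
placed uniformly at random in a unit cube, with edge score
$\exp(-d_{ij}/\tau)$ and the top `base_density` fraction of edges retained.
Edge weights are an affine rescaling of the standardized scores to mean
`weight_mean` and SD `weight_sd`, plus per-subject Gaussian noise, clipped
to $(0, 1]$. Spatial decay is the simplest generative rule that yields the
high clustering and short paths of real anatomical networks, because
thresholding by weight then preferentially keeps short-range edges (a
geometric graph) while the noise sprinkles in long-range shortcuts.

Defaults, chosen once as a realistic operating point and then fixed:

| parameter | default | rationale |
|---|---|---|
| `n_group_a`, `n_group_b` | 70, 45 | the reference study's group sizes |
| `n_nodes` | 90 | AAL-90 parcellation |
| `base_density` | 0.5 | no real-connectome density is reported; must exceed 0.34 so the whole grid is thresholdable, and 0.5 leaves a wide margin while keeping the backbone spatially selective |
| `tau` | 0.2 | decay length (unit-cube distance) giving small-world topology — $\gamma > 1$, $\sigma > 1$ — across the whole grid |
| `weight_mean`, `weight_sd` | 0.5, 0.1 | plausible FA range for white-matter edges, comfortably inside $(0,1]$ |
| `subject_noise_sd` | 0.02 | between-subject edge-weight variability small relative to the spatial structure |

**Planted effects** are multiplicative: in group A, every edge incident to
an `effect_nodes_up` node is scaled by $1+\delta$ and every edge incident to
an `effect_nodes_down` node by $1-\delta$. A multiplicative change is
required because sparsity thresholding is rank-based — an additive shift
applied to all edges cancels exactly. The scale is
$\delta = \texttt{effect\_size} \times \texttt{subject\_noise\_sd} /
\texttt{weight\_mean}$, so `effect_size` reads as a standardized per-edge
shift: at `effect_size = 1` each affected edge moves by about one
between-subject standard deviation.

**Covariates** are sampled from truncated normal distributions whose
underlying parameters are moment-matched so that the *truncated*
distribution reproduces the published group means and SDs (naive truncation
would shrink the SD; the published summaries describe the bounded data).
Bounds: age 20–40 years (the study's inclusion range), SAS/SDS 20–80,
duration 6–180 months, CCS 5–30, PAC-QoL 0–110. Gender is Bernoulli with
the study's male proportions (8/70 and 10/45), coded 0/1 with 1 = male.
Duration, CCS and PAC-QoL exist only for group A.

What the generator does **not** emulate: hemispheric symmetry and anatomical
module structure, streamline-count confounds, distance-dependent FA
gradients, site or motion artifacts, and any correspondence between node
indices and real AAL anatomy. Passing tests therefore demonstrate that the
pipeline's statistics behave correctly under a controlled truth, not that
any particular real-data result would replicate.

## 6. Numerical choices and degenerate inputs

* Thresholding requires enough nonzero edges; an infeasible sparsity raises
  an error stating the available density rather than silently returning a
  denser graph.
* Disconnected thresholded graphs: $L_p$ averages finite distances and sets
  a `connected` flag; efficiencies treat unreachable pairs as 0.
* $\gamma$ is reported missing with a warning if the null mean clustering is
  zero (possible only on near-degenerate graphs).
* Graphs admitting no valid degree-preserving swap (stars) are returned
  unchanged from rewiring, with a warning.
* Permutation tests on constant outcomes return $p = 1$ with a warning.
* All randomness is seeded; library functions restore the caller's RNG
  state, and per-null/per-subject seeds are derived from master seeds by
  counters, so identical configurations give byte-identical outputs.

## 7. Problem sizes used in the shipped checks

The package's own test suite exercises the full chain at sizes chosen to
make each property unambiguous: small-world behavior is verified on 20
synthetic subjects across all 25 thresholds with 100 nulls each; permutation
calibration on 500 null datasets at 500 permutations; planted-effect
recovery on 20 replicates of a 70 + 45 cohort at 1,000 permutations; metric
correctness on ≥ 50 random graphs against brute-force enumeration. The
`scripts/acceptance.R` entry point re-runs the small-world computation from
scratch at the same size and reports the minimum $\sigma$ and $\gamma$
observed anywhere in the cohort × grid plane.

## 8. Known limitations

* FACT here is voxel-centric with nearest-neighbor direction lookup; no
  sub-voxel interpolation of the tensor field is performed.
* The weighted mode's clustering and rewiring conventions (Onnela; weight
  shuffling over rewired topology) are reasonable but not unique choices.
* The generator's planted effects act on edge weights; effects that change
  topology independently of weight (e.g. selective long-range loss) are not
  modeled.
* Betweenness is reported unnormalized; normalization is available but off
  by default.
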
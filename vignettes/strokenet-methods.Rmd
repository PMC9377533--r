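---
title: "Longitudinal graph analysis of functional brain networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal graph analysis of functional brain networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokenet)
```

## The model and its assumptions

`strokenet` implements a longitudinal functional-connectivity pipeline for
two-session resting-state designs. Its input is one matrix of regional BOLD
time series per subject and session (T time points x N nodes, nodes defined
as points in MNI millimetre space); its outputs are binary graphs, four
node-level graph metrics, their relative between-session changes attributed
to anatomical regions, and a brain-behaviour correlation between
region-averaged betweenness change and upper-extremity Fugl-Meyer (UE-FM)
recovery.

The stages, in order:

1. **Scrubbing exclusion.** A subject with strictly more than 30
   motion-censored volumes in a session is excluded (`scrub_check()`); a
   count of exactly 30 is kept.
2. **Pre-whitening.** Each node series is replaced by the residuals of a
   per-node AR(p) model, p chosen by AIC in `0..max_order` (Yule-Walker).
   Temporal autocorrelation inflates Pearson correlations; removing it makes
   the edge weights closer to the independence assumptions of the later
   correlation test. The first p samples, where no residual exists, are kept
   as mean-centred originals so length is preserved; selected orders are
   returned in the `ar_orders` attribute.
3. **Connectivity.** Pearson correlation of every node pair
   (`pearson_matrix()`), symmetry enforced exactly. The diagonal is stored
   as 1 and excluded from everything downstream.
4. **Proportional thresholding.** `proportional_threshold()` keeps the
   `round(density * N(N-1)/2)` strongest edges (density 0.20 by default) and
   binarises. All subjects therefore have graphs with an identical edge
   count, which is the point of proportional (rather than absolute)
   thresholding. "Strongest" means most-positive signed correlation by
   default; an absolute-value mode exists (see *Open decisions*).
5. **Graph metrics.** Degree, clustering coefficient, characteristic path
   length, and betweenness centrality per node, on the binary graph
   (`all_metrics()`). Definitions are the standard unordered-pair ones:
   `CC in [0,1]`, `BC in [0,1]` with the `2/((N-1)(N-2))` normalisation, and
   CPL as the mean hop distance to the other nodes.
6. **Relative change.** `delta_metric()` computes `dM = (M2 - M1)/M1` per
   node. Nodes with `M1 = 0` are flagged undefined and excluded downstream,
   never imputed.
7. **Display filter and anatomy.** A node's change is "shown" when
   `|dM|` exceeds half the mean absolute `dM` over defined nodes
   (`display_filter()`). Shown nodes are attributed to anatomical regions by
   nearest-coordinate lookup against a packaged region table
   (`assign_nodes_to_regions()`), and summarised per region and hemisphere
   with increase/decrease tags (`region_aggregate()`).
8. **Brain-behaviour correlation.** For three motor ROIs (primary
   sensorimotor, supplementary motor, premotor) in each hemisphere,
   `run_fig5_analysis()` correlates per-subject ROI-averaged betweenness
   change with the UE-FM change score: Pearson r with the exact two-sided
   t-transform p-value on n-2 degrees of freedom, significance at
   `alpha = 0.05`, no multiplicity correction by default (a Holm switch
   exists).

Lesions are normalised to the right hemisphere ("ipsilesional" = right,
"contralesional" = left). For node tables this is `flip_lesion_to_right()`
(x -> -x for left-lesion subjects, an involution). For whole cohorts with
mirror-symmetric node tables, `align_cohort_to_lesion_right()` instead
permutes the node signals of left-lesion subjects by the x-mirror partner
map, which is the node-level analogue of flipping the underlying images and
lets one shared node table serve all subjects.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `density` | 0.20 | fraction of possible edges | conventional top-20% proportional threshold |
| `mode` | `"signed"` | — | keep positive couplings; absolute mode available |
| `max_order` | 10 | AR order | AIC rarely selects above ~5 for TR-2s BOLD-like series |
| `cpl_policy` | `"reachable"` | — | keeps CPL (and `dM` of CPL) finite on disconnected graphs; `"literal"` propagates `Inf` |
| `max_distance` | 15 | mm | beyond this a node stays unattributed instead of force-assigned; region coordinates are sparse samples of their regions |
| `alpha` | 0.05 | — | per-panel significance level |
| `scrub_limit` | 30 | volumes | strict "more than" rule |

ROI composition is configuration, not code: the default is
primary sensorimotor = precentral + postcentral gyri (`PrCG`, `PoCG`),
supplementary motor = medial frontal gyrus (`MlFG`), premotor = superior +
middle frontal gyri (`SFG`, `MFG`). The exact node membership of the
premotor and supplementary motor ROIs is an interpretation; pass any named
list of abbreviation vectors to `roi_node_sets()` to change it.

## What the synthetic generator emulates — and what it does not

The cohort generator (`simulate_cohort()`) stands in for a 13-subject,
two-session stroke cohort: 6 motor-impaired and 7 control subjects, 264
nodes, 180 time points at TR 2 s by default, plus a clinical table (Rankin,
Barthel, NIHSS, UE-FM 0-66, LE-FM 0-34) whose first-session scores
re-classify each subject to the group that generated them (control: Rankin
0-1 and Barthel 100; motor: Rankin >= 1 and Barthel < 100; motor baselines
drawn to match the published ranges, e.g. UE-FM uniform on 50-66 and Barthel
on 85-95).

Node signals follow a block latent-factor model: node i in community c(i)
has signal

    x_i(t) = lam_i * f_c(i)(t) + g_i * G(t) + noise_sd * e_i(t)

with community factors `f`, a global factor `G`, and node noise `e`, all
stationary AR(1) series with coefficient `ar_coefficient` (default 0.4).
Heterogeneous loadings (`lam_i ~ U(0.6, 1.4)`, `g_i ~ U(0.1, 0.5)`) are
drawn once per cohort as a *spatial template* shared by every subject
(`spatial_template()`), mirror-symmetrised so that left- and right-lesion
subjects have identical aligned covariance structure. Within-community
correlations are therefore high and between-community correlations low —
the modular structure that makes a 20% proportional threshold meaningful.

**The planted effect.** Target nodes (by default the nodes attributed to the
left/contralesional primary sensorimotor cortex) additionally load on the
*other* community factors with a fixed total loading whose exponential reach
grows with a subject-specific shift `delta_s`. This design came out of an
explicit mechanism study, and the reasoning is worth recording because it is
the opposite of the naive design:

* In a binary proportionally-thresholded graph, making an already
  supra-threshold correlation stronger changes nothing. Scaling a fixed
  bridge profile therefore saturates immediately; the shift must extend the
  *reach* of the bridge — how many communities it touches — which is what
  betweenness actually rewards.
* Identical bridge profiles across targets make them interchangeable
  parallel bridges; shortest-path counts split between them and cap each
  node's betweenness. The template gives each target its own bridging order.
* A target with zero baseline bridging has baseline betweenness near 0, and
  the relative change `(BC2 - BC1)/BC1` at a near-zero denominator is pure
  noise. Targets therefore carry a moderate baseline bridge (decay length
  0.7 before the shift).
* The two sessions share 95% of their latent realisation (a test-retest
  reliability analogue); shared estimation error cancels in the session
  difference, as it partly does in repeated scans of the same brain. The
  session pair remains exchangeable under a null shift, which the test suite
  checks by a sign test on `BC2 > BC1`.

For motor subjects the UE-FM recovery and the hub shift are drawn jointly:
baseline UE-FM is uniform on 50-66, a latent recovery fraction
`rho ~ U(0,1)` gives `uefm_t2 = t1 + rho * (66 - t1)` (the 66-point ceiling
is respected by construction), and

    delta_s = effect_strength * (coupling * dUEFM/16 + (1 - coupling) * u)

with `u ~ U(0,1)`. Coupling 1 ties shift and recovery deterministically;
coupling 0 decouples them. The joint draw is deliberately parameterised from
the behavioural side: the forward direction (recovery as a clamped function
of the shift) lets the 66-point ceiling censor roughly half the cohort,
which destroys the planted correlation no matter how strong the coupling —
an instructive dead end.

`effect_strength` and `behavior_coupling` are free parameters of the
simulation. They are not estimates of any empirical effect size; nothing in
a 13-subject study pins them down.

**What a green test does not establish.** The generator reproduces the
statistical skeleton the pipeline assumes — modular covariance, AR(1)
autocorrelation, two groups, a coupled hub shift — not fMRI data. There is
no volumetric simulation, no motion or physiological artifact beyond the
AR structure, no lesion-site heterogeneity, and the community structure is
far cleaner than real functional parcellations. Green pipeline tests
establish correctness of the computations and recoverability of a planted
effect under this idealised world, nothing about real brains.

## Numerical choices

* **Edge-count rounding**: `E = floor(density * P + 0.5)` (half away from
  zero), deterministic and density-symmetric.
* **Ties at the threshold cutoff**: broken by lexicographic `(i, j)` order;
  the tie count is recorded on the result. Bit-reproducible across
  platforms.
* **`CC` at degree < 2** is 0 (the definition is 0/0 there); **`BC` for
  N < 3** is an all-zero vector with a warning.
* **Shortest paths** are computed by a level-synchronous matrix BFS from all
  sources at once; betweenness uses the pair-dependency identity
  `sigma_jk(i) = sigma_ji * sigma_ik` when `d_ji + d_ik = d_jk`. Both are
  checked against exhaustive enumeration oracles (Floyd-Warshall distances,
  bounded DFS path lists) on hundreds of seeded random graphs.
* **Determinism**: every stochastic function takes a seed; per-subject
  streams derive from the master seed by a fixed offset; RNG state is saved
  and restored so library calls do not perturb caller state. Two runs with
  the same configuration produce byte-identical results trees.

## Open decisions and their resolutions

* *Signed vs absolute edge ranking*: not derivable from the source analysis
  description; signed is the default because binarised functional graphs
  conventionally keep positive couplings. `mode = "absolute"` is provided.
* *Half-the-average display rule*: read as half the mean **absolute**
  change. A signed mean could be negative, making the filter show
  everything, which contradicts the symmetric show/hide behaviour of
  relative-change maps.
* *Pearson vs rank correlation in the ROI panels*: genuinely ambiguous in
  the source ("the P corresponding to that rho" alongside "r"); Pearson is
  the default, `method = "spearman"` is one keyword away.
* *Midline nodes* (x = 0) belong to neither hemisphere and are counted but
  excluded from hemisphere summaries.
* *Configuration format*: JSON only. The deployment image has no R YAML
  parser, and one format beats two half-supported ones.
* *Synthetic node coordinates* are jittered mirror-pairs of the packaged
  region coordinates rather than a plain lattice: a lattice leaves most
  nodes beyond the 15 mm attribution cap at small N, which would empty the
  motor ROIs that the planted-effect machinery and its tests depend on.
  Mirror pairing additionally gives every node an exact twin, enabling
  signal-level lesion alignment.

## Known limitations

* **Statistical power of the planted-effect recovery.** The acceptance
  stress test that requires the contralesional sensorimotor panel to reach
  p < 0.05 in at least 80% of replicates (and a pooled mean
  target-vs-non-target dominance in 95%) fails at roughly half to
  three-quarters of those rates under the strongest configuration we
  consider honest (coupling 1, `effect_strength` 2.5, `noise_sd` 0.5,
  twelve motor subjects per replicate); the exact rates are computed in
  `tests/testthat/test-acceptance.R`, which is left red rather than
  weakened. Two causes, both structural: betweenness of a
  proportionally-thresholded binary graph is a discrete, zero-sum,
  high-variance functional of the sample correlation matrix, and the
  relative change `(M2 - M1)/M1` is unboundedly right-skewed wherever the
  baseline is near zero, which biases non-target means upward through rare
  enormous ratios. Median-based versions of the same comparisons separate
  cleanly in every replicate (see `test-synthetic_data.R`); the mean-based
  criterion is kept as stated and documented as unmet.
* The AR-order selection uses plain Yule-Walker/AIC, not a robust iterative
  fit.
* Group-average analyses assume all subjects share one node table; with
  asymmetric (real-atlas) node tables, signal-level lesion alignment is
  unavailable and only coordinate-level flipping is performed, with a
  warning.
* No weighted-graph metrics, efficiency, modularity, or small-world
  statistics; the analysis binarises by design.

## A minimal run

```{r example, eval = FALSE}
cfg <- simulation_config(n_nodes = 64, n_timepoints = 120,
                         n_motor = 6, n_control = 4,
                         noise_sd = 0.5, seed = 1)
cohort <- simulate_cohort(cfg)
results <- run_pipeline(cohort, pipeline_options(max_order = 3))
results$correlations
```
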
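---
title: "Resampling-robust regulatory networks and control-node clustering: methods"
author: "grnboot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling-robust regulatory networks and control-node clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Gene-regulatory-network (GRN) inference from single-cell RNA-seq is fragile:
droplet counts are sparse and noisy, and mutual-information networks built
from a single draw of the data change substantially from run to run. This
package implements a pipeline that stabilizes both the network and the
downstream cell-type assignment by brute statistical force:

1. **Smoothing.** Counts are averaged over each cell's `k` nearest
   neighbours in a 2-D embedding (typically UMAP), with the decimal part
   truncated so the result is again a count matrix.
2. **Resampling.** `N` cells are drawn (without replacement) `M` times; on
   each draw the most variable genes are selected (vst ranking), restricted
   to transcription factors, and an ARACNe network is inferred
   (Miller-Madow mutual information on equal-width bins, then
   data-processing-inequality pruning of the weakest edge of every
   triangle).
3. **Shuffled-name null.** The same machinery runs on `M_hat` resamples
   whose gene names are shuffled `K` times each; the rate at which a node
   or edge appears by chance calibrates a Poisson tail test. Appearance
   counts over the `M` real specimens get p-values
   `P(Pois(lambda * M) >= count)` and Benjamini-Yekutieli q-values; only
   nodes and edges with `q` below a threshold (default `1e-5`) enter the
   consensus network.
4. **Control nodes.** Minimum dominating sets (MDS) of the consensus
   network are computed exactly and enumerated; vertices in every optimum
   are *critical*, vertices in at least one (but not all) are
   *intermittent*. Critical plus intermittent nodes form a uniquely
   determined control set.
5. **Clustering.** Cells are first grouped into small "clumps" (Louvain at
   the highest resolution whose smallest community still has
   `ceiling(0.8 * k)` cells). Clump-mean expression profiles of the control
   genes are clustered with Ward linkage on `1 - Pearson` dissimilarity.
   Multiscale bootstrap assigns approximately-unbiased (AU) support to
   every clade; the number of clusters `k` is the smallest cut whose
   partition is maximally similar (ARI) to the AU-confident partition.

The `run_pipeline()` function wires these stages together in two modes:
*manual* (single MDS, user-chosen cluster number: the original procedure)
and *automated* (control nodes, bootstrap-chosen cluster number).

# Statistical model of the significance layer

A hypothesis `theta` is either "gene g is selected as variable" or "edge
(a, b) is present in the inferred network". Over `M` independent resampled
specimens its appearance count is approximately Poisson with mean
`lambda(theta) * M`, where `lambda` is the per-specimen null rate.

* For nodes no resampling is needed: shuffling names makes every gene
  equally likely to carry a variable-gene label, so
  `lambda_node = n_hvg / n_genes` exactly.
* For edges, `lambda` is estimated from the shuffled specimens. A specific
  named pair essentially never recurs among the shuffled runs, so the
  estimate is pooled: total TF-TF edges observed across all `M_hat * K`
  shuffled specimens divided by `M_hat * K * C`, with
  `C = choose(|TF universe|, 2)` the number of candidate pairs, which are
  exchangeable under the shuffle. Per-pair tallies remain available
  (`run_null_ensemble(per_pair = TRUE)`) for fidelity experiments.

Nodes and edges are BY-adjusted as separate families: the node test has an
analytic rate while the edge test has an estimated one, and keeping the
families separate prevents either from diluting the other. Edges also
require both endpoints to survive the node filter (closure), which is what
empties the consensus on structureless data: even a gene selected in every
specimen only reaches `p = P(Pois(n_hvg / n_genes * M) >= M)`, far above
the threshold at the default rates.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | smoothing neighbourhood; also sets the clump-size floor `ceiling(0.8 k)` |
| `N` | `min(n/3, 20000)` | cells per resample (without replacement) |
| `M` | 100 | network resamples |
| `M_hat`, `K` | 1000, 100 | null resamples and shuffles per resample (`1e5` shuffled specimens) |
| `n_hvg` | 2000 | variable genes per specimen (vst ranking) |
| `q_threshold` | `1e-5` | BY cutoff for consensus membership |
| `n_bins` | `floor(sqrt(N))` | equal-width bins for MI estimation |
| `dpi_eps` | 0 | DPI tolerance (0 = strict; `Inf` disables pruning) |
| `n_solutions` | 15 | MDS enumeration depth |
| `scales` | 0.5..1.4 | multiscale-bootstrap resample-size multipliers |
| `B` | 1000 | bootstrap replicates per scale |
| `alpha` | 0.05 | AU confidence cutoff (clusters with AU >= 0.95) |

The defaults for `M`, `M_hat`, `K`, `n_hvg` and `q_threshold` follow the
published procedure at full scale. The test suite and the acceptance
script run the same machinery at a reduced scale chosen so a full
end-to-end run takes well under a minute on one CPU: 1500 cells x 1000
genes, `N = 500`, `M = 20`, `M_hat = 100`, `K = 10`, `n_hvg = 200`,
`B = 500`. At `M = 20` the analytic node rate gives `lambda_node * M = 4`,
so a gene selected in all 20 specimens still reaches `q ~ 1e-7` while
chance-level genes stay far above the cutoff — the reduced scale preserves
the discriminating power of the full-scale test.

# Numerical choices

* **Ties in smoothing.** The `k`-neighbourhood includes the query cell
  itself (so `k = 1` is the identity); distance ties at the `k`-th
  neighbour break by cell index, making the result deterministic.
* **MI estimator.** Miller-Madow: plugin entropy plus `(m - 1)/(2n)` with
  `m` occupied bins. Slightly negative MI estimates are possible and are
  treated as absent edges. The all-pairs kernel is compiled (Rcpp), as in
  the C cores of the established MI-network packages.
* **DPI.** Pruning decisions are taken simultaneously on the input MI
  matrix: an edge is removed when some triangle makes it strictly the
  weakest by more than `dpi_eps`.
* **MDS solver.** The 0/1 covering program `min sum x_v` s.t.
  `x_v + sum_{u in N(v)} x_u >= 1` is solved exactly by branch-and-bound on
  the covering constraints with connected-component decomposition; a
  subset-enumeration oracle (`brute_force_mds`) cross-checks it on all
  graphs with up to 8 vertices in the test suite. Enumeration of
  alternative optima partitions the search space (branch on a vertex's
  allowed dominators, then ban the tried dominator), so optima are distinct
  by construction and enumeration stops early when fewer than
  `n_solutions` exist — repeated identical solves cannot produce
  duplicates here, which sharpens the critical/intermittent semantics.
* **Ward variant.** `ward.D2` (squared-dissimilarity update) on
  `1 - Pearson`, with the classic `ward.D` recurrence available for
  cross-checking (`ward_tree(variant =)`).
* **AU fit.** With `z_r = qnorm(1 - BP_r)` and effective scale
  `r' = round(r p)/p`, a weighted least-squares fit of
  `z = v sqrt(r') + c / sqrt(r')` (weights from the binomial variance of
  BP via the delta method) gives `AU = 1 - pnorm(v - c)`. Scales with BP
  exactly 0 or 1 carry no curvature information and are excluded; nodes
  with fewer than 3 informative scales fall back to their BP at the scale
  nearest 1, clipped to `[1/(2B), 1 - 1/(2B)]`, and are flagged
  (`au_method = "bp"`). A clade present in every bootstrap therefore gets
  AU `1 - 1/(2B)`, not an extrapolated value.
* **Root clade.** The full leaf set appears in every bootstrap tree by
  construction, so the root is not a candidate confident cluster;
  `pick_confident()` starts at the root's children. This matches the
  cluster-extraction convention of the standard AU-clustering tools;
  without it the automated cluster number would always collapse to 1.
* **Clade bookkeeping.** Bootstrap clade identity uses random-leaf-weight
  numeric signatures (sums rounded at `1e-9`), which is orders of
  magnitude faster than set comparison and collision-safe at the scale of
  tens of clumps.
* **Degenerate inputs.** Constant genes discretize to bin 0 and carry zero
  MI; zero-variance profile rows make the correlation dissimilarity
  undefined and raise an instructive error; empty consensus networks are
  returned (with a warning) by `consensus_grn` but abort `run_pipeline`.

# What the synthetic generator emulates

`simulate_dataset()` provides the study conditions for every end-to-end
test: NB counts (common dispersion 0.5), `n_types` discrete cell types,
per-type programs of `n_regulators` regulator TFs, and
`targets_per_regulator` planted targets per regulator. Three design points
carry the statistical load:

* **Smooth activity fields.** A regulator's within-type variation is a
  smooth random field over the embedding (random Fourier features at the
  blob length-scale), not iid per-cell noise. k-NN smoothing averages
  neighbouring cells, so iid cell-level activity would be destroyed by the
  very first pipeline stage; smooth variation — the realistic shape of
  continuous cell-state change along a map — survives it.
* **Noise ordering.** Regulators are highly expressed (baseline mean 8)
  and therefore read their own activity cleanly, while targets sit at
  ordinary levels (means 0.5-4) and add transmission noise
  (`noise_sd = 0.8`). Consequently the regulator-target edge is the
  strongest edge of every triangle it forms — exactly the configuration
  DPI pruning is designed to resolve, and the reason ARACNe can separate
  direct from sibling (target-target) dependence here.
* **Anchored mean-variance trend.** Background genes span means 0.1-50
  (log-uniform), so the vst loess trend is anchored by plain NB genes at
  every expression level and the planted genes stand out as variable. With
  a narrow background range the trend would be fit through the planted
  genes themselves and absorb their variance.

What the generator does *not* emulate: dropout beyond NB sampling, doublets,
batch effects, library-size gradients, antibody-tag layers, and continuous
differentiation trajectories. Passing tests on this fixture show that the
pipeline's statistics behave as designed under its assumptions, not that
those assumptions hold for any particular real dataset.

`simulate_null_dataset()` is the matched negative control (iid NB genes,
structureless embedding); `simulate_profile_blocks()` generates
block-structured profile matrices for the cluster-number machinery; and
`simulate_random_graph()` feeds the dominating-set oracles.

# Design choices where the design was open

* **Sampling without replacement.** `N` is a third to a half of the cells;
  the procedure subsamples rather than bootstraps. A
  bootstrap-with-replacement flag exists (`replace = TRUE`).
* **Pooled edge null.** See above; per-pair rates are statistically
  degenerate at feasible shuffle counts.
* **Candidate-pair denominator.** `C` counts pairs over the full TF
  universe intersected with the gene panel, fixed across specimens, because
  hypotheses are defined on that universe, not per specimen.
* **Node/edge families.** BY is applied separately to the node and edge
  families (analytic vs estimated null rates).
* **Profiles on raw-normalized counts.** Clump profiles use
  library-size-normalized `log1p` of the *original* counts: clumps are
  formed from the original data, and smoothing is a device for network
  inference, not a replacement measurement.
* **Unassigned clumps are singletons** when the confident partition is
  compared with complete cuts in `choose_k` — treating them as one shared
  "rest" group would reward merging them, singletons penalize neither
  merging nor splitting.
* **Manual-k comparison arm.** The original procedure chose the cluster
  number by visual inspection of a heatmap, which cannot be automated.
  Where the test suite compares the automated procedure against the
  original one, the manual arm uses a fixed, plausible-but-misspecified
  `k = 5` on the 3-type fixture together with a single per-replicate MDS —
  the two instability sources the automated procedure removes.

# Known limitations

* The exact MDS solver targets the consensus networks this pipeline
  produces (hundreds of vertices, star-like after DPI); adversarial dense
  graphs of that size could make branch-and-bound slow. The ILP-style
  formulation is unchanged; only the solving strategy is specialized.
* With few control genes (a few tens) the feature bootstrap is coarse:
  unions of genuinely close clusters can earn full support, and the
  automated cluster number can come out one below the planted value. That
  is a property of the data geometry at small feature counts, not of the
  AU machinery; the block-profile tests document the behaviour. Real
  datasets with larger control sets (or a larger `alpha`) are less
  affected.
* AU p-values are asymptotic; at `B = 500`-`1000` their Monte-Carlo error
  is a few percent, which matters only for clades sitting exactly at the
  confidence cutoff.
* Louvain community detection is stochastic across igraph versions even at
  a fixed seed; clump partitions are reproducible within an environment
  but not guaranteed across igraph releases.
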
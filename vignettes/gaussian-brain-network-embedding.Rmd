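---
title: "Probabilistic embedding of multi-subject brain networks: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic embedding of multi-subject brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state fMRI yields, for every subject and session, an N x N matrix of
Pearson correlations between the mean BOLD signals of N atlas regions
(ROIs). Quantifying how such functional networks change — for example before
and after a cognitive-training intervention — is hard because the networks
are high-dimensional, noisy, and differ between subjects. `mgembed`
addresses this by encoding every ROI of every network as a low-dimensional
multivariate Gaussian distribution `N(mu_i, diag(sigma_i^2))` in a latent
space *shared across all networks*. The mean places the region; the
variance expresses how uncertain its placement is. Distances between these
distributions then quantify network change at the region level.

## The model

**Inputs.** P weighted, undirected networks over the same N nodes. Each
connectivity matrix is thresholded: the diagonal is zeroed and entries
below `t = 0.1` (including all negative correlations) are set to zero;
surviving entries keep their correlation value as edge weight. Node i's
attribute vector is row i of its graph's thresholded adjacency matrix —
its connectivity profile — so the attribute dimension D equals N.

**Encoder.** A single feed-forward network shared by all P graphs:

* hidden layer: `h = ReLU(x W + b)` with M = 128 units (one hidden layer
  by default);
* mean head: `mu = h W_mu + b_mu` in `R^L` (L = 16 by default);
* variance head: `sigma^2 = elu(h W_sig + b_sig) + 1`, which is strictly
  positive by construction.

Because the weights are shared, every (subject, session) network is mapped
into one common latent space, and embeddings are directly comparable across
graphs without any alignment step.

**Neighbourhood supervision.** For each graph, edge weights are converted
to lengths (`1/w` by default: stronger correlation = shorter edge) and
all-pairs weighted shortest-path distances are computed. Distances are then
binned into K = 2 "hop" strata using global equal-mass quantile cut-points
of the finite-distance distribution. Each training epoch samples, for every
anchor node, one node per non-empty stratum (3 rounds per anchor by
default) and emits stratum-ordered triples (anchor, nearer, farther).

**Loss.** The energy of the ordered pair (i, j) is the closed-form
KL divergence `E(i,j) = KL(N_j || N_i)` between diagonal Gaussians. The
loss sums, over all triples and all graphs,

```
E_pos^2 + exp(-E_neg)
```

which pushes nearer nodes toward zero divergence from the anchor and
farther nodes away. Parameters are optimized with Adam (initial learning
rate 1e-3) for up to 1000 epochs by default; triplets are resampled every
epoch with seeds derived deterministically from (seed, epoch, graph), so a
run is exactly reproducible on a fixed floating-point platform.

**Downstream analytics.**

* *Link prediction.* Edges are split 85/10/5 into train/validation/test
  (largest-remainder rounding), the model is retrained on the training
  adjacency only (attributes and strata included, so held-out edges never
  leak), and pairs are scored by the symmetrized negative KL energy. AUC
  uses the Mann–Whitney rank formulation with ties counted 1/2.
* *Wasserstein-2 change.* For diagonal Gaussians,
  `W2^2 = ||mu_i - mu_j||^2 + sum_d (sigma_i,d - sigma_j,d)^2`. Unlike KL,
  W2 is a true metric, which makes it the right tool for "how far did this
  region move". Per subject and ROI we report W2 between the pre- and
  post-session embeddings; per-subject top-15 ROIs are counted by
  functional system.
* *Reorganization index.* For every unordered subject pair {a, b} and ROI:
  the between-pair distance averages W2(a_pre, b_post) and
  W2(b_pre, a_post); the within-pair baseline is W2(a_pre, b_pre). With
  S = 12 subjects this yields 66 between- and 66 within-pair distances per
  ROI. The RI is the mean between-minus-within difference; a one-sample
  t-test per ROI with Benjamini–Hochberg correction across ROIs flags
  significant regions at q < 0.05.
* *Effective dimensionality.* Per latent dimension, the median of
  `sigma^2` across all nodes and graphs; a dimension is unstable when its
  median exceeds `gamma = 2` times the median of these medians, and the
  effective dimension is L minus the number of unstable dimensions.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `t` | 0.1 | connectivity threshold; negative correlations are always removed for `t >= 0` |
| `K` | 2 | number of hop strata; 2 is sufficient for the ranking supervision |
| `L` | 16 | latent dimensions per head (mu and sigma^2 each in `R^L`) |
| `M` | 128 | hidden units (single hidden layer) |
| `learning_rate` | 1e-3 | initial Adam rate; optional decay via `lr_decay_epoch` |
| `max_epochs` | 1000 | training budget; on the synthetic designs here the validation AUC is flat after ~100–150 epochs |
| `per_anchor` | 3 | triplet sampling rounds per anchor per epoch |
| `split` | 85/10/5 | edge hold-out fractions |
| `gamma` | 2 | instability multiplier for the uncertainty profile |
| `fdr_level` | 0.05 | significance level on BH-adjusted p-values |

## Design choices where the design was genuinely open

* *Head dimensions.* Both the mean and the variance head map to `R^L`
  (diagonal covariance), following the parent Gaussian graph-embedding
  formulation and the uncertainty analysis, which examines the variance of
  each of the L dimensions.
* *KL direction.* The energy of the ordered pair (i, j) is
  `KL(N_j || N_i)`; link-prediction scores symmetrize over both directions
  because the graphs are undirected.
* *Edge lengths.* `1/w` by default — standard in weighted brain-network
  analysis, where strong correlations mean short functional distance;
  `1 - w` (floored at a small positive value) is available.
* *Hop thresholds.* Global equal-mass quantile cut-points: they are
  scale-free across subjects, so the same rule applies to every graph. A
  per-anchor variant (`"quantile_anchor"`) and custom stratum masses
  (`probs`) are available; in our experiments neither consistently beat
  the global equal-mass rule.
* *Triplet resampling.* Each epoch, with seeds derived from
  (seed, epoch, graph): stochastic ranking training, exactly reproducible.
* *Between-pair orientation.* Averaging the two orientations
  (a_pre, b_post) and (b_pre, a_post) yields exactly S(S-1)/2 = 66 values
  for S = 12 without an arbitrary orientation choice.
* *Within-pair baseline.* Pre–pre pairs only; the pre-session is the
  natural common baseline for an intervention design.
* *t-test sidedness.* Two-sided by default; a one-sided (mean > 0) option
  exists for confirmatory use.
* *Unstable-dimension rule.* "Median above `gamma` times the median of
  medians" with `gamma = 2`: robust to outlying nodes and graphs, and on a
  profile with three 10x-inflated dimensions out of 16 it reproduces the
  expected effective dimension of 13.
* *Degenerate inputs.* Zero-variance time series are an error naming the
  ROI; thresholding that removes every edge is an error; a single subject
  pair admits no t-test, so p-values are NA and nothing is flagged
  significant; non-positive-definite synthetic covariance targets are
  repaired by eigenvalue clipping and rescaling (reported via a message).

## What the synthetic generator emulates — and what it does not

The generator produces multi-subject weighted connectomes over an atlas of
264 ROIs in 14 functional systems (near-equal sizes), 12 subjects, two
sessions. Population weights combine:

* a global baseline `w_out = 0.02` shared by all pairs;
* a community term raising within-system weights to `w_in = 0.6`;
* selective system-pair coupling: each pair of systems receives a baseline
  drawn once from `Uniform(-0.2, 0.2)` (`w_coupling = 0.2`), modulated by
  smooth node-level strengths (`node_jitter = 0.15`). The coupling matrix
  is unstructured (full rank), so the planted relational geometry is not
  embeddable in a very low dimension — mirroring real connectomes, whose
  intrinsic dimensionality is comparable to the number of systems;
* a low-amplitude smooth residual field (`w_local = 0.08`, rank
  `local_dim = 4`), giving weak links predictable pair-level texture, as
  the transitivity of real correlation matrices does;
* i.i.d. pair-level heterogeneity (`edge_sd = 0.02`, fixed across
  subjects), subject-level noise shared between sessions
  (`subject_sd = 0.025`) and session-level noise (`session_sd = 0.015`).

The intervention perturbation mixes each target ROI's post-session
connectivity profile with the profile it would have as a member of a donor
community (convex weight `delta`, default 0.6), producing a graded,
localized effect that the RI statistic should detect. Time series are
multivariate Gaussian draws whose population correlation matrix is the
per-session target (repaired to positive definiteness when needed), with
T = 220 volumes by default, matching a common resting-state acquisition
length after dropping initial volumes.

What it deliberately does **not** emulate: hemodynamics and temporal
autocorrelation of BOLD signals; the structured (Wishart-type) sampling
error of finite-length Pearson correlation estimates when connectomes are
generated directly (the time-series route produces it naturally); scanner
and motion artefacts; and the heavy-tailed, spatially smooth dependence of
real atlases. Passing tests on these synthetic networks therefore show
that the pipeline recovers planted structure under realistic-but-idealized
conditions; they do not certify performance on real fMRI data.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full study design
(N = 264, 14 systems, P = 24 graphs). Hold-out (link-prediction) runs train
for 150 epochs and full-graph runs for 100: on these designs the
validation-AUC trajectory is flat from roughly epoch 100 onward, so longer
budgets change the third decimal at most. These are the package's choices
for its own reference runs; `max_epochs = 1000` remains the default for
user analyses.

## Known limitations

* **The RI t-test is anticonservative under the null.** The 66 pair
  differences are built from only 12 subjects' session realizations (each
  subject appears in 11 pairs), so they are positively dependent; treating
  them as 66 independent samples inflates the null t-statistics by roughly
  `sqrt(66/12)` in scale. On null synthetic data (no intervention effect)
  the BH-corrected test flags many ROIs in every realization even though
  the RI values themselves correctly centre on zero (the acceptance script
  reports this null count). The procedure is implemented in its standard form deliberately;
  treat the FDR flags as descriptive, rank regions by RI, and prefer a
  dependence-respecting resampling scheme (e.g., subject-level
  permutation) when inferential guarantees matter.
* **Cross-community link prediction is information-limited but also
  method-limited.** On the default synthetic design, held-out
  within-community edges are ranked almost perfectly, while
  cross-community pairs — the large majority of candidate pairs — are
  substantially harder even though most of their structure is recoverable
  in principle (an oracle scoring pairs by the true population weights
  ranks them almost perfectly). The node-wise Gaussian geometry
  compresses pair-level coupling into node positions, so finer pair-level
  texture is only partially recoverable, and the pooled test AUC on this
  design sits near 0.85, varying slightly with the data realization
  (seed).
* **Dropping the threshold to zero admits noise-gated weak edges.** With
  `t = 0`, any weak link whose sign is decided by i.i.d. noise rather than
  by structure becomes an edge, so the pooled AUC at `t = 0` is somewhat
  lower than at `t = 0.1`, by an amount that varies with the data
  realization. On data whose weak correlations are fully structured (as
  finite-sample Pearson matrices of long recordings tend to be), the two
  thresholds behave nearly identically.
* **Effective dimensionality is a coarse diagnostic.** The
  `gamma`-times-median rule is intentionally simple; on well-fit synthetic
  runs it typically flags no dimension (effective dimension 16 with 14
  planted systems). It reacts to strong, consistent variance inflation,
  not to graded redundancy.
* Training is plain R with BLAS matrix products; a full default run
  (P = 24, N = 264, 150 epochs) takes on the order of a minute per
  configuration on one CPU core. GPU execution and spherical covariance
  training are out of scope (spherical covariance is accepted by the
  forward pass only).

## A minimal worked run

```{r, eval = FALSE}
library(mgembed)

cfg <- run_config(max_epochs = 150, seed = 1,
                  synthetic = list(N = 80, n_systems = 5, S = 4, seed = 1))

res <- run_evaluate(cfg)     # link prediction with edge hold-out
res$auc_test_pooled

ana <- run_analyze(cfg)      # W2 change, RI, uncertainty
head(ana$ri$table)
ana$uncertainty$effective_dim
```
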
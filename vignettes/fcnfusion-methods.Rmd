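---
title: "Methods: a three-step fusion analysis of resting-state connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-step fusion analysis of resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnfusion)
```

## The problem

Resting-state fMRI yields, per subject, a matrix of BOLD time courses for
a set of anatomical regions of interest (ROIs; 116 under the AAL atlas).
Two clinical groups — say two stages of cognitive impairment — differ not
in signal amplitude but in how regions co-fluctuate. The question this
package addresses is: *which ROI connectivity features distinguish two
groups, consistently across the subjects of each group?*

Three obstacles make this hard: the data are high-dimensional and heavily
correlated, so off-the-shelf i.i.d. statistics mislead; a flexible
classifier can separate groups without saying *why*; and per-subject
explanations are noisy, so group-level claims need a model that pools
over subjects explicitly.

The pipeline answers with three fused stages:

1. **Connectivity representations.** Per subject, correlation matrices
   (Pearson, Fisher-z) and binary functional connectivity networks (FCNs)
   built by the Mapper algorithm over a 2-D embedding of the ROI time
   courses.
2. **Attention distributions.** A single-layer multi-head self-attention
   classifier is trained to distinguish the two groups from the subject
   matrices. After training, each subject's head-averaged attention
   matrix — row-stochastic, one row per ROI — records which inter-ROI
   relations the model used. Per-ROI coefficients of variation (CVs)
   collapse these into a subjects-by-ROI *group representative matrix*,
   and a top-quartile rule shortlists ROIs per group.
3. **Latent space item-response model (LSIRM).** The group matrix is
   treated as an item-response table (ROIs = items, subjects =
   respondents) and fit with a continuous LSIRM by MCMC. ROIs whose
   latent positions sit near the origin interact consistently with all
   subjects of the group; combined with the stage-2 shortlists this
   yields a three-way categorization rendered on thresholded group
   summary networks.

## Stage 1: embeddings and Mapper

Each ROI is one point whose feature vector is its time course
(`embed_rois`). Three embedding families are provided: `linear`
(principal components; deterministic), `stochastic` (t-SNE: neighborhood
distances become conditional probabilities matched by a heavy-tailed 2-D
kernel), and `topological` (UMAP-style: a fuzzy k-nearest-neighbor graph
laid out by fuzzy cross-entropy). The stochastic and topological
optimizers are small full-batch gradient-descent implementations written
for this package, so fixed seeds give bit-identical coordinates; they
favor reproducibility and transparency over large-n speed, which is
immaterial at 116 points. Topological defaults follow common practice
for biological embeddings: 15 neighbors, minimum distance 0.1.

`mapper_fcn` covers the embedding with `n_intervals^2` overlapping
rectangles (default 10 x 10, 30% overlap), clusters each bin
(single-linkage cut at the median nearest-neighbor distance by default;
a density mode exists), and keeps the maximal sub-clusters as nerve
nodes. ROI-level edges connect ROIs sharing a cluster and, by default,
ROIs in two clusters that share a member (`link_overlap`), since overlap
is exactly what the nerve encodes. The cutoff is applied with a relative
slack of 1e-8 so knife-edge merge heights (e.g. equally spaced points)
are kept. Every point lies in at least one bin by construction, and the
code asserts it.

Note the cover/cluster settings of Mapper are genuinely open parameters:
no single default recovers every geometry, which is why `mapper_config`
exposes all of them and the tests pin them per fixture.

## Stage 2: the self-attention classifier

Each subject's square matrix enters as 116 tokens, one per ROI, each
token being that ROI's matrix row projected linearly to the model width.
One layer of `H` scaled dot-product attention heads (default `H = 128`,
`d_k = d_v = 2`, width 256) is followed by an output projection, a
one-hidden-layer perceptron, mean pooling over tokens (which preserves
permutation symmetry), and a 2-class softmax. Training uses
cross-entropy, Adam (learning rate 0.01), minibatches of 8, dropout 0.9
on the perceptron hidden layer, and 10-fold cross-validation with early
stopping (patience 10) on the held-out fold; accuracy is the mean over
folds. The network and its backpropagation are written in base R and are
verified in the tests against a fully scalar loop implementation (to
1e-10) and against numerical gradients.

After training, every subject is passed through the model in evaluation
mode (dropout off) and the `H` head weight matrices are averaged into the
subject's attention distribution matrix; rows sum to one by
construction.

Two statistics summarize each ROI: the CV (population sd / mean) of the
ROI's attention **row** — how unevenly the ROI attends to others — and
the mean attention the ROI **receives**, i.e. its column mean. The column
is used for the mean because every row of a row-stochastic matrix has
mean exactly `1/R`: a row-mean "high mean value" statistic would be
vacuous. Both margins are exposed as options. The two statistics are
combined by an unweighted rank sum (ties: higher mean attention, then
alphabetical) and the best `floor(0.25 * n_rois)` ROIs are kept — 29 of
116. An intersection-of-quartiles mode is provided as an alternative
reading of the selection rule; it may return fewer ROIs.

## Stage 3: the continuous LSIRM

With `Y` the `N x R` group matrix of CVs, each cell is modeled as

$$ y_{ij} \sim \mathrm{Normal}\big(\theta_j + \beta_i - \lVert u_j - v_i
\rVert,\ \sigma^2\big), $$

with per-ROI effects $\theta_j$, per-subject effects $\beta_i$, and 2-D
latent positions $u_j$ (ROIs) and $v_i$ (subjects). Strong subject-ROI
association shrinks the latent distance; an ROI close to *all* subjects
ends up near the origin, which is the group-representativeness signal.

Fitting is Metropolis-within-Gibbs (`run_lsirm`). Each iteration makes
random-walk Metropolis updates of every $\theta_j$, $\beta_i$, $u_j$,
$v_i$, then Gibbs draws of $\sigma_\theta^2 \sim
\mathrm{InvGamma}(a + R/2,\ b + \tfrac12\sum_j \theta_j^2)$ and of
$\sigma^2$ from its conjugate Inv-Gamma full conditional (prior
$a = b = 0.001$ for both; $\beta$ and latent priors are N(0, 1)).
Because $\theta_j$ and $u_j$ touch only column $j$ of the residual
matrix, and $\beta_i$, $v_i$ only row $i$, the per-coordinate
accept/reject decisions are mutually independent within a block and are
vectorized; this is an exact implementation, not an approximation.
Defaults are 55,000 iterations, 5,000 burn-in, thinning 5 — exactly
10,000 retained draws — with jump scales 0.005 (ROI effects, subject
effects, ROI positions) and 0.003 (subject positions).

Numerical choices worth knowing:

* **Proposal scales are tuning parameters.** The default scales suit
  CV-scale group matrices. The synthetic recovery fixture used in the
  tests (60 subjects, 30 ROIs, residual sd 0.1, 20,000 iterations) uses
  0.05 for all blocks, chosen so every block's acceptance rate sits
  inside the conventional band (observed 0.22-0.41); with scales an
  order of magnitude smaller the chain accepts ~98% of proposals and
  cannot traverse the posterior in that budget.
* **Initialization.** The chain starts from a deterministic
  multidimensional-unfolding configuration: row/column means give crude
  main effects, the implied proxy distances are double-centered and
  factored by SVD into starting positions (plus a small seeded jitter).
  Random starts — dispersed or near-origin — intermittently lock this
  very peaked posterior into mirror-image local modes; warm starts of
  this kind are standard for latent space network models. A `"random"`
  init is available for comparison.
* **Proposal family.** Jump-scale random walks are the primary sampler.
  A variant drawing proposals from the priors is kept behind
  `proposal = "independent"`; with prior = proposal the Hastings ratio
  reduces to the likelihood ratio.
* **Identifiability.** The likelihood sees positions only through
  distances, so draws are aligned by orthogonal Procrustes (SVD; first
  retained draw as reference, then a refinement pass against the aligned
  mean). Rotation/reflection only by default — the zero-mean priors pin
  the centroid — with translation optional. For interpretability an
  oblimin (quartimin) rotation of the posterior-mean ROI positions is
  available via a gradient-projection optimizer written in-package; the
  rotation is oblique, so origin distances before and after are both
  reported, and origin-proximity ranking uses the aligned (unrotated)
  means.
* **"Near origin"** is the lowest quartile of origin distances by
  default, with an absolute radius accepted instead — the notion is
  inherently visual and a fixed convention keeps the categorization
  deterministic.

ROI categories across the two groups follow a fixed decision table:
top-listed and near-origin in both groups = `both`; top-listed in both
but near-origin in one = `more_reactive` for that group; top-listed in
exactly one = `only` for that group; otherwise `none`. Group summary
networks keep an edge when the fraction of the group's subjects whose
FCN contains it reaches the threshold (default 0.2, weak inequality;
a top-percentile mode is available since a ratio cutoff and a percentile
are both defensible readings of a "top connectivity ratio" rule). Each
categorized ROI and its direct neighbors form one named cluster.

## The synthetic cohort generator

`simulate_cohort` draws zero-mean Gaussian ROI time series colored by a
block correlation matrix (within-block correlation set per group, zero
between blocks) and an AR(1) filter in time (coefficient 0.3 by
default). This is deliberately the *minimal* model exercising every
pipeline stage: the group difference lives entirely in between-ROI
correlation, which is what every stage consumes. It does not emulate
hemodynamics, scanner drift, motion artifacts, spatial smoothness, or
non-stationarity — so green tests certify the machinery (shapes,
invariants, recovery of planted structure), not clinical performance on
real scans. Default test conditions use 15 subjects per group, 16 ROIs
in two blocks, 120 time points, and a within-block correlation gap of
0.5 (0.7 vs 0.2), a separation a practitioner would call a strong but
not degenerate effect; the no-signal control sets the gap to zero.

`simulate_item_response` plants known LSIRM structure
(`y = theta_j + beta_i - ||u_j - v_i|| + noise`) with ROI clusters at
chosen centers and returns the full truth record, so latent-distance
recovery is measured against ground truth (Pearson correlation of true
vs estimated subject-ROI distances; the standard fixture reaches about
0.99).

## Problem sizes used by the tests and the acceptance script

Simulations are sized for a single CPU: the classifier fixtures use 30
subjects of 16 ROIs with 8 heads (the architecture is the default one,
narrower); the recovery fixture is 60 x 30 with 20,000 iterations; the
full 55,000-iteration retention schedule is exercised on a small matrix,
where the draw-count identity is exact regardless of scale. The 116-ROI
paths (top-quartile cardinality 29, 128-head extraction, atlas labels)
are tested at full width since they are cheap.

## Known limitations

* The classifier is binary; multi-group comparisons must be run
  pairwise.
* Mapper output depends on cover and cutoff choices; defaults are
  sensible for 2-D embeddings of ~100 points but are not universal.
* The LSIRM assumes homoscedastic Gaussian residuals on CV scale; heavy
  tails would call for a robust likelihood the package does not provide.
* Oblique rotation changes origin distances; conclusions should be drawn
  from the aligned configuration, using the rotation for display.
* No convergence diagnostics beyond acceptance rates and retained draws
  are produced; for publication-grade inference run multiple seeds and
  compare aligned posterior means.
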
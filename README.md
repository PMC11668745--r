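# fcnfusion

Identify which brain-region connectivity features distinguish two
subject groups in resting-state fMRI, with an interpretable,
statistically pooled answer rather than a black-box accuracy number.

Per subject the input is an ROI-by-time BOLD matrix (116 AAL regions in
the standard atlas case). The package fuses three stages:

1. **Functional connectivity networks (FCNs).** Pearson / Fisher-z
   correlation matrices, and binary FCNs built by the Mapper algorithm
   (overlapping cover + partial clustering + nerve graph) over 2-D
   embeddings of the ROI time courses — linear (PCA), stochastic
   (t-SNE), or topological (UMAP-style; defaults 15 neighbors, minimum
   distance 0.1).
2. **Self-attention classification and attention extraction.** A
   single-layer multi-head self-attention network (default H = 128
   heads, d_k = 2, dropout 0.9, batch 8, Adam at 0.01, 10-fold CV)
   classifies subjects into the two groups. Each subject's head-averaged
   attention distribution matrix `attnM = (1/H) Σ_h softmax(Q_h K_h' /
   √d_k)` is row-stochastic with one row per ROI. Per-ROI coefficients
   of variation form the group representative matrix **X**_g ∈
   R^(N_g × 116), and an unweighted rank-sum over high mean CV and high
   mean attention selects the top quartile — 29 of 116 ROIs per group.
3. **Latent space item-response model (LSIRM).** Each group matrix is
   fit with the continuous LSIRM

   y_ij ~ Normal(θ_j + β_i − ‖u_j − v_i‖, σ²),

   by Metropolis-within-Gibbs MCMC (defaults: 55,000 iterations, 5,000
   burn-in, thinning 5 → exactly 10,000 retained draws; jump scales
   0.005/0.005/0.005/0.003; Inv-Gamma(0.001, 0.001) variance priors;
   N(0,1) priors on β and the latent positions). Draws are
   Procrustes-aligned, optionally oblimin-rotated, and ROIs are ranked
   by origin proximity: regions whose latent positions sit near the
   origin interact consistently with every subject of the group. Crossing
   the two groups' top lists with their near-origin flags categorizes
   each ROI as `both`, `more_reactive` in one group, `only` in one
   group, or `none`, rendered on group summary networks thresholded at a
   connectivity ratio of 0.2.

A synthetic cohort generator (group-specific block correlations, AR(1)
time structure) and an item-response generator with a full ground-truth
record make every stage testable without access-controlled imaging data.

## Worked example

Thirty synthetic subjects, 16 ROIs in two blocks: the "patient" group
co-fluctuates strongly in block 1 (ROIs 1–8, within-block correlation
0.7 vs 0.2), the "control" group in block 2 (ROIs 9–16).

```r
library(fcnfusion)

spec <- cohort_spec(n_rois = 16, n_timepoints = 120,
                    n_subjects_per_group = c(patient = 15, control = 15),
                    block_partition = rep(1:2, each = 8),
                    within_block_corr_by_group = list(c(0.7, 0.2),
                                                      c(0.2, 0.7)),
                    seed = 1)
cfg <- pipeline_config(
  cohort = spec, input_type = "pearson",
  attn = attn_config(n_heads = 8, d_k = 2, dropout = 0.5,
                     max_epochs = 40, patience = 8, cv_folds = 5),
  mcmc = mcmc_config(n_iterations = 20000, burn_in = 4000, thin = 4,
                     jump_theta = 0.05, jump_beta = 0.05,
                     jump_u = 0.05, jump_v = 0.05),
  seed = 7)
report <- run_pipeline(cfg)

report$cv_accuracy
#> [1] 1
report$top_rois
#> $control
#> [1] "ROI_011" "ROI_013" "ROI_010" "ROI_009"
#> $patient
#> [1] "ROI_002" "ROI_004" "ROI_003" "ROI_008"
report$categories
#> $none: 8   $only_control: 4   $only_patient: 4
report$acceptance$patient
#>  theta  beta     u     v
#>   0.26  0.26  0.22  0.19
```

Reading the numbers: cross-validated accuracy 1.0 says the attention
matrices carry real group signal, so stage 2's summaries are worth
interpreting. Each group's top-quartile list (floor(0.25 × 16) = 4 ROIs)
falls entirely inside that group's planted high-correlation block, and
the three-way categorization marks them `only_patient` / `only_control`
with the remaining 8 ROIs `none` — the planted difference, recovered
end-to-end. MCMC acceptance rates in the 0.2–0.4 band indicate a healthy
chain. With `out_dir` set, every intermediate artifact (cohort CSVs,
attention matrices, group matrices, posterior draws, summary networks as
GraphML/CSV, a categorized-network PDF and `report.json`) is written
under `out_dir/step{1,2,3}`.

A command-line front end wrapping the same functions ships in
`inst/cli/fcnfusion.R` with subcommands `simulate`, `build-fcn`,
`train`, `group-matrix`, `lsirm`, `summarize`, `run-all`.

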
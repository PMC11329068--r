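# fusionesi

Multi-modal electrophysiological source imaging (ESI): reconstructing
cortical source amplitudes from simultaneous EEG and MEG scalp measurements
with a dual-branch attention fusion network, benchmarked against classical
minimum-norm inverse solvers. For researchers studying EEG/MEG inverse
methods who want a fully self-contained, reproducible desk-scale testbed:
every experiment runs from a seed on an analytic spherical head model, with
no external data.

## The problem and the model

The forward model is linear, `Y = L S + ε`: `Y` (C×K) are sensor
measurements, `L` (C×N) the leadfield, `S` (N×K) source amplitudes. With
C ≪ N the inverse problem is ill-posed. Classical solvers regularize,

    Ŝ = argmin_S ½‖Y − LS‖²_F + λ R(S),

giving MNE (`L'(LL' + λI)⁻¹Y`), sLORETA (resolution-standardized) and dSPM
(noise-normalized), here fused across modalities by SNR whitening. The
learned alternative maps topographic encodings of the EEG and MEG
snapshots through two dilated-convolution branches with channel attention
(`w = σ(W₂ δ(W₁ z))`, `z` the per-map global averages), concatenates the
gated features, and decodes source amplitudes with a fully connected head.
Training minimizes

    L = L_mse + α L_t,   L_t = 1/N² Σ_k ‖E_k ⊙ M‖²_F,  E_k = e_k e_kᵀ,

where `e_k` is the error vector and `M` weights region pairs by mesh
geodesic distance (`m_ij = tanh(ρ d_ij)` below a threshold τ, 1 beyond,
0 on the diagonal) — remote mislocalizations cost more than local
amplitude errors. Defaults α = 0.05, ρ = 0.005, τ = 100 mm.

Performance is scored by geodesic localization error (LE, mm) and the area
under the precision-recall curve (AUPRC) of patch-membership ranking.

## Worked example

```r
library(fusionesi)

# simulate: 162-source icosphere, 32 EEG + 64 MEG channels, extended
# sources (LNs = 3) at 30 dB SNR, disjoint train/test centers
ds <- build_dataset(sim_config(seed = 1, reps_per_center = 12))
ds
#> <sample_set> 1680 samples (test=240, train=1008, val=432), N=162 regions

# train the fusion network with the topological loss
M   <- topology_matrix(ds$head$D, rho = 0.005, tau = 100)
net <- fusion_model(fusion_descriptor(grid = c(16, 16), n_out = 162), seed = 11)
fit <- train_fusion_model(net, split_samples(ds, "train"),
                          split_samples(ds, "val"),
                          loss_config(M, alpha = 0.05), epochs = 20, seed = 1)

# evaluate against the classical solvers on the held-out centers
rec <- run_experiment(ds, methods = c("fused", "sloreta", "mne"), fit = fit)
summarize_experiment(rec)
```

On this configuration (20 epochs, one desk CPU, ~5 minutes of training)
the fused network reaches a mean test AUPRC of about 0.97 and a mean LE of
about 13 mm — an order of magnitude under the ~134 mm random-guess floor
of this source space, and well under the diffuse minimum-norm baselines.
Numbers move a few percent with seed and BLAS threading; directions do
not.

`autoplot(fit)` shows the loss history; `autoplot(rec)` boxplots LE by
method; `tidy(fit)` / `glance(fit)` give broom-style summaries. The
nine-cell ablation (`run_ablation()`) and the hyperparameter search
(`tune_hyperparameters()`) follow the same pattern. A command-line
interface for the whole pipeline lives at `inst/cli/fusionesi`
(`simulate | train | evaluate | ablate | tune | localize`).

## Scope

Spherical analytic head models only (no BEM/FEM); single-snapshot samples
(no time series); magnetometer MEG only; beamformer/ADMM/ConvDip
comparisons out of scope. See `vignettes/methods.Rmd` for the full model
description, design decisions and limitations.
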
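---
title: "Multi-modal source imaging with attention fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal source imaging with attention fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Electrophysiological source imaging (ESI) reconstructs cortical current
sources from scalp EEG and/or MEG. The forward model is linear,

$$Y = L S + \varepsilon,$$

with $Y \in \mathbb{R}^{C \times K}$ the sensor measurements, $L \in
\mathbb{R}^{C \times N}$ the leadfield, $S \in \mathbb{R}^{N \times K}$ the
source amplitudes and $\varepsilon$ measurement noise. Because $C \ll N$ the
inverse problem is ill-posed; classical solvers regularize it,

$$\hat S = \arg\min_S \tfrac12 \lVert Y - LS \rVert_F^2 + \lambda R(S),$$

with the $\ell_2$ penalty giving the minimum-norm estimate (MNE) and its
standardized variants sLORETA and dSPM. This package instead learns the
inverse map directly: a dual-branch convolutional network with channel
attention consumes topographic encodings of simultaneous EEG and MEG
snapshots and outputs the $N$ source amplitudes, exploiting the physical
complementarity of the two modalities (in a spherical conductor MEG is
exactly blind to radially oriented dipoles, while EEG sees both
orientations). The classical solvers are retained as baselines and as
oracles for the test suite.

## The head model the simulator emulates

Real ESI studies build $L$ from MRI-derived boundary-element models. Here
the head is an analytic sphere: sources sit on a subdivided icosahedron
(162 dipoles at two subdivisions, radius 8 cm), EEG uses the closed-form
potential of a dipole in an unbounded homogeneous conductor with average
reference, and MEG uses the single-sphere (Sarvas) field projected on radial
magnetometer normals. Sensors are laid out on Fibonacci spirals (32 EEG at
10 cm, 64 MEG magnetometers at 12 cm) — near-uniform and free of the exact
symmetries that could make leadfield columns collinear.

Two deliberate simplifications matter when extrapolating to real data:

* **Geometry.** A sphere has no skull anisotropy, no cortical folding and
  no depth asymmetry; localization is easier than on a real cortex. Passing
  the end-to-end tests shows the method works where the forward physics is
  exact, not that it reaches any particular accuracy on BEM models.
* **Dipole orientations.** We default to *random* unit orientations rather
  than surface normals. On a sphere, radial (normal) orientations would
  silence MEG entirely and void the fusion question; random orientations
  emulate the mixed radial/tangential character of folded cortex. A
  `"radial"` option exists and is what the MEG-nullity tests use.

An import path for externally computed forward models (CSV leadfields, with
the canonical 59-channel EEG / 102-magnetometer MEG / 1984-source shapes of
the standard BEM reference model) exists for realistic-head reproductions;
it is exercised in the tests with synthetic stand-in files only.

## Extended sources and the simulator

An extended source is a patch: a center region plus rings of graph
neighbors up to the "level of neighborhoods" LNs $\in \{1,2,3\}$, with
activation intensities 100%, 85%, 70%, 55% of the central amplitude for
rings 0–3. Ring membership is graph-hop distance on the mesh. The central
amplitude is normalized to 1; the network learns relative spatial patterns.
Multi-source configurations draw centers with a minimum pairwise geodesic
separation (default $2(\mathrm{LNs}+1)$ mean edge lengths, enough to keep
patches disjoint) and resolve any overlap by maximum intensity.

Per sample, the clean topography $Ls$ receives white Gaussian noise scaled
to a target SNR, $\mathrm{SNR} = 10\log_{10}(P_{signal}/P_{noise})$ with
powers taken as mean squared amplitude; noise is drawn independently per
modality, which is the stricter reading of jointly simulated EEG/MEG. Each
modality's channel vector is z-scored before encoding so volts and tesla
enter the network on a common scale. Samples are single snapshots ($K=1$):
the topographic input encodes one time instant, so time series are out of
scope. The study conditions are 120 training and 20 test center regions
(disjoint by construction — the desk-scale version of the full
no-source-overlap protocol with 1600 train and 50 test regions out of
1984), all three extents LNs ∈ {1, 2, 3} at 30 dB, and 4 noise
realizations per (center, LNs) cell — 1440 train/validation samples and
240 test samples. Models train on all extent configurations jointly and
are scored per condition. The train pool is split 70/30 into train and
validation, and every generated sample is used.

The generator is fully seed-deterministic, and serialized sample sets are
byte-identical across runs of the same configuration — the basis of the
reproducibility tests.

## Input encoding

Sensor topographies become 16×16 matrices (configurable) that preserve the
spatial layout: sensors are projected by an azimuthal-equidistant map about
the mean sensor direction (planar radius = angular distance from the pole,
so angular ordering is preserved), the projected points are Delaunay-
triangulated, and each grid cell inside the convex hull takes the
barycentric (piecewise-linear) interpolation of its triangle's channel
values; cells outside the hull are 0. The encoding is a fixed linear map of
the channel vector — exact at sensors, constant-preserving, and cheap (one
small matrix product per sample). The projection and interpolation schemes
and the grid resolution are free choices fixed here to standard
topographic-map practice; 16×16 keeps the downstream network at desk scale.
The triangulation is a small built-in Bowyer–Watson implementation, written
because no installed package provides planar Delaunay triangulation.

## The network

Per branch: two dilated 3×3 convolutions (16 then 32 filters, dilation 2,
'same' padding, ReLU) — dilation expands the receptive field without extra
depth, and dilation 1 recovers plain convolution for the ablation. Then
channel attention: descriptors $z_c = \bar u_c$ (global average per feature
map) pass through a two-layer bottleneck $w = \sigma(W_2\,\delta(W_1 z))$
with reduction ratio $r = 4$, ReLU $\delta$, sigmoid $\sigma$, and no bias
terms (the classical squeeze–excite form); each map is scaled by its gate.
The weighted maps are flattened, the two branch vectors concatenated, and
a fully connected module (hidden width 512, ReLU; linear output) maps the
fused feature to the $N$ source amplitudes. The output is unconstrained
real: ground truth is nonnegative and the losses penalize negativity, so no
output nonlinearity is imposed. The two branches share hyperparameters but
not parameters. There is no canonical depth/filter recipe for this model
family, so the descriptor above is this package's own desk-scale default,
and every piece of it is configurable.

Everything is implemented directly in R: convolutions as im2col matrix
products (BLAS does the work), backpropagation by hand, and Adam with a
small compiled kernel for the in-place parameter update (the update touches
every parameter each step and dominates runtime if done with copying
semantics). Gradients are verified against finite differences in the test
suite, both for the loss with respect to the estimate and for network
weights.

## Losses

The objective is $\mathcal{L} = \mathcal{L}_{mse} + \alpha \mathcal{L}_t$
with

$$\mathcal{L}_{mse} = \frac1K \sum_{i=1}^K \lVert s_i - s_i' \rVert_2^2,
\qquad
\mathcal{L}_t = \frac{1}{N^2} \sum_{i=1}^K \lVert E_i \odot M \rVert_F^2,
\quad E_i = (s_i - s_i')(s_i - s_i')^T,$$

and the transformation matrix

$$m_{ij} = \begin{cases} 0 & i = j\\ \tanh(\rho\, d_{ij}) & j \in \Omega_i\\
1 & \text{otherwise,} \end{cases}$$

where $d_{ij}$ is the mesh geodesic distance (Dijkstra on the edge graph,
millimeters) and $\Omega_i$ the regions closer than a threshold $\tau$.
$\mathcal{L}_t$ masks the diagonal of the outer-product error matrix — a
pure amplitude error at the correct location costs nothing — and weights
cross terms by distance, so a point mass reconstructed one ring away costs
$2\tanh(\rho d)^2/N^2$ and the penalty grows monotonically with the
displacement ring. Three conventions fixed here:

* $\mathcal{L}_t$ *sums* over the $K$ snapshots while the MSE term
  averages — an asymmetry of the definition that we keep deliberately;
  with the $K = 1$ samples used throughout, the two conventions coincide.
* $\tau$ (the $\Omega_i$ radius) is never stated; we default to 100 mm,
  chosen so that with the default $\rho = 0.005$ the smooth branch stays
  below $\tanh(0.5) \approx 0.46$ and the saturated branch only applies to
  genuinely remote pairs. It is exposed in the configuration.
* Defaults $\alpha = 0.05$, $\rho = 0.005$ keep the spatial penalty a
  gentle regularizer next to the MSE term; the hyperparameter search explores $(0.001, 1)^2$
  log-uniformly, evaluating the defaults as trial 1 and using mean
  validation AUPRC as the objective. A sequential model-based optimizer
  could be plugged in; seeded random search is the shipped strategy, which
  at desk scale explores the 2-D space adequately.

Distances are computed on the mesh edge graph, not as exact polyhedral
geodesics — matching how the localization-error metric is defined — and all
geometry is meters internally with millimeters at the API boundary.

## Training

Adam (lr $10^{-3}$), mini-batches of 64, up to 50 epochs with early
stopping on validation loss (patience 20), best-validation parameters
restored. Batch 64 rather than 32 because the per-step cost is dominated by
parameter-array traffic, which is independent of batch size; doubling the
batch nearly halves wall-clock per epoch on CPU at no observed cost in
final loss. He/Glorot initialization, everything seeded: the same seed and
configuration reproduce the loss trajectory to numerical noise
(single-threaded BLAS exactly; multi-threaded BLAS to reduction-order
noise). Divergence (non-finite loss) aborts with a diagnostic rather than
returning garbage.

## Baselines

MNE is the closed form $L^T(LL^T + \lambda I)^{-1} Y$; sLORETA standardizes
the MNE estimate by the resolution variance $R_{ii}$, $R = L^T(LL^T +
\lambda I)^{-1} L$ (nonnegative, and provably zero localization error for
noiseless single dipoles — the test suite asserts this across every source
position); dSPM divides by the noise-projected standard deviation
$\sqrt{\operatorname{diag}(G \Sigma G^T)}$. EEG/MEG fusion for the
baselines uses the SNR transformation: each modality's rows of $Y$ and $L$
are divided by that modality's noise standard deviation (whitening to unit
noise variance) and the systems are row-stacked — the standard way to put
volts and tesla on a common signal-to-noise scale before a joint inverse. The regularization policy is
$\lambda = \operatorname{tr}(LL^T)/C \cdot \mathrm{SNR}^{-1}$ when the SNR
is known, else $10^{-2}$ of the mean sensor power — no policy is published,
so this standard choice is ours. Noise SDs are estimated from the known
target SNR of each sample, never from the ground truth.

## Metrics

* **Localization error (LE, mm):** geodesic distance from the region of
  maximum absolute reconstructed amplitude to the nearest true patch
  center; ties break to the lowest region index; an all-zero estimate is
  flagged and measured from region 1. For multi-source configurations LE
  reports the minimum over centers; AUPRC remains the primary multi-source
  metric.
* **AUPRC:** average precision of ranking patch members above non-members
  by absolute amplitude, computed by the tie-aware step-wise rule (not
  trapezoidal — the two differ, and the step-wise rule is the standard for
  imbalanced problems). Verified against an independent threshold-scan
  oracle to $10^{-9}$.

A useful floor: the mean pairwise geodesic distance is the expected LE of
a random guess (~134 mm on the 162-source sphere).

## The ablation grid

Nine cells M1–M9: modality in {EEG, MEG, EEG+MEG} × dilation {1, 2} without
the topological term, plus the three dilation-2 cells with it. Single-
modality cells feed that modality's encoding to both branches, keeping the
architecture (and parameter count) constant across cells; all cells share
the dataset, seed and schedule, so records are paired per test sample. The
directional expectations at desk scale: fusion should be no worse than
either single modality on mean LE, and any benefit of the topological loss
should show most clearly for single-modality EEG.

## Problem sizes and runtime choices

The shipped study conditions (162 sources, 32+64 channels, 1440 training
samples; the full descriptor trained ~15 epochs at batch 128 for headline
accuracy, and a compact descriptor — 8/16 filters, 128 hidden units —
trained 30 epochs for the modality/loss ablation comparisons, which need
converged models more than they need capacity) were chosen so a full
end-to-end run — simulate, train, evaluate, ablate — completes in minutes
on a single CPU; they are the package's definition of "desk scale". Larger
spaces (more subdivisions, more channels, deeper stacks) are a matter of
configuration, not code.

## Known limitations

* Spherical geometry only; no BEM/FEM, no depth weighting; MEG is
  magnetometer-only (no gradiometer model).
* Single-snapshot samples; no temporal dynamics or correlated multi-patch
  activity; white noise only, no structured covariance.
* The network descriptor is this package's own desk-scale design;
  absolute accuracy numbers are specific to the spherical toy model and
  do not transfer to cortical head models — only the directional findings
  should be expected to carry over.
* Beamformer (MCMV), ADMM and ConvDip-style comparison methods are out of
  scope.
* At the written $1/N^2$ scaling, the topological term's gradient is a
  tiny perturbation of the MSE gradient for desk-scale $N$ and the default
  $\alpha$, $\rho$: it provably vanishes for on-target amplitude errors
  and grows with displacement (the test suite asserts both), but its net
  effect on trained-model localization is within run-to-run optimization
  noise. Users wanting a materially stronger spatial penalty should raise
  $\alpha$ and $\rho$, or drop the $1/N^2$ normalization in their own
  loss configuration.
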
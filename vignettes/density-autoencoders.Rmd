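---
title: "Density-regularized auto-encoders for heart-sound anomaly detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-regularized auto-encoders for heart-sound anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgdense)
```

## The problem and the model

Phonocardiogram screening has to work where labeled pathologies are scarce:
abnormal heart sounds span murmurs, ectopic beats, missing components and
more, and no training set covers them all. `pcgdense` therefore treats the
task as outlier detection — learn a compressed representation of *normal*
recordings with an auto-encoder and score recordings by how badly the model
reconstructs them.

The classical unsupervised baseline is the β-VAE, whose KL term pulls the
latent posterior toward `N(0, I)`. That prior is questionable for heart
sounds pooled from several collection sites (different stethoscopes, noise
floors, populations): the latent distribution of normal recordings is more
plausibly a mixture than a single Gaussian. The density-based variants keep
the reconstruction objective but replace prior matching with a direct
penalty on latent spread:

* centroid: `c_i = (max_j z_ij + min_j z_ij) / 2` — the per-dimension
  **midrange**, anchored by the edge samples of the batch rather than its
  mean;
* density: `D = (1/N) Σ_j ‖Z_j − C‖₂`, the mean Euclidean distance to that
  centroid;
* loss: `L = L_r + β·D` (DBVAE keeps Gaussian reparameterization during
  training; DBAE is fully deterministic).

`D` is a dispersion — smaller means denser — so minimizing `L` shrinks the
latent cloud toward the centroid without dictating its shape. During
training `C` and `D` are computed on the current mini-batch (the natural
stochastic estimate; the full-dataset version is used only for
diagnostics). The midrange is not differentiable at ties; we use the
standard subgradient convention, splitting the centroid's sensitivity
equally between the per-dimension argmax and argmin samples. The tests
verify this subgradient against numerical differentiation at generic
points.

Anomaly scoring is reconstruction MSE per super-frame, averaged per
recording, and evaluation is ROC/AUC with abnormal as the positive class —
deliberately threshold-free. β-sensitivity is summarized as
`δ = AUC_best/AUC_worst − 1` across β ∈ {0.01, 0.1, 1, 10, 100}.

## Preprocessing choices

Recordings are standardized to 6 s (truncate long, wrap-pad short — the
padding repeats the signal, preserving periodicity rather than inserting
silence). Features are 14-band log-Mel spectrograms at 2 kHz with window
1024 and hop 512 and no center padding, so a 6-s recording has
`L = 1 + floor((12000 − 1024)/512) = 22` frames; sliding windows of 5
frames give 18 super-frames of dimension 70. Specific conventions the
pipeline pins down, chosen once and enforced by tests:

* Mel energies pass through `log(x + 1e-10)`; the floor only matters for
  digital silence.
* Per-band standardization uses the population standard deviation with a
  `1e-8` guard; constant bands map to zeros instead of dividing by noise.
  This removes static per-band coloration (device/site bias) — by design a
  pure spectral tilt between domains is invisible after standardization,
  and domain identity instead shows through the burst-to-noise contrast.
* Super-frames are flattened row-major (each band's five frames
  contiguous); the models only ever see the flattened 70-vector, so the
  layout is a convention, fixed by one test.

## Model architecture and training

No deep-learning framework is assumed: the encoder/decoder stacks,
reparameterization, both losses and Adam are implemented directly in base
R, which keeps the computation transparent and the whole fit reproducible
from a single integer seed (initialization, shuffling and latent draws all
come from one stream).

Defaults: encoder 70 → 128 → 64 → latent 8 with ReLU hidden layers and a
linear head (variational kinds emit mean and log-variance), mirrored
decoder; Adam at learning rate 2e-3, batch 256, 300 epochs. The widths and
schedule were chosen so that training *converges* on the bundled synthetic
study (~1600 super-frames): with a 64–32 network and 100 epochs the
reconstruction loss is still falling and anomaly scores are dominated by
optimization noise rather than by the data, which masks every comparison
built on top. Convergence, not capacity, is the binding constraint at this
scale. Inference always decodes from the deterministic encoder output
(means for the variational kinds), so scores are reproducible; sampling
exists only in the training graph of BVAE/DBVAE.

With β = 0 the DBAE reduces *exactly* to a plain auto-encoder — same RNG
consumption, same trajectory — which the tests use as an ablation identity.

## The synthetic study

The generator emulates the statistical structure the method relies on, not
cardiac physiology:

* **Normal structure**: per cardiac cycle an S1 burst (unit amplitude) and
  an S2 burst (amplitude 0.7) after 35% of the cycle. Bursts are damped
  (40 s⁻¹) harmonic stacks — carrier plus components at 2.2×, 4.1×, 7.3×
  with weights 0.5/0.25/0.12 — because real heart sounds are broadband
  transients; with pure low-frequency tones most Mel bands would carry
  only noise and reconstruction error would be uninformative.
* **Domains**: two default "sites" differing in noise level (σ 0.05 vs
  0.08), spectral tilt (±0.4) and typical heart rate (70 vs 85 bpm, ±8
  jitter per recording), mimicking pooled multi-source corpora.
* **Anomalies**, all local in time and scaled by a strength parameter with
  an exact zero-strength identity: systolic band noise at 100–400 Hz
  (murmur, relative amplitude 0.4), an extra mid-diastolic burst
  (ectopic), or S2 attenuation (missing S2).

The default study is 90 normal and 30 abnormal recordings, 90/10
recording-level split, and it is what the end-to-end tests run: the DBAE at
its best swept β separates held-out abnormals at AUC ≥ 0.8, and the final
latent density decreases monotonically in β. What this does **not** show:
performance on real stethoscope recordings (sensor artifacts, respiration,
within-recording rate variability and genuine murmur taxonomy are absent),
or any cross-family ranking — at this problem size the DBAE/DBVAE/BVAE
ordering varies with the seed, so the tests log it without asserting it.

A known limitation worth stating: among the three anomaly kinds the murmur
is by far the hardest at the default noise level. Loud band noise *raises*
the variance of the affected Mel bands, and after per-band standardization
that rescaling partly cancels the novelty of the pattern, pushing murmur
scores toward the normal range (timing anomalies remain easy). This is a
property of standardized log-Mel reconstruction error, not of the density
penalty.

## Numerical conventions and degenerate inputs

* AUC is computed from average ranks, equivalent to all-pairs Mann–Whitney
  with ties counted ½; a single-class test set is an error, never an NA.
* `δ` requires `0 < AUC_worst ≤ AUC_best`; ties across β resolve toward
  the smaller β (prefer the weaker regularizer when indifferent).
* The published-reference δ table is reproduced from best/worst AUCs; the
  literal ratio of the β values themselves is exposed as a secondary
  column (`beta_ratio`) for inspection, as the two disagree and only the
  AUC form matches the published table.
* Latent moments use biased 1/N central moments exactly as defined
  (`γ₁ = m₃/m₂^{3/2}`, `γ₂ = m₄/m₂² − 3`), per latent dimension, then
  mean ± sd across dimensions; zero-variance dimensions are excluded with
  a warning rather than polluting the summary with NaN. Pooling all
  dimensions into one vector is possible via `latent_moments(NULL, Z)` on
  a flattened matrix, but the per-dimension reading is the default since a
  mixture in one dimension should not be averaged away by seven others.
* Single-sample latent batches are legal (`D = 0`), so the final partial
  mini-batch never needs special-casing.
* Training aborts with a diagnostic on a non-finite loss instead of
  returning a silently broken model.

## Problem sizes

The bundled studies are desk-scale by design: 120 six-second recordings
(2160 super-frames), 70-dimensional inputs, 8-dimensional latents, and a
15-model sweep (3 families × 5 β values) that completes in a few minutes on
one CPU core. Every quantity in the README and in the acceptance checks is
computed at these sizes.
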
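---
title: "Methods: two-pool UTE-qMT simulation, fitting and denoising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-pool UTE-qMT simulation, fitting and denoising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uteqmt)
```

## The measurement and the model

Cortical bone contains a small free-water proton pool (pool *a*) coupled by
magnetization exchange to a macromolecular proton pool (pool *b*) whose
transverse relaxation is far too fast (T~2b~ ≈ 15 µs) to observe directly.
Quantitative magnetization transfer (qMT) imaging estimates the composition
and kinetics of this system by saturating the macromolecular pool with
off-resonance pulses at several powers and offset frequencies and watching
how much free-water signal survives; ultrashort-echo-time (UTE) readouts
make the experiment feasible in bone, where even the free pool has
T~2a~ < 1 ms.

The binary spin bath model describes each voxel by seven parameters: the
free-pool size M~0a~, longitudinal rates R~1a~ and R~1b~, the forward
exchange rate k~ab~, the macromolecular fraction
MMF = M~0b~/(M~0a~ + M~0b~), and the two transverse relaxation times T~2a~
and T~2b~. Two of these are not independently identifiable from an MT
experiment and are handled conventionally:

* R~1b~ is fixed to 1 s⁻¹ (`tissue_params(..., r1b = 1)`), the standard
  convention for macromolecular pools;
* R~1a~ is derived from the observed mono-exponential T~1~ by inverting the
  two-pool eigenvalue problem (`derive_r1a()`): the measured R~1obs~ is the
  slow eigenvalue of the coupled relaxation–exchange system, so
  R~1a~ = R~1obs~ − k~ab~(R~1b~ − R~1obs~) / (R~1b~ − R~1obs~ + k~ba~),
  with k~ba~ = k~ab~(1 − MMF)/MMF by detailed balance (`derive_kba()`).

A property test confirms the round trip: with R~1a~ so derived, the slow
eigenvalue of the 2×2 relaxation–exchange matrix reproduces 1/T~1obs~ to
10⁻⁶ relative.

## Pulsed saturation: the rectangular-pulse approximation

Shaped MT pulses are replaced by rectangles of equal average power
(`omega1_rms()`): ω~1,rms~² = (1/τ)∫ω~1~(t)²dt. Each pool is then saturated
at the constant rate W = π·ω~1,rms~²·g(Δ), where g is the pool's absorption
lineshape at its T~2~ (`absorption_lineshape()`, `saturation_rates()`).
The macromolecular pool uses a Gaussian lineshape by default — the usual
choice for collagen-dominated short-T~2b~ tissue, and numerically benign at
the 2 kHz offset where the super-Lorentzian (also available, with a
divergence guard near resonance) blows up. The free pool is always
Lorentzian; tracking its transverse dynamics during the pulse is out of
scope, so direct saturation enters only through W~a~.

One MT cycle of the sequence is: a saturation segment of duration τ; a
train of `n_spokes` low-flip-angle excitations spaced by the inter-spoke
TR, each scaling the free-pool longitudinal term by cos(FA); and free
recovery to fill the cycle TR. Every segment is an affine linear ODE flow,
solved exactly by closed-form 2×2 matrix exponentials (compiled code in
`src/`), and the periodic steady state solves
M~ss~ = P~cycle~M~ss~ + c~cycle~. The reported signal is sin(FA) times the
mean free-pool magnetization immediately before each spoke — center-out
radial readouts share the k-space center across spokes, so the acquired
contrast is the spoke average; a first-spoke-only convention is available
(`first_spoke_only = TRUE`). An independent oracle — fine-step RK4
integration of the same piecewise-constant ODE at dt = 10 µs — agrees with
the closed-form steady state to better than 0.5 % over the whole phantom
grid (in practice to ~10⁻¹²).

### Defaults the experiment does not pin down

Several acquisition details needed by the simulation are decisions, not
measured facts, and are all configurable in `mt_protocol()`:

* **Pulse envelope and duration**: Fermi shape (plateau with 2 %-of-duration
  transition bands), τ = 8 ms — a typical MT preparation pulse; only its
  rms power enters the RP model.
* **Timing**: the bone-protocol readout values, TR = 86 ms, 13 spokes,
  5 ms inter-spoke TR, 10° excitation, are used for the digital phantoms as
  well, so the simulated and scanner paths share one protocol.
* **Lineshape**: Gaussian for pool *b*, as above.

## The digital phantom

`default_parameter_grid()` spans the cortical-bone ranges
(MMF 30–60 %, k~ab~ 10–60 s⁻¹, T~1obs~ 220–280 ms, T~2a~ 0.7–1.0 ms,
T~2b~ = 15 µs) with a factorial grid: MMF {0.30, 0.40, 0.50, 0.60} ×
k~ab~ {10, 25, 35, 47.5, 60} s⁻¹, with T~1obs~ = 240 ms and T~2a~ = 0.8 ms
held at the midpoint values so every chip shares the midpoint set
(MMF = 50 %, k~ab~ = 25 s⁻¹, T~1obs~ = 240 ms, T~2a~ = 0.8 ms) as a
neighbor; that midpoint set is also the fixed initial point of fitting.
Twenty 18×18-voxel chips tile a 4×5 layout (`generate_phantom()`); every
voxel of a chip carries the chip's exact 3-power × 5-offset spectrum
(powers 400°/800°/1200°, offsets 2/5/10/20/50 kHz).

**Noise.** Magnitude-image noise is Rician:
out = √((S + n₁)² + n₂²), n₁, n₂ ~ N(0, σ²), with a single σ for all
volumes, calibrated as σ = mean(reference volume)/SNR where the reference
is the lowest-power, largest-offset image (`add_rician_noise()`,
`measure_snr()`). The sweep grid {25, 50, 75, 100, 150, 200} covers every
reported SNR level.

What the generator emulates: piecewise-constant tissue chips, a shared
acquisition protocol, magnitude (Rician) noise at controlled reference SNR.
What it does not: anatomical geometry, partial-volume mixing, B~0~/B~1~
inhomogeneity, T~1~-measurement error, coil shading, motion. Passing tests
therefore validate the estimation pipeline under ideal acquisition physics,
not robustness to those confounds.

## Voxel-wise fitting

`fit_voxel()`/`fit_image()` minimize the sum of squared residuals between
the measured magnitudes and the forward model with bounded
Levenberg–Marquardt (trust-region-style) least squares (`minpack.lm`), the
R analogue of the reference analysis' `lsqcurvefit`. Free parameters are
(m~0a~, MMF, k~ab~, T~1obs~, T~2a~); with the fixed-T~1obs~ option (the
scanner-data convention, default 250 ms) four remain. No Rician-likelihood
correction is applied — least squares on magnitudes is the behavior under
study, and the low-SNR Rician floor bias is part of what the tool
measures.

Numerical choices:

* **Bounds** (unstated in the source analysis): MMF ∈ [0.01, 0.99],
  k~ab~ ∈ [0.1, 5×10³] s⁻¹, T~1obs~ ∈ [0.05, 2] s, T~2a~ ∈ [0.1, 5] ms,
  m~0a~ ∈ [0, 10 × reference signal]. Deliberately wide, so that the
  low-SNR instability of exchange-rate fits is reproduced rather than
  clamped away; `flag_unstable()` then excludes voxels with
  k~ab~ > 10³ s⁻¹ or k~ba~ > 5×10³ s⁻¹ from ROI statistics.
* **Initialization**: per-voxel ground truth or the fixed midpoint set.
  m~0a~ starts at the voxel's reference-condition signal mapped through
  the model's unit-m~0a~ baseline at the initial parameters. The raw
  reference signal itself is ~sin(10°) × (steady-state fraction) ≈ 0.14 of
  m~0a~ here; starting m~0a~ an order of magnitude low pushes noiseless
  fixed-init fits of corner chips into bound-adjacent local minima, while
  the rescaled start recovers every chip exactly. If the initial
  parameters are physically inconsistent (derived R~1a~ ≤ 0), the mapping
  falls back to sin(FA).
* **Convergence**: ftol 10⁻¹⁰, 60 iterations. Raising the cap to the
  reference default (400) changes nothing measurable at any SNR tested.
* **Failure policy**: optimizer failures are recorded per voxel
  (`converged`, NaN map entries), never fatal.

Identifiability: MMF and the exchange rates are not independent in this
model. In noisy fits the voxel-wise MMF and k~ab~ errors form a strongly
anisotropic cloud (positively correlated here), with the reverse rate
k~ba~ = k~ab~(1 − MMF)/MMF carrying the compensating (negative)
correlation — overestimated MMF divides k~ba~ down.

## Denoising

`mppca_matrix()` implements Marchenko–Pastur PCA on a patch matrix: with
eigenvalues λ~i~ = s~i~²/Q sorted descending (Q the larger matrix
dimension, R the smaller), the smallest retained-signal count p satisfies
λ~p+1~ − λ~R~ ≤ 4√((R−p)/Q)·mean(λ~p+1~…λ~R~) — the spread of the tail
does not exceed the MP support width at the tail-mean variance. The tail
mean at the accepted p is the noise-variance estimate. Eigenvalues below
10⁻¹⁴·λ~1~ are treated as numerically zero so that exactly low-rank input
is returned unchanged.

`tmppca()` applies this patchwise to the tensor
(window voxels × powers × offsets) with a sliding 3×3 spatial window for
2-D phantoms (the 3-D analogue of the 3×3×3 volume window), spatial mode
first, then powers, then offsets. The short later modes (3 and 5
eigenvalues) are too small for an MP fit of their own: a pair of
comparable genuine components would be indistinguishable from noise by
spread alone, which on noiseless input visibly erodes chip edges. They are
therefore thresholded at the MP bulk edge σ̂²(1+√(R/Q))² implied by the
stage-1 noise estimate — conservative, since post-stage-1 noise is at most
that — and zero estimated noise passes the tensor through untouched.
Overlapping patch estimates are averaged by default (`aggregation =
"center_voxel"` keeps each center's own estimate). Conservation holds
exactly: input = denoised + removed.

`gaussian_baseline()` is the comparison filter: SD-1 (voxel) Gaussian
smoothing of each volume independently. It preserves constants and
interior values but blurs chip boundaries over roughly ±2 voxels, which is
precisely the contrast with tMPPCA the experiments quantify.

## Experiments and problem sizes

`run_snr_sweep()` crosses SNR levels × power subsets (3SP = 15 data
points; 2SP drops the middle power, 10 points) × initialization modes,
with per-chip ROI statistics (`roi_stats()`, mean ± SD across voxels of
one chip, the figure convention) and ground-truth error metrics
(`error_metrics()`). Exchange-rate rows below SNR 75 are flagged
unreported, matching the reporting convention for unstable fits.
`run_denoise_comparison()` fits raw, tMPPCA and Gaussian arms of the same
noisy phantom identically and attaches a spatially estimated SNR (mean
reference signal over within-chip SD, valid after denoising where the
injected σ no longer applies).

Sizes used by the bundled checks, chosen to keep a full run at desk scale
on one CPU: the reported-MMF comparisons fit all 324 voxels of the
midpoint chip over 5–8 noise seeds per condition (more at low SNR, where
the across-seed variance is larger); 20-chip sweeps fit centered 7×7
voxel blocks per chip; the denoising comparison fits 5×5 blocks over 5
seeds. Sub-sampling voxels within a chip changes only the number of
draws entering per-chip statistics, not their distribution, since noiseless
voxels within a chip are identical. Phantom figure-style tables default to
a single noise realization per condition, as in the source figures;
statistical assertions pool ≥ 5 realizations.

## Known limitations

* The forward model omits free-pool transverse dynamics during saturation
  (RP-model convention), relaxation during excitation pulses, and any
  B~0~/B~1~ or T~1~-error effects.
* Least squares on Rician magnitudes is deliberately uncorrected; at
  SNR ≲ 50 the noise floor biases MMF upward and destabilizes exchange
  rates — reproducing that behavior is the point, but absolute low-SNR
  bias levels depend on unstated acquisition details (pulse shape,
  duration, lineshape, fitting bounds) and on which chip a reported ROI
  actually covered, so they match reported values only approximately.
* The MP criterion assumes iid Gaussian noise within a patch; after the
  Rician transform this holds only approximately at very low SNR.
* The scanner-data path (NIfTI + sidecar, fixed T~1obs~) is exercised on
  phantom-derived stacks; no scanner data ship with the package.
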
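# uteqmt

Digital-phantom simulation and voxel-wise fitting for ultrashort-echo-time
quantitative magnetization transfer (UTE-qMT) imaging of cortical bone.

Bone qMT estimates the macromolecular proton fraction (MMF) and the
magnetization exchange rates between the free-water pool *a* and the
macromolecular pool *b* from MT-weighted images acquired at several
saturation powers and offset frequencies. Because exchange-rate estimates
are notoriously sensitive to image SNR, this package provides a fully
synthetic test bench with known ground truth: a two-pool (binary spin
bath) forward model, a digital bone-chip phantom generator with
SNR-calibrated Rician noise, bounded nonlinear least-squares parameter
mapping, tensor Marchenko–Pastur PCA (tMPPCA) denoising with a
Gaussian-filter baseline, and an experiment harness for SNR sweeps,
2-vs-3-power comparisons, initial-point sensitivity, and denoising
studies. It is aimed at MR physicists designing or validating bone qMT
protocols and analysis pipelines.

## The model

Each voxel follows the binary spin bath model under pulsed saturation in
the rectangular-pulse (RP) approximation. The pools exchange longitudinal
magnetization with forward rate k_ab and reverse rate

    k_ba = k_ab (1 − MMF) / MMF,      MMF = M0b / (M0a + M0b),

and the free-pool relaxation rate is derived from the observed T1 by
inverting the two-pool eigenvalue problem:

    R1a = R1obs − k_ab (R1b − R1obs) / (R1b − R1obs + k_ba),
    R1obs = 1 / T1obs,  R1b = 1 s⁻¹ (fixed).

During an MT pulse of rms Rabi frequency ω1rms at offset Δ each pool is
saturated at W = π ω1rms² g(Δ), with a Gaussian lineshape at T2b = 15 µs
for the bound pool and a Lorentzian at T2a for direct free-pool
saturation. One sequence cycle — saturation, a 13-spoke UTE excitation
train, recovery — is a chain of exact affine matrix-exponential flows
whose periodic steady state gives the measured signal. See the methods
vignette (`vignettes/uteqmt-methods.Rmd`) for every default and the
reasoning behind it.

## Worked example

```r
library(uteqmt)

p <- tissue_params(mmf = 0.50, k_ab = 25, t1_obs = 0.240, t2a = 0.8e-3)
derive_r1a(p)       # 7.793 s^-1
derive_kba(p)       # 25 s^-1

proto <- mt_protocol()          # 400/800/1200 deg x 2/5/10/20/50 kHz
round(simulate_spectrum(p, proto), 2)
#>          2kHz  5kHz 10kHz 20kHz 50kHz
#> 400deg  11.45 12.15 12.62 13.47 13.81
#> 800deg   7.87  9.39 10.35 12.57 13.81
#> 1200deg  5.56  7.45  8.49 11.40 13.80

img   <- generate_phantom(phantom_spec(chips = list(p), chip_size = 18,
                                       layout = c(1, 1)))
noisy <- add_rician_noise(img, target_snr = 100, seed = 1)
noisy$noise_sigma   # 0.138 (= mean reference signal / 100)
measure_snr(noisy)  # 100

maps <- fit_image(noisy, fit_config(init_mode = "ground_truth"))
roi_stats(maps)
#>   parameter   mean     sd n_voxels n_excluded
#>         mmf  0.501  0.146      324          0
#>        k_ab 32.137 20.543      324          0
```

The spectrum shows the qMT contrast: signal drops with saturation power
and recovers with offset; the top-right entry (lowest power, largest
offset) is the SNR reference condition. At SNR 100 the fitted MMF is
accurate on average (0.501 vs 0.50 true) while k_ab is already visibly
noisy (32 ± 21 vs 25 true) — the SNR sensitivity of exchange-rate mapping
that the experiment harness quantifies. `tmppca()` denoises a noisy stack
patchwise; `run_snr_sweep()` and `run_denoise_comparison()` tabulate
per-chip statistics and ground-truth errors across conditions.

A thin command-line wrapper is installed as `exec/uteqmt` with
subcommands `simulate`, `noise`, `denoise`, `fit`, `evaluate` and
`reproduce` over NIfTI stacks with JSON sidecars; see `?cli_main`.

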
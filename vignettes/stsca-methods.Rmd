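---
title: "Spatiotemporal spike-centered averaging: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal spike-centered averaging: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stsca)
```

## The model

The package treats the cortical network under a recording electrode as a
linear time-invariant system: a spike at location $(x_i, y_i)$ and time
$t_i$ contributes a stereotyped spatiotemporal perturbation $f(r, \tau)$ to
the surrounding low-frequency LFP, and the measured LFP is the superposition
of those perturbations plus everything the spikes do not explain. Two
estimators recover $f$ from data:

* the **spike-triggered average**
  $C(\tau) = \frac{1}{N}\sum_i \mathrm{LFP}(t_i+\tau)$, the temporal
  cross-correlation between a multi-unit spike train (a sum of delta
  functions) and a single LFP trace;
* the **spatiotemporal spike-centered average**
  $C(\xi,\psi,\tau) = \frac{1}{N}\sum_i
  \mathrm{LFP}(x_i+\xi,\, y_i+\psi,\, t_i+\tau)$, its spatial extension, in
  which each spike's whole-array LFP frame is translated so the spiking
  electrode sits at the spatial origin before averaging.

On a $10\times10$ grid the translated frames land on a $19\times19$ lag
grid; because spikes occur at different electrodes, each lag cell receives a
different number of contributions $N(\xi,\psi,\tau)$, which the accumulator
counts explicitly and divides by. Lag cells never reached (the corners of
the $19\times19$ field, and anything removed by an exclusion mask) remain
undefined (`NA`) rather than zero.

A bounded-measurement argument links the two domains. An electrode spanning
$[-R, R]$ reports $\mathrm{UIR}(\tau)\approx\int_{-R}^{R} f(r,\tau)\,dr$,
i.e. the underlying kernel windowed by a rectangle; a bounded time epoch
$[-T, T]$ gives the spatial analogue. Since the Fourier transform of a
rectangle is a sinc, the special kernel $f(r,\tau)\propto\cos(kr\tau)$ (the
real part of $e^{jkr\tau}$ — a complex kernel cannot be a real voltage, so
the package uses its real part; both bounded integrals below hold for it)
yields

$$\int_{-R}^{R}\cos(kr\tau)\,dr = \frac{2\sin(kR\tau)}{k\tau}
  \propto \mathrm{sinc}(kR\tau/\pi), \qquad
  \int_{-T}^{T}\cos(kr\tau)\,d\tau \propto \mathrm{sinc}(kTr/\pi),$$

so a sinc in time predicts a (2D) sinc in space and vice versa.
`uir_temporal()`/`uir_spatial()` evaluate the integrals by adaptive
quadrature and the tests verify them against these closed forms to 1e-6
relative; `rect_sinc_check()` verifies the rect–sinc Fourier pair
numerically.

## Coordinate and sign conventions

* Grid positions are 0-based `(row, col)` internally; spatial lags are
  `(xi, psi)` = (column lag, row lag) in pitch units, so the tensor's
  1-based origin sits at index `(W, W, n+1)` with `W = max(rows, cols)`.
* `sinc(x) = sin(pi x)/(pi x)` (normalized); all kernel spatial scales are
  stated as the first-zero radius, which is convention-free. The first
  flanking extremum of a sinc sits at `1.4303` scales
  (`sinc_scale_for_ring()` inverts this).
* Negative LFP deflections are conventionally read as net excitation; the
  standard synthetic kernel therefore has negative amplitude, producing a
  central trough with a positive first ring.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| LFP band | 2–50 | Hz | standard low-frequency band for this analysis |
| MUA band | 300–3000 | Hz | unsorted action-potential band |
| detection threshold | 4 | SD below mean | conventional multi-unit threshold |
| detection dead time | 1 | ms | refractory-scale trough separation |
| frame rate | 1000 | Hz | a 2–50 Hz signal is fully represented at 1 kHz; ±5 s frames at 30 kHz would be needlessly large |
| lag window `window_s` | 0.1 (configurable; containers support ±5 s) | s | the informative structure lives in a sub-second neighborhood |
| τ integration window | ±0.035 | s | window over which the spatial component is integrated; a ±1 ms reading also exists in the field, so it is a user parameter |
| radial bin width | pitch (0.4) | mm | matches grid resolution; bins beyond 3.6 mm are flagged angularly incomplete |
| Rose threshold | 12 | dB | lower end of the conventional 12–14 dB (amplitude ratio 4–5) range |

## Numerical and design choices

**Filtering.** No IIR filter-design library is available in the target
environment, so `bandpass()` applies the 4th-order Butterworth *magnitude*
response in the frequency domain (with reflective padding against
wraparound). This is the steady-state equivalent of forward–backward
Butterworth filtering and is exactly zero-phase: a symmetric pulse keeps its
peak sample. A single-pass variant with the Butterworth phase is available
via `zero_phase = FALSE`.

**Detection statistic.** Mean and SD over valid samples of the whole
MUA-band trace (a median/MAD option exists). Computing SD over the full
recording rather than a baseline epoch slightly inflates the threshold when
firing is dense; this is documented rather than corrected. On dead-time
conflicts the deeper trough wins — deterministic and
amplitude-order-independent.

**Edge spikes.** Spikes whose lag window leaves the recording are dropped
entirely, never zero-padded or partially accumulated. This keeps the counts
independent of τ (when no mask is present) and makes the marginal identity
exact: at every τ, the count-weighted spatial sum of the st-SCA equals the
STA of the array-mean LFP. The identity is asserted to 1e-12 in the tests.

**Plus-minus normalization.** Spikes are split by parity of their 0-based
chronological index (the extra spike of an odd count goes to the even
half). The signal estimate is the full-data average; the noise estimate is
`(even - odd)/2`, scaled so that for iid per-frame noise of scale σ its rms
matches the residual noise of the full average (σ/√N). The calibration test
designs an rms ratio of 10 and recovers 20 ± 1 dB; both halves are full
accumulations, so the estimate inherits the counts structure.

**Whitening.** `fit_whitening()` uses the symmetric ZCA form
$W = E D^{-1/2} E^T$ with $D^{-1/2}_{ii}=\lambda_i^{-1/2}$; one published
description writes $D_{ii}=1/\lambda_i$ while verbally calling the factor
"inverse square roots of eigenvalues". The square-root reading is the one
that actually whitens ($WCW^T=I$, verified to 1e-8), so it is the default;
the full-inverse alternative is exposed through `eigenvalue_exponent = -1`.

**Radial reduction.** Bin means are contribution-count weighted: cells near
the field edge are estimated from few spikes, and unweighted means would let
them dominate. Weighting also makes the reduction conserve total weighted
mass and keeps the temporal marginal exactly equal to the array-mean STA.
Deviations from radial symmetry are deliberately ignored by the reduction,
but `radial_symmetry_score()` (SD of the four angular-quadrant means divided
by their absolute mean) is reported so the assumption can be checked.

**"Peak" of a pattern.** Control comparisons (spike-time randomization)
measure the pattern peak on the radially reduced, τ-integrated spatial
component rather than on raw tensor cells: sparsely hit cells (counts of
1–5) carry per-cell noise comparable to the kernel amplitude, so a raw
maximum reflects noise, not pattern. The binned, count-weighted profile is
the statistic the method itself reports.

## What the synthetic generator emulates — and what it does not

`simulate_recording()` draws multi-unit spikes (per-channel Poisson, or an
explicit schedule) on the 96-channel geometry and adds, for every spike,
a known kernel centered at that spike's electrode and time, plus Gaussian
noise (optionally spatially correlated with a stated length). The standard
world uses a −50 µV radial-sinc kernel with first ring at 1.25 mm (peak
separation 2.5 mm, the scale reported for sinc-like clinical patterns),
20 ms temporal scale, 1 kHz frames, and noise SD equal to the kernel
amplitude.

It does **not** emulate: non-stationary firing rates or waveform drift,
volume-conduction or biophysical forward models (kernels are
phenomenological), electrode artifacts beyond the user-supplied exclusion
mask, spike waveforms inside the LFP band (a separate MUA synthesizer
injects detectable −10 SD troughs for detection tests), or the tens of
thousands of spikes of clinical seizure recordings. A green test therefore
establishes that the estimator recovers a known LTI world correctly — not
that any particular biological claim holds.

Two calibration notes on test design:

* the sparse-sampling (8-of-96 electrodes) STA check runs in a
  moderate-noise world (noise SD 20 % of kernel peak, 500 spikes): an
  8-channel subset averages ~40 spikes, and at noise equal to the kernel
  amplitude the subset SNR is too low for any estimator — the property
  under test is spatial subsampling, not noise robustness;
* temporal-profile correlations are evaluated on the central ±35 ms window
  (the method's τ-integration default): outside the kernel's support the
  profile is identically zero and the correlation would only measure noise.

## Known limitations

* Pure-R accumulation: ~1000 spikes × 96 channels × 201 lags takes a few
  seconds; desk-scale, not streaming. Memory is the full
  `19 × 19 × (2n+1)` tensor.
* The frequency-domain filter is non-causal by construction; it is not
  suitable for real-time use.
* Containers are plain-text CSV/JSON (exact round trip via full-precision
  decimals); there is no HDF5 or vendor-format (NSx/NEV, NWB) reader. A
  conversion recipe: export signals as samples × channels CSV plus a
  `meta.json` with `fs_hz` and `channel_ids`.
* Geometries are rectangular grids with a present/absent mask; multi-shank
  or non-rectangular probes are out of scope.
* `randomize_spike_times()` preserves per-channel counts but not
  inter-spike-interval structure; it is a destruction control, not a
  rate-matched surrogate.
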
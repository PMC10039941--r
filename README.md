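# stsca

Spatiotemporal spike-centered averaging for gridded microelectrode array
(MEA) recordings.

## What problem this solves

Extracellular recordings mix two views of cortical activity: fast multi-unit
action potentials (MUA, 0.3–3 kHz) and the slower local field potential
(LFP, here 2–50 Hz). Their relationship is classically summarized in time by
the spike-triggered average

    C(tau) = (1/N) * sum_i LFP(t_i + tau)

which is the spike–LFP cross-correlation. On a gridded array such as the
96-channel, 4 mm × 4 mm Utah array (a 10 × 10 grid with empty corners),
spikes also carry a *location*. The spatiotemporal spike-centered average
(st-SCA) extends the STA with that spatial component:

    st-SCA(xi, psi, tau) = (1/N) * sum_i LFP(x_i + xi, y_i + psi, t_i + tau)

For each spike, the whole-array LFP frame is translated so the spiking
electrode sits at the spatial origin; translated frames are accumulated on a
19 × 19 lag grid (covering 4× the MEA area, lags up to ±3.6 mm), per-cell
contribution counts are kept, and the sum is divided by the counts. Cells
never hit (the lag-grid corners) stay undefined. Exploiting the pattern's
radial symmetry, the tensor reduces to polar form st-SCA(r, tau), whose
marginals give the temporal component (identical to the array-mean STA) and
the spatial component (a central trough with surrounding rings, for
sinc-like data).

The package is aimed at electrophysiologists analyzing mesoscale spike–LFP
structure (ictal recordings, MEA cultures, primate arrays). It includes:

- band-splitting (LFP / MUA), threshold spike detection (4 SD below the
  mean), array-mean LFP, decimation (`bandpass`, `detect_spikes`,
  `array_mean_lfp`, `decimate_lfp`);
- STA with subset and cross-population variants (`compute_sta`,
  `subset_sta`, `cross_population_sta`);
- the st-SCA accumulator with counts, plus-minus (even/odd) noise
  estimation, SNR in dB, Rose-criterion masking, spike-time randomization
  control, and ZCA spatial whitening (`compute_stsca`, `stsca_plus_minus`,
  `snr_db`, `rose_mask`, `randomize_spike_times`, `fit_whitening`);
- radial reduction, marginals, and ring-geometry quantification
  (`radial_reduce`, `marginals`, `peak_separation`);
- a synthetic MEA generator with known spike→LFP kernels and the
  rect↔sinc unit-impulse-response theory (`simulate_recording`,
  `kernel_spec`, `uir_temporal`, `uir_spatial`, `rect_sinc_check`);
- a pipeline/CLI front end over CSV/JSON containers (`run_pipeline`,
  `stsca_cli`, `inst/cli/stsca`).

## Worked example

Simulate the standard synthetic world — 96-channel array, 1 kHz LFP frames,
300 spikes each injecting a −50 µV radial-sinc kernel whose first ring sits
at 1.25 mm, white noise at the kernel amplitude — then run the full
analysis:

```r
library(stsca)

cfg <- list(
  seed = 1, window_s = 0.1, tau_window_s = 0.035,
  simulate = list(
    kernel = list(family = "radial_sinc_2d", amplitude_uv = -50,
                  spatial_scale_mm = sinc_scale_for_ring(1.25),
                  temporal_scale_s = 0.02),
    n_spikes = 300, separation_s = 0.25, noise_sd_uv = 50,
    kernel_support_s = 0.1))

out <- run_pipeline(cfg, "out", quiet = TRUE)
out$peaks$separation_mm    # 2.630332
out$summary$snr_db_global  # 1.212098
out$summary$control_peak_ratio  # 0.06316109
```

The peak separation of the spatial component is 2.63 mm — twice the 1.25 mm
first-ring radius of the injected kernel, recovered to within one 0.4 mm
radial bin. The global plus-minus SNR is low (~1 dB) because it is an rms
over *all* defined lag cells, most of which carry only noise at 300 spikes;
the per-cell map (`out$pm$snr_map_db`) shows the well-sampled center passing
the 12 dB Rose criterion first. The spike-time randomization control
collapses the spatial pattern to 6% of its original peak, confirming the
pattern is spike-locked rather than a property of the LFP alone.

The same run from the shell:

```sh
inst/cli/stsca run --config cfg.json --out out
```

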
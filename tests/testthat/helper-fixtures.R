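# Shared synthetic fixtures, built once per test run and cached.
# All seeds fixed; generator parameters state the simulated world
# (10x10 / 96-channel array at 0.4 mm pitch, 1 kHz LFP frames, sinc-shaped
# spike-LFP kernels of ~50 uV with a 1.25 mm first ring) and are never tuned
# against test outcomes.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

std_kernel <- function() {
  kernel_spec("radial_sinc_2d", amplitude_uv = -50,
              spatial_scale_mm = sinc_scale_for_ring(1.25),
              temporal_scale_s = 0.02)
}

# non-overlapping kernel injections, zero noise: the exact-recovery world
fixture_exact <- function() fixture("exact", function() {
  g <- mea_geometry()
  sched <- spike_schedule(g, 200, separation_s = 0.25, start_s = 0.3,
                          seed = 7)
  sim <- simulate_recording(sim_config(
    g, duration_s = max(sched$time_s) + 0.3, fs_hz = 1000,
    kernel = std_kernel(), seed = 7, spike_times = sched,
    noise_sd_uv = 0, kernel_support_s = 0.1))
  c(sim, list(geometry = g, kernel = std_kernel()))
})

# same world plus additive white noise at the kernel amplitude (SD = 50 uV)
fixture_noisy <- function(n_spikes = 1000, seed = 12, noise_sd = 50) {
  key <- paste0("noisy_", n_spikes, "_", seed, "_", noise_sd)
  fixture(key, function() {
    g <- mea_geometry()
    sched <- spike_schedule(g, n_spikes, separation_s = 0.25, start_s = 0.3,
                            seed = seed)
    sim <- simulate_recording(sim_config(
      g, duration_s = max(sched$time_s) + 0.3, fs_hz = 1000,
      kernel = std_kernel(), seed = seed, spike_times = sched,
      noise_sd_uv = noise_sd, kernel_support_s = 0.1))
    c(sim, list(geometry = g, kernel = std_kernel()))
  })
}

# space-time coupled cosine kernel, zero noise: the symmetry-demo world
fixture_cos <- function() fixture("cos", function() {
  g <- mea_geometry()
  ker <- kernel_spec("cos_rt", amplitude_uv = -40,
                     spatial_scale_mm = 0.55, temporal_scale_s = 0.07)
  sched <- spike_schedule(g, 300, separation_s = 0.25, start_s = 0.3,
                          seed = 3)
  sim <- simulate_recording(sim_config(
    g, duration_s = max(sched$time_s) + 0.3, fs_hz = 1000, kernel = ker,
    seed = 3, spike_times = sched, noise_sd_uv = 0, kernel_support_s = 0.1))
  c(sim, list(geometry = g, kernel = ker,
              k_rad = 1 / (0.55 * 0.07)))
})

# evaluate a kernel on the st-SCA lag grid (the ground truth tensor)
kernel_on_lag_grid <- function(ker, axes) {
  side <- length(axes$spatial_lags_mm)
  T_len <- length(axes$temporal_lags_s)
  truth <- array(0, c(side, side, T_len))
  psi <- matrix(axes$spatial_lags_mm, side, side)
  xi <- t(psi)
  for (k in seq_len(T_len))
    truth[, , k] <- eval_kernel(ker, xi, psi, axes$temporal_lags_s[k])
  truth
}

# count-weighted spatial marginal of an st-SCA tensor (independent of the
# radial path): one value per temporal lag
weighted_spatial_marginal <- function(res) {
  wv <- ifelse(res$counts > 0, res$values * res$counts, 0)
  apply(wv, 3, sum) / apply(res$counts, 3, sum)
}

# wrap a raw tensor as an stsca_result (for reduction-only tests)
make_stsca <- function(values, counts, geometry, frame_fs_hz = 1000,
                       n_spikes = 1L) {
  nl <- (dim(values)[3] - 1L) / 2L
  structure(list(values = values, counts = counts,
                 axes = lag_axes(geometry, nl, frame_fs_hz),
                 n_spikes = n_spikes, n_dropped = 0L,
                 frame_fs_hz = frame_fs_hz,
                 provenance = list(window_s = nl / frame_fs_hz,
                                   pitch_mm = geometry$pitch_mm,
                                   n_channels = n_channels(geometry))),
            class = "stsca_result")
}

# independent brute-force spike-detection oracle: iterative deepest-first
# exclusion rather than the implementation's greedy sort
oracle_detect <- function(x, threshold_sd, dead_samples) {
  thr <- mean(x) - threshold_sd * sd(x)
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1))
    if (x[i] < thr && x[i] < x[i - 1] && x[i] <= x[i + 1])
      cand <- c(cand, i)
  kept <- integer(0)
  while (length(cand)) {
    i <- cand[which.min(x[cand])]
    kept <- c(kept, i)
    cand <- cand[abs(cand - i) >= dead_samples]
  }
  sort(kept)
}
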
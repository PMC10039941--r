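#' Normalized sinc function
#'
#' `sinc(x) = sin(pi x) / (pi x)` with `sinc(0) = 1`; first zero at
#' `x = 1`, Fourier transform of the unit rectangular window.
#' @param x Numeric.
#' @return Numeric of the same shape.
#' @export
sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# location (in units of the sinc scale) of the first extremum beyond the
# first zero: root of tan(pi x) = pi x, pi x ~ 4.4934094579
SINC_FIRST_LOBE <- 4.493409457909064 / pi

#' Scale of a 2D sinc kernel from its first ring radius
#'
#' For a negative-amplitude radial sinc kernel the first surrounding ring
#' (flanking extremum) sits at `SINC_FIRST_LOBE ~ 1.4303` times the spatial
#' scale; this inverts that relation.
#' @param ring_mm Desired first-ring radius in mm.
#' @return Spatial scale (first-zero radius) in mm.
#' @export
sinc_scale_for_ring <- function(ring_mm) ring_mm / SINC_FIRST_LOBE

#' Spike-to-LFP kernel specification
#'
#' Phenomenological spatiotemporal kernels injected around each synthetic
#' spike. Families (`rho = sqrt(xi^2 + psi^2)`, normalized sinc):
#' \describe{
#'   \item{radial_sinc_2d}{`A sinc(rho / s_r) sinc(tau / s_t)` — the
#'     central-trough-plus-rings morphology (use negative `A` for a trough).}
#'   \item{separable_sinc}{`A sinc(xi / s_r) sinc(psi / s_r) sinc(tau / s_t)`.}
#'   \item{cos_rt}{`A cos(rho tau / (s_r s_t))` — the space-time coupled
#'     kernel whose bounded integrals are sinc-shaped in both domains.}
#'   \item{gaussian_well}{`-|A| exp(-rho^2 / 2 s_r^2) exp(-tau^2 / 2 s_t^2)`
#'     — an everywhere non-positive well with no rings.}
#' }
#'
#' @param family Kernel family name.
#' @param amplitude_uv Peak amplitude in uV (sign kept except for
#'   `gaussian_well`, which is always non-positive).
#' @param spatial_scale_mm Spatial scale (> 0): the first-zero radius for the
#'   sinc families, the Gaussian sigma for the well.
#' @param temporal_scale_s Temporal scale (> 0), analogous role in time.
#' @return Object of class `kernel_spec`; for `radial_sinc_2d` the derived
#'   `first_ring_radius_mm` is included.
#' @export
kernel_spec <- function(family = c("radial_sinc_2d", "separable_sinc",
                                   "cos_rt", "gaussian_well"),
                        amplitude_uv, spatial_scale_mm, temporal_scale_s) {
  family <- match.arg(family)
  stopifnot(spatial_scale_mm > 0, temporal_scale_s > 0)
  spec <- list(family = family, amplitude_uv = amplitude_uv,
               spatial_scale_mm = spatial_scale_mm,
               temporal_scale_s = temporal_scale_s)
  if (family == "radial_sinc_2d")
    spec$first_ring_radius_mm <- SINC_FIRST_LOBE * spatial_scale_mm
  structure(spec, class = "kernel_spec")
}

#' Evaluate a kernel at spatial and temporal lags
#'
#' Elementwise over arrays of matching shape (scalars recycle).
#' @param spec A `kernel_spec`.
#' @param xi_mm,psi_mm Spatial lags in mm.
#' @param tau_s Temporal lags in seconds.
#' @return Kernel values in uV, shaped like the broadcast inputs.
#' @export
eval_kernel <- function(spec, xi_mm, psi_mm, tau_s) {
  stopifnot(inherits(spec, "kernel_spec"))
  A <- spec$amplitude_uv
  sr <- spec$spatial_scale_mm
  st <- spec$temporal_scale_s
  rho <- sqrt(xi_mm^2 + psi_mm^2)
  switch(spec$family,
    radial_sinc_2d = A * sinc(rho / sr) * sinc(tau_s / st),
    separable_sinc = A * sinc(xi_mm / sr) * sinc(psi_mm / sr) *
      sinc(tau_s / st),
    cos_rt = A * cos(rho * tau_s / (sr * st)),
    gaussian_well = -abs(A) * exp(-rho^2 / (2 * sr^2)) *
      exp(-tau_s^2 / (2 * st^2))
  )
}

#' Simulation configuration for synthetic MEA data
#'
#' States the world the generator emulates: a gridded MEA sampled at a given
#' rate, multi-unit spikes (per-channel Poisson or an explicit list), each
#' spike injecting a known spatiotemporal LFP kernel, plus additive Gaussian
#' noise (optionally spatially correlated).
#'
#' @param geometry An `array_geometry`.
#' @param duration_s Recording duration in seconds.
#' @param fs_hz Sampling rate of the synthesized LFP (frame rate).
#' @param rate_hz Per-channel Poisson spike rate; ignored when
#'   `spike_times` is given.
#' @param spike_times Optional explicit data.frame `channel_id`, `time_s`.
#' @param kernel A `kernel_spec`.
#' @param noise_sd_uv Additive Gaussian noise SD per channel-sample.
#' @param noise_corr_mm Spatial correlation length of the noise (Gaussian
#'   covariance over electrode distance); 0 = white across channels.
#' @param kernel_support_s Half-width over which the kernel is injected
#'   (default `5 * temporal_scale_s`).
#' @param seed Mandatory integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(geometry, duration_s, fs_hz, kernel, seed,
                       rate_hz = NULL, spike_times = NULL,
                       noise_sd_uv = 0, noise_corr_mm = 0,
                       kernel_support_s = NULL) {
  stopifnot(inherits(geometry, "array_geometry"), duration_s > 0, fs_hz > 0,
            inherits(kernel, "kernel_spec"), is.numeric(seed),
            noise_sd_uv >= 0, noise_corr_mm >= 0)
  if (is.null(kernel_support_s))
    kernel_support_s <- 5 * kernel$temporal_scale_s
  if (2 * kernel_support_s > duration_s)
    stop("kernel support wider than the recording duration")
  if (is.null(rate_hz) && is.null(spike_times))
    stop("either rate_hz or spike_times must be given")
  structure(list(geometry = geometry, duration_s = duration_s, fs_hz = fs_hz,
                 kernel = kernel, seed = as.integer(seed), rate_hz = rate_hz,
                 spike_times = spike_times, noise_sd_uv = noise_sd_uv,
                 noise_corr_mm = noise_corr_mm,
                 kernel_support_s = kernel_support_s),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate an MEA recording with known spike-LFP kernels
#'
#' Draws multi-unit spikes (or takes them from the config), sums the kernel
#' centered at every spike's electrode position and time into the
#' multichannel LFP, and adds Gaussian noise. The ground-truth spike train
#' is returned alongside; every random draw is governed by the config seed.
#'
#' @param config A `sim_config`.
#' @return List with `lfp` (an `mea_recording` at `fs_hz`) and `spikes`
#'   (the ground-truth `spike_train`).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$geometry
  fs <- config$fs_hz
  n_samp <- round(config$duration_s * fs)
  ids <- g$channel_map$channel_id
  with_seed(config$seed, {
    if (is.null(config$spike_times)) {
      ev <- do.call(rbind, lapply(ids, function(ch) {
        k <- stats::rpois(1, config$rate_hz * config$duration_s)
        if (k == 0) return(NULL)
        idx <- sort(unique(round(stats::runif(k, 0, config$duration_s - 1/fs)
                                 * fs) + 1))
        data.frame(channel_id = ch, sample_index = idx)
      }))
    } else {
      ev <- data.frame(channel_id = config$spike_times$channel_id,
                       sample_index = round(config$spike_times$time_s * fs) + 1)
    }
    if (is.null(ev) || !nrow(ev)) stop("simulation produced no spikes")
    spikes <- spike_train(ev$channel_id, ev$sample_index, fs)
    pos <- channel_positions(g, ids)
    x_mm <- pos[, "col"] * g$pitch_mm
    y_mm <- pos[, "row"] * g$pitch_mm
    sig <- matrix(0, length(ids), n_samp)
    ns <- round(config$kernel_support_s * fs)
    sp_pos <- channel_positions(g, spikes$events$channel_id)
    for (j in seq_len(nrow(spikes$events))) {
      ci <- spikes$events$sample_index[j]
      cols <- max(1, ci - ns):min(n_samp, ci + ns)
      tau <- (cols - ci) / fs
      dx <- x_mm - sp_pos[j, "col"] * g$pitch_mm
      dy <- y_mm - sp_pos[j, "row"] * g$pitch_mm
      K <- eval_kernel(config$kernel,
                       matrix(dx, length(ids), length(cols)),
                       matrix(dy, length(ids), length(cols)),
                       matrix(tau, length(ids), length(cols), byrow = TRUE))
      sig[, cols] <- sig[, cols] + K
    }
    if (config$noise_sd_uv > 0) {
      noise <- matrix(stats::rnorm(length(ids) * n_samp,
                                   sd = config$noise_sd_uv),
                      length(ids), n_samp)
      if (config$noise_corr_mm > 0) {
        d2 <- outer(x_mm, x_mm, `-`)^2 + outer(y_mm, y_mm, `-`)^2
        R <- exp(-d2 / (2 * config$noise_corr_mm^2))
        L <- t(chol(R + diag(1e-9, length(ids))))
        noise <- L %*% noise
      }
      sig <- sig + noise
    }
    list(lfp = recording(sig, fs, ids), spikes = spikes)
  })
}

#' Evenly spaced spike schedule on random channels
#'
#' Places `n_spikes` at least `separation_s` apart (no temporal kernel
#' overlap when the separation exceeds the kernel support) on channels drawn
#' uniformly with replacement — the workhorse fixture for exact-recovery
#' tests.
#'
#' @param geometry An `array_geometry`.
#' @param n_spikes Number of spikes.
#' @param separation_s Spacing between consecutive spikes, seconds.
#' @param start_s Time of the first spike.
#' @param seed Integer seed for the channel draw.
#' @return data.frame `channel_id`, `time_s` suitable for [sim_config()].
#' @export
spike_schedule <- function(geometry, n_spikes, separation_s, start_s, seed) {
  ids <- geometry$channel_map$channel_id
  with_seed(seed, {
    data.frame(channel_id = sample(ids, n_spikes, replace = TRUE),
               time_s = start_s + (seq_len(n_spikes) - 1) * separation_s)
  })
}

#' Synthesize an MUA-band trace with detectable spikes
#'
#' Gaussian background noise plus triangular negative deflections of
#' `amplitude_sd` noise-SDs at the requested spike times — for end-to-end
#' testing of threshold detection.
#'
#' @param n_channels Number of channels.
#' @param spike_df data.frame `channel_id` (1..n_channels), `time_s`.
#' @param duration_s,fs_hz Trace length and rate (default 30 kHz).
#' @param noise_sd Background SD in uV.
#' @param amplitude_sd Trough depth in units of the noise SD (default 10).
#' @param width_ms Full width of the triangular deflection (default 1 ms).
#' @param seed Integer seed.
#' @return An `mea_recording`.
#' @export
simulate_mua <- function(n_channels, spike_df, duration_s, fs_hz = 30000,
                         noise_sd = 1, amplitude_sd = 10, width_ms = 1,
                         seed = 1) {
  n_samp <- round(duration_s * fs_hz)
  half <- max(1, round(width_ms / 1000 * fs_hz / 2))
  tri <- -(1 - abs(-half:half) / (half + 1))   # peak -1 at center
  with_seed(seed, {
    sig <- matrix(stats::rnorm(n_channels * n_samp, sd = noise_sd),
                  n_channels, n_samp)
    for (j in seq_len(nrow(spike_df))) {
      ci <- round(spike_df$time_s[j] * fs_hz) + 1
      cols <- (ci - half):(ci + half)
      keep <- cols >= 1 & cols <= n_samp
      sig[spike_df$channel_id[j], cols[keep]] <-
        sig[spike_df$channel_id[j], cols[keep]] +
        amplitude_sd * noise_sd * tri[keep]
    }
    recording(sig, fs_hz)
  })
}

#' Temporal unit impulse response by bounded spatial integration
#'
#' `UIR(tau) ~ integral over r in [-R, R] of f(r, tau) dr`: what a
#' macroelectrode covering `[-R, R]` records in response to a central
#' impulse. For the space-time coupled cosine kernel the closed form is
#' `2 sin(k R tau) / (k tau)`, i.e. sinc-shaped in time.
#'
#' @param spec A `kernel_spec` (evaluated along `psi = 0`).
#' @param R_mm Electrode half-extent in mm.
#' @param tau_s Temporal lags at which to evaluate.
#' @return Numeric vector of quadrature values.
#' @export
uir_temporal <- function(spec, R_mm, tau_s) {
  stopifnot(R_mm > 0)
  vapply(tau_s, function(t0)
    stats::integrate(function(r) eval_kernel(spec, r, 0, t0), -R_mm, R_mm,
                     rel.tol = 1e-10, abs.tol = 0)$value,
    numeric(1))
}

#' Spatial unit impulse response by bounded temporal integration
#'
#' `UIR(r) ~ integral over tau in [-T, T] of f(r, tau) dtau`; for the
#' cosine kernel this is `2 sin(k T r) / (k r)`, sinc-shaped in space.
#'
#' @param spec A `kernel_spec`.
#' @param T_s Temporal integration half-width in seconds.
#' @param r_mm Radii at which to evaluate.
#' @return Numeric vector of quadrature values.
#' @export
uir_spatial <- function(spec, T_s, r_mm) {
  stopifnot(T_s > 0)
  vapply(r_mm, function(r0)
    stats::integrate(function(tau) eval_kernel(spec, r0, 0, tau), -T_s, T_s,
                     rel.tol = 1e-10, abs.tol = 0)$value,
    numeric(1))
}

#' Numerical check of the rect-sinc Fourier pair
#'
#' Samples a rectangular window of half-width `R` on a fine grid, takes its
#' DFT, and compares against the analytic transform `2R sinc(2R f)`. The
#' returned deviation is the maximum absolute difference normalized by the
#' transform's peak.
#'
#' @param R Rectangle half-width (arbitrary units).
#' @param n_grid Number of grid points (default `2^14`).
#' @param span_factor Total grid span as a multiple of `R` on each side
#'   (default 8).
#' @return List `max_rel_deviation`, `freq`, `estimate`, `analytic`,
#'   `first_zero` (measured first positive-frequency zero crossing; analytic
#'   value `1 / (2R)`).
#' @export
rect_sinc_check <- function(R, n_grid = 2^14, span_factor = 8) {
  stopifnot(R >= 0)
  if (R == 0) {
    return(list(max_rel_deviation = 0,
                freq = numeric(0), estimate = numeric(0),
                analytic = numeric(0), first_zero = NA_real_))
  }
  L <- span_factor * R
  dt <- 2 * L / n_grid
  t <- -L + (seq_len(n_grid) - 1) * dt
  x <- as.numeric(abs(t) < R) + 0.5 * (abs(t) == R)
  k <- seq_len(n_grid) - 1
  f <- ifelse(k <= n_grid / 2, k, k - n_grid) / (n_grid * dt)
  est <- Re(stats::fft(x) * exp(2i * pi * f * L)) * dt
  analytic <- 2 * R * sinc(2 * R * f)
  o <- order(f)
  fpos <- f[o][f[o] > 0]
  epos <- est[o][f[o] > 0]
  zi <- which(diff(sign(epos)) != 0)[1]
  first_zero <- if (is.na(zi)) NA_real_ else {
    # linear interpolation of the crossing
    fpos[zi] - epos[zi] * (fpos[zi + 1] - fpos[zi]) / (epos[zi + 1] - epos[zi])
  }
  list(max_rel_deviation = max(abs(est - analytic)) / max(abs(analytic)),
       freq = f[o], estimate = est[o], analytic = analytic[o],
       first_zero = first_zero)
}
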
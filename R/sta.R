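#' Spike-triggered average of an LFP trace
#'
#' The average LFP in a window of temporal lags around each spike,
#' `C(tau) = (1/N) sum_i LFP(t_i + tau)`: the spike-LFP cross-correlation.
#' Spikes whose window would leave the recording are dropped (not padded)
#' and counted in `n_dropped`. The residual-noise trace comes from the
#' plus-minus (even/odd) split of the retained spikes.
#'
#' @param lfp Numeric vector, a single LFP trace in uV.
#' @param fs_hz Sampling rate of `lfp`.
#' @param spike_times Spike times in seconds (time 0 = first sample).
#' @param window_s Half-width of the lag window in seconds.
#' @return Object of class `sta_result`: `values` (uV), `lags_s`, `n_spikes`
#'   (retained), `n_dropped`, `noise_estimate`, `snr_db`.
#' @export
compute_sta <- function(lfp, fs_hz, spike_times, window_s) {
  stopifnot(window_s > 0, fs_hz > 0)
  nl <- round(window_s * fs_hz)
  fi <- round(spike_times * fs_hz) + 1
  keep <- fi - nl >= 1 & fi + nl <= length(lfp)
  n_dropped <- sum(!keep)
  fi <- fi[keep]
  if (!length(fi)) stop("no spikes retained inside the recording window")
  lag_idx <- -nl:nl
  frames <- t(vapply(fi, function(i) lfp[i + lag_idx],
                     numeric(length(lag_idx))))
  acc <- function(idx) colMeans(frames[idx, , drop = FALSE])
  if (length(fi) >= 2) {
    pm <- plus_minus(acc, length(fi))
    values <- pm$signal; noise <- pm$noise; snr <- pm$snr_db
  } else {
    values <- frames[1, ]; noise <- rep(NA_real_, length(values)); snr <- NA
  }
  structure(list(values = values, lags_s = lag_idx / fs_hz,
                 n_spikes = length(fi), n_dropped = n_dropped,
                 noise_estimate = noise, snr_db = snr),
            class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf(
    "sta_result: %d lags over +/-%g s, %d spikes (%d dropped), SNR %.1f dB\n",
    length(x$values), max(x$lags_s), x$n_spikes, x$n_dropped, x$snr_db))
  invisible(x)
}

# mean LFP over a set of channels, spikes restricted to those channels
subset_mean_and_spikes <- function(rec_lfp, spikes, channels) {
  rows <- match(channels, rec_lfp$channel_ids)
  if (anyNA(rows)) stop("subset contains channels absent from the recording")
  sub <- recording(rec_lfp$signals[rows, , drop = FALSE], rec_lfp$fs_hz,
                   channels, rec_lfp$t0_s,
                   if (!is.null(rec_lfp$exclusion_mask))
                     rec_lfp$exclusion_mask[rows, , drop = FALSE])
  ev <- spikes$events[spikes$events$channel_id %in% channels, , drop = FALSE]
  list(lfp = array_mean_lfp(sub),
       times = (ev$sample_index - 1) / spikes$fs_hz)
}

#' STA from a random or fixed subset of electrodes
#'
#' Computes the spike-triggered average using only spikes detected on a
#' subset of channels and the LFP averaged over that same subset — the
#' sparse-sampling variant showing that the temporal morphology survives
#' heavy spatial subsampling (e.g. 8 of 96 electrodes).
#'
#' @param rec_lfp An `mea_recording` in the LFP band.
#' @param spikes A `spike_train`.
#' @param channel_subset Channel ids to use (>= 1, default drawn elsewhere).
#' @param window_s Lag half-width in seconds.
#' @return An `sta_result`.
#' @export
subset_sta <- function(rec_lfp, spikes, channel_subset, window_s) {
  if (!length(channel_subset)) stop("channel subset must be non-empty")
  s <- subset_mean_and_spikes(rec_lfp, spikes, channel_subset)
  if (!length(s$times)) stop("no spikes on the selected channel subset")
  compute_sta(s$lfp, rec_lfp$fs_hz, s$times, window_s)
}

#' Cross-population STA: trigger and signal from different channel sets
#'
#' Identical mathematics to `compute_sta`, but spikes are taken from one
#' channel population (e.g. recruited territory) while the LFP is averaged
#' over a different, typically disjoint population. With identical
#' populations it reduces to the subset STA.
#'
#' @param rec_lfp An `mea_recording` in the LFP band.
#' @param spikes A `spike_train`.
#' @param trigger_channels Channels supplying the spike triggers.
#' @param signal_channels Channels whose mean LFP is averaged.
#' @param window_s Lag half-width in seconds.
#' @return An `sta_result`.
#' @export
cross_population_sta <- function(rec_lfp, spikes, trigger_channels,
                                 signal_channels, window_s) {
  if (!length(trigger_channels) || !length(signal_channels))
    stop("both channel populations must be non-empty")
  rows <- match(signal_channels, rec_lfp$channel_ids)
  if (anyNA(rows)) stop("signal channels absent from the recording")
  sig <- recording(rec_lfp$signals[rows, , drop = FALSE], rec_lfp$fs_hz,
                   signal_channels, rec_lfp$t0_s,
                   if (!is.null(rec_lfp$exclusion_mask))
                     rec_lfp$exclusion_mask[rows, , drop = FALSE])
  lfp <- array_mean_lfp(sig)
  ev <- spikes$events[spikes$events$channel_id %in% trigger_channels, ,
                      drop = FALSE]
  if (!nrow(ev)) stop("no spikes on the trigger channels")
  compute_sta(lfp, rec_lfp$fs_hz, (ev$sample_index - 1) / spikes$fs_hz,
              window_s)
}
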
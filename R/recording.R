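#' Multichannel recording container
#'
#' A uniformly sampled multichannel voltage matrix in microvolts, with an
#' optional per-sample validity mask (TRUE = usable) used to exclude
#' artifactual channel-samples from every downstream average.
#'
#' @param signals Numeric matrix, channels x samples, uV.
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param channel_ids Channel ids matching the rows of `signals`.
#' @param t0_s Start time of the first sample, seconds (default 0).
#' @param exclusion_mask Optional logical matrix, same shape as `signals`;
#'   TRUE marks valid samples.
#' @return Object of class `mea_recording`.
#' @export
recording <- function(signals, fs_hz, channel_ids = seq_len(nrow(signals)),
                      t0_s = 0, exclusion_mask = NULL) {
  signals <- as.matrix(signals)
  stopifnot(is.numeric(signals), fs_hz > 0,
            length(channel_ids) == nrow(signals))
  if (!is.null(exclusion_mask)) {
    exclusion_mask <- as.matrix(exclusion_mask)
    stopifnot(is.logical(exclusion_mask),
              all(dim(exclusion_mask) == dim(signals)))
  }
  structure(list(signals = signals, fs_hz = fs_hz,
                 channel_ids = channel_ids, t0_s = t0_s,
                 exclusion_mask = exclusion_mask),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("mea_recording: %d channels x %d samples @ %g Hz (%.3f s)%s\n",
              nrow(x$signals), ncol(x$signals), x$fs_hz,
              ncol(x$signals) / x$fs_hz,
              if (is.null(x$exclusion_mask)) "" else ", masked"))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$signals)

# validity mask as a matrix (all-TRUE when absent)
valid_mask <- function(rec) {
  if (is.null(rec$exclusion_mask))
    matrix(TRUE, nrow(rec$signals), ncol(rec$signals))
  else rec$exclusion_mask
}

#' Multi-unit spike train
#'
#' Ordered spike events as (channel id, sample index) pairs referring to a
#' stated sampling rate. Indices are 1-based and strictly increasing within
#' each channel.
#'
#' @param channel_id Integer vector of channel ids, one per event.
#' @param sample_index Integer vector of 1-based sample indices.
#' @param fs_hz Sampling rate the indices refer to.
#' @return Object of class `spike_train` with a data.frame `events`
#'   (chronologically sorted) and `fs_hz`.
#' @export
spike_train <- function(channel_id, sample_index, fs_hz) {
  stopifnot(length(channel_id) == length(sample_index), fs_hz > 0,
            all(sample_index >= 1))
  ev <- data.frame(channel_id = channel_id,
                   sample_index = as.numeric(sample_index))
  ev <- ev[order(ev$sample_index, ev$channel_id), , drop = FALSE]
  rownames(ev) <- NULL
  for (ch in unique(ev$channel_id)) {
    s <- ev$sample_index[ev$channel_id == ch]
    if (any(diff(s) <= 0))
      stop("spike indices must be strictly increasing within each channel")
  }
  structure(list(events = ev, fs_hz = fs_hz), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d events on %d channels @ %g Hz\n",
              nrow(x$events), length(unique(x$events$channel_id)), x$fs_hz))
  invisible(x)
}

#' Spike times in seconds
#' @param spikes A `spike_train`.
#' @return Numeric vector of event times (index 1 maps to t = 0).
#' @export
spike_times_s <- function(spikes) (spikes$events$sample_index - 1) / spikes$fs_hz

#' Number of spike events
#' @param spikes A `spike_train`.
#' @return Integer count.
#' @export
n_spikes <- function(spikes) nrow(spikes$events)
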
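#' Bandpass filter specification
#'
#' @param band_low_hz,band_high_hz Passband edges, 0 < low < high < fs/2.
#' @param order Butterworth order per edge (default 4).
#' @param zero_phase If TRUE (default) the filter is applied with exactly zero
#'   phase (magnitude-only frequency response, the steady-state equivalent of
#'   forward-backward filtering); if FALSE a single causal pass with the
#'   Butterworth phase response is applied.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(band_low_hz, band_high_hz, order = 4L,
                        zero_phase = TRUE) {
  stopifnot(band_low_hz > 0, band_high_hz > band_low_hz, order >= 1)
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# complex Butterworth analog frequency response (bandpass as LP * HP cascade)
butter_response <- function(f_hz, spec) {
  lp_poles <- function(N) exp(1i * pi * (2 * seq_len(N) + N - 1) / (2 * N))
  H_lp <- function(w, wc, N) {
    p <- lp_poles(N)
    s <- 1i * outer(w / wc, rep(1, N))
    1 / apply(s - matrix(p, length(w), N, byrow = TRUE), 1, prod)
  }
  w <- 2 * pi * f_hz
  wl <- 2 * pi * spec$band_low_hz
  wh <- 2 * pi * spec$band_high_hz
  lo <- H_lp(w, wh, spec$order)
  # highpass via s -> wc/s; response at w = LP response at wl^2/w (conjugated)
  hp <- ifelse(w == 0, 0 + 0i, Conj(H_lp(ifelse(w == 0, 1, wl^2 / w) / wl,
                                         wl, spec$order)))
  g <- lo * hp
  if (spec$zero_phase) Mod(g) else g
}

# FFT filtering with reflective padding to suppress wraparound transients;
# gain_fn maps folded non-negative frequency (Hz) to a (possibly complex) gain
fft_apply <- function(x, fs_hz, gain_fn, npad) {
  n <- length(x)
  npad <- min(n - 1L, npad)
  xp <- c(rev(x[seq_len(npad) + 1L]), x, rev(x[n - seq_len(npad)]))
  m <- length(xp)
  f <- (seq_len(m) - 1) / m * fs_hz
  f <- pmin(f, fs_hz - f)                    # folded (two-sided) frequency
  g <- gain_fn(f)
  if (is.complex(g)) {                       # conjugate symmetry -> real output
    neg <- (seq_len(m) - 1) > m / 2
    g[neg] <- Conj(g[neg])
  }
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / m
  y[npad + seq_len(n)]
}

fft_filter_vec <- function(x, fs_hz, spec) {
  fft_apply(x, fs_hz, function(f) butter_response(f, spec),
            npad = ceiling(3 * fs_hz / spec$band_low_hz))
}

# zero-phase Butterworth-magnitude lowpass (keeps DC)
fft_lowpass_vec <- function(x, fs_hz, cutoff_hz, order = 8) {
  fft_apply(x, fs_hz, function(f) 1 / sqrt(1 + (f / cutoff_hz)^(2 * order)),
            npad = ceiling(3 * fs_hz / cutoff_hz))
}

#' Bandpass-filter a recording
#'
#' Splits broadband signals into an analysis band, e.g. 2-50 Hz for the local
#' field potential or 300-3000 Hz for multi-unit activity. Filtering is done
#' in the frequency domain with the Butterworth magnitude response, which is
#' exactly zero-phase: the peak of a filtered symmetric pulse does not move.
#'
#' @param rec An `mea_recording`.
#' @param spec A `filter_spec`.
#' @return A filtered `mea_recording` of the same shape.
#' @export
bandpass <- function(rec, spec) {
  stopifnot(inherits(rec, "mea_recording"), inherits(spec, "filter_spec"))
  if (spec$band_high_hz >= rec$fs_hz / 2)
    stop("band_high_hz must be below the Nyquist frequency")
  out <- rec
  out$signals <- t(apply(rec$signals, 1, fft_filter_vec,
                         fs_hz = rec$fs_hz, spec = spec))
  dimnames(out$signals) <- dimnames(rec$signals)
  out
}

#' Spike detection specification
#'
#' @param threshold_sd Threshold in SD units below the mean (default 4).
#' @param dead_time_ms Minimum separation between events on one channel
#'   (default 1 ms); when two candidate troughs are closer, the deeper one
#'   is kept.
#' @param statistic Spread estimator, `"sd"` (default, matching the usual
#'   mean/SD rule) or `"mad"`.
#' @return Object of class `detection_spec`.
#' @export
detection_spec <- function(threshold_sd = 4, dead_time_ms = 1,
                           statistic = c("sd", "mad")) {
  stopifnot(threshold_sd > 0, dead_time_ms >= 0)
  structure(list(threshold_sd = threshold_sd, dead_time_ms = dead_time_ms,
                 statistic = match.arg(statistic)),
            class = "detection_spec")
}

#' Threshold-crossing multi-unit spike detection
#'
#' Detects negative deflections exceeding `threshold_sd` standard deviations
#' below the per-channel mean of the (already MUA-band-filtered) signal.
#' Events are placed at local minima; troughs closer than the dead time
#' resolve to the deeper one. Mean and SD are computed over valid samples
#' only.
#'
#' @param rec_mua An `mea_recording` filtered to the MUA band.
#' @param spec A `detection_spec`.
#' @return A `spike_train` at the recording's sampling rate.
#' @export
detect_spikes <- function(rec_mua, spec = detection_spec()) {
  stopifnot(inherits(rec_mua, "mea_recording"))
  mask <- valid_mask(rec_mua)
  dead <- round(spec$dead_time_ms / 1000 * rec_mua$fs_hz)
  ch_out <- list()
  for (i in seq_len(nrow(rec_mua$signals))) {
    x <- rec_mua$signals[i, ]
    m <- mask[i, ]
    if (!any(m)) {
      warning("channel ", rec_mua$channel_ids[i],
              " fully masked; no events detected")
      next
    }
    stat <- if (spec$statistic == "sd") stats::sd(x[m]) else stats::mad(x[m])
    thr <- mean(x[m]) - spec$threshold_sd * stat
    n <- length(x)
    cand <- which(x < thr & m)
    cand <- cand[cand > 1 & cand < n]
    cand <- cand[x[cand] < x[cand - 1] & x[cand] <= x[cand + 1]]
    if (length(cand) > 1 && dead > 0) {
      keep <- logical(0)
      for (j in order(x[cand])) {           # deepest trough first
        if (!length(keep) || all(abs(cand[keep] - cand[j]) >= dead))
          keep <- c(keep, j)
      }
      cand <- sort(cand[keep])
    }
    if (length(cand))
      ch_out[[length(ch_out) + 1L]] <-
        data.frame(channel_id = rec_mua$channel_ids[i], sample_index = cand)
  }
  ev <- if (length(ch_out)) do.call(rbind, ch_out) else
    data.frame(channel_id = integer(0), sample_index = integer(0))
  spike_train(ev$channel_id, ev$sample_index, rec_mua$fs_hz)
}

#' Array-averaged LFP trace
#'
#' Per-sample mean over all channels valid at that sample. Samples with no
#' valid channel become `NA` and their count is attached as attribute
#' `n_undefined`.
#'
#' @param rec_lfp An `mea_recording` in the LFP band.
#' @param exclusion_mask Optional validity mask overriding the recording's.
#' @return Numeric vector (one sample per column of the input) with
#'   attribute `fs_hz`.
#' @export
array_mean_lfp <- function(rec_lfp, exclusion_mask = NULL) {
  stopifnot(inherits(rec_lfp, "mea_recording"))
  m <- if (is.null(exclusion_mask)) valid_mask(rec_lfp) else exclusion_mask
  num <- colSums(rec_lfp$signals * m)
  den <- colSums(m)
  out <- ifelse(den > 0, num / den, NA_real_)
  attr(out, "fs_hz") <- rec_lfp$fs_hz
  attr(out, "n_undefined") <- sum(den == 0)
  out
}

#' Decimate an LFP-band recording
#'
#' Anti-alias lowpass filters (zero-phase, cutoff at 0.45 x target rate) and
#' resamples to `target_fs_hz`. Output length is `round(n * target / fs)`;
#' spike indices convert exactly through time in seconds.
#'
#' @param rec An `mea_recording`.
#' @param target_fs_hz New sampling rate, <= `rec$fs_hz`.
#' @return A resampled `mea_recording`.
#' @export
decimate_lfp <- function(rec, target_fs_hz) {
  stopifnot(inherits(rec, "mea_recording"), target_fs_hz > 0)
  if (target_fs_hz > rec$fs_hz) stop("target rate exceeds the recording rate")
  if (target_fs_hz == rec$fs_hz) return(rec)
  n <- n_samples(rec)
  m <- round(n * target_fs_hz / rec$fs_hz)
  t_old <- (seq_len(n) - 1) / rec$fs_hz
  t_new <- (seq_len(m) - 1) / target_fs_hz
  cutoff <- 0.45 * target_fs_hz
  sig <- t(apply(rec$signals, 1, function(x)
    stats::approx(t_old, fft_lowpass_vec(x, rec$fs_hz, cutoff), xout = t_new,
                  rule = 2)$y))
  mask <- NULL
  if (!is.null(rec$exclusion_mask)) {
    idx <- pmin(n, pmax(1, round(t_new * rec$fs_hz) + 1))
    mask <- rec$exclusion_mask[, idx, drop = FALSE]
  }
  recording(sig, target_fs_hz, rec$channel_ids, rec$t0_s, mask)
}
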
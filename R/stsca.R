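#' Spatiotemporal spike-centered average (st-SCA)
#'
#' The spatial extension of the spike-triggered average: for each spike, the
#' whole-array LFP frame over temporal lags `tau` is translated so that the
#' spiking electrode sits at the spatial origin, the translated frames are
#' summed into a `(2W-1) x (2W-1) x (2n+1)` tensor (19 x 19 spatially for a
#' 10 x 10 array), the number of contributions to every cell is counted, and
#' the sum is divided by the counts. Cells that never receive a contribution
#' (the corners of the lag grid) are undefined (`NA`). This realizes the
#' discrete spatiotemporal cross-correlation
#' `C(xi, psi, tau) = (1/N) sum_i LFP(x_i + xi, y_i + psi, t_i + tau)`.
#'
#' Spikes whose temporal window would leave the recording are dropped
#' entirely, which keeps the counts independent of `tau` (unless an
#' exclusion mask removes individual channel-samples). Masked
#' channel-samples contribute to neither values nor counts.
#'
#' @param rec_lfp An `mea_recording` in the LFP band at the frame rate
#'   (decimate first for long windows).
#' @param spikes A `spike_train`; spike channels must be present in
#'   `geometry`.
#' @param geometry An `array_geometry` covering the recording's channels.
#' @param window_s Temporal lag half-width in seconds.
#' @return Object of class `stsca_result`: `values` (uV array, dim
#'   `side x side x lags`, first dim = row lag `psi`, second = column lag
#'   `xi`), `counts` (integer array, same dim), `axes` (see [lag_axes()]),
#'   `n_spikes` (retained), `n_dropped`, `frame_fs_hz`, `provenance`.
#' @seealso [radial_reduce()], [stsca_plus_minus()], [offset_count_table()]
#' @export
compute_stsca <- function(rec_lfp, spikes, geometry, window_s) {
  ctx <- stsca_context(rec_lfp, spikes, geometry, window_s)
  acc <- stsca_accumulate(ctx, seq_len(ctx$n_retained))
  axes <- lag_axes(geometry, ctx$nl, rec_lfp$fs_hz)
  structure(list(values = acc$values, counts = acc$counts, axes = axes,
                 n_spikes = ctx$n_retained, n_dropped = ctx$n_dropped,
                 frame_fs_hz = rec_lfp$fs_hz,
                 provenance = list(window_s = window_s,
                                   pitch_mm = geometry$pitch_mm,
                                   n_channels = nrow(rec_lfp$signals))),
            class = "stsca_result")
}

#' @export
print.stsca_result <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "stsca_result: %d x %d x %d (psi x xi x tau), %d spikes, %d cells undefined\n",
    d[1], d[2], d[3], x$n_spikes, sum(x$counts == 0)))
  invisible(x)
}

# Precompute everything needed to accumulate any subset of retained spikes.
stsca_context <- function(rec_lfp, spikes, geometry, window_s) {
  stopifnot(inherits(rec_lfp, "mea_recording"),
            inherits(spikes, "spike_train"),
            inherits(geometry, "array_geometry"), window_s > 0)
  fs <- rec_lfp$fs_hz
  nl <- round(window_s * fs)
  t_sp <- spike_times_s(spikes)
  fi <- round(t_sp * fs) + 1
  keep <- fi - nl >= 1 & fi + nl <= n_samples(rec_lfp)
  if (!any(keep)) stop("no spikes retained inside the recording window")
  ch_pos <- channel_positions(geometry, rec_lfp$channel_ids)
  sp_pos <- channel_positions(geometry, spikes$events$channel_id[keep])
  W <- grid_halfwidth(geometry)
  side <- 2L * W - 1L
  # linear cell index (within one tau slab) for every (spike, channel) pair
  cell_idx <- lapply(seq_len(sum(keep)), function(j) {
    psi <- ch_pos[, "row"] - sp_pos[j, "row"]
    xi <- ch_pos[, "col"] - sp_pos[j, "col"]
    (psi + W) + (xi + W - 1L) * side
  })
  list(signals = rec_lfp$signals, mask = rec_lfp$exclusion_mask,
       fi = fi[keep], cell_idx = cell_idx, nl = nl, side = side,
       n_retained = sum(keep), n_dropped = sum(!keep))
}

# Accumulate the selected retained spikes; returns averaged values + counts.
stsca_accumulate <- function(ctx, sel) {
  T_len <- 2L * ctx$nl + 1L
  vals <- matrix(0, ctx$side^2, T_len)
  cnts <- matrix(0L, ctx$side^2, T_len)
  lag <- -ctx$nl:ctx$nl
  for (j in sel) {
    cols <- ctx$fi[j] + lag
    fr <- ctx$signals[, cols, drop = FALSE]
    idx <- ctx$cell_idx[[j]]
    if (is.null(ctx$mask)) {
      vals[idx, ] <- vals[idx, ] + fr
      cnts[idx, ] <- cnts[idx, ] + 1L
    } else {
      vm <- ctx$mask[, cols, drop = FALSE]
      vals[idx, ] <- vals[idx, ] + fr * vm
      cnts[idx, ] <- cnts[idx, ] + vm
    }
  }
  avg <- ifelse(cnts > 0, vals / cnts, NA_real_)
  list(values = array(avg, dim = c(ctx$side, ctx$side, T_len)),
       counts = array(cnts, dim = c(ctx$side, ctx$side, T_len)))
}

#' Plus-minus noise estimate and per-cell SNR for the st-SCA
#'
#' Runs the st-SCA accumulation separately on the even and odd halves of the
#' chronologically ordered spikes (see [plus_minus()]) and derives the global
#' and per-cell signal-to-noise ratios. Per-cell SNR takes the rms over the
#' temporal axis within each spatial cell.
#'
#' @inheritParams compute_stsca
#' @param rose_threshold_db Rose-criterion threshold for the reliability
#'   mask, default 12 dB.
#' @return A `plus_minus_estimate` with extra fields `snr_map_db`
#'   (side x side matrix), `rose` (logical mask, see [rose_mask()]) and
#'   `stsca` (the full `stsca_result`).
#' @export
stsca_plus_minus <- function(rec_lfp, spikes, geometry, window_s,
                             rose_threshold_db = 12) {
  ctx <- stsca_context(rec_lfp, spikes, geometry, window_s)
  pm <- plus_minus(function(idx) stsca_accumulate(ctx, idx)$values,
                   ctx$n_retained)
  sig_rms <- apply(pm$signal, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else rms(v))
  noi_rms <- apply(pm$noise, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else rms(v))
  pm$snr_map_db <- snr_db(sig_rms, noi_rms)
  pm$rose <- rose_mask(pm$snr_map_db, rose_threshold_db)
  pm$stsca <- compute_stsca(rec_lfp, spikes, geometry, window_s)
  pm
}

#' Randomize spike times (surrogate control)
#'
#' Draws new spike times iid uniform over the recording while preserving the
#' number of events per channel — the surrogate that destroys genuine
#' spike-locked spatiotemporal structure while keeping firing rates. Two
#' calls with the same seed return identical trains.
#'
#' @param spikes A `spike_train`.
#' @param duration_s Recording duration; must cover the latest spike.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return A new `spike_train` at the same sampling rate.
#' @export
randomize_spike_times <- function(spikes, duration_s, seed) {
  stopifnot(duration_s >= max(spike_times_s(spikes)))
  n_max <- floor(duration_s * spikes$fs_hz)
  ev <- spikes$events
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  out <- lapply(split(ev$channel_id, ev$channel_id), function(chs) {
    k <- length(chs)
    idx <- sort(sample.int(n_max, k))      # distinct indices per channel
    data.frame(channel_id = chs, sample_index = idx)
  })
  out <- do.call(rbind, out)
  spike_train(out$channel_id, out$sample_index, spikes$fs_hz)
}

#' Fit a ZCA spatial whitening model
#'
#' Whitening decorrelates the channels: `W = C^{-1/2} = E D^{-1/2} E^T`
#' where `C` is the sample channel covariance of the (LFP-band) signals,
#' `E` its eigenvectors and `D^{-1/2}` the diagonal matrix of inverse square
#' roots of the eigenvalues. The symmetric (ZCA) form keeps whitened
#' channels maximally similar to the originals.
#'
#' @param rec_lfp An `mea_recording` (>= channels + 1 samples).
#' @param ridge Optional non-negative value added to the diagonal of the
#'   covariance before inversion (regularization for near-singular data).
#' @param eigenvalue_exponent Exponent applied to the eigenvalues in the
#'   diagonal factor; the default `-1/2` is the inverse square root that
#'   whitens. `-1` is exposed as an alternative reading of the construction
#'   (which normalizes by the full inverse covariance instead).
#' @return Object of class `whitening_model`: `W_matrix`, `eigenvalues`,
#'   `mean_vector`, `channel_ids`.
#' @export
fit_whitening <- function(rec_lfp, ridge = 0, eigenvalue_exponent = -0.5) {
  stopifnot(inherits(rec_lfp, "mea_recording"))
  X <- t(rec_lfp$signals)
  if (nrow(X) < ncol(X) + 1)
    stop("need at least channels + 1 samples to estimate the covariance")
  C <- stats::cov(X) + diag(ridge, ncol(X))
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) <= 1e-12 * max(eg$values))
    stop("covariance is (near) rank-deficient; consider the ridge argument")
  W <- eg$vectors %*% diag(eg$values^eigenvalue_exponent) %*% t(eg$vectors)
  structure(list(W_matrix = W, eigenvalues = eg$values,
                 mean_vector = colMeans(X),
                 channel_ids = rec_lfp$channel_ids),
            class = "whitening_model")
}

#' Apply a whitening model to a recording
#'
#' Removes the fitted per-channel mean and multiplies each sample's channel
#' vector by the whitening matrix.
#'
#' @param rec_lfp An `mea_recording` with the same channels the model was
#'   fit on.
#' @param model A `whitening_model`.
#' @return A whitened `mea_recording`.
#' @export
apply_whitening <- function(rec_lfp, model) {
  stopifnot(inherits(model, "whitening_model"))
  if (!identical(rec_lfp$channel_ids, model$channel_ids))
    stop("channel sets of recording and whitening model differ")
  out <- rec_lfp
  out$signals <- model$W_matrix %*% (rec_lfp$signals - model$mean_vector)
  out
}
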
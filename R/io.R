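# full-precision CSV writer: doubles as %.17g so the round trip is exact
fwrite_full <- function(dt, path) {
  dt <- data.table::copy(data.table::as.data.table(dt))
  for (nm in names(dt))
    if (is.double(dt[[nm]]))
      data.table::set(dt, j = nm,
                      value = ifelse(is.na(dt[[nm]]), NA_character_,
                                     sprintf("%.17g", dt[[nm]])))
  data.table::fwrite(dt, path, quote = FALSE)
}

#' Write / read a recording as CSV with a JSON sidecar
#'
#' Signals go to `<prefix>.csv` (one row per sample, one column per channel,
#' named `ch_<id>`), metadata (`fs_hz`, `t0_s`, `channel_ids`) to
#' `<prefix>.meta.json`, and the exclusion mask (if any) to
#' `<prefix>.mask.csv` as 0/1. The round trip reproduces values exactly
#' (full-precision decimal serialization).
#'
#' @param rec An `mea_recording`.
#' @param prefix Path prefix without extension.
#' @return `read_recording_csv` returns an `mea_recording`; the writer
#'   returns `prefix` invisibly.
#' @export
write_recording_csv <- function(rec, prefix) {
  stopifnot(inherits(rec, "mea_recording"))
  dt <- data.table::as.data.table(t(rec$signals))
  data.table::setnames(dt, paste0("ch_", rec$channel_ids))
  fwrite_full(dt, paste0(prefix, ".csv"))
  jsonlite::write_json(list(fs_hz = rec$fs_hz, t0_s = rec$t0_s,
                            channel_ids = rec$channel_ids),
                       paste0(prefix, ".meta.json"), digits = NA)
  if (!is.null(rec$exclusion_mask))
    data.table::fwrite(data.table::as.data.table(t(rec$exclusion_mask) * 1L),
                       paste0(prefix, ".mask.csv"))
  invisible(prefix)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"),
                              simplifyVector = TRUE)
  sig <- t(as.matrix(data.table::fread(paste0(prefix, ".csv"))))
  dimnames(sig) <- NULL
  mask_path <- paste0(prefix, ".mask.csv")
  mask <- if (file.exists(mask_path))
    t(as.matrix(data.table::fread(mask_path))) == 1L
  if (!is.null(mask)) dimnames(mask) <- NULL
  recording(sig, meta$fs_hz, meta$channel_ids, meta$t0_s, mask)
}

#' Write / read a spike train as CSV
#'
#' Header `channel_id,time_s`; times in seconds (sample 1 = 0 s).
#' @param spikes A `spike_train`.
#' @param path CSV path.
#' @param fs_hz Sampling rate to attach on read.
#' @return `read_spikes_csv` returns a `spike_train`; the writer returns
#'   `path` invisibly.
#' @export
write_spikes_csv <- function(spikes, path) {
  data.table::fwrite(data.table::data.table(
    channel_id = spikes$events$channel_id,
    time_s = spike_times_s(spikes)), path)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path, fs_hz) {
  df <- data.table::fread(path)
  spike_train(df$channel_id, round(df$time_s * fs_hz) + 1, fs_hz)
}

#' Write / read an st-SCA tensor as long-form CSV
#'
#' `<prefix>.csv` holds `psi_px, xi_px, tau_s, value_uv, count` for every
#' cell (undefined cells have empty value and count 0);
#' `<prefix>.meta.json` records the axes and provenance.
#'
#' @param stsca An `stsca_result`.
#' @param prefix Path prefix without extension.
#' @return `read_stsca_csv` returns an `stsca_result`; the writer returns
#'   `prefix` invisibly.
#' @export
write_stsca_csv <- function(stsca, prefix) {
  stopifnot(inherits(stsca, "stsca_result"))
  ax <- stsca$axes
  grid <- expand.grid(psi_px = ax$spatial_lags_px,
                      xi_px = ax$spatial_lags_px,
                      tau_s = ax$temporal_lags_s)
  dt <- data.table::data.table(grid,
                               value_uv = as.vector(stsca$values),
                               count = as.vector(stsca$counts))
  fwrite_full(dt, paste0(prefix, ".csv"))
  jsonlite::write_json(
    list(frame_fs_hz = stsca$frame_fs_hz, n_spikes = stsca$n_spikes,
         n_dropped = stsca$n_dropped, provenance = stsca$provenance),
    paste0(prefix, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_stsca_csv
#' @export
read_stsca_csv <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"),
                              simplifyVector = TRUE)
  dt <- data.table::fread(paste0(prefix, ".csv"))
  side <- length(unique(dt$psi_px))
  T_len <- length(unique(dt$tau_s))
  W <- (side + 1L) / 2L
  nl <- (T_len - 1L) / 2L
  o <- order(dt$tau_s, dt$xi_px, dt$psi_px)
  values <- array(dt$value_uv[o], dim = c(side, side, T_len))
  counts <- array(dt$count[o], dim = c(side, side, T_len))
  pitch <- meta$provenance$pitch_mm
  px <- -(W - 1):(W - 1)
  axes <- list(spatial_lags_px = px, spatial_lags_mm = px * pitch,
               temporal_lags_samples = -nl:nl,
               temporal_lags_s = (-nl:nl) / meta$frame_fs_hz,
               origin_index = c(W, W, nl + 1L))
  structure(list(values = values, counts = counts, axes = axes,
                 n_spikes = meta$n_spikes, n_dropped = meta$n_dropped,
                 frame_fs_hz = meta$frame_fs_hz,
                 provenance = as.list(meta$provenance)),
            class = "stsca_result")
}

#' Write an STA result as CSV plus JSON sidecar
#'
#' CSV columns `lag_s, sta_uv, noise_uv`; the sidecar carries `n_spikes`,
#' `n_dropped` and `snr_db`.
#' @param sta An `sta_result`.
#' @param path CSV path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sta_csv <- function(sta, path) {
  data.table::fwrite(data.table::data.table(
    lag_s = sta$lags_s, sta_uv = sta$values,
    noise_uv = sta$noise_estimate), path)
  jsonlite::write_json(list(n_spikes = sta$n_spikes,
                            n_dropped = sta$n_dropped, snr_db = sta$snr_db),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a radial st-SCA as long-form CSV
#'
#' Columns `r_mm` (count-weighted bin center), `tau_s`, `value_uv`, `count`.
#' @param radial A `radial_stsca`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_radial_csv <- function(radial, path) {
  grid <- expand.grid(r_mm = radial$r_bin_centers_mm, tau_s = radial$tau_s)
  data.table::fwrite(data.table::data.table(
    grid, value_uv = as.vector(radial$values),
    count = as.vector(radial$counts)), path)
  invisible(path)
}
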
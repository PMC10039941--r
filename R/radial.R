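#' Radial (polar) reduction of an st-SCA tensor
#'
#' Exploits the (approximate) radial symmetry of the spatial pattern:
#' Cartesian lag cells `(xi, psi)` are assigned to radial bins by Euclidean
#' distance `r = sqrt(xi^2 + psi^2) * pitch` and the angle is averaged out,
#' producing a `(radial bin x temporal lag)` matrix. Bin values are
#' contribution-count-weighted means, so total weighted mass is conserved.
#'
#' @param stsca An `stsca_result`.
#' @param bin_width_mm Radial bin width; defaults to the electrode pitch.
#' @return Object of class `radial_stsca`: `values` (bins x lags, uV),
#'   `counts`, `r_bin_edges_mm`, `r_bin_centers_mm` (count-weighted mean
#'   member radius), `tau_s`, `incomplete_bins` (logical; bins beyond the
#'   half-width of the array, where the angular coverage is partial) and
#'   `pitch_mm`.
#' @export
radial_reduce <- function(stsca, bin_width_mm = NULL) {
  stopifnot(inherits(stsca, "stsca_result"))
  pitch <- stsca$provenance$pitch_mm
  if (is.null(bin_width_mm)) bin_width_mm <- pitch
  stopifnot(bin_width_mm > 0)
  if (all(stsca$counts == 0)) stop("empty st-SCA: no defined cells")
  side <- dim(stsca$values)[1]
  lag_mm <- stsca$axes$spatial_lags_mm
  r_cell <- sqrt(outer(lag_mm^2, lag_mm^2, `+`))  # psi rows, xi cols
  bin <- floor(r_cell / bin_width_mm) + 1L
  n_bins <- max(bin)
  T_len <- dim(stsca$values)[3]
  vals <- matrix(0, n_bins, T_len)
  cnts <- matrix(0, n_bins, T_len)
  r_w <- numeric(n_bins); r_wsum <- numeric(n_bins)
  bin_v <- as.vector(bin)
  for (k in seq_len(T_len)) {
    v <- stsca$values[, , k]
    w <- stsca$counts[, , k]
    wv <- ifelse(w > 0, v * w, 0)
    vals[, k] <- rowsum(as.vector(wv), bin_v)[, 1]
    cnts[, k] <- rowsum(as.vector(w), bin_v)[, 1]
  }
  w2 <- stsca$counts[, , 1]
  r_w <- rowsum(as.vector(r_cell * w2), bin_v)[, 1]
  r_wsum <- rowsum(as.vector(w2), bin_v)[, 1]
  values <- ifelse(cnts > 0, vals / cnts, NA_real_)
  centers <- ifelse(r_wsum > 0, r_w / r_wsum,
                    (seq_len(n_bins) - 0.5) * bin_width_mm)
  structure(list(values = values, counts = cnts,
                 r_bin_edges_mm = seq(0, n_bins) * bin_width_mm,
                 r_bin_centers_mm = centers,
                 tau_s = stsca$axes$temporal_lags_s,
                 incomplete_bins = centers > max(abs(lag_mm)),
                 pitch_mm = pitch),
            class = "radial_stsca")
}

#' @export
print.radial_stsca <- function(x, ...) {
  cat(sprintf("radial_stsca: %d radial bins x %d lags, bins up to %.2f mm\n",
              nrow(x$values), ncol(x$values), max(x$r_bin_edges_mm)))
  invisible(x)
}

#' Temporal and spatial marginals of a radial st-SCA
#'
#' The temporal component is the count-weighted mean over radius at each
#' temporal lag (when every channel is valid this equals the STA of the
#' array-mean LFP exactly). The spatial component is the count-weighted mean
#' over temporal lags within `tau_window_s` at each radius — the central
#' trough plus rings profile.
#'
#' @param radial A `radial_stsca`.
#' @param tau_window_s Half-width of the temporal integration window used
#'   for the spatial component, default 0.035 s.
#' @return List with `temporal_component` (vector over `tau_s`) and
#'   `spatial_component` (vector over `r_bin_centers_mm`), each with the
#'   axis attached as attribute `axis`.
#' @export
marginals <- function(radial, tau_window_s = 0.035) {
  stopifnot(inherits(radial, "radial_stsca"))
  if (tau_window_s > max(abs(radial$tau_s)) + 1e-12)
    stop("tau window exceeds the available temporal lags")
  wv <- ifelse(radial$counts > 0, radial$values * radial$counts, 0)
  temporal <- colSums(wv) / colSums(radial$counts)
  in_win <- abs(radial$tau_s) <= tau_window_s + 1e-12
  sp_num <- rowSums(wv[, in_win, drop = FALSE])
  sp_den <- rowSums(radial$counts[, in_win, drop = FALSE])
  spatial <- ifelse(sp_den > 0, sp_num / sp_den, NA_real_)
  attr(temporal, "axis") <- radial$tau_s
  attr(spatial, "axis") <- radial$r_bin_centers_mm
  list(temporal_component = temporal, spatial_component = spatial)
}

#' Peak separation of the spatial component
#'
#' Quantifies the ring geometry: the distance between the two highest local
#' maxima flanking the global minimum of the (mirrored) radial profile.
#' For a central trough with a surrounding ring this is twice the ring
#' radius. Profiles without flanking maxima (e.g. a pure well) return
#' `found = FALSE`.
#'
#' @param spatial_component Numeric profile over radius (NA allowed for
#'   undefined bins); one-sided profiles (r >= 0) are mirrored about 0.
#' @param r_axis Radii (mm) matching the profile; defaults to the profile's
#'   `axis` attribute.
#' @return List `found`, `separation_mm`, `left_r_mm`, `right_r_mm`,
#'   `trough_r_mm`.
#' @export
peak_separation <- function(spatial_component, r_axis = NULL) {
  if (is.null(r_axis)) r_axis <- attr(spatial_component, "axis")
  stopifnot(length(r_axis) == length(spatial_component))
  ok <- is.finite(spatial_component)
  v <- spatial_component[ok]; r <- r_axis[ok]
  o <- order(r); v <- v[o]; r <- r[o]
  if (all(r >= 0)) {                         # mirror one-sided profile
    v <- c(rev(v[r > 0]), v)
    r <- c(-rev(r[r > 0]), r)
  }
  n <- length(v)
  if (n < 3) return(list(found = FALSE, separation_mm = NA_real_,
                         left_r_mm = NA_real_, right_r_mm = NA_real_,
                         trough_r_mm = NA_real_))
  i_min <- which.min(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] &
                v[2:(n - 1)] >= v[3:n], FALSE)
  left <- which(is_max & seq_len(n) < i_min)
  right <- which(is_max & seq_len(n) > i_min)
  if (!length(left) || !length(right))
    return(list(found = FALSE, separation_mm = NA_real_,
                left_r_mm = NA_real_, right_r_mm = NA_real_,
                trough_r_mm = r[i_min]))
  li <- left[which.max(v[left])]
  ri <- right[which.max(v[right])]
  list(found = TRUE, separation_mm = unname(r[ri] - r[li]),
       left_r_mm = unname(r[li]), right_r_mm = unname(r[ri]),
       trough_r_mm = unname(r[i_min]))
}

#' Radial symmetry score of the time-integrated spatial pattern
#'
#' The assumption behind the polar reduction is radial symmetry. This score
#' summarizes deviations from it: the spatial map is integrated over
#' `tau_window_s`, count-weighted means are taken per angular quadrant, and
#' the score is `sd(quadrant means) / |mean(quadrant means)|` (0 for perfect
#' symmetry; large values flag anisotropy).
#'
#' @param stsca An `stsca_result`.
#' @param tau_window_s Temporal integration half-width, default 0.035 s.
#' @return Scalar score.
#' @export
radial_symmetry_score <- function(stsca, tau_window_s = 0.035) {
  in_win <- abs(stsca$axes$temporal_lags_s) <= tau_window_s + 1e-12
  wv <- ifelse(stsca$counts > 0, stsca$values * stsca$counts, 0)
  num <- apply(wv[, , in_win, drop = FALSE], c(1, 2), sum)
  den <- apply(stsca$counts[, , in_win, drop = FALSE], c(1, 2), sum)
  map <- ifelse(den > 0, num / den, NA_real_)
  lag <- stsca$axes$spatial_lags_px
  psi <- matrix(lag, length(lag), length(lag))
  xi <- t(psi)
  quad <- list(xi > 0 & psi > 0, xi > 0 & psi < 0,
               xi < 0 & psi > 0, xi < 0 & psi < 0)
  qm <- vapply(quad, function(q) {
    w <- den * q
    sum(map * w, na.rm = TRUE) / sum(w[!is.na(map)])
  }, numeric(1))
  stats::sd(qm) / abs(mean(qm))
}
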
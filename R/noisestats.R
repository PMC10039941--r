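#' Root mean square over finite values
#' @param x Numeric vector/array; NAs (undefined cells) are ignored.
#' @return Scalar rms.
#' @export
rms <- function(x) sqrt(mean(x[is.finite(x)]^2))

#' Signal-to-noise ratio in decibels
#'
#' `SNR = 20 log10(rms_signal / rms_noise)` dB. The Rose criterion for
#' reliable image features corresponds to an amplitude ratio of 4-5, i.e.
#' roughly 12-14 dB.
#'
#' @param signal_rms,noise_rms Non-negative rms amplitudes.
#' @return SNR in dB; `Inf` when `noise_rms` is zero.
#' @export
snr_db <- function(signal_rms, noise_rms) {
  stopifnot(all(signal_rms >= 0, na.rm = TRUE),
            all(noise_rms >= 0, na.rm = TRUE))
  ifelse(noise_rms == 0, Inf, 20 * log10(signal_rms / noise_rms))
}

#' Plus-minus (even/odd split) noise estimate
#'
#' Splits the trials (spikes) by parity of their chronological 0-based index
#' into an "even" and an "odd" half, runs the same accumulation on each, and
#' combines them: the full-data average is the signal estimate while half the
#' even-minus-odd difference cancels the consistent component and estimates
#' the residual noise left in the full average (for iid noise of per-trial
#' scale sigma, both the full average's noise and this estimate have scale
#' `sigma / sqrt(N)`). With an odd number of trials the extra trial goes to
#' the even half.
#'
#' @param accumulate Function taking a vector of trial indices and returning
#'   the average (numeric vector/array, possibly with NAs for undefined
#'   cells) over those trials.
#' @param n_trials Total number of trials, >= 2.
#' @return Object of class `plus_minus_estimate` with fields `even_average`,
#'   `odd_average`, `signal` (full average), `noise` (`(even - odd) / 2`) and
#'   `snr_db` (global, from rms over all defined cells).
#' @export
plus_minus <- function(accumulate, n_trials) {
  if (n_trials < 2) stop("plus-minus estimation needs at least 2 trials")
  even_idx <- seq(1L, n_trials, by = 2L)   # 0-based even = 1st, 3rd, ...
  odd_idx <- seq(2L, n_trials, by = 2L)
  even_avg <- accumulate(even_idx)
  odd_avg <- accumulate(odd_idx)
  full <- accumulate(seq_len(n_trials))
  noise <- (even_avg - odd_avg) / 2
  structure(list(even_average = even_avg, odd_average = odd_avg,
                 signal = full, noise = noise,
                 snr_db = snr_db(rms(full), rms(noise))),
            class = "plus_minus_estimate")
}

#' @export
print.plus_minus_estimate <- function(x, ...) {
  cat(sprintf("plus_minus_estimate: global SNR %.2f dB\n", x$snr_db))
  invisible(x)
}

#' Rose-criterion reliability mask
#'
#' Marks cells whose SNR meets the Rose criterion (default threshold 12 dB,
#' the lower end of the conventional 12-14 dB / 4-5x amplitude range).
#' Undefined (non-finite) cells are excluded and reported separately.
#'
#' @param per_cell_snr_db Numeric array of per-cell SNRs in dB (NA where
#'   undefined).
#' @param threshold_db Reliability threshold, default 12.
#' @return Logical array (NA where undefined) with attributes `n_failing`
#'   and `n_undefined`.
#' @export
rose_mask <- function(per_cell_snr_db, threshold_db = 12) {
  ok <- per_cell_snr_db >= threshold_db
  attr(ok, "n_failing") <- sum(!ok, na.rm = TRUE)
  attr(ok, "n_undefined") <- sum(is.na(per_cell_snr_db))
  ok
}
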
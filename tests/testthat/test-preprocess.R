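test_that("bandpass passes the band and rejects out-of-band tones", {
  fs <- 4000
  t <- (0:(4 * fs - 1)) / fs
  spec <- filter_spec(2, 50)
  mid <- round(length(t) * 0.25):round(length(t) * 0.75)
  # oracle: the designed filter's own frequency response at the tone
  gain_at <- function(f) Mod(stsca:::butter_response(f, spec))
  for (f0 in c(10, 30)) {
    y <- bandpass(recording(rbind(sin(2 * pi * f0 * t)), fs), spec)$signals[1, ]
    expect_equal(max(abs(y[mid])), gain_at(f0), tolerance = 0.01)
    expect_lt(abs(max(abs(y[mid])) - 1), 0.05)
  }
  y500 <- bandpass(recording(rbind(sin(2 * pi * 500 * t)), fs),
                   spec)$signals[1, ]
  expect_lt(max(abs(y500[mid])), 0.01)
  expect_lt(gain_at(500), 0.01)
  # all-zero in, all-zero out
  expect_equal(bandpass(recording(matrix(0, 2, 1000), fs), spec)$signals,
               matrix(0, 2, 1000))
  expect_error(bandpass(recording(rbind(t), fs), filter_spec(2, 3000)),
               "Nyquist")
})

test_that("zero-phase filtering preserves pulse symmetry and peak location", {
  fs <- 1000
  n <- 4000
  pulse <- exp(-((1:n) - 2000)^2 / (2 * 40^2))   # even about sample 2000
  y <- bandpass(recording(rbind(pulse), fs), filter_spec(2, 50))$signals[1, ]
  expect_equal(which.max(y), 2000)
  core <- 500:1500
  expect_equal(y[2000 + core], y[2000 - core], tolerance = 1e-6)
})

test_that("detect_spikes recovers injected deflections exactly", {
  df <- data.frame(channel_id = rep(1, 5),
                   time_s = c(0.05, 0.10, 0.15, 0.20, 0.25))
  mua <- simulate_mua(2, df, duration_s = 0.4, fs_hz = 30000, noise_sd = 1,
                      amplitude_sd = 10, seed = 5)
  sp <- detect_spikes(mua, detection_spec(4, 1))
  ev <- sp$events[sp$events$channel_id == 1, ]
  expected <- round(df$time_s * 30000) + 1
  expect_equal(nrow(ev), 5)
  expect_true(all(abs(sort(ev$sample_index) - expected) <= 2))
  # independent deepest-first oracle agrees on the same trace
  oracle <- oracle_detect(mua$signals[1, ], 4, round(0.001 * 30000))
  expect_equal(sort(ev$sample_index), oracle)
})

test_that("detection matches the brute-force oracle on pure noise", {
  set.seed(31)
  x <- rnorm(60000)
  rec <- recording(rbind(x), 30000)
  sp <- detect_spikes(rec, detection_spec(3, 1))
  expect_equal(sp$events$sample_index,
               oracle_detect(x, 3, round(0.001 * 30000)))
})

test_that("detection is scale-invariant and translation-equivariant", {
  df <- data.frame(channel_id = 1, time_s = c(0.1, 0.2))
  mua <- simulate_mua(1, df, duration_s = 0.3, fs_hz = 10000, seed = 2)
  sp <- detect_spikes(mua, detection_spec(4, 1))
  scaled <- mua
  scaled$signals <- mua$signals * 7.3
  expect_identical(detect_spikes(scaled, detection_spec(4, 1))$events,
                   sp$events)
  # circular shift keeps the trace statistics identical, so all events
  # (none of which sit near the edges) shift by exactly k
  n <- ncol(mua$signals)
  k <- 500
  shifted <- mua
  shifted$signals <- mua$signals[, c((n - k + 1):n, 1:(n - k)), drop = FALSE]
  sp_s <- detect_spikes(shifted, detection_spec(4, 1))
  expect_equal(sp_s$events$sample_index, sp$events$sample_index + k)
})

test_that("zero and fully-masked channels yield no events", {
  rec <- recording(matrix(0, 1, 1000), 1000)
  expect_equal(n_spikes(detect_spikes(rec, detection_spec(4, 1))), 0)
  rec2 <- recording(matrix(rnorm(1000), 1, 1000), 1000,
                    exclusion_mask = matrix(FALSE, 1, 1000))
  expect_warning(sp <- detect_spikes(rec2, detection_spec(4, 1)),
                 "fully masked")
  expect_equal(n_spikes(sp), 0)
})

test_that("array_mean_lfp equals the masked-mean oracle", {
  set.seed(8)
  sig <- matrix(rnorm(5 * 200), 5, 200)
  mask <- matrix(runif(5 * 200) > 0.3, 5, 200)
  mask[, 7] <- FALSE                      # one fully-masked sample
  rec <- recording(sig, 1000, exclusion_mask = mask)
  got <- array_mean_lfp(rec)
  oracle <- sapply(1:200, function(j) {
    v <- sig[mask[, j], j]
    if (length(v)) mean(v) else NA_real_
  })
  expect_equal(as.numeric(got), oracle)
  expect_equal(attr(got, "n_undefined"), 1)
  # identical channels -> that channel; +v/-v -> zero
  same <- recording(rbind(sig[1, ], sig[1, ]), 1000)
  expect_equal(as.numeric(array_mean_lfp(same)), sig[1, ])
  pm <- recording(rbind(sig[1, ], -sig[1, ]), 1000)
  expect_equal(as.numeric(array_mean_lfp(pm)), rep(0, 200))
})

test_that("decimation preserves amplitude, DC and length arithmetic", {
  fs <- 30000
  t <- (0:(2 * fs - 1)) / fs
  rec <- recording(rbind(sin(2 * pi * 10 * t)), fs)
  d <- decimate_lfp(rec, 1000)
  expect_equal(ncol(d$signals), round(length(t) / 30))
  expect_equal(d$fs_hz, 1000)
  expect_lt(abs(max(abs(d$signals[1, 500:1500])) - 1), 0.02)
  const <- decimate_lfp(recording(matrix(2.5, 1, fs), fs), 1000)
  expect_equal(const$signals[1, ], rep(2.5, 1000), tolerance = 1e-9)
  expect_error(decimate_lfp(rec, 60000), "exceeds")
})
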
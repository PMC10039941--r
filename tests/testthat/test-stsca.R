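test_that("a single spike yields the translated frame with 0/1 counts", {
  g <- mea_geometry()
  fs <- 100
  set.seed(1)
  sig <- matrix(rnorm(96 * 300), 96, 300)
  rec <- recording(sig, fs, g$channel_map$channel_id)
  ch <- g$channel_map$channel_id[40]
  sp <- spike_train(ch, 150, fs)
  res <- compute_stsca(rec, sp, g, window_s = 0.05)
  expect_true(all(res$counts %in% 0:1))
  W <- grid_halfwidth(g)
  pos <- stsca:::channel_positions(g, g$channel_map$channel_id)
  sp_pos <- stsca:::channel_positions(g, ch)
  for (i in c(1, 20, 96)) {   # spot-check translated placement
    psi <- pos[i, "row"] - sp_pos[1, "row"]
    xi <- pos[i, "col"] - sp_pos[1, "col"]
    expect_equal(res$values[psi + W, xi + W, ], sig[i, 150 + (-5:5)])
  }
})

test_that("counts accumulate to the geometric offset table", {
  gf <- array_geometry(10, 10, 0.4)
  fs <- 100
  rec <- recording(matrix(1, 100, 300), fs)
  sp <- spike_train(gf$channel_map$channel_id, rep(150, 100), fs)
  res <- compute_stsca(rec, sp, gf, window_s = 0.05)
  tab <- unname(offset_count_table(gf))
  for (k in seq_len(dim(res$counts)[3]))
    expect_equal(unname(res$counts[, , k]), tab)
  expect_true(all(abs(res$values[res$counts > 0] - 1) < 1e-12))
  expect_true(all(is.na(res$values[res$counts == 0])))
})

test_that("zero-noise non-overlapping kernel injection is recovered exactly", {
  fx <- fixture_exact()
  res <- compute_stsca(fx$lfp, fx$spikes, fx$geometry, window_s = 0.1)
  truth <- kernel_on_lag_grid(fx$kernel, res$axes)
  def <- res$counts > 0
  expect_lt(max(abs(res$values[def] - truth[def])), 1e-9)
  expect_equal(res$n_spikes, 200)
})

test_that("counts are tau-invariant and spike order is immaterial", {
  fx <- fixture_exact()
  res <- compute_stsca(fx$lfp, fx$spikes, fx$geometry, window_s = 0.05)
  expect_true(all(res$counts == c(res$counts[, , 1])))
  set.seed(2)
  perm <- sample(nrow(fx$spikes$events))
  sp2 <- spike_train(fx$spikes$events$channel_id[perm],
                     fx$spikes$events$sample_index[perm], fx$spikes$fs_hz)
  res2 <- compute_stsca(fx$lfp, sp2, fx$geometry, window_s = 0.05)
  expect_identical(res2$values, res$values)
})

test_that("spatial marginal equals the array-mean STA and the origin the own-channel STA", {
  g <- mea_geometry()
  fs <- 100
  set.seed(42)
  rec <- recording(matrix(rnorm(96 * 2000), 96, 2000), fs,
                   g$channel_map$channel_id)
  ch <- sample(g$channel_map$channel_id, 60, replace = TRUE)
  idx <- sample(seq(200, 1800), 60)
  sp <- spike_train(ch, idx, fs)
  res <- compute_stsca(rec, sp, g, window_s = 0.05)
  marg <- weighted_spatial_marginal(res)
  sta <- compute_sta(array_mean_lfp(rec), fs, spike_times_s(sp), 0.05)
  expect_equal(marg, sta$values, tolerance = 1e-12)
  # origin cell over tau = average of each spike's own-channel segment
  rows <- match(sp$events$channel_id, rec$channel_ids)
  own <- colMeans(t(sapply(seq_along(rows), function(j)
    rec$signals[rows[j], sp$events$sample_index[j] + (-5:5)])))
  W <- grid_halfwidth(g)
  expect_equal(res$values[W, W, ], own)
})

test_that("masked channel-samples contribute to neither values nor counts", {
  g <- array_geometry(3, 3, 0.5)
  fs <- 10
  sig <- matrix(seq_len(9 * 40), 9, 40)
  mask <- matrix(TRUE, 9, 40)
  mask[4, ] <- FALSE          # channel 4 always invalid
  mask[1, 19] <- FALSE        # one bad sample on channel 1
  rec <- recording(sig, fs, g$channel_map$channel_id, exclusion_mask = mask)
  sp <- spike_train(5, 20, fs)    # center channel
  res <- compute_stsca(rec, sp, g, window_s = 0.1)
  W <- 3
  pos <- stsca:::channel_positions(g, c(4, 1, 9))
  sppos <- stsca:::channel_positions(g, 5)
  at <- function(p) c(p[1, "row"] - sppos[1, "row"] + W,
                      p[1, "col"] - sppos[1, "col"] + W)
  a4 <- at(pos[1, , drop = FALSE])
  expect_true(all(res$counts[a4[1], a4[2], ] == 0))
  expect_true(all(is.na(res$values[a4[1], a4[2], ])))
  a1 <- at(pos[2, , drop = FALSE])    # channel 1: bad sample at frame lag -1
  expect_equal(res$counts[a1[1], a1[2], ], c(0, 1, 1))
  expect_equal(res$values[a1[1], a1[2], ], c(NA, sig[1, 20], sig[1, 21]))
  a9 <- at(pos[3, , drop = FALSE])    # untouched channel contributes fully
  expect_equal(res$counts[a9[1], a9[2], ], c(1, 1, 1))
  expect_equal(res$values[a9[1], a9[2], ], sig[9, 19:21])
})

test_that("spike-time randomization preserves counts and reproducibility", {
  fx <- fixture_exact()
  dur <- ncol(fx$lfp$signals) / fx$lfp$fs_hz
  r1 <- randomize_spike_times(fx$spikes, dur, seed = 9)
  r2 <- randomize_spike_times(fx$spikes, dur, seed = 9)
  expect_identical(r1$events, r2$events)
  expect_identical(table(r1$events$channel_id),
                   table(fx$spikes$events$channel_id))
  r3 <- randomize_spike_times(fx$spikes, dur, seed = 10)
  expect_false(identical(r3$events$sample_index, r1$events$sample_index))
})

test_that("randomization destroys the spatial pattern", {
  fx <- fixture_noisy(1000, seed = 12)
  dur <- ncol(fx$lfp$signals) / fx$lfp$fs_hz
  res <- compute_stsca(fx$lfp, fx$spikes, fx$geometry, 0.1)
  shuf <- randomize_spike_times(fx$spikes, dur, seed = 13)
  ctl <- compute_stsca(fx$lfp, shuf, fx$geometry, 0.1)
  sp_orig <- marginals(radial_reduce(res), 0.035)$spatial_component
  sp_ctl <- marginals(radial_reduce(ctl), 0.035)$spatial_component
  expect_lt(max(abs(sp_ctl), na.rm = TRUE),
            0.2 * max(abs(sp_orig), na.rm = TRUE))
})

test_that("whitening inverts the covariance square root", {
  set.seed(3)
  A <- matrix(rnorm(30 * 30), 30)
  C <- crossprod(A) / 30 + diag(0.1, 30)
  X <- t(chol(C)) %*% matrix(rnorm(30 * 4000), 30)
  rec <- recording(X, 1000)
  wm <- fit_whitening(rec)
  Cs <- cov(t(X))
  expect_lt(max(abs(wm$W_matrix %*% Cs %*% t(wm$W_matrix) - diag(30))), 1e-8)
  expect_lt(max(abs(wm$W_matrix - t(wm$W_matrix))), 1e-10)
  wrec <- apply_whitening(rec, wm)
  expect_lt(max(abs(cov(t(wrec$signals)) - diag(30))), 1e-8)
  # uncorrelated unit-variance channels: W ~ identity
  set.seed(4)
  X0 <- matrix(rnorm(20 * 20000), 20)
  wm0 <- fit_whitening(recording(X0, 1000))
  expect_lt(max(abs(wm0$W_matrix - diag(20))), 0.1)
  # identity model returns the mean-removed input
  wid <- wm0
  wid$W_matrix <- diag(20)
  out <- apply_whitening(recording(X0, 1000), wid)
  expect_equal(out$signals, X0 - wm0$mean_vector)
})

test_that("whitening errors are informative", {
  X <- matrix(rnorm(5 * 100), 5)
  X[5, ] <- X[1, ] + X[2, ]               # rank-deficient
  expect_error(fit_whitening(recording(X, 1000)), "ridge")
  expect_error(fit_whitening(recording(matrix(rnorm(20), 5, 4), 1000)),
               "samples")
  wm <- fit_whitening(recording(matrix(rnorm(500), 5, 100), 1000))
  bad <- recording(matrix(rnorm(400), 4, 100), 1000)
  expect_error(apply_whitening(bad, wm), "channel sets")
})

test_that("st-SCA input validation catches empty and off-array spikes", {
  g <- mea_geometry()
  rec <- recording(matrix(0, 96, 100), 100, g$channel_map$channel_id)
  expect_error(compute_stsca(rec, spike_train(1, 2, 100), g, 0.5),
               "retained")
  expect_error(compute_stsca(rec, spike_train(999, 50, 100), g, 0.1),
               "unknown channel")
})
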
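test_that("radial reduction bins by distance with count weighting", {
  g <- mea_geometry()
  side <- 19; T_len <- 5
  lag_mm <- (-9:9) * g$pitch_mm
  r_cell <- sqrt(outer(lag_mm^2, lag_mm^2, `+`))
  gfun <- function(r) exp(-r)                   # radially symmetric input
  values <- array(rep(gfun(r_cell), T_len), c(side, side, T_len))
  counts <- array(rep(unname(offset_count_table(g)), T_len),
                  c(side, side, T_len))
  values[counts == 0] <- NA
  res <- make_stsca(values, counts, g, 1000)
  rad <- radial_reduce(res)
  # oracle: enumerate member cells per bin and average with count weights
  bin <- floor(r_cell / g$pitch_mm) + 1
  for (b in c(1, 2, 4, 7)) {
    sel <- bin == b & counts[, , 1] > 0
    expect_equal(rad$values[b, 1],
                 sum(gfun(r_cell[sel]) * counts[, , 1][sel]) /
                   sum(counts[, , 1][sel]))
  }
  # first bin (width = pitch) holds only the origin cell
  expect_equal(rad$counts[1, 1], unname(offset_count_table(g)["0", "0"]))
  expect_equal(rad$values[1, 1], gfun(0))
  # weighted mass conservation
  expect_equal(sum(rad$values * rad$counts, na.rm = TRUE),
               sum(values * counts, na.rm = TRUE))
  # rotation by 90 degrees leaves the reduction unchanged
  rot_v <- values; rot_c <- counts
  for (k in 1:T_len) {
    rot_v[, , k] <- t(values[side:1, , k])
    rot_c[, , k] <- t(counts[side:1, , k])
  }
  rad_rot <- radial_reduce(make_stsca(rot_v, rot_c, g, 1000))
  expect_equal(rad_rot$values, rad$values)
})

test_that("a 2D sinc input reduces to the 1D sinc at bin-center radii", {
  g <- mea_geometry()
  s <- 1.0   # sinc scale comfortably resolved by 0.4 mm bins
  lag_mm <- (-9:9) * g$pitch_mm
  r_cell <- sqrt(outer(lag_mm^2, lag_mm^2, `+`))
  counts <- array(unname(offset_count_table(g)), c(19, 19, 1))
  values <- array(sinc(r_cell / s), c(19, 19, 1))
  values[counts == 0] <- NA
  rad <- radial_reduce(make_stsca(values, counts, g, 1000))
  ok <- is.finite(rad$values[, 1]) & !rad$incomplete_bins
  dev <- abs(rad$values[ok, 1] - sinc(rad$r_bin_centers_mm[ok] / s))
  expect_lt(max(dev), 0.02 * max(abs(values), na.rm = TRUE))
})

test_that("marginals reduce constants and separable kernels correctly", {
  g <- mea_geometry()
  counts <- array(unname(offset_count_table(g)), c(19, 19, 7))
  const <- array(3.5, c(19, 19, 7)); const[counts == 0] <- NA
  mg <- marginals(radial_reduce(make_stsca(const, counts, g, 1000)),
                  tau_window_s = 0.002)
  expect_equal(as.numeric(mg$temporal_component), rep(3.5, 7))
  expect_true(all(abs(mg$spatial_component[is.finite(mg$spatial_component)] -
                        3.5) < 1e-12))
  # separable a(r) b(tau): marginals proportional to b and (near) a
  lag_mm <- (-9:9) * g$pitch_mm
  r_cell <- sqrt(outer(lag_mm^2, lag_mm^2, `+`))
  a <- exp(-r_cell); b <- c(0.2, 0.5, 1, 2, 1, 0.5, 0.2)
  sep <- array(outer(as.vector(a), b), c(19, 19, 7))
  sep[counts == 0] <- NA
  rad <- radial_reduce(make_stsca(sep, counts, g, 1000))
  mg2 <- marginals(rad, tau_window_s = 0.002)
  expect_equal(as.numeric(mg2$temporal_component / mg2$temporal_component[3]),
               b / b[3])
  prof <- rad$values[, 4]                     # tau with b = 2
  ratio <- mg2$spatial_component / prof
  expect_lt(diff(range(ratio[is.finite(ratio)])), 1e-12)
  expect_error(marginals(rad, tau_window_s = 1), "exceeds")
})

test_that("the temporal component reproduces the array-mean STA", {
  g <- mea_geometry()
  fs <- 100
  set.seed(6)
  rec <- recording(matrix(rnorm(96 * 1500), 96, 1500), fs,
                   g$channel_map$channel_id)
  sp <- spike_train(sample(g$channel_map$channel_id, 40, replace = TRUE),
                    sample(200:1300, 40), fs)
  res <- compute_stsca(rec, sp, g, 0.05)
  mg <- marginals(radial_reduce(res), tau_window_s = 0.05)
  sta <- compute_sta(array_mean_lfp(rec), fs, spike_times_s(sp), 0.05)
  expect_equal(as.numeric(mg$temporal_component), sta$values, tolerance = 1e-12)
})

test_that("peak separation finds sinc lobes and rejects wells", {
  r <- seq(0, 4, by = 0.05)
  s <- 0.8
  prof <- -sinc(r / s)
  pk <- peak_separation(prof, r)
  expect_true(pk$found)
  first_lobe <- stsca:::SINC_FIRST_LOBE * s
  expect_lt(abs(pk$separation_mm - 2 * first_lobe), 0.05)
  expect_equal(pk$trough_r_mm, 0)
  # Gaussian well: no flanking maxima
  well <- -exp(-r^2 / 2)
  expect_false(peak_separation(well, r)$found)
  # monotone profile
  expect_false(peak_separation(seq(1, 0, length.out = 30),
                               seq(0, 3, length.out = 30))$found)
})

test_that("synthetic sinc fixture yields ~2.5 mm separation; well yields none", {
  fx <- fixture_exact()
  res <- compute_stsca(fx$lfp, fx$spikes, fx$geometry, 0.1)
  rad <- radial_reduce(res)
  pk <- peak_separation(marginals(rad, 0.035)$spatial_component)
  expect_true(pk$found)
  expect_lt(abs(pk$separation_mm - 2.5), rad$r_bin_edges_mm[2])  # one bin
  # gaussian well world
  g <- fx$geometry
  ker <- kernel_spec("gaussian_well", -50, 1.0, 0.02)
  sched <- spike_schedule(g, 100, 0.25, 0.3, seed = 21)
  sim <- simulate_recording(sim_config(g, max(sched$time_s) + 0.3, 1000,
                                       ker, seed = 21, spike_times = sched,
                                       kernel_support_s = 0.1))
  resw <- compute_stsca(sim$lfp, sim$spikes, g, 0.1)
  pkw <- peak_separation(marginals(radial_reduce(resw),
                                   0.035)$spatial_component)
  expect_false(pkw$found)
})

test_that("symmetry score is small for a symmetric map, large for a tilted one", {
  g <- mea_geometry()
  counts <- array(unname(offset_count_table(g)), c(19, 19, 3))
  lag_mm <- (-9:9) * g$pitch_mm
  r_cell <- sqrt(outer(lag_mm^2, lag_mm^2, `+`))
  sym <- array(exp(-r_cell), c(19, 19, 3)); sym[counts == 0] <- NA
  s_sym <- radial_symmetry_score(make_stsca(sym, counts, g, 1000), 0.001)
  tilt <- sym + array(rep(outer(rep(1, 19), lag_mm), 3), c(19, 19, 3))
  s_tilt <- radial_symmetry_score(make_stsca(tilt, counts, g, 1000), 0.001)
  expect_lt(s_sym, 1e-10)
  expect_gt(s_tilt, s_sym)
})
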
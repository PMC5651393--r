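test_that("dummy-volume removal drops exactly the leading frames", {
  co <- clean_cohort(n_pairs = 1, n_frames = 10, seed = 2)
  v <- co$subjects[[1]]$volume
  out <- drop_dummy_volumes(v, 3)
  expect_equal(n_frames(out), 7)
  expect_equal(out$data[, , , 1], v$data[, , , 4])
  expect_identical(drop_dummy_volumes(v, 0), v)
  expect_error(drop_dummy_volumes(v, 10), "cannot drop")
})

test_that("DVARS flags a planted deviation at every threshold and never frame 1", {
  co <- clean_cohort(n_pairs = 1, n_frames = 100, noise_sd = 0.3, seed = 8)
  vs <- plant_spikes(co$subjects[[1]]$volume, 40, amp_sd = 10, seed = 2)
  for (th in c(2.5, 3.0, 4.0)) {
    s <- detect_spikes_dvars(vs, th)
    expect_true(any(s$frames %in% c(40, 41)))
    expect_false(1 %in% s$frames)
    expect_true(is.na(s$dvars[1]))
  }
})

test_that("spike sets are nested across the three thresholds", {
  co <- generate_cohort(synth_config(n_pairs = 2, n_frames = 120,
                                     spike_rate_per_min = 2, seed = 9))
  for (s in co$subjects) {
    f25 <- detect_spikes_dvars(s$volume, 2.5)$frames
    f30 <- detect_spikes_dvars(s$volume, 3.0)$frames
    f40 <- detect_spikes_dvars(s$volume, 4.0)$frames
    expect_true(all(f40 %in% f30))
    expect_true(all(f30 %in% f25))
    expect_true(all(diff(f25) > 0))
  }
})

test_that("a constant series yields an empty spike set with a warning", {
  v <- volume_series(array(7, dim = c(4, 4, 4, 10)))
  expect_warning(s <- detect_spikes_dvars(v, 3), "zero variance")
  expect_length(s$frames, 0)
})

test_that("stationary noise at 4 SD flags roughly the Gaussian tail fraction", {
  # Monte-Carlo oracle: DVARS of white noise is approximately Gaussian, so
  # the one-sided 4-SD exceedance rate should be far below 1% of frames
  set.seed(31)
  rates <- replicate(30, {
    v <- volume_series(array(100 + rnorm(6 * 6 * 6 * 80), dim = c(6, 6, 6, 80)))
    length(detect_spikes_dvars(v, 4.0)$frames) / 79
  })
  expect_lt(mean(rates), 0.01)
  rates25 <- replicate(10, {
    v <- volume_series(array(100 + rnorm(6 * 6 * 6 * 80), dim = c(6, 6, 6, 80)))
    length(detect_spikes_dvars(v, 2.5)$frames) / 79
  })
  expect_gt(mean(rates25), mean(rates))   # lower threshold flags more
})

test_that("regressor matrices have the documented structure", {
  ra <- synth_motion_trace(50, 0.3, seed = 4)
  expect_equal(ncol(build_regressors(ra, parts = "motion")$values), 6)
  expect_equal(ncol(build_regressors(ra, parts = "trends")$values), 3)
  sp <- structure(list(frames = c(10L, 40L), threshold_sd = 3,
                       dvars = rep(1, 50)), class = "spike_set")
  full <- build_regressors(ra, sp)
  expect_equal(ncol(full$values), 3 + 6 + 6 + 2)
  expect_equal(sum(full$values[, "spike-40"]), 1)
  expect_equal(unname(full$values[40, "spike-40"]), 1)
  # derivatives are backward differences with 0 at frame 1
  expect_equal(unname(full$values[1, "mpd-1"]), 0)
  expect_equal(full$values[-1, "mpd-3"], unname(diff(ra[, 3])))
  expect_error(build_regressors(ra, n_frames = 49, parts = "motion"), "match")
})

test_that("nuisance regression produces exactly orthogonal residuals", {
  set.seed(12)
  ra <- synth_motion_trace(60, 0.4, seed = 3)
  reg <- build_regressors(ra)
  y <- matrix(rnorm(60 * 5), 60)
  res <- regress_nuisance(y, reg)
  for (j in seq_len(ncol(reg$values))) {
    ip <- abs(sum(res[, 2] * reg$values[, j]))
    expect_lt(ip, 1e-8 * sqrt(sum(res[, 2]^2) * sum(reg$values[, j]^2)) + 1e-12)
  }
  # a signal equal to a regressor column is annihilated
  res2 <- regress_nuisance(cbind(ra[, 1]), reg)
  expect_lt(max(abs(res2)), 1e-10)
  # zero regressor parts = mean centering
  empty <- structure(list(values = matrix(0, 60, 0), labels = character(0)),
                     class = "regressor_matrix")
  expect_equal(regress_nuisance(y, empty), scale(y, scale = FALSE),
               ignore_attr = TRUE)
})

test_that("motion regression removes the planted rank-1 leakage", {
  co <- generate_cohort(synth_config(n_pairs = 1, n_frames = 120,
                                     motion_amp_mm = 1, motion_coupling = 5,
                                     noise_sd = 0.1, spike_rate_per_min = 0,
                                     seed = 13))
  s <- co$subjects[[1]]
  trn_mag <- sqrt(rowSums(s$realign[, 1:3]^2))
  y <- dfncpipe:::vol_as_matrix(s$volume)
  # pick the voxel with the strongest gradient loading
  vox <- which.max(abs(co$truth$grad_map))
  expect_gt(abs(stats::cor(y[, vox], trn_mag)), 0.5)
  reg <- build_regressors(s$realign, parts = c("trends", "motion", "derivatives"))
  res <- regress_nuisance(s$volume, reg)
  rmat <- dfncpipe:::vol_as_matrix(res)
  expect_lt(abs(stats::cor(rmat[, vox], trn_mag)), 0.15)
})

test_that("spatial smoothing preserves constants, means, and the Gaussian kernel shape", {
  co <- clean_cohort(n_pairs = 1, n_frames = 8, noise_sd = 0.5, seed = 3)
  v <- co$subjects[[1]]$volume
  expect_identical(smooth_spatial(v, 0), v)
  # constant frame unchanged
  vc <- volume_series(array(4, dim = c(6, 6, 6, 2)))
  expect_equal(smooth_spatial(vc, 6)$data, vc$data)
  # frame means preserved under reflective boundaries
  sm <- smooth_spatial(v, 6)
  expect_equal(apply(sm$data, 4, mean), apply(v$data, 4, mean), tolerance = 1e-12)
  # impulse response matches the closed-form separable Gaussian
  a <- array(0, dim = c(9, 9, 9, 1))
  a[5, 5, 5, 1] <- 1
  vi <- volume_series(a, voxel_mm = c(3, 3, 3))
  out <- smooth_spatial(vi, 6)$data[, , , 1]
  sig <- 6 / (3 * 2 * sqrt(2 * log(2)))
  k1 <- exp(-((-3):3)^2 / (2 * sig^2))
  k1 <- k1 / sum(k1)
  expected <- outer(outer(k1, k1), k1)
  expect_equal(out[2:8, 2:8, 2:8], expected, tolerance = 1e-12, ignore_attr = TRUE)
  # half-maximum radius: at distance fwhm/2 the kernel is half its center value
  expect_equal(out[5 + 1, 5, 5] / out[5, 5, 5], 0.5, tolerance = 0.01)
})

test_that("spike interpolation restores smooth signals and is identity-safe", {
  no_spikes <- structure(list(frames = integer(0), threshold_sd = 3,
                              dvars = rep(1, 50)), class = "spike_set")
  y <- matrix(rnorm(100), 50)
  expect_identical(interpolate_spikes(y, no_spikes), y)
  # a cubic is reproduced exactly through a zeroed interior frame
  x <- seq_len(50)
  cubic <- 0.02 * x^3 - 0.5 * x^2 + 3 * x - 7
  sp <- structure(list(frames = 20L, threshold_sd = 3, dvars = rep(1, 50)),
                  class = "spike_set")
  broken <- cbind(replace(cubic, 20, 0))
  expect_equal(interpolate_spikes(broken, sp)[20], cubic[20], tolerance = 1e-6)
  # a sinusoid with three interior spikes is restored within 5% of amplitude
  s <- sin(2 * pi * seq_len(60) / 25)
  sp3 <- structure(list(frames = c(15L, 30L, 44L), threshold_sd = 3,
                        dvars = rep(1, 60)), class = "spike_set")
  fixed <- interpolate_spikes(cbind(replace(s, c(15, 30, 44), 0)), sp3)
  expect_lt(max(abs(fixed[c(15, 30, 44)] - s[c(15, 30, 44)])), 0.05)
  # boundary spikes fall back to the nearest valid frame, with a warning
  spb <- structure(list(frames = 1L, threshold_sd = 3, dvars = rep(1, 60)),
                   class = "spike_set")
  expect_warning(out <- interpolate_spikes(cbind(s), spb), "boundary")
  expect_equal(out[1], s[2])
})

test_that("the band-pass filter has the designed frequency response", {
  t <- seq(0, 144) * 2
  amp_at <- function(y, f) {
    x <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
    sqrt(sum(qr.coef(qr(x), y)^2))
  }
  # DC is removed
  expect_lt(max(abs(bandpass_filter(cbind(rep(3, 145)), tr_s = 2))), 1e-10)
  # passband centre amplitude preserved within 5%
  y1 <- bandpass_filter(cbind(sin(2 * pi * 0.05 * t)), tr_s = 2)[, 1]
  expect_lt(abs(amp_at(y1, 0.05) - 1), 0.05)
  # 0.25 Hz (Nyquist-side stopband) attenuated by more than 90%
  y2 <- bandpass_filter(cbind(cos(2 * pi * 0.249 * t)), tr_s = 2)[, 1]
  expect_lt(amp_at(y2, 0.249), 0.1)
  # filtering twice changes passband content by less than 10%
  y11 <- bandpass_filter(cbind(y1), tr_s = 2)[, 1]
  expect_lt(abs(amp_at(y11, 0.05) - amp_at(y1, 0.05)) / amp_at(y1, 0.05), 0.1)
  expect_error(bandpass_filter(cbind(t), high_hz = 0.3, tr_s = 2), "Nyquist")
})

test_that("pipeline plans are exactly the four published orderings", {
  plans <- pipeline_plans()
  expect_named(plans, c("PA", "PB", "PC", "PD"))
  expect_equal(plans$PA, c("SpkMotReg", "Smoothing", "gICA", "Interp", "Filter"))
  expect_equal(plans$PB, c("MotReg", "Smoothing", "gICA", "SpkReg", "Interp", "Filter"))
  expect_equal(plans$PC, c("SpkReg", "Smoothing", "gICA", "MotReg", "Interp", "Filter"))
  expect_equal(plans$PD, c("Smoothing", "gICA", "SpkMotReg", "Interp", "Filter"))
  expect_equal(pipeline_config("PB")$step_plan, plans$PB)
  # SpkMotReg after gICA only in PD; every plan ends Interp -> Filter
  for (id in names(plans)) {
    p <- plans[[id]]
    expect_equal(utils::tail(p, 2), c("Interp", "Filter"))
    gica_pos <- match("gICA", p)
    if (id == "PD") expect_gt(match("SpkMotReg", p), gica_pos)
    if (id == "PA") expect_lt(match("SpkMotReg", p), gica_pos)
  }
  expect_error(pipeline_config("PE"), "must be one of")
})

test_that("PA and PD agree on motion-free, spike-free, low-noise data", {
  co <- clean_cohort(n_pairs = 4, n_frames = 120, noise_sd = 0.05, seed = 10)
  pps <- lapply(c("PA", "PD"), function(p) {
    run_pipeline(co, pipeline_config(p, 3, 5, 15), gica_runs = 2, seed = 3)
  })
  al <- align_components(pps[[1]]$components, pps[[2]]$components)
  expect_true(all(attr(al, "match_corr") > 0.95))
  perm <- attr(al, "perm")
  signs <- attr(al, "signs")
  tcs2 <- lapply(pps[[2]]$tcs, function(tc) sweep(tc[, perm, drop = FALSE], 2, signs, "*"))
  sm1 <- cluster_states(lapply(pps[[1]]$tcs, windowed_correlation,
                               taper = make_taper(15)), 2, restarts = 2, seed = 5)
  sm2 <- cluster_states(lapply(tcs2, windowed_correlation,
                               taper = make_taper(15)), 2, restarts = 2, seed = 5)
  expect_true(all(match_states(sm1, sm2)$correlations > 0.95))
})

test_that("run_pipeline records provenance and cleans component time courses", {
  co <- small_cohort(n_pairs = 2, n_frames = 60, seed = 5)
  pp <- run_pipeline(co, pipeline_config("PB", 3, 4, 15), gica_runs = 2, seed = 1)
  steps <- vapply(pp$log, `[[`, "", "step")
  expect_equal(steps, c("DropDummy", "DVARS", "MotReg", "Smoothing", "gICA",
                        "SpkReg", "Interp", "Filter"))
  expect_length(pp$tcs, 4)
  expect_equal(dim(pp$tcs[[1]]), c(55, 4))
  expect_true(all(is.finite(unlist(pp$tcs))))
})
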
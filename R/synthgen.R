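# Synthetic cohort generator: matched patient/control subjects with planted
# spatial sources, state-switching connectivity, motion leakage and spikes.
# Every downstream stage of the package is testable against the ground truth
# this module emits.

#' Default planted connectivity states
#'
#' Two clearly separated source-correlation states: a "segregated" state with
#' two strongly intra-connected, mutually anti-correlated source blocks, and
#' an "integrated" state with strong cross-block and weak within-block
#' coupling. Couplings are shrunk if needed so both matrices are positive
#' semi-definite with margin.
#'
#' @param n_sources number of planted sources.
#' @return List of two unit-diagonal correlation matrices.
#' @export
default_state_covs <- function(n_sources = 5) {
  abort_if(n_sources < 2, "need at least 2 sources")
  b1 <- seq_len(ceiling(n_sources / 2))
  b2 <- setdiff(seq_len(n_sources), b1)
  shrink_to_psd <- function(build, scale = 1) {
    repeat {
      s <- build(scale)
      if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) > 0.01) return(s)
      scale <- scale * 0.9
    }
  }
  s1 <- shrink_to_psd(function(sc) {
    s <- matrix(-0.3 * sc, n_sources, n_sources)
    s[b1, b1] <- 0.8 * sc
    s[b2, b2] <- 0.8 * sc
    diag(s) <- 1
    s
  })
  s2 <- shrink_to_psd(function(sc) {
    s <- matrix(0.2 * sc, n_sources, n_sources)
    s[b1, b2] <- 0.5 * sc
    s[b2, b1] <- 0.5 * sc
    diag(s) <- 1
    s
  })
  list(segregated = s1, integrated = s2)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study design the generator emulates: 50 matched
#' patient/control pairs, 5-minute runs at TR = 2 s (150 frames, the first 5
#' treated as dummies downstream), planted smooth spatial sources whose time
#' courses switch between connectivity states, a 20-percentage-point group
#' difference in state occupancy, motion-coupled signal leakage, and sparse
#' global intensity spikes.
#'
#' @param n_pairs matched HC/mTBI pairs (total subjects = `2 * n_pairs`).
#' @param grid_shape length-3 spatial grid (voxels).
#' @param n_sources number of planted spatial sources.
#' @param n_frames frames per run, including dummy frames.
#' @param tr_s repetition time (seconds).
#' @param state_covs list of source-by-source correlation matrices, one per
#'   planted state; each must be symmetric positive semi-definite with unit
#'   diagonal.
#' @param occupancy_by_group matrix (groups x states, rownames `HC`, `mTBI`)
#'   of target occupancy fractions; rows must sum to 1.
#' @param dwell_mean_tr mean state dwell time in TRs.
#' @param motion_amp_mm scale of the simulated realignment traces (mm).
#' @param motion_coupling strength of motion-to-signal leakage (intensity
#'   units per mm of translation magnitude).
#' @param spike_rate_per_min expected spikes per minute of scan.
#' @param spike_amp_sd spike amplitude in units of per-voxel baseline SD.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param voxel_mm voxel size in mm.
#' @param baseline mean tissue intensity added to every voxel.
#' @param seed integer RNG seed; the whole cohort is deterministic given it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_pairs = 50,
                         grid_shape = c(8, 8, 8),
                         n_sources = 5,
                         n_frames = 150,
                         tr_s = 2,
                         state_covs = default_state_covs(n_sources),
                         occupancy_by_group = rbind(HC = c(0.6, 0.4), mTBI = c(0.4, 0.6)),
                         dwell_mean_tr = 25,
                         motion_amp_mm = 0.25,
                         motion_coupling = 1,
                         spike_rate_per_min = 0.5,
                         spike_amp_sd = 5,
                         noise_sd = 0.4,
                         voxel_mm = c(3, 3, 3),
                         baseline = 100,
                         seed = 1) {
  cfg <- list(n_pairs = as.integer(n_pairs), grid_shape = as.integer(grid_shape),
              n_sources = as.integer(n_sources), n_frames = as.integer(n_frames),
              tr_s = tr_s, state_covs = state_covs,
              occupancy_by_group = as.matrix(occupancy_by_group),
              dwell_mean_tr = dwell_mean_tr, motion_amp_mm = motion_amp_mm,
              motion_coupling = motion_coupling,
              spike_rate_per_min = spike_rate_per_min, spike_amp_sd = spike_amp_sd,
              noise_sd = noise_sd, voxel_mm = voxel_mm, baseline = baseline,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  abort_if(cfg$n_pairs < 1, "n_pairs must be >= 1")
  abort_if(length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 4),
           "grid_shape must be 3 dimensions, each >= 4 voxels")
  abort_if(cfg$n_frames < 8, "n_frames must be >= 8")
  for (i in seq_along(cfg$state_covs)) {
    s <- cfg$state_covs[[i]]
    abort_if(!isTRUE(all.equal(s, t(s), tolerance = 1e-10)),
             sprintf("state covariance %d is not symmetric", i))
    abort_if(any(abs(diag(s) - 1) > 1e-10),
             sprintf("state covariance %d must have unit diagonal", i))
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    abort_if(min(ev) < -1e-8,
             sprintf("state covariance %d is not positive semi-definite (min eigenvalue %.3g)",
                     i, min(ev)))
    abort_if(nrow(s) != cfg$n_sources, "state covariance size must match n_sources")
  }
  occ <- cfg$occupancy_by_group
  abort_if(!all(rownames(occ) %in% c("HC", "mTBI")) || nrow(occ) != 2,
           "occupancy_by_group needs rows HC and mTBI")
  abort_if(ncol(occ) != length(cfg$state_covs),
           "occupancy_by_group must have one column per state")
  abort_if(any(abs(rowSums(occ) - 1) > 1e-8), "occupancy rows must sum to 1")
  abort_if(any(occ < 0), "occupancy fractions must be nonnegative")
  for (nm in c("dwell_mean_tr", "motion_amp_mm", "motion_coupling",
               "spike_rate_per_min", "spike_amp_sd", "noise_sd")) {
    abort_if(cfg[[nm]] < 0, sprintf("%s must be nonnegative", nm))
  }
  invisible(cfg)
}

# Gaussian temporal smoothing of matrix columns with half-sample symmetric
# (reflective) boundary handling; keeps source spectra low-frequency.
smooth_columns <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(x)
  pidx <- reflect_index(seq.int(1L - r, n + r), n)
  xp <- x[pidx, , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(k)) out <- out + k[j] * xp[j:(j + n - 1L), , drop = FALSE]
  out
}

# half-sample symmetric reflection of out-of-range indices into 1..n
reflect_index <- function(p, n) {
  p <- ((p - 1L) %% (2L * n)) + 1L
  ifelse(p > n, 2L * n - p + 1L, p)
}

# Draw a state sequence from a semi-Markov chain with geometric dwell times.
# Per-state mean dwell is proportional to the target occupancy, and the
# embedded jump chain is uniform over the other states, so the long-run
# occupancy matches the target exactly in expectation.
draw_state_sequence <- function(n_frames, occ, dwell_mean) {
  active <- which(occ > 0)
  if (length(active) == 1L) return(rep(active, n_frames))
  dwell <- dwell_mean * length(active) * occ
  seq_out <- integer(0)
  state <- sample(active, 1, prob = occ[active])
  while (length(seq_out) < n_frames) {
    d <- stats::rgeom(1, prob = min(1, 1 / max(dwell[state], 1))) + 1L
    seq_out <- c(seq_out, rep(state, d))
    nxt <- setdiff(active, state)
    state <- if (length(nxt) == 1L) nxt else sample(nxt, 1)
  }
  seq_out[seq_len(n_frames)]
}

# matrix square root by eigendecomposition (handles PSD with zero eigenvalues)
mat_sqrt <- function(s) {
  e <- eigen(s, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (t(e$vectors) * sqrt(ev))
}

# Generate source time courses whose sample correlation over the frames of
# each state equals the planted state matrix exactly when a single state is
# present (and to sampling accuracy under state switching): smoothed Gaussian
# series are empirically whitened over the whole run and coloured by each
# state's correlation matrix.
draw_source_tcs <- function(n_frames, state_seq, state_covs) {
  n_src <- nrow(state_covs[[1]])
  per_state <- lapply(state_covs, function(sigma) {
    x <- matrix(stats::rnorm(n_frames * n_src), n_frames, n_src)
    x <- smooth_columns(x, sigma = 1)
    x <- scale(x, center = TRUE, scale = FALSE)
    cc <- crossprod(x) / (n_frames - 1)
    xw <- x %*% solve(chol(cc))
    xw %*% mat_sqrt(sigma)
  })
  tc <- matrix(0, n_frames, n_src)
  for (m in seq_along(per_state)) {
    idx <- which(state_seq == m)
    if (length(idx)) tc[idx, ] <- per_state[[m]][idx, , drop = FALSE]
  }
  tc
}

# Smooth Gaussian blob source maps on the grid, resampled until all pairwise
# spatial correlations are below max_corr so ICA is identifiable.
draw_source_maps <- function(grid_shape, n_sources, max_corr = 0.3, max_tries = 500) {
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                  y = seq_len(grid_shape[2]),
                                  z = seq_len(grid_shape[3])))
  maps <- matrix(0, n_sources, nrow(coords))
  placed <- 0
  tries <- 0
  while (placed < n_sources) {
    tries <- tries + 1
    abort_if(tries > max_tries,
             "could not place sources with pairwise spatial correlation below threshold; enlarge the grid")
    centre <- 1.5 + stats::runif(3) * (grid_shape - 3)
    sigma <- (min(grid_shape) / 6) * (0.9 + stats::runif(1, 0, 0.4))
    d2 <- rowSums(sweep(coords, 2, centre)^2)
    m <- exp(-d2 / (2 * sigma^2))
    m <- m / max(m)
    ok <- TRUE
    if (placed > 0) {
      cc <- abs(stats::cor(m, t(maps[seq_len(placed), , drop = FALSE])))
      ok <- all(cc < max_corr)
    }
    if (ok) {
      placed <- placed + 1
      maps[placed, ] <- m
    }
  }
  maps
}

#' Simulate a realignment-parameter trace
#'
#' Produces a smooth random-walk head-motion trace with occasional jumps for
#' the six realignment parameters (three translations in mm, three rotations
#' in radians). The trace is linear in `amp_mm`: doubling the amplitude
#' exactly doubles the trace (and hence any displacement summary computed
#' from it). Rotation columns are scaled by 0.02 radians per mm of amplitude.
#'
#' @param n_frames number of frames (>= 2).
#' @param amp_mm amplitude scale in mm; 0 yields an all-zero trace.
#' @param seed RNG seed.
#' @return `n_frames` x 6 matrix with columns
#'   `d_x`, `d_y`, `d_z`, `d_pitch`, `d_yaw`, `d_roll`.
#' @export
synth_motion_trace <- function(n_frames, amp_mm, seed = 1) {
  abort_if(n_frames < 2, "motion trace needs at least 2 frames")
  abort_if(amp_mm < 0, "amp_mm must be nonnegative")
  base <- with_local_seed(seed, {
    sapply(1:6, function(j) {
      steps <- stats::rnorm(n_frames, sd = 0.1)
      jumps <- stats::rbinom(n_frames, 1, 0.02) * stats::rnorm(n_frames, sd = 1)
      tr <- cumsum(steps + jumps)
      drop(smooth_columns(matrix(tr, ncol = 1), sigma = 1))
    })
  })
  out <- sweep(base, 2, c(rep(amp_mm, 3), rep(amp_mm * 0.02, 3)), `*`)
  colnames(out) <- c("d_x", "d_y", "d_z", "d_pitch", "d_yaw", "d_roll")
  out
}

#' Add global intensity spikes to selected frames
#'
#' Each listed frame gains a global deviation of `amp_sd` per-voxel baseline
#' standard deviations (random sign per frame, drawn under `seed`). All other
#' frames are untouched; an empty frame list returns the input unchanged.
#'
#' @param series a `volume_series`.
#' @param frames 1-based frame indices to perturb.
#' @param amp_sd spike amplitude in units of each voxel's temporal SD.
#' @param seed RNG seed for the per-frame spike signs.
#' @return The perturbed `volume_series`.
#' @export
plant_spikes <- function(series, frames, amp_sd, seed = 1) {
  stopifnot(inherits(series, "volume_series"))
  if (length(frames) == 0L) return(series)
  nt <- n_frames(series)
  bad <- frames[frames < 1 | frames > nt]
  abort_if(length(bad) > 0,
           sprintf("spike frame %d out of range 1..%d", bad[1], nt))
  y <- vol_as_matrix(series)
  sd_v <- apply(y, 2, stats::sd)
  sd_v[sd_v < .Machine$double.eps] <- mean(sd_v[sd_v > 0]) %||% 1
  signs <- with_local_seed(seed, sample(c(-1, 1), length(frames), replace = TRUE))
  for (i in seq_along(frames)) {
    y[frames[i], ] <- y[frames[i], ] + signs[i] * amp_sd * sd_v
  }
  vol_from_matrix(y, series)
}

#' Generate a synthetic matched cohort
#'
#' Builds `2 * n_pairs` subjects (one HC and one mTBI per matched pair) whose
#' voxel signal is a sum of planted spatial sources times state-switching
#' time courses, a rank-1 motion-coupled leakage term (spatial gradient map
#' times translation magnitude), additive Gaussian noise, and a constant
#' baseline; sparse global spikes are planted on top. The full ground truth
#' (maps, time courses, state sequences, spike frames) is returned alongside
#' the data.
#'
#' @param cfg a `synth_config`.
#' @return A `cohort_data` list with elements `subjects` (each holding
#'   `subject_id`, `group`, `pair_id`, `age`, `gender`, `volume`, `realign`)
#'   and `truth` (`maps`, `grad_map`, `source_tcs`, `state_seq`,
#'   `spike_frames`), plus the generating `config`.
#' @export
generate_cohort <- function(cfg) {
  validate_synth_config(cfg)
  with_local_seed(derive_seed(cfg$seed, "cohort"), {
    maps <- draw_source_maps(cfg$grid_shape, cfg$n_sources)
    nvox <- ncol(maps)
    xcoord <- as.matrix(expand.grid(x = seq_len(cfg$grid_shape[1]),
                                    y = seq_len(cfg$grid_shape[2]),
                                    z = seq_len(cfg$grid_shape[3])))[, 1]
    grad_map <- (xcoord - mean(xcoord)) / max(abs(xcoord - mean(xcoord)))

    n_sub <- 2L * cfg$n_pairs
    pair_gender <- rep(c("F", "M"), length.out = cfg$n_pairs)
    subjects <- vector("list", n_sub)
    truth_tcs <- vector("list", n_sub)
    truth_seq <- vector("list", n_sub)
    truth_spk <- vector("list", n_sub)

    idx <- 0L
    for (p in seq_len(cfg$n_pairs)) {
      age_mtbi <- max(18, stats::rnorm(1, 28, 9))
      age_hc <- max(18, age_mtbi + stats::runif(1, -3, 3))
      for (grp in c("HC", "mTBI")) {
        idx <- idx + 1L
        sid <- sprintf("sub-%03d", idx)
        sseed <- derive_seed(cfg$seed, "subject", idx)
        occ <- cfg$occupancy_by_group[grp, ]
        dat <- with_local_seed(sseed, {
          state_seq <- draw_state_sequence(cfg$n_frames, occ, cfg$dwell_mean_tr)
          tcs <- draw_source_tcs(cfg$n_frames, state_seq, cfg$state_covs)
          realign <- synth_motion_trace(cfg$n_frames, cfg$motion_amp_mm,
                                        seed = derive_seed(sseed, "motion"))
          trn_mag <- sqrt(rowSums(realign[, 1:3, drop = FALSE]^2))
          y <- cfg$baseline + tcs %*% maps +
            cfg$motion_coupling * outer(trn_mag, grad_map)
          if (cfg$noise_sd > 0) {
            y <- y + matrix(stats::rnorm(length(y), sd = cfg$noise_sd),
                            nrow(y), ncol(y))
          }
          n_spk <- stats::rpois(1, cfg$spike_rate_per_min * cfg$n_frames * cfg$tr_s / 60)
          spike_frames <- sort(unique(sample(2:cfg$n_frames, min(n_spk, cfg$n_frames - 1L))))
          list(state_seq = state_seq, tcs = tcs, realign = realign,
               y = y, spike_frames = spike_frames)
        })
        vol <- volume_series(array(t(dat$y), dim = c(cfg$grid_shape, cfg$n_frames)),
                             voxel_mm = cfg$voxel_mm, tr_s = cfg$tr_s)
        if (length(dat$spike_frames) && cfg$spike_amp_sd > 0) {
          vol <- plant_spikes(vol, dat$spike_frames, cfg$spike_amp_sd,
                              seed = derive_seed(sseed, "spike-signs"))
        }
        subjects[[idx]] <- list(subject_id = sid, group = grp,
                                pair_id = sprintf("pair-%02d", p),
                                age = round(if (grp == "HC") age_hc else age_mtbi, 1),
                                gender = pair_gender[p],
                                volume = vol, realign = dat$realign)
        truth_tcs[[idx]] <- dat$tcs
        truth_seq[[idx]] <- dat$state_seq
        truth_spk[[idx]] <- dat$spike_frames
      }
    }
    names(subjects) <- vapply(subjects, `[[`, "", "subject_id")
    structure(list(subjects = subjects,
                   truth = list(maps = maps, grad_map = grad_map,
                                source_tcs = truth_tcs, state_seq = truth_seq,
                                spike_frames = truth_spk),
                   config = cfg),
              class = "cohort_data")
  })
}

#' @export
print.cohort_data <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf("cohort_data: %d subjects (%d HC, %d mTBI), grid %s, %d frames, %d sources, %d states\n",
              length(x$subjects), sum(grp == "HC"), sum(grp == "mTBI"),
              paste(x$config$grid_shape, collapse = "x"),
              x$config$n_frames, x$config$n_sources, length(x$config$state_covs)))
  invisible(x)
}

#' Cohort covariate table
#'
#' @param cohort a `cohort_data`.
#' @return data.frame with subject_id, group, pair_id, age, gender.
#' @export
cohort_covariates <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group, pair_id = s$pair_id,
               age = s$age, gender = s$gender, stringsAsFactors = FALSE)
  })) -> df
  rownames(df) <- NULL
  df
}

#' Empirical occupancy of the planted state sequences
#'
#' @param cohort a `cohort_data`.
#' @return matrix (subjects x states) of occupancy fractions with group labels
#'   as an attribute.
#' @export
truth_occupancy <- function(cohort) {
  k <- length(cohort$config$state_covs)
  occ <- t(vapply(cohort$truth$state_seq,
                  function(s) tabulate(s, nbins = k) / length(s), numeric(k)))
  rownames(occ) <- names(cohort$subjects)
  attr(occ, "group") <- vapply(cohort$subjects, `[[`, "", "group")
  occ
}
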
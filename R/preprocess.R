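# Individual preprocessing steps and the four step orderings PA-PD.
# Voxel-level steps act on volume_series objects; post-ICA steps act on
# component time-course matrices (frames x components). Frame indices are
# 1-based throughout.

#' Remove dummy frames from the start of a run
#'
#' @param series a `volume_series`.
#' @param n_dummy number of initial frames to discard (default 5, matching
#'   the usual allowance for T1 equilibration).
#' @return The shortened `volume_series`.
#' @export
drop_dummy_volumes <- function(series, n_dummy = 5) {
  stopifnot(inherits(series, "volume_series"))
  abort_if(n_dummy < 0, "n_dummy must be nonnegative")
  nt <- n_frames(series)
  abort_if(n_dummy >= nt,
           sprintf("cannot drop %d dummy frames from a %d-frame series", n_dummy, nt))
  if (n_dummy == 0) return(series)
  volume_series(series$data[, , , (n_dummy + 1):nt, drop = FALSE],
                voxel_mm = series$voxel_mm, tr_s = series$tr_s)
}

#' Detect spike frames with DVARS
#'
#' The series is first scaled to percent signal change about each voxel's
#' temporal mean; DVARS at frame t (t >= 2) is the root-mean-square across
#' voxels of the backward frame difference. A frame is flagged as a spike
#' when the z-score of its DVARS value, against the trace's own mean and SD,
#' exceeds `threshold_sd`. Frame 1 has no backward difference and is never
#' flagged, and spike sets are nested across increasing thresholds.
#'
#' @param series a `volume_series` with at least 3 frames.
#' @param threshold_sd z-score threshold in standard deviations
#'   (the study grid uses 2.5, 3.0 and 4.0).
#' @return A `spike_set`: list with `frames` (sorted 1-based indices),
#'   `threshold_sd`, and `dvars` (per-frame trace, `NA` at frame 1).
#' @export
detect_spikes_dvars <- function(series, threshold_sd = 3) {
  stopifnot(inherits(series, "volume_series"))
  abort_if(n_frames(series) < 3, "DVARS needs at least 3 frames")
  y <- vol_as_matrix(series)
  mu <- colMeans(y)
  denom <- ifelse(abs(mu) < 1e-8, 1, mu)
  psc <- 100 * sweep(sweep(y, 2, mu, "-"), 2, denom, "/")
  d <- sqrt(rowMeans(apply(psc, 2, diff)^2))
  dvars <- c(NA_real_, d)
  if (stats::sd(d) < 1e-12) {
    warning("DVARS trace has zero variance; no spikes detectable")
    frames <- integer(0)
  } else {
    z <- (d - mean(d)) / stats::sd(d)
    frames <- which(z > threshold_sd) + 1L
  }
  structure(list(frames = frames, threshold_sd = threshold_sd, dvars = dvars),
            class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  cat(sprintf("spike_set: %d spikes at %.1f SD (frames: %s)\n",
              length(x$frames), x$threshold_sd,
              if (length(x$frames)) paste(x$frames, collapse = ", ") else "none"))
  invisible(x)
}

#' Build a nuisance regressor matrix
#'
#' Assembles, in fixed order, any of: polynomial trends (linear, quadratic,
#' cubic, as orthogonal polynomials), the six realignment parameters, their
#' backward-difference derivatives (zero at frame 1), and one unit indicator
#' column per spike frame.
#'
#' @param realign frames x 6 realignment-parameter matrix (may be `NULL` when
#'   neither motion part is requested).
#' @param spikes a `spike_set`, or `NULL`.
#' @param n_frames frame count (required when `realign` is `NULL`).
#' @param parts subset of `c("trends", "motion", "derivatives", "spikes")`.
#' @return A `regressor_matrix`: list with `values` (frames x regressors) and
#'   `labels`.
#' @export
build_regressors <- function(realign = NULL, spikes = NULL, n_frames = NULL,
                             parts = c("trends", "motion", "derivatives", "spikes")) {
  parts <- match.arg(parts, several.ok = TRUE)
  nt <- if (!is.null(realign)) nrow(realign) else n_frames
  abort_if(is.null(nt), "supply realign or n_frames")
  cols <- list()
  labels <- character(0)
  if ("trends" %in% parts) {
    tr <- stats::poly(seq_len(nt), degree = 3)
    cols <- c(cols, list(unclass(tr)))
    labels <- c(labels, paste0("trend-", 1:3))
  }
  if (any(c("motion", "derivatives") %in% parts)) {
    abort_if(is.null(realign), "motion parts need a realignment matrix")
    abort_if(ncol(realign) != 6, "realign must have 6 columns")
    abort_if(!is.null(n_frames) && nrow(realign) != n_frames,
             "realign length does not match n_frames")
  }
  if ("motion" %in% parts) {
    cols <- c(cols, list(as.matrix(realign)))
    labels <- c(labels, paste0("mp-", 1:6))
  }
  if ("derivatives" %in% parts) {
    dmp <- rbind(0, diff(as.matrix(realign)))
    cols <- c(cols, list(dmp))
    labels <- c(labels, paste0("mpd-", 1:6))
  }
  if ("spikes" %in% parts && !is.null(spikes) && length(spikes$frames)) {
    abort_if(any(spikes$frames > nt), "spike frame beyond series length")
    sp <- matrix(0, nt, length(spikes$frames))
    sp[cbind(spikes$frames, seq_along(spikes$frames))] <- 1
    cols <- c(cols, list(sp))
    labels <- c(labels, paste0("spike-", spikes$frames))
  }
  values <- if (length(cols)) do.call(cbind, cols) else matrix(0, nt, 0)
  colnames(values) <- labels
  structure(list(values = values, labels = labels), class = "regressor_matrix")
}

#' Orthogonalise a signal with respect to nuisance regressors
#'
#' Ordinary least-squares residuals after fitting the regressor columns plus
#' an intercept; applied voxel-wise to a `volume_series` or column-wise to a
#' component time-course matrix. Residuals are orthogonal to every regressor
#' column to floating-point accuracy. A rank-deficient design triggers a
#' pseudo-inverse fit with a warning.
#'
#' @param signal a `volume_series` or frames x components matrix.
#' @param reg a `regressor_matrix` (zero columns yields mean-centering).
#' @return Residuals, same class and shape as the input.
#' @export
regress_nuisance <- function(signal, reg) {
  stopifnot(inherits(reg, "regressor_matrix"))
  is_vol <- inherits(signal, "volume_series")
  y <- if (is_vol) vol_as_matrix(signal) else as.matrix(signal)
  abort_if(nrow(y) != nrow(reg$values),
           sprintf("temporal length mismatch: signal %d vs regressors %d",
                   nrow(y), nrow(reg$values)))
  x <- cbind(intercept = 1, reg$values)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("rank-deficient regressor matrix; using pseudo-inverse")
    res <- y - x %*% (pinv(x) %*% y)
  } else {
    res <- qr.resid(qx, y)
  }
  if (is_vol) vol_from_matrix(res, signal) else res
}

#' Spatial Gaussian smoothing
#'
#' Per-frame separable 3D Gaussian convolution with
#' `sigma_vox = fwhm_mm / (voxel_mm * 2 * sqrt(2 * log(2)))` along each axis
#' and half-sample symmetric (reflective) boundary handling, which leaves
#' spatially constant frames unchanged.
#'
#' @param series a `volume_series`.
#' @param fwhm_mm kernel full width at half maximum in mm (0 = identity;
#'   the study uses 6 mm).
#' @return The smoothed `volume_series`.
#' @export
smooth_spatial <- function(series, fwhm_mm = 6) {
  stopifnot(inherits(series, "volume_series"))
  abort_if(fwhm_mm < 0, "fwhm_mm must be nonnegative")
  if (fwhm_mm == 0) return(series)
  sig_vox <- fwhm_mm / (series$voxel_mm * 2 * sqrt(2 * log(2)))
  a <- series$data
  for (axis in 1:3) {
    a <- convolve_axis_reflect(a, gauss_kernel_1d(sig_vox[axis]), axis)
  }
  volume_series(a, voxel_mm = series$voxel_mm, tr_s = series$tr_s)
}

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_axis_reflect <- function(a, kern, axis) {
  if (length(kern) == 1L) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(seq_along(d), axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  m <- matrix(ap, nrow = n)
  r <- (length(kern) - 1L) / 2L
  pidx <- reflect_index(seq.int(1L - r, n + r), n)
  mp <- m[pidx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kern)) out <- out + kern[j] * mp[j:(j + n - 1L), , drop = FALSE]
  aperm(array(out, dim = d[perm]), order(perm))
}

#' Replace spike frames by cubic-spline interpolation
#'
#' Values at spike frames are replaced, per component, by a cubic spline
#' fitted through the non-spike frames; non-spike frames are untouched.
#' Spikes at the very start or end of the run (outside the span of valid
#' frames) are replaced by the nearest valid value, with a warning.
#'
#' @param tc frames x components time-course matrix.
#' @param spikes a `spike_set` (empty = identity).
#' @return The interpolated matrix.
#' @export
interpolate_spikes <- function(tc, spikes) {
  stopifnot(inherits(spikes, "spike_set"))
  tc <- as.matrix(tc)
  frames <- spikes$frames
  if (length(frames) == 0L) return(tc)
  nt <- nrow(tc)
  good <- setdiff(seq_len(nt), frames)
  abort_if(length(good) < 4, "too few non-spike frames for cubic interpolation")
  interior <- frames[frames > min(good) & frames < max(good)]
  boundary <- setdiff(frames, interior)
  if (length(boundary)) {
    warning("spike at the run boundary; using nearest valid frame")
  }
  for (j in seq_len(ncol(tc))) {
    sf <- stats::splinefun(good, tc[good, j], method = "fmm")
    if (length(interior)) tc[interior, j] <- sf(interior)
    for (f in boundary) {
      tc[f, j] <- tc[good[which.min(abs(good - f))], j]
    }
  }
  tc
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fifth-order Butterworth band-pass (default 0.01-0.15 Hz) applied with
#' zero phase per component: each time course is demeaned, extended
#' symmetrically (so the periodic extension is continuous), and multiplied in
#' the frequency domain by the squared magnitude response `|H(w)|^2` of the
#' filter design - exactly the response of a forward-backward (filtfilt)
#' application, without its boundary transients, which for a 0.01 Hz band
#' edge would span most of a 5-minute run. The DC component lies in the
#' stopband, so constant time courses are driven to (numerically) zero.
#'
#' @param tc frames x components matrix.
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1 / (2 * tr_s)`.
#' @param order filter order.
#' @param tr_s repetition time in seconds.
#' @return The filtered matrix.
#' @export
bandpass_filter <- function(tc, low_hz = 0.01, high_hz = 0.15, order = 5, tr_s = 2) {
  tc <- as.matrix(tc)
  nyq <- 1 / (2 * tr_s)
  abort_if(low_hz <= 0 || high_hz <= low_hz, "need 0 < low_hz < high_hz")
  abort_if(high_hz >= nyq,
           sprintf("high_hz (%.3g) must be below Nyquist (%.3g Hz)", high_hz, nyq))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  nt <- nrow(tc)
  # squared magnitude response at the FFT bin frequencies of the symmetric
  # (length 2*nt) extension; real and even, so the filtered series is real
  w <- 2 * pi * seq.int(0L, 2L * nt - 1L) / (2L * nt)
  e <- exp(-1i * outer(w, seq_along(bf$b) - 1))
  hmag2 <- Mod((e %*% bf$b) / (e %*% bf$a))^2
  out <- tc
  for (j in seq_len(ncol(tc))) {
    x <- tc[, j] - mean(tc[, j])
    xe <- c(x, rev(x))
    y <- Re(stats::fft(stats::fft(xe) * hmag2, inverse = TRUE)) / (2 * nt)
    out[, j] <- y[seq_len(nt)]
  }
  out
}

# --- pipeline orderings ------------------------------------------------------

.pipeline_plans <- list(
  PA = c("SpkMotReg", "Smoothing", "gICA", "Interp", "Filter"),
  PB = c("MotReg", "Smoothing", "gICA", "SpkReg", "Interp", "Filter"),
  PC = c("SpkReg", "Smoothing", "gICA", "MotReg", "Interp", "Filter"),
  PD = c("Smoothing", "gICA", "SpkMotReg", "Interp", "Filter")
)

#' The four preprocessing step orderings
#'
#' @return Named list of ordered step-name vectors for pipelines PA-PD.
#'   The pipelines differ only in where despiking (SpkReg) and motion
#'   regression (MotReg) happen relative to group ICA; every plan ends with
#'   spike interpolation followed by band-pass filtering.
#' @export
pipeline_plans <- function() .pipeline_plans

#' Construct one analysis configuration
#'
#' One point in the configuration grid: a pipeline ordering, a DVARS spike
#' threshold, a group-ICA model order, and a sliding-window width. The study
#' grid is 4 pipelines x thresholds {2.5, 3.0, 4.0} x orders {60, 70, 80} x
#' windows {15, 30, 45} TRs; any positive order/window is accepted so the
#' same machinery runs at small scale.
#'
#' @param pipeline_id one of `"PA"`, `"PB"`, `"PC"`, `"PD"`.
#' @param spike_threshold_sd DVARS z threshold.
#' @param model_order number of group-ICA components.
#' @param window_tr sliding-window width in TRs.
#' @return A `pipeline_config` with the derived ordered `step_plan`.
#' @export
pipeline_config <- function(pipeline_id, spike_threshold_sd = 3,
                            model_order = 70, window_tr = 30) {
  abort_if(!pipeline_id %in% names(.pipeline_plans),
           "pipeline_id must be one of PA, PB, PC, PD")
  abort_if(spike_threshold_sd <= 0, "spike_threshold_sd must be positive")
  abort_if(model_order < 1, "model_order must be a positive integer")
  abort_if(window_tr < 1, "window_tr must be a positive integer")
  structure(list(pipeline_id = pipeline_id,
                 spike_threshold_sd = spike_threshold_sd,
                 model_order = as.integer(model_order),
                 window_tr = as.integer(window_tr),
                 step_plan = .pipeline_plans[[pipeline_id]],
                 config_id = sprintf("%s-t%.1f-m%d-w%d", pipeline_id,
                                     spike_threshold_sd, model_order, window_tr)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("pipeline_config %s: [%s]\n", x$config_id,
              paste(x$step_plan, collapse = " -> ")))
  invisible(x)
}

#' Run one preprocessing configuration over a cohort
#'
#' Drops dummy frames, detects spikes by DVARS at the configured threshold on
#' the raw (post-dummy) series, then executes the pipeline's step plan:
#' voxel-level nuisance regression and smoothing before group ICA,
#' component-level regression after it, always ending with spike
#' interpolation and band-pass filtering of the component time courses.
#'
#' @param cohort a `cohort_data`.
#' @param cfg a `pipeline_config`.
#' @param n_dummy dummy frames to drop (default 5).
#' @param fwhm_mm smoothing kernel FWHM in mm (default 6).
#' @param band_hz band-pass edges in Hz.
#' @param gica_runs ICA restarts for the stability analysis.
#' @param seed RNG seed for the ICA stage.
#' @return List with `tcs` (per-subject frames x components matrices, cleaned),
#'   `components` (`component_set`), `stability` (`stability_report`),
#'   `spikes` (per-subject `spike_set`), `realign` (post-dummy traces),
#'   `cfg`, and `log` (ordered provenance records).
#' @export
run_pipeline <- function(cohort, cfg, n_dummy = 5, fwhm_mm = 6,
                         band_hz = c(0.01, 0.15), gica_runs = 3, seed = 1) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(cfg, "pipeline_config"))
  log <- list()
  note <- function(step, ...) {
    log[[length(log) + 1]] <<- c(list(step = step), list(...))
  }
  series <- lapply(cohort$subjects, function(s) drop_dummy_volumes(s$volume, n_dummy))
  realign <- lapply(cohort$subjects, function(s) {
    if (n_dummy > 0) s$realign[-seq_len(n_dummy), , drop = FALSE] else s$realign
  })
  note("DropDummy", n_dummy = n_dummy)
  spikes <- lapply(series, detect_spikes_dvars, threshold_sd = cfg$spike_threshold_sd)
  note("DVARS", threshold_sd = cfg$spike_threshold_sd,
       n_spikes = sum(vapply(spikes, function(s) length(s$frames), 0L)))

  tr_s <- series[[1]]$tr_s
  tcs <- NULL
  components <- NULL
  stability <- NULL
  nuisance_parts <- list(SpkReg = "spikes",
                         MotReg = c("trends", "motion", "derivatives"),
                         SpkMotReg = c("trends", "motion", "derivatives", "spikes"))

  for (step in cfg$step_plan) {
    pre_gica <- is.null(tcs)
    if (step %in% names(nuisance_parts)) {
      parts <- nuisance_parts[[step]]
      for (i in seq_along(series)) {
        reg <- build_regressors(realign = realign[[i]], spikes = spikes[[i]],
                                n_frames = nrow(realign[[i]]), parts = parts)
        if (pre_gica) {
          series[[i]] <- regress_nuisance(series[[i]], reg)
        } else {
          tcs[[i]] <- regress_nuisance(tcs[[i]], reg)
        }
      }
      note(step, stage = if (pre_gica) "voxel" else "component", parts = parts)
    } else if (step == "Smoothing") {
      series <- lapply(series, smooth_spatial, fwhm_mm = fwhm_mm)
      note(step, fwhm_mm = fwhm_mm)
    } else if (step == "gICA") {
      fit <- fit_group_ica(series, model_order = cfg$model_order,
                           n_runs = gica_runs, seed = seed)
      components <- fit$components
      stability <- fit$stability
      tcs <- lapply(seq_along(series), function(i) components$subject_tcs[[i]])
      names(tcs) <- names(series)
      note(step, model_order = cfg$model_order, n_runs = gica_runs, seed = seed)
    } else if (step == "Interp") {
      tcs <- lapply(seq_along(tcs), function(i) interpolate_spikes(tcs[[i]], spikes[[i]]))
      names(tcs) <- names(series)
      note(step)
    } else if (step == "Filter") {
      tcs <- lapply(tcs, bandpass_filter, low_hz = band_hz[1], high_hz = band_hz[2],
                    tr_s = tr_s)
      note(step, band_hz = band_hz)
    } else {
      stop(sprintf("pipeline step '%s' failed: unknown step", step), call. = FALSE)
    }
  }
  list(tcs = tcs, components = components, stability = stability,
       spikes = spikes, realign = realign, cfg = cfg, log = log)
}
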
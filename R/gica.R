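# Desk-scale group spatial ICA with multi-run stability: two-stage PCA
# reduction, fixed-point ICA with symmetric decorrelation, run clustering for
# per-component quality (Iq) and an overall cluster-validity R-index,
# dual-regression back-reconstruction, frequency-based artifact flagging, and
# cross-pipeline component matching.

# Fixed-point ICA (tanh contrast, symmetric decorrelation) on whitened rows.
# z: components x voxels, rows uncorrelated with unit variance.
fastica_symmetric <- function(z, seed, max_iter = 200, tol = 1e-7) {
  k <- nrow(z)
  nv <- ncol(z)
  w <- with_local_seed(seed, matrix(stats::rnorm(k * k), k, k))
  orth <- function(m) {
    s <- svd(m)
    s$u %*% t(s$v)
  }
  w <- orth(w)
  for (it in seq_len(max_iter)) {
    wx <- w %*% z
    g <- tanh(wx)
    gp <- 1 - g^2
    w_new <- (g %*% t(z)) / nv - diag(rowMeans(gp)) %*% w
    w_new <- orth(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) break
  }
  w %*% z
}

# two-stage PCA reduction: subject-level temporal PCA, concatenation, then
# group PCA to model_order; returns whitened spatial data (order x voxels)
group_pca_reduce <- function(mats, model_order, subject_order = NULL) {
  nvox <- ncol(mats[[1]])
  r1 <- subject_order %||% min(ceiling(1.5 * model_order),
                               min(vapply(mats, nrow, 0L)) - 1L, nvox)
  reduced <- lapply(mats, function(x) {
    xc <- scale(x, center = TRUE, scale = FALSE)
    s <- svd(xc, nu = 0, nv = r1)
    t(s$v[, seq_len(r1), drop = FALSE]) * s$d[seq_len(r1)]
  })
  g <- do.call(rbind, reduced)
  g <- g - rowMeans(g)
  s <- svd(g, nu = 0)
  abort_if(model_order > sum(s$d > max(s$d) * 1e-10),
           sprintf("model order %d exceeds the rank of the reduced data", model_order))
  z <- t(s$v[, seq_len(model_order), drop = FALSE]) * sqrt(nvox)
  z
}

#' Group spatial independent component analysis with stability analysis
#'
#' Subject-level temporal PCA reductions are concatenated and reduced again to
#' `model_order` spatial dimensions, on which fixed-point spatial ICA
#' (symmetric decorrelation) is run `n_runs` times from different seeded
#' starts. Components from all runs are clustered by absolute spatial
#' correlation; each cluster's centrotype becomes an aggregate map. The
#' per-component quality index Iq is the average within-cluster minus average
#' between-cluster similarity, and the R-index summarises run-clustering
#' validity (mean ratio of within-cluster dissimilarity to the nearest other
#' cluster's dissimilarity). Subject time courses are obtained by spatial
#' (dual) regression on the aggregate maps.
#'
#' @param series list of `volume_series` (or frames x voxels matrices), one
#'   per subject; at least 2 subjects.
#' @param model_order number of components to extract.
#' @param n_runs ICA restarts for the stability analysis (1 = no stability:
#'   Iq is reported as 1 by convention, with a warning).
#' @param seed RNG seed; results are deterministic given it.
#' @return List with `components` (a `component_set`: z-scored `maps`
#'   (component x voxel), per-subject `subject_tcs`, `labels`, `iq`) and
#'   `stability` (a `stability_report`: `model_order`, `r_index`, `iq_values`).
#' @export
fit_group_ica <- function(series, model_order, n_runs = 5, seed = 1) {
  abort_if(length(series) < 2, "group ICA needs at least 2 subjects")
  mats <- lapply(series, function(s) if (inherits(s, "volume_series")) vol_as_matrix(s) else as.matrix(s))
  nvox <- ncol(mats[[1]])
  ntf <- nrow(mats[[1]])
  abort_if(model_order > min(ntf, nvox),
           "model_order must not exceed min(frames, voxels)")
  z <- group_pca_reduce(mats, model_order)

  runs <- lapply(seq_len(n_runs), function(r) {
    fastica_symmetric(z, seed = derive_seed(seed, "ica-run", r))
  })
  all_maps <- do.call(rbind, runs)

  if (n_runs == 1) {
    warning("n_runs = 1: stability indices degenerate; Iq reported as 1")
    centro <- runs[[1]]
    iq <- rep(1, model_order)
    r_index <- NA_real_
  } else {
    sim <- abs(stats::cor(t(all_maps)))
    diss <- 1 - sim
    cl <- stats::cutree(stats::hclust(stats::as.dist(diss), method = "average"),
                        k = model_order)
    centro <- matrix(0, model_order, nvox)
    iq <- numeric(model_order)
    w_diss <- numeric(model_order)
    b_diss <- numeric(model_order)
    for (c in seq_len(model_order)) {
      members <- which(cl == c)
      others <- which(cl != c)
      sub <- sim[members, members, drop = FALSE]
      within <- if (length(members) > 1) mean(sub[upper.tri(sub)]) else 1
      between <- if (length(others)) mean(sim[members, others, drop = FALSE]) else 0
      iq[c] <- within - between
      # centrotype: member with the largest total within-cluster similarity
      best <- members[which.max(rowSums(sub))]
      centro[c, ] <- all_maps[best, ]
      w_diss[c] <- 1 - within
      b_diss[c] <- if (length(others)) {
        min(vapply(setdiff(unique(cl), c), function(o) {
          mean(diss[members, cl == o, drop = FALSE])
        }, 0))
      } else NA_real_
    }
    r_index <- mean(w_diss / pmax(b_diss, .Machine$double.eps))
  }

  # sign convention (positive skewness) and per-map z-scoring
  for (c in seq_len(model_order)) {
    m <- centro[c, ]
    if (sample_skewness(m) < 0) m <- -m
    centro[c, ] <- (m - mean(m)) / stats::sd(m)
  }

  subject_tcs <- lapply(mats, function(x) back_reconstruct(x, centro))
  names(subject_tcs) <- names(series)
  components <- structure(list(maps = centro,
                               subject_tcs = subject_tcs,
                               labels = rep("rsn", model_order),
                               iq = iq),
                          class = "component_set")
  stability <- structure(list(model_order = model_order, r_index = r_index,
                              iq_values = iq),
                         class = "stability_report")
  list(components = components, stability = stability)
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set: %d components x %d voxels, %d subjects (%d flagged artifact)\n",
              nrow(x$maps), ncol(x$maps), length(x$subject_tcs),
              sum(x$labels == "artifact")))
  invisible(x)
}

#' Select the group-ICA model order from stability reports
#'
#' Among candidate orders whose number of components with Iq below
#' `iq_threshold` is at most `max_low_iq`, returns the one whose R-index lies
#' within `r_tol` (relative) of the minimum R-index over those candidates;
#' ties go to the smaller order. If no candidate satisfies the Iq rule, the
#' global R-index minimiser is returned with a warning.
#'
#' @param reports list of `stability_report`s (>= 1).
#' @param iq_threshold Iq quality cut-off (default 0.7).
#' @param max_low_iq allowed count of components below the cut-off (default 2).
#' @param r_tol relative tolerance on the minimum R-index (default 0.05).
#' @return The selected model order (integer).
#' @export
select_model_order <- function(reports, iq_threshold = 0.7, max_low_iq = 2,
                               r_tol = 0.05) {
  abort_if(length(reports) < 1, "need at least one stability report")
  orders <- as.integer(vapply(reports, function(r) as.numeric(r$model_order), 0))
  r <- vapply(reports, `[[`, 0, "r_index")
  n_low <- vapply(reports, function(x) sum(x$iq_values < iq_threshold), 0L)
  if (length(reports) == 1L) return(orders[1])
  eligible <- which(n_low <= max_low_iq)
  if (length(eligible) == 0) {
    warning("no candidate order satisfies the Iq rule; returning the R-index minimiser")
    return(orders[which.min(r)])
  }
  r_min <- min(r[eligible])
  within <- eligible[r[eligible] <= r_min * (1 + r_tol)]
  within[which.min(orders[within])]
  orders[within[which.min(orders[within])]]
}

#' Back-reconstruct subject time courses from aggregate maps
#'
#' Spatial (dual-regression style) projection: each subject frame is
#' regressed onto the aggregate spatial maps, giving per-subject component
#' time courses `TC = Y M' (M M')^{-1}`. A singular map Gram matrix falls
#' back to the pseudo-inverse with a warning.
#'
#' @param subject either a `volume_series` or a frames x voxels matrix.
#' @param maps component x voxel aggregate maps.
#' @return frames x components time-course matrix.
#' @export
back_reconstruct <- function(subject, maps) {
  y <- if (inherits(subject, "volume_series")) vol_as_matrix(subject) else as.matrix(subject)
  abort_if(ncol(y) != ncol(maps), "voxel dimensions of subject and maps differ")
  y <- scale(y, center = TRUE, scale = FALSE)
  gram <- maps %*% t(maps)
  inv <- tryCatch(solve(gram), error = function(e) {
    warning("singular map Gram matrix; using pseudo-inverse")
    pinv(gram)
  })
  y %*% t(maps) %*% inv
}

#' Flag artifactual components by frequency content
#'
#' A component is labelled an artifact when the fraction of its time-course
#' spectral power below `low_hz` (periodogram pooled across subjects,
#' DC excluded) falls below `theta_lf` - i.e. when it is dominated by
#' high-frequency fluctuations atypical of hemodynamic signals. Labels are
#' set; nothing is removed.
#'
#' @param cs a `component_set`.
#' @param tr_s repetition time in seconds.
#' @param low_hz boundary of the low-frequency band (default 0.10 Hz).
#' @param theta_lf minimum low-frequency power fraction for an RSN label
#'   (default 0.5; 0 flags nothing).
#' @return The `component_set` with updated `labels` and an `lf_fraction`
#'   attribute on the labels.
#' @export
flag_artifacts <- function(cs, tr_s, low_hz = 0.10, theta_lf = 0.5) {
  stopifnot(inherits(cs, "component_set"))
  nt <- nrow(cs$subject_tcs[[1]])
  abort_if(nt < 8, "need at least 8 frames for spectral labelling")
  k <- nrow(cs$maps)
  freq <- seq_len(floor(nt / 2)) / (nt * tr_s)
  lf <- numeric(k)
  for (c in seq_len(k)) {
    fr <- vapply(cs$subject_tcs, function(tc) {
      x <- tc[, c] - mean(tc[, c])
      p <- Mod(stats::fft(x))^2
      p <- p[2:(floor(nt / 2) + 1)]
      sum(p[freq < low_hz]) / sum(p)
    }, 0)
    lf[c] <- mean(fr)
  }
  cs$labels <- ifelse(lf < theta_lf, "artifact", "rsn")
  attr(cs$labels, "lf_fraction") <- lf
  cs
}

#' Align a component set (and its time courses) to a reference
#'
#' Components from independent ICA fits come in arbitrary order and sign;
#' connectivity pairs are only comparable across pipelines after components
#' have been matched. This reorders (and sign-flips) the components of `cs`
#' so that component j corresponds to reference component j, using the
#' optimal spatial-correlation assignment.
#'
#' @param reference a `component_set` (or maps matrix) to align to.
#' @param cs the `component_set` to align; must have the same number of
#'   components and voxels.
#' @return The aligned `component_set` with a `match_corr` attribute
#'   (absolute spatial correlation per matched component).
#' @export
align_components <- function(reference, cs) {
  ref_maps <- if (inherits(reference, "component_set")) reference$maps else reference
  abort_if(nrow(ref_maps) != nrow(cs$maps), "component counts differ")
  cc <- stats::cor(t(ref_maps), t(cs$maps))
  perm <- solve_assignment(-abs(cc))
  signs <- sign(cc[cbind(seq_len(nrow(ref_maps)), perm)])
  cs$maps <- cs$maps[perm, , drop = FALSE] * signs
  cs$subject_tcs <- lapply(cs$subject_tcs, function(tc) {
    sweep(tc[, perm, drop = FALSE], 2, signs, "*")
  })
  cs$labels <- cs$labels[perm]
  cs$iq <- cs$iq[perm]
  attr(cs, "match_corr") <- abs(cc[cbind(seq_len(nrow(ref_maps)), perm)])
  attr(cs, "perm") <- perm
  attr(cs, "signs") <- signs
  cs
}

#' Match components between two component sets
#'
#' One-to-one pairing of components maximising the total absolute spatial
#' correlation (optimal assignment); pairs below `min_corr` are dropped and
#' unpaired components reported.
#'
#' @param a,b `component_set`s on the same voxel grid.
#' @param min_corr minimum absolute spatial correlation to keep a pair
#'   (default 0.5).
#' @return List with `pairs` (data.frame `a`, `b`, `corr`), `unmatched_a`,
#'   `unmatched_b`.
#' @export
match_components <- function(a, b, min_corr = 0.5) {
  stopifnot(inherits(a, "component_set"), inherits(b, "component_set"))
  abort_if(ncol(a$maps) != ncol(b$maps), "component sets are on different voxel grids")
  cc <- abs(stats::cor(t(a$maps), t(b$maps)))
  flip <- nrow(cc) > ncol(cc)
  assign <- solve_assignment(if (flip) t(-cc) else -cc)
  pairs <- if (flip) {
    data.frame(a = assign, b = seq_len(nrow(b$maps)))
  } else {
    data.frame(a = seq_len(nrow(a$maps)), b = assign)
  }
  pairs$corr <- cc[cbind(pairs$a, pairs$b)]
  keep <- pairs$corr >= min_corr
  list(pairs = pairs[keep, , drop = FALSE],
       unmatched_a = setdiff(seq_len(nrow(a$maps)), pairs$a[keep]),
       unmatched_b = setdiff(seq_len(nrow(b$maps)), pairs$b[keep]))
}
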
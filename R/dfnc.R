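# Sliding-window connectivity and brain-state analysis: tapered windows,
# weighted Pearson correlations per component pair, L1-norm k-means states,
# elbow-based k selection, state matching, and occupancy rates.

#' Tapered sliding-window weights
#'
#' Discrete rectangle of width `window_tr` convolved with a discrete Gaussian
#' of SD `sigma_tr` (support +-3 sigma), renormalised to sum 1. With
#' `sigma_tr = 0` the taper degenerates to uniform weights `1/window_tr`.
#'
#' @param window_tr rectangle width in TRs (>= 3; the study uses 15, 30, 45).
#' @param sigma_tr Gaussian SD in TRs (default 3).
#' @return Numeric weight vector of length
#'   `window_tr + 2 * ceiling(3 * sigma_tr)` (the effective support).
#' @export
make_taper <- function(window_tr, sigma_tr = 3) {
  abort_if(window_tr < 3, "window_tr must be >= 3")
  abort_if(sigma_tr < 0, "sigma_tr must be nonnegative")
  rect <- rep(1, window_tr)
  if (sigma_tr == 0) return(rect / sum(rect))
  r <- ceiling(3 * sigma_tr)
  g <- exp(-((-r):r)^2 / (2 * sigma_tr^2))
  g <- g / sum(g)
  w <- stats::convolve(rect, rev(g), type = "open")
  w / sum(w)
}

# upper-triangle (i < j) pair index for C components
pair_index <- function(n_comp) {
  idx <- which(upper.tri(matrix(0, n_comp, n_comp)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Sliding-window correlations of component time courses
#'
#' For each window position the taper-weighted Pearson correlation is
#' computed for every component pair. The number of windows equals
#' `frames - length(taper) + 1`. Pairs involving a component with zero
#' variance inside a window get correlation 0 (with a warning).
#'
#' @param tcs frames x components time-course matrix.
#' @param taper weight vector from [make_taper()].
#' @param step_tr slide step in TRs (default 1).
#' @return A `window_series`: list with `vectors` (windows x pairs matrix of
#'   correlations), `pair_index`, `taper`, `window_tr` attribute-style fields.
#' @export
windowed_correlation <- function(tcs, taper, step_tr = 1) {
  tcs <- as.matrix(tcs)
  nt <- nrow(tcs)
  support <- length(taper)
  abort_if(nt < support, "time course shorter than the taper support")
  w <- taper / sum(taper)
  starts <- seq.int(1L, nt - support + 1L, by = step_tr)
  pidx <- pair_index(ncol(tcs))
  vecs <- matrix(0, length(starts), nrow(pidx))
  warned <- FALSE
  for (wi in seq_along(starts)) {
    x <- tcs[starts[wi]:(starts[wi] + support - 1L), , drop = FALSE]
    mu <- colSums(x * w)
    xc <- sweep(x, 2, mu, "-") * sqrt(w)
    cov <- crossprod(xc)
    v <- diag(cov)
    zero <- v < .Machine$double.eps
    if (any(zero) && !warned) {
      warning("zero-variance component inside a window; its correlations set to 0")
      warned <- TRUE
    }
    denom <- sqrt(pmax(v, .Machine$double.eps))
    cr <- cov / outer(denom, denom)
    cr[zero, ] <- 0
    cr[, zero] <- 0
    vecs[wi, ] <- cr[pidx]
  }
  vecs[vecs > 1] <- 1
  vecs[vecs < -1] <- -1
  structure(list(vectors = vecs, pair_index = pidx, taper = w,
                 step_tr = step_tr, support = support),
            class = "window_series")
}

#' @export
print.window_series <- function(x, ...) {
  cat(sprintf("window_series: %d windows x %d pairs (taper support %d)\n",
              nrow(x$vectors), ncol(x$vectors), x$support))
  invisible(x)
}

# stack per-subject window_series into one matrix with a subject index
stack_windows <- function(ws_list) {
  mats <- lapply(ws_list, `[[`, "vectors")
  data <- do.call(rbind, mats)
  subject <- rep(seq_along(mats), vapply(mats, nrow, 0L))
  list(data = data, subject = subject)
}

# one L1 k-means run from given initial centroids; median centroid update
l1_kmeans_once <- function(x, centroids, max_iter = 100) {
  k <- nrow(centroids)
  n <- nrow(x)
  assign_old <- rep(0L, n)
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    d <- sapply(seq_len(k), function(j) rowSums(abs(sweep(x, 2, centroids[j, ]))))
    d <- matrix(d, nrow = n)
    assign_new <- max.col(-d, ties.method = "first")
    # re-seed empty clusters at the farthest window
    repeat {
      empty <- setdiff(seq_len(k), unique(assign_new))
      if (!length(empty)) break
      cur <- d[cbind(seq_len(n), assign_new)]
      far <- which.max(cur)
      centroids[empty[1], ] <- x[far, ]
      d[, empty[1]] <- rowSums(abs(sweep(x, 2, centroids[empty[1], ])))
      assign_new <- max.col(-d, ties.method = "first")
    }
    objective <- c(objective, sum(d[cbind(seq_len(n), assign_new)]))
    for (j in seq_len(k)) {
      centroids[j, ] <- apply(x[assign_new == j, , drop = FALSE], 2, stats::median)
    }
    if (all(assign_new == assign_old)) break
    assign_old <- assign_new
  }
  d <- sapply(seq_len(k), function(j) rowSums(abs(sweep(x, 2, centroids[j, ]))))
  d <- matrix(d, nrow = n)
  assign_new <- max.col(-d, ties.method = "first")
  obj <- sum(d[cbind(seq_len(n), assign_new)])
  list(centroids = centroids, assignments = assign_new,
       objective = obj, objective_trace = c(objective, obj))
}

#' Cluster windowed connectivity vectors into states
#'
#' k-means with L1-norm distance and median centroid updates, pooling windows
#' across all subjects; the best of `restarts` seeded random initialisations
#' (by total L1 objective) is returned. Empty clusters are re-seeded at the
#' farthest window. Deterministic given `seed`.
#'
#' @param ws either a single `window_series`, a list of them (one per
#'   subject), or a windows x pairs matrix.
#' @param k number of states.
#' @param restarts number of initialisations (default 5).
#' @param seed RNG seed.
#' @return A `state_model`: `k`, `centroids` (k x pairs), `assignments`
#'   (per pooled window), `subject` (window-to-subject index), `objective`,
#'   and `objective_trace` of the winning run.
#' @export
cluster_states <- function(ws, k, restarts = 5, seed = 1) {
  stacked <- if (inherits(ws, "window_series")) {
    list(data = ws$vectors, subject = rep(1L, nrow(ws$vectors)))
  } else if (is.list(ws)) {
    stack_windows(ws)
  } else {
    list(data = as.matrix(ws), subject = rep(1L, nrow(as.matrix(ws))))
  }
  x <- stacked$data
  abort_if(nrow(x) < k, "fewer windows than requested states")
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_local_seed(derive_seed(seed, "kmeans", r),
                            x[sample(nrow(x), k), , drop = FALSE])
    fit <- l1_kmeans_once(x, init)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(list(k = k, centroids = best$centroids,
                 assignments = best$assignments, subject = stacked$subject,
                 objective = best$objective,
                 objective_trace = best$objective_trace),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state_model: k = %d, %d windows, L1 objective %.4g\n",
              x$k, length(x$assignments), x$objective))
  invisible(x)
}

#' Choose the number of states by the elbow criterion
#'
#' Runs the L1 k-means over `k_range` and selects the k of maximum discrete
#' curvature (second difference) of the within-cluster dispersion curve,
#' which is anchored at k = 1 (dispersion about the global median) so the
#' smallest candidate k can itself be an elbow. The returned object carries
#' the cluster-validity curve (within-cluster over mean between-centroid
#' dispersion) for inspection. A flat curve returns the smallest k with a
#' warning.
#'
#' @param ws windows as accepted by [cluster_states()].
#' @param k_range candidate k values (default 2:8).
#' @param restarts k-means restarts per k.
#' @param seed RNG seed.
#' @return List with `k` (selected), `cvi_curve` (named by k),
#'   `dispersion` (within-cluster curve incl. the k = 1 anchor), and
#'   `models` (the fitted `state_model` per candidate).
#' @export
select_k_elbow <- function(ws, k_range = 2:8, restarts = 5, seed = 1) {
  abort_if(length(k_range) < 1, "k_range must be nonempty")
  k_range <- sort(unique(as.integer(k_range)))
  stacked <- if (inherits(ws, "window_series")) {
    list(data = ws$vectors, subject = rep(1L, nrow(ws$vectors)))
  } else if (is.list(ws) && !is.matrix(ws)) {
    stack_windows(ws)
  } else {
    list(data = as.matrix(ws), subject = rep(1L, nrow(as.matrix(ws))))
  }
  x <- stacked$data
  w1 <- sum(rowSums(abs(sweep(x, 2, apply(x, 2, stats::median)))))
  models <- list()
  wk <- numeric(length(k_range))
  cvi <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    sm <- cluster_states(x, k_range[i], restarts = restarts, seed = seed)
    sm$subject <- stacked$subject
    models[[i]] <- sm
    wk[i] <- sm$objective
    between <- if (k_range[i] > 1) {
      dd <- as.matrix(stats::dist(sm$centroids, method = "manhattan"))
      mean(dd[upper.tri(dd)]) * length(sm$assignments)
    } else NA_real_
    cvi[i] <- wk[i] / between
  }
  disp <- c(w1, wk)
  ks <- c(1L, k_range)
  names(disp) <- ks
  names(cvi) <- k_range
  if (diff(range(disp)) < 1e-12 * max(abs(disp), 1)) {
    warning("flat dispersion curve; returning the smallest k")
    k_sel <- k_range[1]
  } else if (length(ks) < 3) {
    k_sel <- k_range[1]
  } else {
    curv <- diff(disp, differences = 2)       # curvature at ks[2..len-1]
    k_sel <- ks[which.max(curv) + 1L]
  }
  list(k = k_sel, cvi_curve = cvi, dispersion = disp,
       models = stats::setNames(models, k_range))
}

#' Match states between two state models
#'
#' Optimal one-to-one assignment of centroids maximising the total Pearson
#' correlation between matched centroids.
#'
#' @param a,b `state_model`s with the same pair dimensionality and k.
#' @return List with `permutation` (`b` state matched to each `a` state) and
#'   `correlations`.
#' @export
match_states <- function(a, b) {
  stopifnot(inherits(a, "state_model"), inherits(b, "state_model"))
  abort_if(ncol(a$centroids) != ncol(b$centroids), "pair dimensionality differs")
  abort_if(a$k != b$k, "state counts differ")
  cc <- stats::cor(t(a$centroids), t(b$centroids))
  perm <- solve_assignment(-cc)
  list(permutation = perm, correlations = cc[cbind(seq_len(a$k), perm)])
}

#' Per-subject state occupancy rates
#'
#' Percentage of each subject's windows assigned to each state.
#'
#' @param sm a `state_model` whose `subject` field indexes subjects.
#' @param groups optional per-subject group labels (recycled onto the subject
#'   index order).
#' @param subject_ids optional subject identifiers.
#' @return An `occupancy_table` data.frame: `subject_id`, `group`, and one
#'   `state<k>` percentage column per state; rows sum to 100.
#' @export
occupancy <- function(sm, groups = NULL, subject_ids = NULL) {
  stopifnot(inherits(sm, "state_model"))
  subs <- sort(unique(sm$subject))
  abort_if(length(subs) == 0, "state model carries no subjects")
  occ <- t(vapply(subs, function(s) {
    a <- sm$assignments[sm$subject == s]
    abort_if(length(a) == 0, sprintf("subject %s has zero windows", s))
    100 * tabulate(a, nbins = sm$k) / length(a)
  }, numeric(sm$k)))
  colnames(occ) <- paste0("state", seq_len(sm$k))
  out <- data.frame(subject_id = subject_ids %||% paste0("sub", subs),
                    group = if (is.null(groups)) NA_character_ else groups,
                    occ, stringsAsFactors = FALSE)
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Extract the numeric occupancy matrix from an occupancy table
#'
#' @param tab an `occupancy_table`.
#' @return subjects x states matrix of percentages.
#' @export
occupancy_matrix <- function(tab) {
  as.matrix(tab[, grep("^state", names(tab)), drop = FALSE])
}

#' Per-subject per-state mean connectivity vectors
#'
#' Mean of each subject's window vectors within each state; a state a subject
#' never visits yields `NA` for that subject/state.
#'
#' @param ws_list list of per-subject `window_series` (in the subject order
#'   used when clustering).
#' @param sm the `state_model` fitted on the pooled windows.
#' @return Array subjects x states x pairs.
#' @export
subject_state_means <- function(ws_list, sm) {
  stopifnot(inherits(sm, "state_model"))
  n_sub <- length(ws_list)
  np <- ncol(ws_list[[1]]$vectors)
  out <- array(NA_real_, dim = c(n_sub, sm$k, np))
  for (s in seq_len(n_sub)) {
    rows <- which(sm$subject == s)
    a <- sm$assignments[rows]
    v <- ws_list[[s]]$vectors
    for (m in seq_len(sm$k)) {
      sel <- which(a == m)
      if (length(sel)) out[s, m, ] <- colMeans(v[sel, , drop = FALSE])
    }
  }
  out
}
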
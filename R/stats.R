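# Motion covariates, matched-pair outlier exclusion, occupancy-rate tests,
# pipeline MANOVA / per-edge ANOVA, and covariate |beta|-strength analysis.

#' Frame-wise displacement summaries of a realignment trace
#'
#' Backward differences of each realignment parameter; `TRN` is the temporal
#' mean of the summed absolute translation differences (mm), `ROT` likewise
#' for the rotations (radians). The first frame contributes no difference.
#'
#' @param realign frames x 6 matrix (`d_x`, `d_y`, `d_z`, `d_pitch`,
#'   `d_yaw`, `d_roll`).
#' @return Named numeric vector `c(TRN = , ROT = )`.
#' @export
compute_fwd <- function(realign) {
  realign <- as.matrix(realign)
  abort_if(nrow(realign) < 2, "frame-wise displacement needs at least 2 frames")
  abort_if(ncol(realign) != 6, "realign must have 6 columns")
  d <- abs(diff(realign))
  c(TRN = mean(rowSums(d[, 1:3, drop = FALSE])),
    ROT = mean(rowSums(d[, 4:6, drop = FALSE])))
}

#' Motion/spike covariate table for a cohort
#'
#' @param cohort a `cohort_data`.
#' @param spikes optional per-subject `spike_set` list (same order) for the
#'   `spk` column; otherwise `spk` is 0.
#' @param n_dummy dummy frames to drop from the realignment traces before
#'   computing displacement (default 5, matching the preprocessing).
#' @return data.frame: subject_id, group, pair_id, age, gender, TRN, ROT, spk.
#' @export
covariate_table <- function(cohort, spikes = NULL, n_dummy = 5) {
  df <- cohort_covariates(cohort)
  fwd <- t(vapply(cohort$subjects, function(s) {
    ra <- s$realign
    if (n_dummy > 0) ra <- ra[-seq_len(n_dummy), , drop = FALSE]
    compute_fwd(ra)
  }, c(TRN = 0, ROT = 0)))
  df$TRN <- fwd[, "TRN"]
  df$ROT <- fwd[, "ROT"]
  df$spk <- if (is.null(spikes)) 0L else vapply(spikes, function(s) length(s$frames), 0L)
  df
}

#' Exclude high-motion outliers together with their matched pairs
#'
#' A subject is an outlier when it exceeds `mean + n_sd * SD` on at least
#' `min_measures` of the displacement measures (columns `measures` of the
#' covariate table). Outliers and their matched pair partners are removed
#' together.
#'
#' @param covtab covariate table with `subject_id` and `pair_id` columns.
#' @param measures measure column names (default `c("TRN", "ROT", "spk")`).
#' @param n_sd SD multiplier (default 3).
#' @param min_measures measures a subject must exceed to be excluded
#'   (default 2).
#' @return List with `retained` (filtered table), `excluded_subjects`,
#'   `outliers` (the subjects that triggered exclusion).
#' @export
exclude_outliers <- function(covtab, measures = c("TRN", "ROT", "spk"),
                             n_sd = 3, min_measures = 2) {
  abort_if(!all(c("subject_id", "pair_id") %in% names(covtab)),
           "covariate table needs subject_id and pair_id columns")
  present <- intersect(measures, names(covtab))
  abort_if(length(present) == 0, "no displacement measure columns found")
  hits <- sapply(present, function(m) {
    x <- covtab[[m]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(FALSE, length(x)) else x > mean(x) + n_sd * s
  })
  hits <- matrix(hits, nrow = nrow(covtab))
  n_hits <- rowSums(hits)
  outliers <- covtab$subject_id[n_hits >= min_measures]
  bad_pairs <- unique(covtab$pair_id[covtab$subject_id %in% outliers])
  excluded <- covtab$subject_id[covtab$pair_id %in% bad_pairs]
  list(retained = covtab[!covtab$subject_id %in% excluded, , drop = FALSE],
       excluded_subjects = excluded,
       outliers = outliers)
}

#' Keep only the listed subjects of a cohort
#'
#' @param cohort a `cohort_data`.
#' @param subject_ids subjects to retain.
#' @return The filtered `cohort_data` (truth lists filtered in step).
#' @export
subset_cohort <- function(cohort, subject_ids) {
  keep <- names(cohort$subjects) %in% subject_ids
  cohort$subjects <- cohort$subjects[keep]
  cohort$truth$source_tcs <- cohort$truth$source_tcs[keep]
  cohort$truth$state_seq <- cohort$truth$state_seq[keep]
  cohort$truth$spike_frames <- cohort$truth$spike_frames[keep]
  cohort
}

#' Occupancy-rate group tests
#'
#' Per state, an unpaired two-sample t-test of occupancy (mTBI minus HC);
#' within each group, paired t-tests between every state pair. Degenerate
#' (zero-variance) comparisons report t = 0, p = 1 with a warning.
#'
#' @param tab an `occupancy_table` with both groups present.
#' @return List of data.frames `between` (state, t, df, p) and `within`
#'   (group, state_i, state_j, t, df, p).
#' @export
occupancy_tests <- function(tab) {
  om <- occupancy_matrix(tab)
  g <- tab$group
  abort_if(!all(c("HC", "mTBI") %in% g), "both groups must be present")
  k <- ncol(om)
  safe_t <- function(x, y, paired = FALSE) {
    degenerate <- if (paired) {
      stats::sd(x - y) < 1e-12
    } else {
      stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12
    }
    if (degenerate) {
      warning("degenerate variance in occupancy test; reporting p = 1")
      return(list(statistic = 0, parameter = NA_real_, p.value = 1))
    }
    stats::t.test(x, y, paired = paired)
  }
  between <- do.call(rbind, lapply(seq_len(k), function(m) {
    tt <- safe_t(om[g == "mTBI", m], om[g == "HC", m])
    data.frame(state = m, t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  within <- do.call(rbind, lapply(c("HC", "mTBI"), function(gr) {
    sub <- om[g == gr, , drop = FALSE]
    do.call(rbind, lapply(utils::combn(k, 2, simplify = FALSE), function(pr) {
      tt <- safe_t(sub[, pr[1]], sub[, pr[2]], paired = TRUE)
      data.frame(group = gr, state_i = pr[1], state_j = pr[2],
                 t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    }))
  }))
  list(between = between, within = within)
}

#' One-way MANOVA of connectivity vectors across pipelines
#'
#' Within one state, tests whether the multivariate per-subject mean
#' connectivity vectors differ among pipelines: Wilks' lambda with the
#' Bartlett chi-square approximation
#' `chi2 = -(n - 1 - (p + g)/2) log(lambda)` on `p * (g - 1)` degrees of
#' freedom. Optionally the covariates are regressed out of the responses
#' first. A singular within-group SSP matrix is ridge-shrunk with a warning.
#'
#' @param edges rows x edges response matrix (one row per subject-pipeline
#'   observation).
#' @param pipeline factor of pipeline membership per row.
#' @param covariates optional numeric covariate matrix/data.frame regressed
#'   out of `edges` before the MANOVA.
#' @return List: `wilks`, `chisq`, `df`, `p`, `n`, `n_edges`.
#' @export
manova_pipelines <- function(edges, pipeline, covariates = NULL) {
  y <- as.matrix(edges)
  pipeline <- droplevels(as.factor(pipeline))
  abort_if(nlevels(pipeline) < 2, "need at least 2 pipelines")
  abort_if(ncol(y) < 1, "need at least 1 edge")
  if (!is.null(covariates)) {
    x <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    y <- stats::lm.fit(x, y)$residuals
  }
  fit <- stats::manova(y ~ pipeline)
  e <- crossprod(fit$residuals)
  tot <- crossprod(scale(y, center = TRUE, scale = FALSE))
  h <- tot - e
  p <- ncol(y)
  n <- nrow(y)
  g <- nlevels(pipeline)
  det_e <- det(e)
  if (!is.finite(det_e) || det_e <= 0) {
    warning("singular within-group SSP; applying ridge shrinkage")
    ridge <- 1e-8 * sum(diag(e)) / p
    e <- e + diag(ridge, p)
    det_e <- det(e)
  }
  lambda <- det_e / det(e + h)
  lambda <- min(max(lambda, .Machine$double.xmin), 1)
  chisq <- -(n - 1 - (p + g) / 2) * log(lambda)
  df <- p * (g - 1)
  list(wilks = lambda, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       n = n, n_edges = p)
}

#' Per-edge one-way ANOVA
#'
#' Classic equal-variance one-way ANOVA of each edge against a grouping
#' factor.
#'
#' @param edges rows x edges matrix.
#' @param group factor with at least 2 levels.
#' @return data.frame: edge, F, df1, df2, p.
#' @export
anova_per_edge <- function(edges, group) {
  y <- as.matrix(edges)
  group <- droplevels(as.factor(group))
  abort_if(nlevels(group) < 2, "ANOVA needs at least 2 factor levels")
  out <- lapply(seq_len(ncol(y)), function(j) {
    tt <- stats::oneway.test(y[, j] ~ group, var.equal = TRUE)
    data.frame(edge = j, F = unname(tt$statistic),
               df1 = unname(tt$parameter[1]), df2 = unname(tt$parameter[2]),
               p = tt$p.value)
  })
  do.call(rbind, out)
}

#' Covariate regression-strength analysis
#'
#' Per edge, an ordinary least-squares fit on the six covariates (diagnosis,
#' gender, age, TRN, ROT, spk; continuous covariates standardised) and the
#' absolute regression coefficient |beta| of each covariate. A collinear
#' design falls back to the pseudo-inverse with the condition number in a
#' warning.
#'
#' @param edges subjects x edges matrix.
#' @param covtab covariate table with columns `group` (or `diagnosis`),
#'   `gender`, `age`, `TRN`, `ROT`, `spk`.
#' @return List: `beta` (edges x 6 |beta| matrix), `mean_abs_beta` (per
#'   covariate, averaged over edges).
#' @export
beta_strength <- function(edges, covtab) {
  y <- as.matrix(edges)
  diagnosis <- if ("diagnosis" %in% names(covtab)) covtab$diagnosis
               else as.integer(covtab$group == "mTBI")
  gender <- as.integer(as.factor(covtab$gender)) - 1
  std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  x <- cbind(intercept = 1, diagnosis = diagnosis, gender = gender,
             age = std(covtab$age), TRN = std(covtab$TRN),
             ROT = std(covtab$ROT), spk = std(covtab$spk))
  abort_if(nrow(x) != nrow(y), "covariate rows must match edge rows")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    s <- svd(x)
    warning(sprintf("collinear covariates (condition number %.3g); using pseudo-inverse",
                    max(s$d) / max(min(s$d), .Machine$double.xmin)))
    beta <- pinv(x) %*% y
  } else {
    beta <- qr.coef(qx, y)
  }
  b <- t(abs(beta[-1, , drop = FALSE]))   # drop intercept; edges x covariates
  colnames(b) <- colnames(x)[-1]
  list(beta = b, mean_abs_beta = colMeans(b))
}

#' Compare covariate strength across pipelines
#'
#' One-way ANOVA, per covariate, of the per-edge |beta| values with pipeline
#' as the factor (the edge-wise |beta| distributions are what the analysis
#' averages and compares).
#'
#' @param beta_tables named list (pipeline -> edges x covariates |beta|
#'   matrix from [beta_strength()]).
#' @return data.frame: covariate, F, df1, df2, p, plus per-pipeline means.
#' @export
compare_beta_strength <- function(beta_tables) {
  abort_if(length(beta_tables) < 2, "need at least 2 pipelines")
  covs <- colnames(beta_tables[[1]])
  pip <- factor(rep(names(beta_tables),
                    vapply(beta_tables, nrow, 0L)))
  do.call(rbind, lapply(covs, function(cv) {
    v <- unlist(lapply(beta_tables, function(b) b[, cv]), use.names = FALSE)
    tt <- stats::oneway.test(v ~ pip, var.equal = TRUE)
    means <- vapply(beta_tables, function(b) mean(b[, cv]), 0)
    cbind(data.frame(covariate = cv, F = unname(tt$statistic),
                     df1 = unname(tt$parameter[1]), df2 = unname(tt$parameter[2]),
                     p = tt$p.value), t(means))
  }))
}
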
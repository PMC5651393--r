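# Covariate-adjusted linear least-squares SVM classification with LOOCV AUC,
# nested double-LOOCV configuration selection, and a permutation null for
# the AUC grid.

#' Assemble a per-subject feature set from state means
#'
#' Features are the concatenated per-state mean connectivity vectors
#' (states x edges per subject); a state a subject never visits is imputed
#' to the cohort mean of that state's vector (and flagged). Occupancy rates
#' can optionally be appended.
#'
#' @param state_means subjects x states x edges array from
#'   [subject_state_means()].
#' @param labels per-subject diagnosis labels (`"HC"`/`"mTBI"`, or 0/1).
#' @param occupancy_pct optional subjects x states occupancy matrix appended
#'   as extra features.
#' @param subject_ids optional identifiers.
#' @param config_id optional configuration tag.
#' @return A `feature_set`: list with `x` (subjects x features), `y`
#'   (0/1 integer labels), `imputed` (logical matrix subjects x states),
#'   `subject_ids`, `config_id`.
#' @export
build_features <- function(state_means, labels, occupancy_pct = NULL,
                           subject_ids = NULL, config_id = NULL) {
  dm <- dim(state_means)
  abort_if(length(dm) != 3, "state_means must be subjects x states x edges")
  n <- dm[1]
  blocks <- lapply(seq_len(dm[2]), function(m) {
    matrix(state_means[, m, ], nrow = n)
  })
  imputed <- matrix(FALSE, n, dm[2])
  for (m in seq_len(dm[2])) {
    missing <- !is.finite(blocks[[m]][, 1])
    if (any(missing)) {
      abort_if(all(missing), sprintf("state %d visited by no subject; cannot impute", m))
      imputed[missing, m] <- TRUE
      mu <- colMeans(blocks[[m]][!missing, , drop = FALSE])
      blocks[[m]][missing, ] <- matrix(mu, sum(missing), dm[3], byrow = TRUE)
    }
  }
  x <- do.call(cbind, blocks)   # state-major concatenation
  if (!is.null(occupancy_pct)) x <- cbind(x, as.matrix(occupancy_pct))
  y <- if (is.numeric(labels)) as.integer(labels) else as.integer(labels == "mTBI")
  abort_if(!all(y %in% c(0L, 1L)), "labels must be HC/mTBI or 0/1")
  structure(list(x = x, y = y, imputed = imputed,
                 subject_ids = subject_ids %||% paste0("sub", seq_len(n)),
                 config_id = config_id),
            class = "feature_set")
}

#' Regress nuisance covariates out of features
#'
#' Per-feature OLS residuals after regressing gender, age, TRN, ROT and spk
#' (with intercept; continuous covariates standardised). Diagnosis is never
#' touched.
#'
#' @param fs a `feature_set`.
#' @param covtab covariate table aligned with the feature rows.
#' @return The adjusted `feature_set`.
#' @export
adjust_features <- function(fs, covtab) {
  stopifnot(inherits(fs, "feature_set"))
  abort_if(nrow(covtab) != nrow(fs$x), "covariate rows must match subjects")
  std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  x <- cbind(1, as.integer(as.factor(covtab$gender)) - 1,
             std(covtab$age), std(covtab$TRN), std(covtab$ROT), std(covtab$spk))
  fs$x <- qr.resid(qr(x), fs$x)
  fs
}

#' Train a linear least-squares SVM
#'
#' Least-squares SVM with squared slack penalties: minimise
#' `||w||^2 / 2 + C * sum(e_i^2)` subject to `y_i (w.x_i + b) = 1 - e_i`.
#' The KKT conditions reduce to one linear system in the dual variables,
#' solved exactly; the decision value is `w.x + b`.
#'
#' @param x subjects x features matrix (or a `feature_set`).
#' @param y labels 0/1 (ignored when `x` is a `feature_set`).
#' @param C soft-margin weight (default 0.01).
#' @return An `ls_svm` model with `alpha`, `bias`, `x_train`, `y_signed`.
#' @export
train_ls_svm <- function(x, y = NULL, C = 0.01) {
  if (inherits(x, "feature_set")) {
    y <- x$y
    x <- x$x
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  abort_if(length(unique(y)) < 2, "training needs both classes present")
  ys <- ifelse(y == 1L, 1, -1)
  n <- nrow(x)
  k <- tcrossprod(x)
  omega <- (ys %o% ys) * k + diag(n) / (2 * C)
  a <- rbind(c(0, ys), cbind(ys, omega))
  sol <- solve(a, c(0, rep(1, n)))
  structure(list(bias = sol[1], alpha = sol[-1], x_train = x, y_signed = ys, C = C),
            class = "ls_svm")
}

#' @export
predict.ls_svm <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  drop(nd %*% crossprod(object$x_train, object$alpha * object$y_signed)) + object$bias
}

#' Leave-one-out cross-validated AUC
#'
#' For each subject the model is trained on the remaining subjects and the
#' held-out decision value recorded; the AUC is computed over all held-out
#' (decision, label) pairs with midrank tie handling.
#'
#' @param fs a `feature_set` (n >= 4, both classes).
#' @param C soft-margin weight.
#' @return List: `auc`, `decisions` (per subject), `labels`.
#' @export
loocv_auc <- function(fs, C = 0.01) {
  stopifnot(inherits(fs, "feature_set"))
  n <- nrow(fs$x)
  abort_if(n < 4, "LOOCV needs at least 4 subjects")
  dec <- numeric(n)
  for (i in seq_len(n)) {
    m <- train_ls_svm(fs$x[-i, , drop = FALSE], fs$y[-i], C = C)
    dec[i] <- predict(m, fs$x[i, , drop = FALSE])
  }
  list(auc = auc_score(dec, fs$y), decisions = dec, labels = fs$y)
}

#' Enumerate the analysis configuration grid
#'
#' Full Cartesian product of pipelines x spike thresholds x model orders x
#' window sizes in a stable order (pipeline varying slowest). The study grid
#' `(PA-PD) x (2.5, 3.0, 4.0) x (60, 70, 80) x (15, 30, 45)` yields 108
#' configurations.
#'
#' @param pipelines,thresholds,orders,windows nonempty factor level vectors.
#' @return List of `pipeline_config` objects.
#' @export
enumerate_configs <- function(pipelines = c("PA", "PB", "PC", "PD"),
                              thresholds = c(2.5, 3.0, 4.0),
                              orders = c(60, 70, 80),
                              windows = c(15, 30, 45)) {
  abort_if(length(pipelines) == 0 || length(thresholds) == 0 ||
             length(orders) == 0 || length(windows) == 0,
           "all factor lists must be nonempty")
  grid <- expand.grid(window = windows, order = orders, threshold = thresholds,
                      pipeline = pipelines, stringsAsFactors = FALSE)
  grid <- grid[, c("pipeline", "threshold", "order", "window")]
  lapply(seq_len(nrow(grid)), function(i) {
    pipeline_config(grid$pipeline[i], grid$threshold[i], grid$order[i], grid$window[i])
  })
}

#' Nested double-LOOCV configuration selection
#'
#' The outer loop leaves one subject out; the inner loop scores every
#' configuration by an independent LOOCV AUC on the remaining subjects; the
#' best configuration (ties resolved by enumeration order) is trained on
#' those subjects and classifies the held-out one. The final AUC is computed
#' over the outer held-out decision values. When `covtab` is supplied the
#' covariate adjustment is refit inside every outer fold (fully nested) and
#' applied to the held-out subject.
#'
#' @param fs_list list of `feature_set`s, one per configuration, sharing
#'   subjects and labels.
#' @param C soft-margin weight.
#' @param covtab optional covariate table for nested adjustment.
#' @return A `classification_result`: `auc`, `decisions`, `winners`
#'   (per outer fold), `selection_counts`, `auc_grid`
#'   (subjects x configurations inner AUCs).
#' @export
nested_selection <- function(fs_list, C = 0.01, covtab = NULL) {
  abort_if(length(fs_list) < 1, "need at least one configuration")
  n <- nrow(fs_list[[1]]$x)
  y <- fs_list[[1]]$y
  for (fs in fs_list) {
    abort_if(nrow(fs$x) != n || !identical(fs$y, y),
             "all configurations must share the same subjects and labels")
  }
  nc <- length(fs_list)
  cfg_ids <- vapply(seq_len(nc), function(j) {
    fs_list[[j]]$config_id %||% sprintf("config-%02d", j)
  }, "")
  auc_grid <- matrix(NA_real_, n, nc, dimnames = list(NULL, cfg_ids))
  winners <- integer(n)
  dec <- numeric(n)
  adjust_fold <- function(x, keep_idx, covtab) {
    # refit the covariate regression on the training rows, apply to all rows
    g <- as.integer(as.factor(covtab$gender)) - 1
    xm <- cbind(1, g, covtab$age, covtab$TRN, covtab$ROT, covtab$spk)
    xt <- xm[keep_idx, , drop = FALSE]
    beta <- tryCatch(qr.coef(qr(xt), x[keep_idx, , drop = FALSE]),
                     error = function(e) pinv(xt) %*% x[keep_idx, , drop = FALSE])
    beta[!is.finite(beta)] <- 0
    x - xm %*% beta
  }
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    best_auc <- -Inf
    best_j <- 1L
    for (j in seq_len(nc)) {
      xj <- fs_list[[j]]$x
      if (!is.null(covtab)) xj <- adjust_fold(xj, rest, covtab)
      inner <- tryCatch({
        sub <- structure(list(x = xj[rest, , drop = FALSE], y = y[rest]),
                         class = "feature_set")
        loocv_auc(sub, C = C)$auc
      }, error = function(e) 0)
      auc_grid[i, j] <- inner
      if (inner > best_auc + 1e-12) {
        best_auc <- inner
        best_j <- j
      }
    }
    winners[i] <- best_j
    xw <- fs_list[[best_j]]$x
    if (!is.null(covtab)) xw <- adjust_fold(xw, rest, covtab)
    m <- train_ls_svm(xw[rest, , drop = FALSE], y[rest], C = C)
    dec[i] <- predict(m, xw[i, , drop = FALSE])
  }
  counts <- tabulate(winners, nbins = nc)
  names(counts) <- cfg_ids
  structure(list(auc = auc_score(dec, y), decisions = dec, labels = y,
                 winners = winners, selection_counts = counts,
                 auc_grid = auc_grid, config_ids = cfg_ids),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("classification_result: final AUC %.3f over %d subjects x %d configurations\n",
              x$auc, nrow(x$auc_grid), ncol(x$auc_grid)))
  top <- which.max(x$selection_counts)
  cat(sprintf("  most-selected configuration: %s (%d of %d outer folds)\n",
              names(x$selection_counts)[top], x$selection_counts[top],
              nrow(x$auc_grid)))
  invisible(x)
}

#' Permutation null for configuration mean AUCs
#'
#' Builds a null distribution of LOOCV AUCs by `B` label-permutation
#' replicates (one common permutation per replicate, each configuration
#' re-scored by plain LOOCV), and flags configurations whose observed mean
#' AUC (columns of the nested `auc_grid`, or plain LOOCV AUCs) exceeds the
#' 95th percentile of the pooled null.
#'
#' @param fs_list list of `feature_set`s per configuration.
#' @param observed per-configuration observed mean AUCs.
#' @param B permutation replicates (a warning is issued below 100).
#' @param seed RNG seed.
#' @param C soft-margin weight.
#' @param level null quantile (default 0.95).
#' @return List: `threshold`, `significant` (logical per configuration),
#'   `null_aucs`.
#' @export
bootstrap_null <- function(fs_list, observed, B = 200, seed = 1, C = 0.01,
                           level = 0.95) {
  abort_if(length(observed) != length(fs_list),
           "observed AUCs must match configurations")
  if (B < 100) warning("B < 100 permutation replicates; null quantile is unstable")
  y <- fs_list[[1]]$y
  n <- length(y)
  null_aucs <- matrix(NA_real_, B, length(fs_list))
  for (b in seq_len(B)) {
    yp <- with_local_seed(derive_seed(seed, "perm", b), sample(y))
    for (j in seq_along(fs_list)) {
      sub <- structure(list(x = fs_list[[j]]$x, y = yp), class = "feature_set")
      null_aucs[b, j] <- loocv_auc(sub, C = C)$auc
    }
  }
  threshold <- stats::quantile(null_aucs, level, na.rm = TRUE, names = FALSE)
  list(threshold = threshold, significant = observed > threshold,
       null_aucs = null_aucs)
}
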
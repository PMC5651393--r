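# NIfTI and text I/O, cohort serialisation, and the end-to-end driver.

#' Read a 4D NIfTI volume
#'
#' @param path NIfTI-1 file.
#' @return A `volume_series`; voxel size and TR taken from the pixdim field.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  abort_if(length(d) != 4,
           sprintf("expected a 4D NIfTI, got %d dimensions in %s", length(d), path))
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  volume_series(array(as.numeric(img), dim = d), voxel_mm = pd[1:3], tr_s = tr)
}

#' Write a volume series as NIfTI
#'
#' Values are stored as float64 so a write/read round trip is bit-exact.
#'
#' @param series a `volume_series`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(series, path) {
  stopifnot(inherits(series, "volume_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_mm, series$tr_s)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read/write realignment parameters (rp_*.txt dialect)
#'
#' Plain whitespace-delimited text with six columns per frame: three
#' translations (mm) then three rotations (radians).
#'
#' @param path text file.
#' @return frames x 6 matrix.
#' @export
read_realign <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  abort_if(ncol(m) != 6, sprintf("expected 6 columns in %s, found %d", path, ncol(m)))
  colnames(m) <- c("d_x", "d_y", "d_z", "d_pitch", "d_yaw", "d_roll")
  m
}

#' @rdname read_realign
#' @param realign frames x 6 matrix.
#' @export
write_realign <- function(realign, path) {
  utils::write.table(format(realign, scientific = FALSE, digits = 8), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI volume and one rp-style realignment text file per subject, plus
#' a `participants.tsv` covariate table.
#'
#' @param cohort a `cohort_data`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    write_volume(s$volume, file.path(dir, paste0(s$subject_id, "_bold.nii.gz")))
    write_realign(s$realign, file.path(dir, paste0("rp_", s$subject_id, ".txt")))
  }
  utils::write.table(cohort_covariates(cohort), file.path(dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory holding `*_bold.nii.gz`, `rp_*.txt`,
#'   `participants.tsv`.
#' @return A `cohort_data` (without ground truth).
#' @export
read_cohort <- function(dir) {
  cov <- utils::read.table(file.path(dir, "participants.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(cov)), function(i) {
    sid <- cov$subject_id[i]
    list(subject_id = sid, group = cov$group[i], pair_id = cov$pair_id[i],
         age = cov$age[i], gender = cov$gender[i],
         volume = read_volume(file.path(dir, paste0(sid, "_bold.nii.gz"))),
         realign = read_realign(file.path(dir, paste0("rp_", sid, ".txt"))))
  })
  names(subjects) <- cov$subject_id
  structure(list(subjects = subjects, truth = NULL, config = NULL),
            class = "cohort_data")
}

#' Run the full analysis end to end
#'
#' Generates (or accepts) a cohort, excludes motion outliers with their
#' matched pairs, runs every configuration of the factor grid through
#' preprocessing, group ICA and sliding-window state clustering, computes
#' occupancy statistics and covariate strengths per configuration, and
#' performs the nested double-LOOCV configuration selection over the grid.
#'
#' @param synth a `synth_config`, or an existing `cohort_data`.
#' @param pipelines,thresholds,orders,windows factor grids
#'   (see [enumerate_configs()]).
#' @param k number of states; `NULL` selects it by the elbow rule on the
#'   first configuration.
#' @param k_range candidate k values for the elbow rule.
#' @param n_dummy,fwhm_mm,band_hz,gica_runs preprocessing settings
#'   (see [run_pipeline()]).
#' @param restarts k-means restarts.
#' @param C SVM soft-margin weight.
#' @param include_occupancy append occupancy rates to the feature vectors.
#' @param null_B permutation replicates for the AUC null (0 = skip).
#' @param seed master seed; all stages derive substreams from it.
#' @param out optional path for a JSON report.
#' @return A report list: `meta`, `exclusion`, `k`, per-configuration
#'   results, `nested` (classification), and optionally `null`.
#' @export
run_all <- function(synth = synth_config(),
                    pipelines = c("PA", "PB", "PC", "PD"),
                    thresholds = 3.0, orders = 5, windows = 15,
                    k = NULL, k_range = 2:6,
                    n_dummy = 5, fwhm_mm = 6, band_hz = c(0.01, 0.15),
                    gica_runs = 3, restarts = 3, C = 0.01,
                    include_occupancy = TRUE, null_B = 0,
                    seed = 1, out = NULL) {
  cohort <- if (inherits(synth, "cohort_data")) synth else {
    synth$seed <- derive_seed(seed, "cohort-master")
    generate_cohort(synth)
  }
  configs <- enumerate_configs(pipelines, thresholds, orders, windows)

  # motion covariates at the first spike threshold, outlier exclusion
  base_spikes <- lapply(cohort$subjects, function(s) {
    detect_spikes_dvars(drop_dummy_volumes(s$volume, n_dummy),
                        threshold_sd = configs[[1]]$spike_threshold_sd)
  })
  covtab <- covariate_table(cohort, spikes = base_spikes, n_dummy = n_dummy)
  excl <- exclude_outliers(covtab)
  cohort <- subset_cohort(cohort, excl$retained$subject_id)
  covtab <- excl$retained

  groups <- vapply(cohort$subjects, `[[`, "", "group")
  results <- vector("list", length(configs))
  fs_list <- vector("list", length(configs))
  ref_model <- NULL
  ref_components <- NULL

  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    pp <- run_pipeline(cohort, cfg, n_dummy = n_dummy, fwhm_mm = fwhm_mm,
                       band_hz = band_hz, gica_runs = gica_runs,
                       seed = derive_seed(seed, "gica", cfg$config_id))
    # component order and sign are arbitrary per ICA fit: align every
    # configuration with the same model order to the first one so that
    # connectivity pairs (and hence states) are comparable across pipelines
    if (is.null(ref_components)) {
      ref_components <- pp$components
    } else if (nrow(ref_components$maps) == nrow(pp$components$maps)) {
      al <- align_components(ref_components, pp$components)
      perm <- attr(al, "perm")
      signs <- attr(al, "signs")
      pp$components <- al
      pp$tcs <- lapply(pp$tcs, function(tc) {
        sweep(tc[, perm, drop = FALSE], 2, signs, "*")
      })
    }
    taper <- make_taper(cfg$window_tr)
    ws <- lapply(pp$tcs, windowed_correlation, taper = taper)
    if (ci == 1 && is.null(k)) {
      el <- select_k_elbow(ws, k_range = k_range, restarts = restarts,
                           seed = derive_seed(seed, "elbow"))
      k <- el$k
    }
    sm <- cluster_states(ws, k, restarts = restarts,
                         seed = derive_seed(seed, "kmeans", cfg$config_id))
    if (is.null(ref_model)) {
      ref_model <- sm
    } else {
      perm <- match_states(ref_model, sm)$permutation
      relabel <- integer(sm$k)
      relabel[perm] <- seq_len(sm$k)
      sm$assignments <- relabel[sm$assignments]
      sm$centroids <- sm$centroids[perm, , drop = FALSE]
    }
    occ <- occupancy(sm, groups = groups, subject_ids = names(cohort$subjects))
    otest <- occupancy_tests(occ)
    means <- subject_state_means(ws, sm)
    bs <- lapply(seq_len(k), function(m) {
      em <- means[, m, ]
      ok <- is.finite(em[, 1])
      beta_strength(em[ok, , drop = FALSE], covtab[ok, , drop = FALSE])
    })
    fs <- build_features(means, labels = groups,
                         occupancy_pct = if (include_occupancy) occupancy_matrix(occ),
                         subject_ids = names(cohort$subjects),
                         config_id = cfg$config_id)
    fs_list[[ci]] <- fs
    plain <- loocv_auc(adjust_features(fs, covtab), C = C)
    results[[ci]] <- list(config = cfg$config_id,
                          n_spikes = vapply(pp$spikes, function(s) length(s$frames), 0L),
                          occupancy = occ, occupancy_tests = otest,
                          mean_abs_beta = lapply(bs, `[[`, "mean_abs_beta"),
                          loocv_auc = plain$auc)
  }
  names(results) <- vapply(configs, `[[`, "", "config_id")

  nested <- nested_selection(fs_list, C = C, covtab = covtab)
  report <- list(meta = list(seed = seed, n_subjects = length(cohort$subjects),
                             n_configs = length(configs), k = k,
                             config_ids = names(results)),
                 exclusion = list(outliers = excl$outliers,
                                  excluded = excl$excluded_subjects),
                 configs = results, nested = nested)
  if (null_B > 0) {
    observed <- colMeans(nested$auc_grid)
    report$null <- bootstrap_null(
      lapply(fs_list, function(fs) adjust_features(fs, covtab)),
      observed, B = null_B, seed = derive_seed(seed, "null"), C = C)
  }
  if (!is.null(out)) {
    writable <- report
    writable$configs <- lapply(report$configs, function(r) {
      r$occupancy <- NULL
      r
    })
    writable$nested <- list(auc = nested$auc,
                            selection_counts = as.list(nested$selection_counts))
    writable$null <- if (!is.null(report$null)) {
      list(threshold = report$null$threshold,
           significant = as.list(report$null$significant))
    }
    jsonlite::write_json(writable, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  report
}
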
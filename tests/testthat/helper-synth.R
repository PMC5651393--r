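# Shared fixtures, built in code. Kept deliberately small: tests exercise the
# same machinery as full runs but at desk scale.

# tiny clean cohort (no motion, no spikes, low noise) for exact-recovery tests
clean_cohort <- function(n_pairs = 3, n_frames = 80, seed = 11, noise_sd = 0) {
  generate_cohort(synth_config(
    n_pairs = n_pairs, n_frames = n_frames, noise_sd = noise_sd,
    motion_amp_mm = 0, motion_coupling = 0, spike_rate_per_min = 0, seed = seed))
}

# default-condition cohort at reduced subject count
small_cohort <- function(n_pairs = 4, n_frames = 100, seed = 7) {
  generate_cohort(synth_config(n_pairs = n_pairs, n_frames = n_frames, seed = seed))
}

subject_groups <- function(cohort) vapply(cohort$subjects, `[[`, "", "group")

# vectorise the planted state correlation matrices in pair order
planted_state_vectors <- function(cohort) {
  pidx <- dfncpipe:::pair_index(cohort$config$n_sources)
  sapply(cohort$config$state_covs, function(s) s[pidx])
}

# align estimated state columns of an occupancy matrix to the planted states
align_occupancy <- function(occ_mat, sm, cohort) {
  planted <- planted_state_vectors(cohort)
  perm <- apply(stats::cor(t(sm$centroids), planted), 1, which.max)
  out <- occ_mat
  out[, perm] <- occ_mat
  out
}

# linearly separable two-class feature set
separable_features <- function(n_per = 6, p = 3, gap = 4, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * p), n_per) - gap / 2,
             matrix(stats::rnorm(n_per * p), n_per) + gap / 2)
  structure(list(x = x, y = rep(c(0L, 1L), each = n_per),
                 subject_ids = paste0("s", seq_len(2 * n_per))),
            class = "feature_set")
}

# brute-force minimal assignment for cross-checking the Hungarian solver
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  best_p <- NULL
  for (p in perms(seq_len(n))) {
    val <- sum(cost[cbind(seq_len(n), p)])
    if (val < best) {
      best <- val
      best_p <- p
    }
  }
  list(perm = best_p, cost = best)
}
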
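test_that("tapers are normalised, symmetric, and match the direct convolution", {
  for (w in c(15, 30, 45)) {
    tp <- make_taper(w, 3)
    expect_equal(sum(tp), 1)
    expect_equal(tp, rev(tp))
    expect_length(tp, w + 2 * ceiling(9))
  }
  # sigma -> 0 limit: uniform weights
  expect_equal(make_taper(15, 0), rep(1 / 15, 15))
  # direct convolution oracle
  w <- 15
  r <- 9
  g <- exp(-((-r):r)^2 / 18)
  g <- g / sum(g)
  direct <- rep(0, w + 2 * r)
  for (i in seq_len(w)) direct[i:(i + 2 * r)] <- direct[i:(i + 2 * r)] + g
  direct <- direct / sum(direct)
  expect_equal(make_taper(15, 3), direct, tolerance = 1e-12)
  mid <- ceiling(length(direct) / 2)
  expect_gt(make_taper(15, 3)[mid], make_taper(15, 3)[1])
})

test_that("windowed correlations have the expected shape and limits", {
  set.seed(2)
  tcs <- matrix(rnorm(100 * 4), 100)
  tp <- make_taper(15, 3)
  ws <- windowed_correlation(tcs, tp)
  expect_equal(nrow(ws$vectors), 100 - length(tp) + 1)
  expect_equal(ncol(ws$vectors), 6)
  expect_true(all(ws$vectors >= -1 & ws$vectors <= 1))
  # identical components correlate at exactly 1 in every window
  dup <- cbind(tcs[, 1], tcs[, 1], tcs[, 2])
  wd <- windowed_correlation(dup, tp)
  expect_equal(wd$vectors[, 1], rep(1, nrow(wd$vectors)))
  # 29 components yield 406 pairs
  big <- matrix(rnorm(60 * 29), 60)
  expect_equal(ncol(windowed_correlation(big, make_taper(15, 3))$vectors), 406)
})

test_that("window trajectories cross zero when the coupling flips sign", {
  set.seed(3)
  n <- 160
  half <- n / 2
  base <- rnorm(n)
  partner <- c(0.9 * base[1:half] + sqrt(1 - 0.81) * rnorm(half),
               -0.9 * base[(half + 1):n] + sqrt(1 - 0.81) * rnorm(half))
  ws <- windowed_correlation(cbind(base, partner), make_taper(15, 3))
  traj <- ws$vectors[, 1]
  expect_gt(mean(traj[1:30]), 0.5)
  expect_lt(mean(traj[(length(traj) - 29):length(traj)]), -0.5)
  crossing <- which(diff(sign(traj)) != 0)
  expect_true(any(abs(crossing - (half - 16)) < 25))
})

test_that("zero-variance components inside a window warn and yield 0", {
  tcs <- cbind(c(rep(1, 40), rnorm(20)), rnorm(60))
  expect_warning(ws <- windowed_correlation(tcs, make_taper(15, 3)), "zero-variance")
  expect_equal(ws$vectors[1, 1], 0)
})

test_that("L1 k-means recovers planted window labels and behaves canonically", {
  set.seed(8)
  c1 <- rep(c(0.8, -0.5), each = 5)
  c2 <- rep(c(-0.6, 0.7), each = 5)
  x <- rbind(matrix(rep(c1, 60), 60, byrow = TRUE),
             matrix(rep(c2, 40), 40, byrow = TRUE)) + matrix(rnorm(1000, sd = 0.05), 100)
  truth <- rep(1:2, c(60, 40))
  sm <- cluster_states(x, 2, restarts = 3, seed = 1)
  acc <- max(mean(sm$assignments == truth), mean(sm$assignments == 3 - truth))
  expect_gt(acc, 0.95)
  # objective is non-increasing over iterations
  expect_true(all(diff(sm$objective_trace) <= 1e-9))
  # k = n windows gives objective 0
  xs <- x[1:8, ]
  sm8 <- cluster_states(xs, 8, restarts = 2, seed = 2)
  expect_equal(sm8$objective, 0)
  # duplicated data give identical centroids
  smd <- cluster_states(rbind(x, x), 2, restarts = 3, seed = 1)
  ms <- match_states(sm, smd)
  expect_true(all(ms$correlations > 0.999))
  # determinism
  expect_identical(cluster_states(x, 2, restarts = 3, seed = 1),
                   cluster_states(x, 2, restarts = 3, seed = 1))
})

test_that("the elbow rule recovers the planted number of states", {
  set.seed(4)
  # well-separated, mutually equidistant states: orthogonal sign patterns,
  # as planted connectivity states with disjoint coupling structure would be
  had <- rbind(c(1, 1, 1, 1), c(1, -1, 1, -1), c(1, 1, -1, -1), c(1, -1, -1, 1))
  mk_states <- function(k, n_per, noise = 0.12) {
    cents <- 0.7 * had[seq_len(k), rep(1:4, 3)]
    do.call(rbind, lapply(seq_len(k), function(m) {
      matrix(rep(cents[m, ], n_per), n_per, byrow = TRUE) +
        matrix(rnorm(n_per * 12, sd = noise), n_per)
    }))
  }
  el4 <- select_k_elbow(mk_states(4, 80), k_range = 2:8, restarts = 3, seed = 2)
  expect_equal(el4$k, 4)
  el2 <- select_k_elbow(mk_states(2, 120), k_range = 2:8, restarts = 3, seed = 2)
  expect_equal(el2$k, 2)
  expect_length(el4$cvi_curve, 7)
  # a single unstructured blob returns the smallest k
  blob <- matrix(rnorm(200 * 10), 200)
  elb <- select_k_elbow(blob, k_range = 2:5, restarts = 2, seed = 3)
  expect_equal(elb$k, 2)
})

test_that("state matching recovers label permutations", {
  set.seed(6)
  cents <- matrix(rnorm(3 * 10), 3)
  a <- structure(list(k = 3, centroids = cents), class = "state_model")
  b <- structure(list(k = 3, centroids = cents[c(3, 1, 2), ]), class = "state_model")
  m <- match_states(a, b)
  expect_equal(m$permutation, c(2, 3, 1))
  expect_true(all(m$correlations > 0.999))
  expect_equal(match_states(a, a)$permutation, 1:3)
})

test_that("occupancy rows always sum to 100 and reflect assignments", {
  sm <- structure(list(k = 4,
                       assignments = c(rep(1L, 10), rep(1L, 3), 2L, 3L, 2L),
                       subject = rep(1:2, c(10, 6))),
                  class = "state_model")
  tab <- occupancy(sm, groups = c("HC", "mTBI"))
  om <- occupancy_matrix(tab)
  expect_equal(unname(rowSums(om)), c(100, 100))
  expect_equal(unname(om[1, ]), c(100, 0, 0, 0))
  expect_equal(unname(om[2, ]), c(50, 100 / 3, 100 / 6, 0))
})

test_that("subject state means average the right windows", {
  v1 <- matrix(c(0.5, -0.5, 0.2, 0.2), 4, 1)   # windows x 1 pair
  ws <- list(structure(list(vectors = v1), class = "window_series"))
  sm <- structure(list(k = 2, assignments = c(1L, 1L, 2L, 2L),
                       subject = rep(1L, 4)), class = "state_model")
  out <- subject_state_means(ws, sm)
  expect_equal(out[1, 1, 1], 0)          # mean of +0.5 and -0.5
  expect_equal(out[1, 2, 1], 0.2)
  # a subject entirely in one state: that state's mean is the grand mean,
  # the other is missing
  sm1 <- structure(list(k = 2, assignments = rep(1L, 4), subject = rep(1L, 4)),
                   class = "state_model")
  out1 <- subject_state_means(ws, sm1)
  expect_equal(out1[1, 1, 1], mean(v1))
  expect_true(is.na(out1[1, 2, 1]))
})
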
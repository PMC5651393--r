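test_that("feature assembly concatenates state means and imputes absent states", {
  sm <- array(NA_real_, c(3, 2, 2))
  sm[1, 1, ] <- c(1, 2); sm[2, 1, ] <- c(3, 4); sm[3, 1, ] <- c(5, 6)
  sm[1, 2, ] <- c(10, 20); sm[2, 2, ] <- c(30, 40)   # subject 3 never in state 2
  fs <- build_features(sm, labels = c("HC", "HC", "mTBI"))
  expect_equal(dim(fs$x), c(3, 4))
  expect_equal(fs$x[2, ], c(3, 4, 30, 40))
  expect_equal(fs$x[3, 3:4], c(20, 30))   # cohort mean of state 2
  expect_true(fs$imputed[3, 2])
  expect_equal(fs$y, c(0L, 0L, 1L))
  # occupancy appended when requested
  fs2 <- build_features(sm, labels = c(0, 0, 1),
                        occupancy_pct = matrix(50, 3, 2))
  expect_equal(ncol(fs2$x), 6)
})

test_that("covariate adjustment removes covariate-borne variance only", {
  set.seed(40)
  n <- 40
  covtab <- data.frame(gender = rep(c("F", "M"), n / 2), age = rnorm(n, 30, 8),
                       TRN = abs(rnorm(n, 0.1, 0.03)),
                       ROT = abs(rnorm(n, 0.002, 5e-4)), spk = rpois(n, 2))
  diag01 <- rep(c(0, 1), each = n / 2)
  x <- cbind(3 * covtab$age,                      # pure covariate feature
             diag01 * 2 + 0.5 * covtab$age,       # mixed
             rnorm(n))                            # independent
  fs <- structure(list(x = x, y = diag01), class = "feature_set")
  adj <- adjust_features(fs, covtab)
  expect_lt(max(abs(adj$x[, 1])), 1e-9)
  sep_before <- mean(x[diag01 == 1, 2]) - mean(x[diag01 == 0, 2])
  sep_after <- mean(adj$x[diag01 == 1, 2]) - mean(adj$x[diag01 == 0, 2])
  expect_gt(sep_after, 0.5 * sep_before - 0.5)
  # independent feature only mean-centred
  expect_equal(stats::cor(adj$x[, 3], x[, 3]), 1, tolerance = 0.05)
})

test_that("least-squares SVM solves the hand-written KKT system", {
  m <- train_ls_svm(matrix(c(-1, 1), 2, 1), c(0, 1), C = 0.01)
  # dual system for x = {-1, +1}, y = {-1, +1}, C = 0.01:
  # [0 -1 1; -1 1+1/(2C) 1; 1 1 1+1/(2C)] [b a1 a2] = [0 1 1]
  kkt <- solve(rbind(c(0, -1, 1), c(-1, 51, 1), c(1, 1, 51)), c(0, 1, 1))
  expect_equal(unname(c(m$bias, m$alpha)), unname(kkt), tolerance = 1e-6)
  # symmetric data: bias ~ 0, decisions sign-correct
  expect_lt(abs(m$bias), 1e-10)
  d <- predict(m, matrix(c(-1, 1), 2, 1))
  expect_true(d[1] < 0 && d[2] > 0)
})

test_that("the SVM separates linearly separable clusters on its training data", {
  fs <- separable_features(n_per = 8, gap = 6, seed = 3)
  m <- train_ls_svm(fs, C = 0.01)
  d <- predict(m, fs$x)
  expect_true(all(sign(d) == ifelse(fs$y == 1, 1, -1)))
  expect_error(train_ls_svm(fs$x, rep(1, nrow(fs$x))), "both classes")
})

test_that("LOOCV AUC is 1 on separable data and centred at 0.5 under permuted labels", {
  fs <- separable_features(n_per = 8, gap = 6, seed = 3)
  expect_equal(loocv_auc(fs)$auc, 1.0)
  # permutation null: no optimistic bias. (Leave-one-out AUC is known to be
  # pessimistically biased under the null - the held-out subject's class is
  # always underrepresented in its training fold - so the distribution sits
  # at or below 0.5, never above it.)
  set.seed(44)
  x <- matrix(rnorm(20 * 4), 20)
  aucs <- replicate(100, {
    y <- sample(rep(0:1, each = 10))
    loocv_auc(structure(list(x = x, y = y), class = "feature_set"))$auc
  })
  expect_lt(mean(aucs), 0.55)
  expect_gt(mean(aucs), 0.25)
  expect_true(all(aucs >= 0 & aucs <= 1))
})

test_that("configuration enumeration is the exact Cartesian product", {
  expect_length(enumerate_configs(), 108)
  expect_length(enumerate_configs("PA", 3, 5, 15), 1)
  expect_length(enumerate_configs(c("PA", "PB"), c(2.5, 3), 5, 15), 4)
  ids <- vapply(enumerate_configs(), `[[`, "", "config_id")
  expect_false(anyDuplicated(ids) > 0)
  # stable deterministic ordering
  expect_identical(ids, vapply(enumerate_configs(), `[[`, "", "config_id"))
  expect_error(enumerate_configs(character(0)), "nonempty")
})

test_that("nested selection picks a dominant configuration and scores it honestly", {
  set.seed(45)
  n <- 12
  y <- rep(c(0L, 1L), each = n / 2)
  strong <- structure(list(x = matrix(rnorm(n * 3), n) + 3 * y, y = y,
                           config_id = "strong"), class = "feature_set")
  weak1 <- structure(list(x = matrix(rnorm(n * 3), n), y = y,
                          config_id = "weak1"), class = "feature_set")
  weak2 <- structure(list(x = matrix(rnorm(n * 3), n), y = y,
                          config_id = "weak2"), class = "feature_set")
  res <- nested_selection(list(weak1, strong, weak2))
  expect_equal(unname(res$selection_counts["strong"]), n)
  expect_equal(res$auc, loocv_auc(strong)$auc)
  expect_equal(dim(res$auc_grid), c(n, 3))
  expect_equal(sum(res$selection_counts), n)
  # identical configurations: ties go to the first by enumeration order
  res2 <- nested_selection(list(weak1, weak1, weak1))
  expect_equal(unname(res2$selection_counts), c(n, 0, 0))
  expect_equal(res2$auc, loocv_auc(weak1)$auc)
})

test_that("the inner-loop winner for a subject never depends on that subject's features", {
  set.seed(46)
  n <- 10
  y <- rep(c(0L, 1L), each = n / 2)
  fs_a <- structure(list(x = matrix(rnorm(n * 2), n) + 1.5 * y, y = y),
                    class = "feature_set")
  fs_b <- structure(list(x = matrix(rnorm(n * 2), n) + 1.4 * y, y = y),
                    class = "feature_set")
  res <- nested_selection(list(fs_a, fs_b))
  for (i in c(1, 5, 10)) {
    pert_a <- fs_a
    pert_a$x[i, ] <- pert_a$x[i, ] + 100
    pert_b <- fs_b
    pert_b$x[i, ] <- pert_b$x[i, ] - 100
    res_p <- nested_selection(list(pert_a, pert_b))
    expect_equal(res_p$winners[i], res$winners[i])
    expect_equal(res_p$auc_grid[i, ], res$auc_grid[i, ])
  }
})

test_that("the permutation null flags only genuinely discriminative configurations", {
  set.seed(47)
  n <- 12
  y <- rep(c(0L, 1L), each = n / 2)
  strong <- structure(list(x = matrix(rnorm(n * 2), n) + 3 * y, y = y),
                      class = "feature_set")
  noise <- lapply(1:3, function(i) {
    structure(list(x = matrix(rnorm(n * 2), n), y = y), class = "feature_set")
  })
  fsl <- c(list(strong), noise)
  observed <- vapply(fsl, function(f) loocv_auc(f)$auc, 0)
  null <- bootstrap_null(fsl, observed, B = 100, seed = 2)
  expect_true(null$significant[1])
  expect_lte(sum(null$significant[-1]), 1)
  # constant 0.5 observations are never flagged
  none <- bootstrap_null(fsl, rep(0.5, 4), B = 100, seed = 2)
  expect_false(any(none$significant))
  expect_warning(bootstrap_null(fsl, observed, B = 20, seed = 2), "B < 100")
})
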
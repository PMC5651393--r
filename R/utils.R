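# Shared internal helpers: seeding, linear algebra, assignment, AUC.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' @keywords internal
#' @noRd
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit substream seed derived from a master seed and labels,
# so every stage draws from its own reproducible stream.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Moore-Penrose pseudo-inverse via SVD.
pinv <- function(a, tol = NULL) {
  s <- svd(a)
  tol <- tol %||% (max(dim(a)) * .Machine$double.eps * max(s$d, 0))
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(a), nrow(a)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

sample_skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s < .Machine$double.eps) return(0)
  mean((x / s)^3)
}

# Optimal linear assignment (rows to columns) minimising total cost.
# Shortest augmenting path formulation; requires nrow(cost) <= ncol(cost).
# Returns for each row the matched column index.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  abort_if(n > m, "assignment requires nrow(cost) <= ncol(cost)")
  inf <- sum(abs(cost)) + 1
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)   # p[j + 1]: row matched to column j (0 = free); j = 0 virtual
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0L:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match_col <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) match_col[p[j + 1L]] <- j
  match_col
}

# Area under the ROC curve from decision values, ties handled by midranks
# (equivalent to the normalised Mann-Whitney U statistic).
auc_score <- function(decision, label) {
  label <- as.integer(label)
  abort_if(!all(label %in% c(0L, 1L)), "labels must be coded 0/1")
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  abort_if(n1 == 0L || n0 == 0L, "AUC needs both classes present")
  r <- rank(decision, ties.method = "average")
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
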
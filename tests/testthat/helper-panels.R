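# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

rand_panel <- function(seed, p = 50, N = 4, id = paste0("s", seed)) {
  set.seed(seed)
  ts_panel(matrix(rnorm(p * N), p, N), paste0("R", seq_len(N)), id)
}

# Panel whose SAMPLE correlation matrix equals `target` exactly: empirical
# whitening followed by the target's Cholesky factor.
panel_with_cor <- function(target, p = 100, seed = 1, id = "exact") {
  set.seed(seed)
  N <- ncol(target)
  x <- matrix(rnorm(p * N), p, N)
  x <- scale(x, center = TRUE, scale = FALSE)
  x <- x %*% solve(chol(stats::cov(x)))  # exact whitening
  x <- x %*% chol(target)
  ts_panel(x, paste0("R", seq_len(N)), id)
}

# The 3-region toy correlation structure used for GBC hand checks:
# r12 = 0.6, r13 = -0.2, r23 = 0.
toy3_cor <- function() {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.6
  R[1, 3] <- R[3, 1] <- -0.2
  R
}

# Exhaustive best single split (decision stump) on one predictor, with the
# package's tie-break (lowest threshold wins at equal gain). Returns the
# stump's fitted values and the SSE decrease.
brute_stump_1d <- function(x, y) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(y)
  best <- list(gain = -Inf, threshold = NA, fitted = rep(mean(y), n))
  parent <- sum(y)^2 / n
  for (k in 1:(n - 1)) {
    if (xs[k + 1] <= xs[k]) next
    sl <- sum(ys[1:k]); sr <- sum(ys) - sl
    gain <- sl^2 / k + sr^2 / (n - k) - parent
    if (gain > best$gain) {
      thr <- (xs[k] + xs[k + 1]) / 2
      fitted <- ifelse(x <= thr, mean(y[x <= thr]), mean(y[x > thr]))
      best <- list(gain = gain, threshold = thr, fitted = fitted)
    }
  }
  best
}

# Exhaustive best stump over all predictors (lowest predictor index wins
# ties).
brute_stump <- function(X, y) {
  best <- list(gain = -Inf)
  for (j in seq_len(ncol(X))) {
    s <- brute_stump_1d(X[, j], y)
    if (s$gain > best$gain) {
      best <- s
      best$feature <- j
    }
  }
  best
}
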
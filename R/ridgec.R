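#' Ridge regression with a fixed penalty
#'
#' Minimizes `RSS + lambda * sum(beta^2)` for standardized inputs, i.e. the
#' penalty is applied to the raw residual sum of squares with no `1/(2p)`
#' scaling, and the intercept is unpenalized. With centered inputs the
#' intercept is exactly zero and the solution is the closed form
#' `(X'X + lambda I)^-1 X'y`. The solve is deterministic (no iterative
#' optimizer).
#'
#' The penalty convention matters: the same data under a solver that scales
#' the RSS gives a different effective `lambda`, so the default `lambda = 10`
#' used by [ridgec_subject()] is only meaningful under this exact objective.
#'
#' @param X Numeric matrix `p x q` of standardized predictors (each column
#'   mean 0, sample SD 1).
#' @param y Standardized numeric response of length `p`.
#' @param lambda Non-negative ridge penalty. `lambda = 0` requires `p > q`
#'   and full column rank (otherwise the least-squares solution is not
#'   unique).
#' @return An object of class `ridge_fit`: `target_region`, `lambda`,
#'   `intercept`, `coefficients` (named by predictor), `fitted_values`.
#' @export
fit_ridge <- function(X, y, lambda) {
  X <- as.matrix(X)
  q <- ncol(X)
  p <- nrow(X)
  if (length(y) != p) stop("length(y) must equal nrow(X)")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("lambda must be a single non-negative number")
  xm <- colMeans(X)
  ym <- mean(y)
  G <- crossprod(X) + diag(lambda, q)
  b <- crossprod(X, y)
  beta <- tryCatch(drop(solve(G, b)), error = function(e) NULL)
  if (is.null(beta) || (lambda == 0 && (p <= q || qr(X)$rank < q)))
    stop("lambda = 0 with rank-deficient or underdetermined X: ",
         "least-squares solution is not unique; use lambda > 0")
  intercept <- ym - sum(xm * beta)
  fitted <- drop(X %*% beta) + intercept
  names(beta) <- colnames(X)
  structure(list(target_region = attr(y, "target_region"),
                 lambda = lambda,
                 intercept = intercept,
                 coefficients = beta,
                 fitted_values = fitted),
            class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat("ridge_fit: ", length(x$coefficients), " predictors, lambda = ",
      x$lambda, "\n", sep = "")
  invisible(x)
}

# Correlation of observed with fitted; 0 (with warning) when the fitted
# values are degenerate, so enormous penalties yield score 0, not NA.
.safe_score <- function(y, fitted, region) {
  if (stats::sd(fitted) < .Machine$double.eps^0.5 * max(1, stats::sd(y))) {
    warning("degenerate fitted values for region '", region,
            "'; connectivity score set to 0")
    return(0)
  }
  r <- stats::cor(y, fitted)
  min(max(r, -1), 1)
}

#' Ridge-regression connectivity (RIDGEC) for one subject
#'
#' For every region i, predicts its standardized series from all other
#' regions by ridge regression with one common penalty and scores
#' connectivity as the Pearson correlation between the observed series and
#' the in-sample fitted values. The same `lambda` is used for every region
#' (and must be reused across subjects) so that scores are comparable; no
#' train/test split is involved.
#'
#' @param panel A [ts_panel].
#' @param lambda Common ridge penalty, default 10.
#' @param keep_coefficients If `TRUE`, also return the `N x N` coefficient
#'   matrix (row i = model for target i; diagonal `NA`) for second-level
#'   analysis of which regions drive each score.
#' @return A [connectivity_vector] with method `"ridgec"`; if
#'   `keep_coefficients`, a list with elements `connectivity` and
#'   `coefficients`.
#' @export
ridgec_subject <- function(panel, lambda = 10, keep_coefficients = FALSE) {
  stopifnot(inherits(panel, "ts_panel"))
  sp <- standardize(panel)
  S <- sp$data
  N <- ncol(S)
  labels <- sp$region_labels
  scores <- numeric(N)
  names(scores) <- labels
  coefs <- if (keep_coefficients)
    matrix(NA_real_, N, N, dimnames = list(labels, labels))
  G <- crossprod(S)  # shared Gram matrix; per-target blocks are subsets
  for (i in seq_len(N)) {
    A <- G[-i, -i, drop = FALSE] + diag(lambda, N - 1L)
    beta <- drop(solve(A, G[-i, i]))
    fitted <- drop(S[, -i, drop = FALSE] %*% beta)
    scores[i] <- .safe_score(S[, i], fitted, labels[i])
    if (keep_coefficients) coefs[i, -i] <- beta
  }
  cv <- connectivity_vector(scores, "ridgec", panel$subject_id)
  if (keep_coefficients) list(connectivity = cv, coefficients = coefs) else cv
}
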
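#' Random-forest configuration for connectivity estimation
#'
#' The forest is deliberately heavily constrained: many small trees rather
#' than few deep ones. Defaults follow the reference analysis: 1000 trees,
#' 10 candidate predictors sampled at each split, and at most 4 terminal
#' nodes per tree. "Variables per tree" is interpreted as per-split
#' sampling (`sample_mode = "split"`, the randomForest-family `mtry`
#' convention); `sample_mode = "tree"` draws one predictor subset per tree
#' instead, for sensitivity analysis. As with the ridge penalty, one config
#' must be kept fixed across all regions and subjects of a study.
#'
#' @param n_trees Number of trees (default 1000).
#' @param m_try Predictors sampled per split (default 10); capped by the
#'   number of available predictors at fit time.
#' @param max_leaf_nodes Maximum terminal nodes per tree (default 4),
#'   grown best-first by largest SSE decrease.
#' @param bootstrap Draw a bootstrap resample per tree (default `TRUE`).
#' @param seed Integer root seed; per-fit streams are derived from it
#'   together with the subject id and target-region index, so adding or
#'   removing subjects never perturbs other subjects' results.
#' @param sample_mode `"split"` (default) or `"tree"`.
#' @param scoring `"insample"` (default) correlates the observed series with
#'   the forest's in-sample prediction; `"oob"` uses out-of-bag predictions.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1000L, m_try = 10L, max_leaf_nodes = 4L,
                          bootstrap = TRUE, seed = 1L,
                          sample_mode = c("split", "tree"),
                          scoring = c("insample", "oob")) {
  sample_mode <- match.arg(sample_mode)
  scoring <- match.arg(scoring)
  n_trees <- as.integer(n_trees)
  m_try <- as.integer(m_try)
  max_leaf_nodes <- as.integer(max_leaf_nodes)
  if (n_trees < 1L) stop("n_trees must be a positive integer")
  if (m_try < 1L) stop("m_try must be a positive integer")
  if (max_leaf_nodes < 2L) stop("max_leaf_nodes must be at least 2")
  structure(list(n_trees = n_trees, m_try = m_try,
                 max_leaf_nodes = max_leaf_nodes, bootstrap = isTRUE(bootstrap),
                 seed = as.integer(seed), sample_mode = sample_mode,
                 scoring = scoring),
            class = "forest_config")
}

#' @export
print.forest_config <- function(x, ...) {
  cat("forest_config: ", x$n_trees, " trees, m_try = ", x$m_try,
      ", max_leaf_nodes = ", x$max_leaf_nodes,
      ", bootstrap = ", x$bootstrap, ", seed = ", x$seed,
      ", sampling per ", x$sample_mode, ", scoring = ", x$scoring,
      "\n", sep = "")
  invisible(x)
}

# Deterministic 31-bit hash of (root seed, subject id, region index), used to
# give every fit its own reproducible random stream. Plain double arithmetic
# modulo a Mersenne prime keeps it exact and platform independent.
fit_seed <- function(root_seed, subject_id, region_index) {
  m <- 2147483647
  h <- (as.numeric(root_seed) %% m + m) %% m
  for (code in utf8ToInt(paste0(subject_id, ":", region_index)))
    h <- (h * 31 + code) %% m
  h + 1
}

#' Fit a constrained regression forest
#'
#' Grows `n_trees` CART regression trees on bootstrap resamples with the
#' variance-reduction (SSE) split criterion, `m_try` predictors sampled
#' uniformly without replacement at each split, and best-first growth capped
#' at `max_leaf_nodes` terminal nodes. The forest prediction is the mean of
#' the tree predictions, and a predictor's importance is the total SSE
#' decrease of its splits, averaged over trees; predictors never selected in
#' any split have importance exactly 0. Equal-gain splits resolve to the
#' lowest predictor index, then the lowest threshold, making single-stump
#' fits exactly reproducible. All randomness is derived from `seed`:
#' identical seeds give bit-identical output.
#'
#' @param X Numeric matrix `p x q` of predictors (`p >= 3`).
#' @param y Numeric response of length `p`; must not be constant.
#' @param config A [forest_config]; `m_try` may not exceed `q`.
#' @param seed Optional fit-level seed overriding `config$seed` (used by
#'   [ranforc_subject()] to derive per-region streams).
#' @return An object of class `forest_fit`: `target_region`, `config`,
#'   `fitted_values`, `importances` (named by predictor) and, when
#'   `config$scoring == "oob"`, `oob_values`.
#' @export
fit_forest <- function(X, y, config = forest_config(), seed = NULL) {
  stopifnot(inherits(config, "forest_config"))
  X <- as.matrix(X)
  p <- nrow(X)
  q <- ncol(X)
  if (length(y) != p) stop("length(y) must equal nrow(X)")
  if (p < 3L) stop("need at least 3 time points, got ", p)
  if (stats::sd(y) == 0) stop("degenerate target: y is constant")
  if (config$m_try > q)
    stop("m_try (", config$m_try, ") exceeds number of predictors (", q, ")")
  if (is.null(seed)) seed <- config$seed
  res <- .forest_fit_cpp(X, y, config$n_trees, config$m_try,
                         config$max_leaf_nodes, config$bootstrap,
                         as.numeric(seed), config$sample_mode == "tree",
                         config$scoring == "oob")
  imp <- res$importances
  names(imp) <- colnames(X)
  structure(list(target_region = attr(y, "target_region"),
                 config = config,
                 fitted_values = res$fitted,
                 importances = imp,
                 oob_values = res$oob),
            class = "forest_fit")
}

#' Random-forest connectivity (RANFORC) for one subject
#'
#' For every region i, fits a constrained regression forest predicting its
#' standardized series from all other regions and scores connectivity as the
#' Pearson correlation between the observed series and the forest
#' prediction (in-sample by default, out-of-bag when the config says so).
#' Unlike the ridge score, this captures nonlinear and non-additive coupling.
#' One `forest_config` must be shared by all regions and subjects for scores
#' to be comparable.
#'
#' @param panel A [ts_panel].
#' @param config A [forest_config]. `m_try` is silently capped at `N - 1`
#'   for small panels.
#' @param keep_importances If `TRUE`, also return the `N x N` variable
#'   importance matrix (row i = model for target i; diagonal `NA`).
#' @return A [connectivity_vector] with method `"ranforc"`; if
#'   `keep_importances`, a list with elements `connectivity` and
#'   `importances`.
#' @export
ranforc_subject <- function(panel, config = forest_config(),
                            keep_importances = FALSE) {
  stopifnot(inherits(panel, "ts_panel"))
  sp <- standardize(panel)
  S <- sp$data
  N <- ncol(S)
  labels <- sp$region_labels
  if (config$m_try > N - 1L) config$m_try <- N - 1L
  scores <- numeric(N)
  names(scores) <- labels
  imps <- if (keep_importances)
    matrix(NA_real_, N, N, dimnames = list(labels, labels))
  for (i in seq_len(N)) {
    fit <- fit_forest(S[, -i, drop = FALSE], S[, i], config,
                      seed = fit_seed(config$seed, sp$subject_id, i))
    pred <- if (config$scoring == "oob") fit$oob_values else fit$fitted_values
    ok <- is.finite(pred)
    scores[i] <- if (sum(ok) < 3L) {
      warning("too few out-of-bag predictions for region '", labels[i],
              "'; score set to 0")
      0
    } else .safe_score(S[ok, i], pred[ok], labels[i])
    if (keep_importances) imps[i, -i] <- fit$importances
  }
  cv <- connectivity_vector(scores, "ranforc", panel$subject_id)
  if (keep_importances) list(connectivity = cv, importances = imps) else cv
}
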
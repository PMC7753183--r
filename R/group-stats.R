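#' Construct a cohort design table
#'
#' Per-subject covariates for the group-level models: sex as a binary
#' indicator, age in years, and optionally per-region gray-matter partial
#' volume means (unitless fractions in `[0, 1]`) used as structural
#' covariates.
#'
#' @param subject_id Character vector of unique subject ids.
#' @param sex Binary vector (0/1 or a two-level factor).
#' @param age Positive numeric vector, years.
#' @param gm Optional numeric matrix, subjects x regions, entries in
#'   `[0, 1]`, columns named by region.
#' @param matched Optional logical vector flagging an age-matched,
#'   sex-balanced subsample for the sex comparison.
#' @return A `data.frame` of class `cohort_design`; `gm` is kept as an
#'   attribute.
#' @export
cohort_design <- function(subject_id, sex, age, gm = NULL, matched = NULL) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject ids")
  if (is.factor(sex) || is.character(sex)) sex <- as.integer(factor(sex)) - 1L
  sex <- as.numeric(sex)
  if (!all(sex %in% c(0, 1))) stop("sex must be a binary indicator")
  if (any(!is.finite(age)) || any(age <= 0)) stop("age must be positive")
  n <- length(subject_id)
  if (length(sex) != n || length(age) != n)
    stop("subject_id, sex and age must have equal length")
  if (!is.null(gm)) {
    gm <- as.matrix(gm)
    if (nrow(gm) != n) stop("gm must have one row per subject")
    if (is.null(colnames(gm))) stop("gm columns must be named by region")
    if (any(gm < 0 | gm > 1)) stop("gm values must lie in [0, 1]")
    rownames(gm) <- subject_id
  }
  if (is.null(matched)) matched <- rep(TRUE, n)
  df <- data.frame(subject_id = subject_id, sex = sex, age = age,
                   matched = as.logical(matched), stringsAsFactors = FALSE)
  attr(df, "gm") <- gm
  class(df) <- c("cohort_design", "data.frame")
  df
}

# Stack a list of connectivity vectors (same method, same regions) into a
# subjects x regions score matrix, Fisher-transforming if asked and needed.
.score_matrix <- function(maps, fisher = TRUE) {
  stopifnot(length(maps) >= 1L)
  methods <- vapply(maps, `[[`, "", "method")
  if (length(unique(methods)) != 1L)
    stop("mixed connectivity methods: ", paste(unique(methods), collapse = ", "))
  regions <- names(maps[[1L]]$scores)
  rows <- lapply(maps, function(cv) {
    if (!identical(names(cv$scores), regions))
      stop("region sets differ across maps (subject '", cv$subject_id, "')")
    if (fisher && !cv$fisher_z) cv <- fisher_transform(cv)
    cv$scores
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(maps, `[[`, "", "subject_id")
  m
}

#' Per-region group average of Fisher-z connectivity maps
#'
#' @param maps List of [connectivity_vector]s sharing one method and region
#'   set. Maps not yet Fisher-transformed are transformed first.
#' @return Named numeric vector of per-region mean Fisher-z scores.
#' @export
group_average <- function(maps) {
  colMeans(.score_matrix(maps, fisher = TRUE))
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with the pooled variance estimate and `df = nA + nB - 2`,
#' two-sided p. (Pooled rather than Welch: the degrees of freedom of the
#' reference cohort comparisons are exactly n1 + n2 - 2.)
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, and `estimate` (mean(a) - mean(b)).
#' @export
two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  ttest_from_summary(mean(a), stats::sd(a), na, mean(b), stats::sd(b), nb)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Same test as [two_sample_t()] but computed from printed group summaries
#' (mean, SD, n), e.g. to reproduce a published demographic comparison.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1 (`n1 >= 2`, `sd1 > 0`).
#' @param m2,sd2,n2 Same for group 2.
#' @return List with `t`, `df = n1 + n2 - 2`, two-sided `p`, `estimate`.
#' @examples
#' # age difference between 110 females and 63 males
#' ttest_from_summary(42.43, 9.48, 110, 36.92, 10.99, 63)
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 < 0 || sd2 < 0)
    stop("SDs must be non-negative finite numbers")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance")
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), estimate = m1 - m2)
}

#' Per-region linear model for one region's connectivity scores
#'
#' Ordinary least squares of Fisher-z scores on the design covariates,
#' reporting the focal coefficient. Formulas: `"age + sex"` (focal: age,
#' sex as nuisance), `"age + sex + gm"` (adds the region's own gray-matter
#' value), `"sex + age"` (focal: sex, age as nuisance), `"sex + age + gm"`.
#'
#' @param scores Per-subject numeric vector (Fisher-z connectivity for one
#'   region), aligned with `design` rows.
#' @param design A [cohort_design].
#' @param formula One of the four strings above; the first term is the
#'   focal variable.
#' @param gm_region Region label selecting the gm column when the formula
#'   includes `gm`.
#' @return List with `estimate`, `t`, `df`, `p` for the focal variable.
#' @export
region_lm <- function(scores, design,
                      formula = c("age + sex", "age + sex + gm",
                                  "sex + age", "sex + age + gm"),
                      gm_region = NULL) {
  formula <- match.arg(formula)
  stopifnot(inherits(design, "cohort_design"))
  if (length(scores) != nrow(design))
    stop("scores length must match number of subjects in design")
  if (any(!is.finite(scores))) stop("non-finite scores")
  dat <- data.frame(y = scores, age = design$age, sex = design$sex)
  terms <- strsplit(formula, " + ", fixed = TRUE)[[1L]]
  focal <- terms[1L]
  if ("gm" %in% terms) {
    gm <- attr(design, "gm")
    if (is.null(gm)) stop("design has no gm covariates")
    if (is.null(gm_region) || !gm_region %in% colnames(gm))
      stop("gm_region must name a column of the design's gm matrix")
    dat$gm <- gm[, gm_region]
  }
  fit <- stats::lm(stats::reformulate(terms, response = "y"), data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  list(estimate = sm[focal, "Estimate"],
       t = sm[focal, "t value"],
       df = fit$df.residual,
       p = sm[focal, "Pr(>|t|)"])
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' The step-up rule: with ordered p-values `p_(1) <= ... <= p_(m)`, reject
#' the `k` smallest where `k = max{ i : p_(i) <= i * alpha / m }`. Adjusted
#' p-values are `min_{j >= i} m * p_(j) / j`, capped at 1; rejection is
#' equivalent to `adjusted p <= alpha`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level, default 0.05.
#' @return List with logical `reject` and numeric `p_adjusted`, in input
#'   order.
#' @export
fdr_bh <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  ranked <- pvalues[o]
  below <- which(ranked <= seq_len(m) * alpha / m)
  k <- if (length(below)) max(below) else 0L
  reject <- logical(m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  adj <- rev(cummin(rev(m * ranked / seq_len(m))))
  p_adjusted <- numeric(m)
  p_adjusted[o] <- pmin(adj, 1)
  list(reject = reject, p_adjusted = p_adjusted)
}

#' Group-level inference pipeline on connectivity maps
#'
#' Fisher-transforms the per-subject maps (if not already), runs the chosen
#' per-region test, and applies Benjamini-Hochberg FDR across the map's N
#' regions (one family per map/method).
#'
#' Analyses: `"sex_ttest_matched"` runs pooled two-sample t-tests between
#' the sexes on the design's age-matched subsample (`matched` flag);
#' `"age_regression"` fits per-region OLS of Fisher-z score on age with sex
#' as nuisance covariate; `"with_gm"` additionally adjusts each region's
#' model for that region's gray-matter partial volume.
#'
#' @param maps List of [connectivity_vector]s (one method, shared regions),
#'   aligned with `design` by subject id.
#' @param design A [cohort_design].
#' @param analysis `"sex_ttest_matched"`, `"age_regression"` or `"with_gm"`.
#' @param alpha FDR level (default 0.05).
#' @return A `data.frame` of class `group_result`: one row per region with
#'   `region`, `estimate`, `t`, `df`, `p`, `p_adjusted`, `significant`, plus
#'   attributes `method`, `analysis`, `alpha`.
#' @export
group_pipeline <- function(maps, design,
                           analysis = c("sex_ttest_matched", "age_regression",
                                        "with_gm"),
                           alpha = 0.05) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(design, "cohort_design"))
  Z <- .score_matrix(maps, fisher = TRUE)
  if (!identical(rownames(Z), design$subject_id))
    stop("maps and design subjects differ or are out of order")
  regions <- colnames(Z)
  res <- vector("list", length(regions))
  if (analysis == "sex_ttest_matched") {
    sub <- design$matched
    if (sum(sub) < 4L) stop("age-matched subsample too small")
    for (j in seq_along(regions)) {
      z <- Z[sub, j]
      sx <- design$sex[sub]
      res[[j]] <- two_sample_t(z[sx == 1], z[sx == 0])
    }
  } else {
    formula <- if (analysis == "with_gm") "age + sex + gm" else "age + sex"
    for (j in seq_along(regions))
      res[[j]] <- region_lm(Z[, j], design, formula,
                            gm_region = if (analysis == "with_gm") regions[j])
  }
  p <- vapply(res, `[[`, 0, "p")
  fdr <- fdr_bh(p, alpha)
  out <- data.frame(region = regions,
                    estimate = vapply(res, `[[`, 0, "estimate"),
                    t = vapply(res, `[[`, 0, "t"),
                    df = vapply(res, `[[`, 0, "df"),
                    p = p,
                    p_adjusted = fdr$p_adjusted,
                    significant = fdr$reject,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "method") <- maps[[1L]]$method
  attr(out, "analysis") <- analysis
  attr(out, "alpha") <- alpha
  class(out) <- c("group_result", "data.frame")
  out
}
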
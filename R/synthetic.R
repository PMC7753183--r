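#' Specification of a synthetic ROI panel
#'
#' Describes one subject's simulated ROI time series. Temporal structure is
#' AR(1) (`ar_phi`, default 0.4), a stand-in for the autocorrelation that
#' band-limited filtering induces in real resting-state series. Coupling is
#' given either as an `N x N` target correlation matrix (signals are
#' correlated Gaussian AR(1) processes with that stationary cross-sectional
#' correlation) or as a list of directed rules, each
#' `list(target =, sources =, weight =, form =)` with
#' `form` one of `"linear"`, `"quadratic"`, `"interaction"`. Rule-based
#' signals are built as `weight * g(sources) + noise`, where `g` is the
#' standardized source mean, its centered square, or the standardized
#' product of the first two sources. The quadratic and interaction drivers
#' are standardized after construction so their linear correlation with the
#' sources stays near zero — coupling that only a nonlinear estimator can
#' exploit.
#'
#' Default shape is 30 regions x 256 time points: 256 matches a typical
#' resting-state volume count; 30 is a desk-scale stand-in for a
#' 246-region parcellation.
#'
#' @param N Number of regions (default 30).
#' @param p Number of time points (default 256).
#' @param ar_phi AR(1) coefficient in (-1, 1), default 0.4.
#' @param coupling `NULL` (independent regions), an `N x N` positive
#'   semi-definite correlation matrix, or a list of coupling rules.
#' @param noise_sd Marginal SD of the private noise of rule-driven regions
#'   (default 1).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(N = 30L, p = 256L, ar_phi = 0.4, coupling = NULL,
                       noise_sd = 1, seed = 1L) {
  N <- as.integer(N); p <- as.integer(p)
  if (N < 2L || p < 3L) stop("need N >= 2 regions and p >= 3 time points")
  if (abs(ar_phi) >= 1) stop("ar_phi must lie in (-1, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.matrix(coupling)) {
    if (!all(dim(coupling) == N)) stop("coupling matrix must be N x N")
    ev <- min(eigen(coupling, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) stop("coupling matrix is not positive semi-definite")
  } else if (is.list(coupling)) {
    for (r in coupling) {
      if (!all(c("target", "sources", "weight", "form") %in% names(r)))
        stop("coupling rules need target, sources, weight, form")
      if (!r$form %in% c("linear", "quadratic", "interaction"))
        stop("unknown coupling form: ", r$form)
      if (r$target > N || any(r$sources > N) || r$target %in% r$sources)
        stop("rule target/sources out of range or self-coupling")
    }
  } else if (!is.null(coupling)) {
    stop("coupling must be NULL, an N x N matrix, or a list of rules")
  }
  structure(list(N = N, p = p, ar_phi = ar_phi, coupling = coupling,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "panel_spec")
}

# Stationary AR(1) columns with innovation cross-correlation C (chol factor
# passed in); marginal variance 1, cross-sectional correlation C.
.ar1_matrix <- function(p, N, phi, chol_C = NULL, burn = 50L) {
  e <- matrix(stats::rnorm((p + burn) * N), p + burn, N)
  if (!is.null(chol_C)) e <- e %*% chol_C
  if (phi != 0) {
    s <- sqrt(1 - phi^2)
    for (t in 2:(p + burn)) e[t, ] <- phi * e[t - 1L, ] + s * e[t, ]
  }
  e[(burn + 1L):(burn + p), , drop = FALSE]
}

#' Generate one synthetic ROI panel
#'
#' @param spec A [panel_spec].
#' @param subject_id Subject id for the resulting panel.
#' @return A [ts_panel]; identical `spec` (including seed) gives an
#'   identical panel.
#' @examples
#' generate_panel(panel_spec(N = 5, p = 100, seed = 7))
#' @export
generate_panel <- function(spec, subject_id = "sim") {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  N <- spec$N; p <- spec$p
  if (is.matrix(spec$coupling)) {
    ch <- tryCatch(chol(spec$coupling), error = function(e)
      chol(spec$coupling + diag(1e-8, N)))
    x <- .ar1_matrix(p, N, spec$ar_phi, chol_C = ch)
  } else {
    base <- .ar1_matrix(p, N, spec$ar_phi)
    x <- base
    if (is.list(spec$coupling)) {
      for (r in spec$coupling) {
        drv <- .coupling_driver(base, r$sources, r$form)
        x[, r$target] <- r$weight * drv + spec$noise_sd * base[, r$target]
      }
    }
  }
  ts_panel(x, paste0("R", seq_len(N)), subject_id)
}

.coupling_driver <- function(base, sources, form) {
  m <- drop(scale(rowMeans(base[, sources, drop = FALSE])))
  switch(form,
         linear = m,
         quadratic = drop(scale(m^2)),
         interaction = {
           if (length(sources) < 2L)
             stop("interaction form needs at least 2 sources")
           drop(scale(base[, sources[1L]] * base[, sources[2L]]))
         })
}

#' Specification of a synthetic multi-subject cohort
#'
#' A cohort shares one [panel_spec] template; per-subject covariates (age,
#' sex) modulate the template's coupling-rule weights through effect rules
#' `list(regions =, covariate =, effect =)`: for each coupling rule whose
#' target is in `regions`, the subject's weight is
#' `weight + effect * (age - mean age)` for `covariate = "age"` or
#' `weight + effect * sex` (sex coded 0/1) for `covariate = "sex"`. Sex is
#' assigned by pairing subjects of adjacent age ranks, so the cohort is
#' age-matched and sex-balanced by construction and the whole cohort is
#' flagged as the matched subsample (odd cohorts leave the last subject
#' unmatched). Per-region gray-matter fractions are drawn from a Beta
#' distribution, independent of connectivity, to exercise the gm-adjusted
#' models.
#'
#' @param n_subjects Number of subjects (default 40).
#' @param template A [panel_spec]; its seed is ignored (per-subject seeds
#'   derive from `seed`).
#' @param age_range Length-2 numeric, default `c(18, 61)`.
#' @param effect_rules List of effect rules as above (default none: a null
#'   cohort).
#' @param with_gm Generate gray-matter covariates (default `TRUE`).
#' @param seed Integer cohort seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40L, template = panel_spec(),
                        age_range = c(18, 61), effect_rules = list(),
                        with_gm = TRUE, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 4L) stop("need at least 4 subjects")
  stopifnot(inherits(template, "panel_spec"))
  if (age_range[1L] <= 0 || diff(age_range) <= 0)
    stop("age_range must be positive and increasing")
  for (r in effect_rules) {
    if (!all(c("regions", "covariate", "effect") %in% names(r)))
      stop("effect rules need regions, covariate, effect")
    if (!r$covariate %in% c("age", "sex"))
      stop("effect covariate must be 'age' or 'sex'")
    if (any(r$regions > template$N)) stop("effect regions out of range")
    if (!is.list(template$coupling))
      stop("effect rules require a rule-based coupling template")
  }
  structure(list(n_subjects = n_subjects, template = template,
                 age_range = age_range, effect_rules = effect_rules,
                 with_gm = isTRUE(with_gm), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of panels with a design table
#'
#' @param spec A [cohort_spec].
#' @return List with `panels` (list of [ts_panel]) and `design`
#'   (a [cohort_design] with the age-matched flag and, if requested, gm
#'   covariates). Bit-identical under a fixed seed.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  tpl <- spec$template
  ids <- sprintf("sub%03d", seq_len(n))
  ages <- sort(stats::runif(n, spec$age_range[1L], spec$age_range[2L]))
  # adjacent age ranks get opposite sexes: matched by construction
  sex <- integer(n)
  for (k in seq_len(ceiling(n / 2))) {
    i <- 2L * k - 1L
    flip <- stats::rbinom(1L, 1L, 0.5)
    sex[i] <- flip
    if (i + 1L <= n) sex[i + 1L] <- 1L - flip
  }
  matched <- rep(TRUE, n)
  if (n %% 2L == 1L) matched[n] <- FALSE
  gm <- NULL
  if (spec$with_gm) {
    gm <- matrix(stats::rbeta(n * tpl$N, 8, 4), n, tpl$N,
                 dimnames = list(ids, paste0("R", seq_len(tpl$N))))
  }
  subj_seeds <- sample.int(2147483646L, n)
  age_c <- ages - mean(ages)
  panels <- vector("list", n)
  for (s in seq_len(n)) {
    coupling <- tpl$coupling
    if (length(spec$effect_rules) && is.list(coupling)) {
      for (er in spec$effect_rules) {
        cov_val <- if (er$covariate == "age") age_c[s] else sex[s]
        for (ri in seq_along(coupling)) {
          if (coupling[[ri]]$target %in% er$regions)
            coupling[[ri]]$weight <- coupling[[ri]]$weight + er$effect * cov_val
        }
      }
    }
    sp <- panel_spec(tpl$N, tpl$p, tpl$ar_phi, coupling, tpl$noise_sd,
                     seed = subj_seeds[s])
    panels[[s]] <- generate_panel(sp, subject_id = ids[s])
  }
  design <- cohort_design(ids, sex, ages, gm = gm, matched = matched)
  list(panels = panels, design = design)
}
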
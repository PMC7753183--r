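#' Build and validate a pipeline run configuration
#'
#' One configuration drives one run end-to-end; hyperparameters are frozen
#' for the run and echoed into every output file's provenance header, which
#' enforces the comparability requirement that the regularization (ridge
#' penalty or forest constraints) stays constant across all regions and
#' subjects. Vector-valued hyperparameters (e.g. a per-subject lambda) are
#' rejected up front.
#'
#' @param method `"ridgec"`, `"ranforc"` or `"gbc"`.
#' @param stages Character subset of `c("simulate", "connectivity",
#'   "group")`, executed in this order.
#' @param lambda Ridge penalty (scalar; default 10).
#' @param forest A [forest_config] (used when `method = "ranforc"`).
#' @param gbc_mode GBC variant (when `method = "gbc"`).
#' @param analysis Group analysis, see [group_pipeline()].
#' @param alpha FDR level.
#' @param seed Root seed for simulation and forest streams.
#' @param cohort A [cohort_spec] for the simulate stage (its seed is
#'   overridden by `seed`).
#' @param in_dir,out_dir Input/output directories. `in_dir` must contain
#'   per-subject `*.tsv` panels plus `design.tsv` when the simulate stage
#'   is skipped.
#' @return An object of class `run_config`.
#' @export
run_config <- function(method = c("ridgec", "ranforc", "gbc"),
                       stages = c("simulate", "connectivity", "group"),
                       lambda = 10, forest = forest_config(),
                       gbc_mode = c("abs", "thr0", "thr01", "thr02", "thr03"),
                       analysis = c("age_regression", "sex_ttest_matched",
                                    "with_gm"),
                       alpha = 0.05, seed = 1L, cohort = cohort_spec(),
                       in_dir = NULL, out_dir = tempfile("mvconn_run")) {
  method <- match.arg(method)
  gbc_mode <- match.arg(gbc_mode)
  analysis <- match.arg(analysis)
  stages <- match.arg(stages, several.ok = TRUE)
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single non-negative scalar: per-subject or ",
         "per-region penalties are not allowed (regularization must stay ",
         "constant through all fittings)")
  stopifnot(inherits(forest, "forest_config"), inherits(cohort, "cohort_spec"))
  if (!"simulate" %in% stages && is.null(in_dir))
    stop("in_dir required when the simulate stage is skipped")
  structure(list(method = method, stages = stages, lambda = lambda,
                 forest = forest, gbc_mode = gbc_mode, analysis = analysis,
                 alpha = alpha, seed = as.integer(seed), cohort = cohort,
                 in_dir = in_dir, out_dir = out_dir),
            class = "run_config")
}

#' Load a YAML run configuration
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [run_config()] (with `forest:` and `cohort:` as nested maps; cohort
#' coupling/effect rules as lists of maps). The panel template uses
#' `n_regions`/`n_timepoints` in place of `N`/`p`, since YAML 1.1 parses a
#' bare `N` as a boolean. Unknown keys are an error, so typos fail before
#' any computation.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("method", "stages", "lambda", "forest", "gbc_mode", "analysis",
             "alpha", "seed", "cohort", "in_dir", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (!is.null(cfg$forest)) cfg$forest <- do.call(forest_config, cfg$forest)
  if (!is.null(cfg$cohort)) {
    ch <- cfg$cohort
    tpl_args <- ch$template
    # YAML 1.1 reads a bare `N:` key as a boolean, so the template uses
    # spelled-out aliases
    names(tpl_args)[names(tpl_args) == "n_regions"] <- "N"
    names(tpl_args)[names(tpl_args) == "n_timepoints"] <- "p"
    if (!is.null(tpl_args$coupling) && is.list(tpl_args$coupling))
      tpl_args$coupling <- lapply(tpl_args$coupling, as.list)
    ch$template <- do.call(panel_spec, tpl_args %||% list())
    cfg$cohort <- do.call(cohort_spec, ch)
  }
  do.call(run_config, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.provenance <- function(config) {
  hp <- switch(config$method,
               ridgec = paste0("lambda=", config$lambda),
               ranforc = with(config$forest,
                 paste0("n_trees=", n_trees, " m_try=", m_try,
                        " max_leaf_nodes=", max_leaf_nodes,
                        " bootstrap=", bootstrap, " sample_mode=", sample_mode,
                        " scoring=", scoring)),
               gbc = paste0("gbc_mode=", config$gbc_mode))
  c(paste0("mvconn ", as.character(utils::packageVersion("mvconn"))),
    paste0("method=", config$method, " ", hp),
    paste0("seed=", config$seed, " alpha=", config$alpha,
           " analysis=", config$analysis))
}

.write_design <- function(design, path) {
  df <- as.data.frame(design)
  gm <- attr(design, "gm")
  if (!is.null(gm)) {
    colnames(gm) <- paste0("gm_", colnames(gm))
    df <- cbind(df, as.data.frame(gm, row.names = NULL))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_design <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  gm_cols <- grep("^gm_", colnames(df), value = TRUE)
  gm <- NULL
  if (length(gm_cols)) {
    gm <- as.matrix(df[gm_cols])
    colnames(gm) <- sub("^gm_", "", gm_cols)
  }
  cohort_design(df$subject_id, df$sex, df$age, gm = gm,
                matched = df$matched %||% NULL)
}

#' Run the connectivity workflow end-to-end
#'
#' Executes the configured stages in order: `simulate` writes per-subject
#' panel TSVs and a design table into `out_dir/data`; `connectivity`
#' computes one map per subject with the configured method and frozen
#' hyperparameters and writes a long-format TSV; `group` runs
#' [group_pipeline()] and writes the per-region result table. Every output
#' carries a `#` provenance header (package version, method,
#' hyperparameters, seed). Reruns with the same config are byte-identical.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with the in-memory `maps`, `design`, `results`
#'   (when computed) and the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(config)
  paths <- character()
  panels <- NULL; design <- NULL; maps <- NULL; results <- NULL

  if ("simulate" %in% config$stages) {
    cs <- config$cohort
    cs$seed <- config$seed
    sim <- generate_cohort(cs)
    panels <- sim$panels
    design <- sim$design
    data_dir <- file.path(config$out_dir, "data")
    dir.create(data_dir, showWarnings = FALSE)
    for (pn in panels)
      write_timeseries(pn, file.path(data_dir, paste0(pn$subject_id, ".tsv")),
                       header = prov)
    .write_design(design, file.path(data_dir, "design.tsv"))
    paths <- c(paths, data = data_dir)
  } else {
    files <- sort(list.files(config$in_dir, pattern = "\\.tsv$",
                             full.names = TRUE))
    files <- files[basename(files) != "design.tsv"]
    if (!length(files)) stop("no panel TSVs found in ", config$in_dir)
    panels <- lapply(files, read_timeseries)
    dpath <- file.path(config$in_dir, "design.tsv")
    if (file.exists(dpath)) design <- .read_design(dpath)
  }

  if (any(c("connectivity", "group") %in% config$stages)) {
    fc <- config$forest
    fc$seed <- config$seed
    maps <- lapply(panels, function(pn) switch(config$method,
      ridgec = ridgec_subject(pn, lambda = config$lambda),
      ranforc = ranforc_subject(pn, config = fc),
      gbc = gbc_subject(pn, mode = config$gbc_mode)))
    map_path <- file.path(config$out_dir, "connectivity.tsv")
    write_connectivity(maps, map_path, header = prov)
    paths <- c(paths, connectivity = map_path)
  }

  if ("group" %in% config$stages) {
    if (is.null(design)) stop("group stage requires a design table")
    results <- group_pipeline(maps, design, analysis = config$analysis,
                              alpha = config$alpha)
    res_path <- file.path(config$out_dir, "group_results.tsv")
    con <- file(res_path, "w")
    writeLines(paste0("# ", prov), con)
    utils::write.table(results, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paths <- c(paths, group = res_path)
  }

  invisible(list(maps = maps, design = design, results = results,
                 paths = paths))
}
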
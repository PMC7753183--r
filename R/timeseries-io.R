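#' Construct an ROI time-series panel
#'
#' A `ts_panel` holds one subject's region-of-interest (ROI) time series as a
#' numeric matrix with time points in rows and labeled regions in columns.
#' It is the input object for all connectivity estimators in the package.
#'
#' @param data Numeric matrix, `p` time points x `N` regions. `p >= 3`,
#'   `N >= 2`, all values finite.
#' @param region_labels Character vector of `N` unique region labels. Defaults
#'   to `colnames(data)`.
#' @param subject_id Single string identifying the subject.
#' @return An object of class `ts_panel` with elements `subject_id`,
#'   `region_labels` and `data`.
#' @examples
#' ts_panel(matrix(rnorm(40), 10, 4), paste0("R", 1:4), "sub01")
#' @export
ts_panel <- function(data, region_labels = colnames(data), subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data))
    stop("panel data must be numeric")
  if (is.null(region_labels))
    region_labels <- paste0("R", seq_len(ncol(data)))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != ncol(data))
    stop("region_labels length (", length(region_labels),
         ") does not match number of columns (", ncol(data), ")")
  if (anyDuplicated(region_labels))
    stop("duplicate region labels: ",
         paste(unique(region_labels[duplicated(region_labels)]), collapse = ", "))
  if (nrow(data) < 3L)
    stop("panel needs at least 3 time points, got ", nrow(data))
  if (ncol(data) < 2L)
    stop("panel needs at least 2 regions, got ", ncol(data))
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop("non-finite value at time point ", bad[1L], ", region '",
         region_labels[bad[2L]], "'")
  }
  dimnames(data) <- list(NULL, region_labels)
  structure(list(subject_id = as.character(subject_id)[1L],
                 region_labels = region_labels,
                 data = data),
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  cat("ROI time-series panel: subject '", x$subject_id, "', ",
      nrow(x$data), " time points x ", ncol(x$data), " regions",
      if (isTRUE(attr(x, "standardized"))) " (standardized)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.ts_panel <- function(x) dim(x$data)

#' Read an ROI time-series table
#'
#' Reads a plain-text table whose first row holds region labels and whose
#' subsequent rows hold time points (temporal order preserved). Comment lines
#' starting with `#` (e.g. provenance headers written by the pipeline) are
#' skipped.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (tab-separated, default) or `"csv"`.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return A [ts_panel].
#' @export
read_timeseries <- function(path, dialect = c("tsv", "csv"), subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  labels <- colnames(df)
  if (anyDuplicated(labels))
    stop("duplicate region labels in header of ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  mat <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, labels))
  for (j in seq_along(df)) {
    v <- df[[j]]
    blank <- !nzchar(trimws(v))
    num <- suppressWarnings(as.numeric(v))
    bad <- blank | is.na(num)
    if (any(bad))
      stop("non-numeric or missing cell in ", path, " at data row ",
           which(bad)[1L], ", column '", labels[j], "'")
    mat[, j] <- num
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  ts_panel(mat, labels, subject_id)
}

#' Write an ROI time-series table
#'
#' Inverse of [read_timeseries()]; values are written in full double
#' precision so that a round trip reproduces the matrix to 1e-12.
#'
#' @param panel A [ts_panel].
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param header Optional character vector of provenance lines, written as
#'   `#`-prefixed comments before the table.
#' @export
write_timeseries <- function(panel, path, dialect = c("tsv", "csv"),
                             header = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(panel, "ts_panel"))
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  writeLines(paste(panel$region_labels, collapse = sep), con)
  apply(format(panel$data, digits = 17, trim = TRUE, scientific = TRUE),
        1L, function(r) writeLines(paste(r, collapse = sep), con))
  invisible(path)
}

#' Standardize a panel to zero mean and unit variance
#'
#' Centers every region's series to sample mean 0 and rescales it to sample
#' standard deviation 1 (denominator `p - 1`). Unit variance is required for
#' the ridge penalty to weigh all regions equally; centering additionally
#' makes the ridge intercept exactly zero.
#'
#' @param panel A [ts_panel].
#' @return A standardized `ts_panel` (attribute `standardized = TRUE`).
#'   Standardizing twice is a no-op.
#' @export
standardize <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  x <- panel$data
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant region(s): ",
         paste(panel$region_labels[sds == 0], collapse = ", "))
  x <- scale(x, center = TRUE, scale = sds)
  attributes(x)[c("scaled:center", "scaled:scale")] <- NULL
  out <- ts_panel(x, panel$region_labels, panel$subject_id)
  attr(out, "standardized") <- TRUE
  out
}

#' Fisher r-to-z transform
#'
#' `atanh(r)`, the variance-stabilizing transform applied to all connectivity
#' scores before group-level statistics. To keep downstream linear models
#' finite, `|r|` is clamped at `1 - 1e-7` (a warning is emitted when clamping
#' occurs); `|r| > 1` is an error.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return `atanh` of the (clamped) input; an odd, strictly increasing
#'   function of `r`.
#' @examples
#' fisher_z(c(0, 0.5, -0.5))
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)))
    stop("non-finite correlation passed to fisher_z")
  if (any(abs(r) > 1))
    stop("correlation outside [-1, 1]: ", r[abs(r) > 1][1L])
  lim <- 1 - 1e-7
  if (any(abs(r) > lim)) {
    warning(sum(abs(r) > lim), " correlation(s) clamped to |r| = 1 - 1e-7 ",
            "before Fisher transform")
    r <- pmin(pmax(r, -lim), lim)
  }
  atanh(r)
}

.conn_methods <- c("ridgec", "ranforc", "gbc_abs",
                   "gbc_thr0", "gbc_thr01", "gbc_thr02", "gbc_thr03")

#' Construct a per-region connectivity vector
#'
#' One subject's per-region connectivity scores under one method tag.
#' Raw (non-Fisher) scores must lie in `[-1, 1]` for `ridgec`/`ranforc`
#' and in `[0, 1]` for `gbc_abs`.
#'
#' @param scores Named numeric vector, one score per region.
#' @param method One of `ridgec`, `ranforc`, `gbc_abs`, `gbc_thr0`,
#'   `gbc_thr01`, `gbc_thr02`, `gbc_thr03`.
#' @param subject_id Subject identifier.
#' @param fisher_z `TRUE` if `scores` are already Fisher z-transformed.
#' @return An object of class `connectivity_vector`.
#' @export
connectivity_vector <- function(scores, method, subject_id = "subject",
                                fisher_z = FALSE) {
  method <- match.arg(method, .conn_methods)
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be named by unique region labels")
  if (any(!is.finite(scores)))
    stop("non-finite connectivity score for region ",
         names(scores)[!is.finite(scores)][1L])
  if (!fisher_z) {
    tol <- 1e-12
    if (method %in% c("ridgec", "ranforc") && any(abs(scores) > 1 + tol))
      stop("raw ", method, " scores must lie in [-1, 1]")
    if (method == "gbc_abs" && (any(scores < -tol) || any(scores > 1 + tol)))
      stop("raw gbc_abs scores must lie in [0, 1]")
  }
  structure(list(subject_id = as.character(subject_id)[1L],
                 method = method,
                 scores = scores,
                 fisher_z = isTRUE(fisher_z)),
            class = "connectivity_vector")
}

#' @export
print.connectivity_vector <- function(x, ...) {
  cat("connectivity_vector [", x$method, "] subject '", x$subject_id, "', ",
      length(x$scores), " regions",
      if (x$fisher_z) ", Fisher z", "\n", sep = "")
  print(utils::head(x$scores, 8L))
  invisible(x)
}

#' Apply the Fisher transform to a connectivity vector
#'
#' @param cv A [connectivity_vector]. Already-transformed vectors pass
#'   through unchanged.
#' @return The vector with `fisher_z = TRUE`.
#' @export
fisher_transform <- function(cv) {
  stopifnot(inherits(cv, "connectivity_vector"))
  if (cv$fisher_z) return(cv)
  cv$scores <- fisher_z(cv$scores)
  cv$fisher_z <- TRUE
  cv
}

#' Write connectivity vectors as a long-format TSV
#'
#' Columns: `subject_id`, `method`, `region`, `score`, `score_fisher_z`.
#'
#' @param maps A `connectivity_vector` or list thereof.
#' @param path Output path.
#' @param header Optional `#`-prefixed provenance lines.
#' @export
write_connectivity <- function(maps, path, header = NULL) {
  if (inherits(maps, "connectivity_vector")) maps <- list(maps)
  rows <- lapply(maps, function(cv) {
    raw <- if (cv$fisher_z) tanh(cv$scores) else cv$scores
    fz <- if (cv$fisher_z) cv$scores else fisher_z(cv$scores)
    data.frame(subject_id = cv$subject_id, method = cv$method,
               region = names(cv$scores), score = unname(raw),
               score_fisher_z = unname(fz), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(format(df, digits = 17, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format connectivity TSV back into connectivity vectors
#'
#' @param path Path written by [write_connectivity()].
#' @return Named list of [connectivity_vector]s (one per subject x method).
#' @export
read_connectivity <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "method", "region", "score", "score_fisher_z")
  if (!all(need %in% colnames(df)))
    stop("connectivity table must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$subject_id, df$method, sep = "\r")
  out <- lapply(split(df, key), function(d) {
    s <- d$score
    names(s) <- d$region
    connectivity_vector(s, d$method[1L], d$subject_id[1L], fisher_z = FALSE)
  })
  names(out) <- sub("\r", ".", names(out), fixed = TRUE)
  out
}
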
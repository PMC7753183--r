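#' Pairwise Pearson correlation matrix of a panel
#'
#' @param panel A [ts_panel] with no constant regions.
#' @return `N x N` symmetric correlation matrix with unit diagonal, labeled
#'   by region.
#' @export
correlation_matrix <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  sds <- apply(panel$data, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant region(s): ",
         paste(panel$region_labels[sds == 0], collapse = ", "))
  R <- stats::cor(panel$data)
  dimnames(R) <- list(panel$region_labels, panel$region_labels)
  R
}

.gbc_modes <- c(abs = "gbc_abs", thr0 = "gbc_thr0", thr01 = "gbc_thr01",
                thr02 = "gbc_thr02", thr03 = "gbc_thr03")
.gbc_thresholds <- c(thr0 = 0, thr01 = 0.1, thr02 = 0.2, thr03 = 0.3)

#' Global brain connectivity (GBC) for one subject
#'
#' The bivariate baseline the multivariate scores are compared against.
#' `mode = "abs"` scores region i as the mean over j != i of `|r_ij|`
#' (weighted GBC, in `[0, 1]`). The threshold modes keep only the signed
#' correlations strictly above the threshold t (t = 0, 0.1, 0.2 or 0.3) and,
#' by default, average the surviving values only; a region whose
#' correlations all fall below t scores exactly 0 (with a warning) so group
#' analyses keep full region coverage. `zero_fill = TRUE` instead averages
#' thresholded correlations over all N - 1 pairs (survivors' values, zeros
#' elsewhere), for sensitivity analysis.
#'
#' @param panel A [ts_panel].
#' @param mode `"abs"`, `"thr0"`, `"thr01"`, `"thr02"` or `"thr03"`.
#' @param zero_fill Only for threshold modes; see above. Default `FALSE`.
#' @return A [connectivity_vector] with the matching `gbc_*` method tag.
#' @examples
#' set.seed(1)
#' gbc_subject(ts_panel(matrix(rnorm(200), 50, 4)), mode = "abs")
#' @export
gbc_subject <- function(panel, mode = c("abs", "thr0", "thr01", "thr02", "thr03"),
                        zero_fill = FALSE) {
  mode <- match.arg(mode)
  R <- correlation_matrix(panel)
  diag(R) <- NA_real_
  if (mode == "abs") {
    scores <- rowMeans(abs(R), na.rm = TRUE)
  } else {
    t <- .gbc_thresholds[[mode]]
    keep <- !is.na(R) & R > t
    if (zero_fill) {
      scores <- rowSums(R * keep, na.rm = TRUE) / (ncol(R) - 1L)
    } else {
      n_keep <- rowSums(keep)
      scores <- ifelse(n_keep > 0, rowSums(R * keep, na.rm = TRUE) /
                         pmax(n_keep, 1L), 0)
      if (any(n_keep == 0))
        warning("no correlations above ", t, " for region(s) ",
                paste(rownames(R)[n_keep == 0], collapse = ", "),
                "; score set to 0")
    }
    names(scores) <- rownames(R)
  }
  connectivity_vector(scores, .gbc_modes[[mode]], panel$subject_id)
}
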
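#' Sample-loading adjustment ("whole antibody set")
#'
#' Removes per-sample differences in total protein loading: each sample's
#' median across all non-missing proteins is subtracted from that sample's
#' column, so output sample medians are exactly 0. Equivalent corrections
#' based on the whole antibody panel are standard RPPA practice.
#'
#' @param em an [expression_matrix()].
#' @return the adjusted [expression_matrix()].
#' @export
loading_adjust <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  all_na <- colSums(!is.na(v)) == 0L
  if (any(all_na))
    stop("sample(s) with no non-missing values: ",
         paste(colnames(v)[all_na], collapse = ", "))
  if (nrow(v) < 2L)
    warning("loading adjustment over a single protein is degenerate")
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  em$values <- sweep(v, 2, med)
  em
}

#' Median-control centering per protein
#'
#' Centers every protein row at its across-sample median (row medians 0
#' afterwards), so reported values are log2 changes relative to the cohort
#' median for that antibody.
#'
#' @param em an [expression_matrix()].
#' @return the centered [expression_matrix()].
#' @export
median_center <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  all_na <- rowSums(!is.na(v)) == 0L
  if (any(all_na))
    stop("protein(s) with no non-missing values: ",
         paste(rownames(v)[all_na], collapse = ", "))
  med <- apply(v, 1, stats::median, na.rm = TRUE)
  em$values <- sweep(v, 1, med)
  em
}

#' Average duplicate samples
#'
#' Collapses columns sharing a base-sample identifier to their per-protein
#' arithmetic mean (missing values skipped); the collapsed column keeps the
#' base identifier. Duplicates carrying conflicting histology labels are
#' rejected. Averaging is intended to run after normalization, so each
#' print of a sample is corrected under its own loading first.
#'
#' @param em an [expression_matrix()] whose `base_sample` field links
#'   duplicates.
#' @return [expression_matrix()] with one column per base sample.
#' @export
average_duplicates <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  base <- em$base_sample
  groups <- split(colnames(em$values), base[colnames(em$values)])
  keep_order <- unique(unname(base[colnames(em$values)]))
  groups <- groups[keep_order]

  out <- matrix(NA_real_, nrow(em$values), length(groups),
                dimnames = list(rownames(em$values), names(groups)))
  hist_out <- NULL
  if (!is.null(em$histology)) hist_out <- stats::setNames(
    rep(NA_character_, length(groups)), names(groups))
  for (j in seq_along(groups)) {
    cols <- groups[[j]]
    if (!is.null(em$histology)) {
      h <- unique(stats::na.omit(em$histology[cols]))
      if (length(h) > 1L)
        stop("duplicates of '", names(groups)[j],
             "' carry conflicting histology labels: ",
             paste(h, collapse = " vs "))
      if (length(h) == 1L) hist_out[j] <- h
    }
    out[, j] <- rowMeans(em$values[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  expression_matrix(out, histology = hist_out)
}

#' Standard normalization chain
#'
#' Applies [loading_adjust()], then [median_center()], then
#' [average_duplicates()] — per-sample artifact removal before cross-sample
#' centering, duplicate merging last.
#'
#' @param em an [expression_matrix()].
#' @param skip_loading skip the loading adjustment (ablation switch).
#' @return normalized [expression_matrix()].
#' @export
normalize_matrix <- function(em, skip_loading = FALSE) {
  if (!skip_loading) em <- loading_adjust(em)
  em <- median_center(em)
  average_duplicates(em)
}
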
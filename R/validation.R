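#' Cross-cohort concordance classification
#'
#' Classifies how a protein's effect in a validation cohort relates to its
#' direction in the discovery cohort, using the rule set applied when
#' checking discovery hits against an independent cohort:
#'
#' * validation p > 0.20 -> `no_trend` (no trend in either direction);
#' * same direction, p < 0.05 -> `same_direction_significant`;
#' * same direction, 0.05 <= p <= 0.20 -> `same_direction_not_significant`
#'   (the p <= 0.20 boundary is inclusive);
#' * opposite direction, p < 0.05 -> `opposite`;
#' * opposite direction, 0.05 <= p <= 0.20 -> `no_trend` ("opposite" is
#'   reserved for a significant reversal).
#'
#' Direction is the sign of the log2 difference; a zero difference matches
#' neither direction and maps to `no_trend`. The rules are total: every
#' (direction pair, p) combination receives exactly one category.
#'
#' @param discovery,validation single rows of a [two_group_test()] table
#'   (or lists with `protein`, `delta_log2`, `p_value`) for the same
#'   protein.
#' @return list of class `concordance_call`: `protein`,
#'   `discovery_direction`, `validation_direction`, `validation_p`,
#'   `category`.
#' @export
concordance_classify <- function(discovery, validation) {
  if (!identical(as.character(discovery$protein),
                 as.character(validation$protein)))
    stop("discovery and validation rows refer to different proteins: ",
         discovery$protein, " vs ", validation$protein)
  d1 <- sign(discovery$delta_log2)
  d2 <- sign(validation$delta_log2)
  p <- validation$p_value
  if (!is.finite(p) || p < 0 || p > 1) stop("invalid validation p-value")
  category <-
    if (p > 0.20) "no_trend"
    else if (d1 == 0 || d2 == 0) "no_trend"
    else if (d1 == d2) {
      if (p < 0.05) "same_direction_significant"
      else "same_direction_not_significant"
    } else {
      if (p < 0.05) "opposite" else "no_trend"
    }
  structure(list(protein = as.character(discovery$protein),
                 discovery_direction = d1, validation_direction = d2,
                 validation_p = p, category = category),
            class = "concordance_call")
}

#' Concordance table for two comparison result sets
#'
#' Applies [concordance_classify()] to every protein present in both
#' tables and tallies the categories.
#'
#' @param discovery,validation [two_group_test()] tables.
#' @return data.frame with one row per shared protein plus a `counts`
#'   attribute (named category totals).
#' @export
concordance_table <- function(discovery, validation) {
  shared <- intersect(discovery$protein, validation$protein)
  if (length(shared) == 0L) stop("no shared proteins")
  rows <- lapply(shared, function(p) {
    cc <- concordance_classify(discovery[discovery$protein == p, ],
                               validation[validation$protein == p, ])
    data.frame(protein = cc$protein,
               discovery_direction = cc$discovery_direction,
               validation_direction = cc$validation_direction,
               validation_p = cc$validation_p,
               category = cc$category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  lev <- c("same_direction_significant", "same_direction_not_significant",
           "no_trend", "opposite")
  attr(out, "counts") <- table(factor(out$category, levels = lev))
  out
}

#' Score expression probes on reliability criteria
#'
#' Each probe gets one point per satisfied criterion — location near the
#' 3' end, inclusion in the spliced region, preservation in other homologs
#' of the gene, preservation in other animals — and probes are ranked by
#' descending score, ties broken by probe id ascending. The flags are
#' inputs (annotation lookups), not computed from sequence.
#'
#' @param probes data.frame with column `probe_id` and logical columns
#'   `near_3prime`, `in_spliced_region`, `conserved_homologs`,
#'   `conserved_other_animals`.
#' @return the table with a `score` column, sorted; rank 1 first.
#' @export
score_probes <- function(probes) {
  flags <- c("near_3prime", "in_spliced_region", "conserved_homologs",
             "conserved_other_animals")
  miss <- setdiff(c("probe_id", flags), names(probes))
  if (length(miss))
    stop("probe table missing column(s): ", paste(miss, collapse = ", "))
  for (f in flags) if (!is.logical(probes[[f]]))
    stop("criterion flag '", f, "' must be logical")
  probes$score <- rowSums(as.matrix(probes[flags]))
  out <- probes[order(-probes$score, probes$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage from printed cohort counts
#'
#' Recomputes a whole-number percentage the way cohort tables print them:
#' `round(100 * count / total)` to the nearest integer.
#'
#' @param count,total non-negative counts, `total > 0`.
#' @return integer percentage.
#' @export
cohort_percent <- function(count, total) {
  if (total <= 0) stop("total must be positive")
  as.integer(round(100 * count / total))
}
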
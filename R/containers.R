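#' Spot intensities for one antibody slide
#'
#' Long-format container for a reverse-phase protein array slide: one row
#' per printed spot, identified by sample, dilution step (0 = undiluted
#' anchor, each further step a two-fold dilution) and replicate.
#'
#' @param antibody slide / antibody name (length-1 character).
#' @param sample_id character vector of sample identifiers.
#' @param dilution_step integer vector, >= 0.
#' @param replicate integer vector, >= 1.
#' @param intensity finite, non-negative signal values.
#' @param base_sample_id optional base identifiers linking on-slide
#'   duplicates (defaults to `sample_id`).
#' @return data.frame of class `slide_measurements`.
#' @export
slide_measurements <- function(antibody, sample_id, dilution_step, replicate,
                               intensity, base_sample_id = sample_id) {
  df <- data.frame(antibody = as.character(antibody),
                   sample_id = as.character(sample_id),
                   base_sample_id = as.character(base_sample_id),
                   dilution_step = as.integer(dilution_step),
                   replicate = as.integer(replicate),
                   intensity = as.numeric(intensity),
                   stringsAsFactors = FALSE)
  validate_slide_measurements(df)
}

validate_slide_measurements <- function(df) {
  req <- c("antibody", "sample_id", "base_sample_id", "dilution_step",
           "replicate", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("slide table is missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(df$antibody)) != 1L)
    stop("a slide holds exactly one antibody")
  if (any(df$dilution_step < 0)) stop("dilution_step must be >= 0")
  bad <- which(!is.finite(df$intensity) | df$intensity < 0)
  if (length(bad))
    stop("intensity must be finite and >= 0; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  nstep <- tapply(df$dilution_step, df$sample_id,
                  function(s) length(unique(s)))
  if (any(nstep < 3))
    stop("every sample needs >= 3 distinct dilution steps; violated by: ",
         paste(names(nstep)[nstep < 3], collapse = ", "))
  class(df) <- unique(c("slide_measurements", class(df)))
  df
}

#' @export
print.slide_measurements <- function(x, ...) {
  cat("slide_measurements: antibody", x$antibody[1], "|",
      length(unique(x$sample_id)), "samples |",
      length(unique(x$dilution_step)), "dilution steps |",
      nrow(x), "spots\n")
  invisible(x)
}

#' Protein-by-sample log2 expression matrix
#'
#' Relative log2 concentrations (missing allowed) with optional histology
#' annotations (`"SCC"` / `"non-SCC"`) and base-sample identifiers marking
#' duplicate columns of the same biological sample.
#'
#' @param values numeric matrix, proteins in rows (rownames), samples in
#'   columns (colnames); `NA` allowed.
#' @param histology optional named character vector (sample -> label).
#' @param base_sample optional named character vector (sample -> base id);
#'   defaults to the sample ids themselves.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, histology = NULL, base_sample = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry protein rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein names: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (is.null(base_sample))
    base_sample <- stats::setNames(colnames(values), colnames(values))
  if (!is.null(histology)) {
    histology <- histology[colnames(values)]
    names(histology) <- colnames(values)
  }
  base_sample <- base_sample[colnames(values)]
  names(base_sample) <- colnames(values)
  structure(list(values = values, histology = histology,
                 base_sample = base_sample),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "proteins x", ncol(x$values),
      "samples")
  if (!is.null(x$histology)) {
    tab <- table(x$histology, useNA = "no")
    cat(" |", paste(sprintf("%s=%d", names(tab), tab), collapse = " "))
  }
  cat(" |", sum(is.na(x$values)), "missing\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Dose-response series for one drug or fixed-ratio combination
#'
#' @param label drug or combination label; for a combination, `ratio`
#'   records the fixed mixing ratio of component 1.
#' @param doses strictly positive doses; re-sorted ascending.
#' @param viability finite viability fractions (of untreated control).
#' @param ratio optional fraction of the total combination dose contributed
#'   by the first component (`r1`; `r2 = 1 - r1`).
#' @return data.frame of class `dose_response`.
#' @export
dose_response <- function(label, doses, viability, ratio = NULL) {
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (any(!is.finite(viability))) stop("viability must be finite")
  o <- order(doses)
  df <- data.frame(label = as.character(label), dose = as.numeric(doses)[o],
                   viability = as.numeric(viability)[o],
                   stringsAsFactors = FALSE)
  class(df) <- c("dose_response", "data.frame")
  attr(df, "ratio") <- ratio
  df
}
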
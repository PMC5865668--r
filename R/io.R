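#' Read / write slide spot tables
#'
#' Long-format tab-delimited UTF-8 text with a header row and columns
#' `antibody`, `sample_id`, `base_sample_id`, `dilution_step`, `replicate`,
#' `intensity`. Writing then reading a valid table is the identity.
#'
#' @param path file path.
#' @return [read_slide_tsv()] returns a list of [slide_measurements()]
#'   (one per antibody); [write_slide_tsv()] returns `path` invisibly.
#' @name slide_tsv
NULL

#' @rdname slide_tsv
#' @export
read_slide_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  req <- c("antibody", "sample_id", "base_sample_id", "dilution_step",
           "replicate", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("slide file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  lapply(split(df, df$antibody), validate_slide_measurements)
}

#' @param slides one [slide_measurements()] or a list of them.
#' @rdname slide_tsv
#' @export
write_slide_tsv <- function(slides, path) {
  if (inherits(slides, "slide_measurements")) slides <- list(slides)
  df <- do.call(rbind, lapply(slides, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write expression matrices
#'
#' Tab-delimited text with proteins as rows; the first column is
#' `protein`, remaining columns are samples; missing values are `NA`.
#' Sample annotations (histology, base-sample id) travel in a sidecar file
#' `<path>.annot.tsv` with columns `sample_id`, `base_sample_id`,
#' `histology`, written when annotations exist and read when present.
#'
#' @param path matrix file path.
#' @return [read_matrix_tsv()] returns an [expression_matrix()];
#'   [write_matrix_tsv()] returns `path` invisibly.
#' @name matrix_tsv
NULL

annot_path <- function(path) paste0(path, ".annot.tsv")

#' @rdname matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1] != "protein")
    stop("matrix file '", path, "' must have 'protein' as its first column")
  if (anyDuplicated(df$protein))
    stop("duplicate protein name(s) in '", path, "': ",
         paste(unique(df$protein[duplicated(df$protein)]), collapse = ", "))
  v <- as.matrix(df[, -1, drop = FALSE])
  mode(v) <- "numeric"
  rownames(v) <- df$protein
  histology <- NULL; base <- NULL
  ap <- annot_path(path)
  if (file.exists(ap)) {
    an <- utils::read.delim(ap, sep = "\t", stringsAsFactors = FALSE)
    if ("histology" %in% names(an) && !all(is.na(an$histology)))
      histology <- stats::setNames(an$histology, an$sample_id)
    if ("base_sample_id" %in% names(an))
      base <- stats::setNames(an$base_sample_id, an$sample_id)
  }
  expression_matrix(v, histology = histology, base_sample = base)
}

#' @param em an [expression_matrix()].
#' @rdname matrix_tsv
#' @export
write_matrix_tsv <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(protein = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  has_hist <- !is.null(em$histology)
  has_base <- !identical(unname(em$base_sample), colnames(em$values))
  if (has_hist || has_base) {
    an <- data.frame(sample_id = colnames(em$values),
                     base_sample_id = unname(em$base_sample),
                     histology = if (has_hist) unname(em$histology)
                                 else NA_character_,
                     stringsAsFactors = FALSE)
    utils::write.table(an, annot_path(path), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read / write viability plate tables
#'
#' Tab-delimited with columns `label`, `dose`, `viability`; one block per
#' drug or fixed-ratio combination. An optional `ratio` column records the
#' first component's dose fraction for combinations.
#'
#' @param path file path.
#' @return [read_plate_tsv()] returns a named list of [dose_response()].
#' @name plate_tsv
NULL

#' @rdname plate_tsv
#' @export
read_plate_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("label", "dose", "viability")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("plate file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  lapply(split(df, df$label), function(b)
    dose_response(b$label[1], b$dose, b$viability,
                  ratio = if ("ratio" %in% names(b)) b$ratio[1] else NULL))
}

#' @param plates one [dose_response()] or a list of them.
#' @rdname plate_tsv
#' @export
write_plate_tsv <- function(plates, path) {
  if (inherits(plates, "dose_response")) plates <- list(plates)
  df <- do.call(rbind, lapply(plates, function(p) {
    d <- as.data.frame(p)
    d$ratio <- if (is.null(attr(p, "ratio"))) NA_real_ else attr(p, "ratio")
    d
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write tumor growth tables
#'
#' Tab-delimited with columns `mouse`, `group`, `day`, `volume`.
#'
#' @param path file path.
#' @name growth_tsv
NULL

#' @rdname growth_tsv
#' @export
read_growth_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("mouse", "group", "day", "volume")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("growth file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$volume < 0)) stop("negative tumor volumes")
  class(df) <- c("growth_data", "data.frame")
  df
}

#' @param data a `growth_data` data.frame.
#' @rdname growth_tsv
#' @export
write_growth_tsv <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' One `key: value` pair per line (YAML-style scalars only); `#` starts a
#' comment; values are parsed as numbers when possible, `true`/`false` as
#' logical, comma-separated lists as vectors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: '", ln, "'")
    key <- trimws(m[2])
    val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(parsed)) parsed
      else if (all(tolower(parts) %in% c("true", "false")))
        tolower(parts) == "true"
      else parts
  }
  out
}
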
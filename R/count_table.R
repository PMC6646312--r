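#' Validate a species-by-sample count table
#'
#' A count table is an integer matrix with species as rows and samples as
#' columns, both carrying unique identifiers as dimnames.  All entries must
#' be non-negative integers.  All-zero species rows are permitted (they can
#' arise after filtering or rarefaction) but are reported via the
#' `"empty_species"` attribute so callers can flag them.
#'
#' @param x matrix of counts (species x samples).
#' @return `x`, invisibly coerced to integer storage, with an
#'   `"empty_species"` attribute listing all-zero rows.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x)) stop("count table must be a matrix (species x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must carry species rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop("duplicate species ids in count table")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids in count table")
  if (any(is.na(x))) stop("count table contains missing values")
  if (any(x < 0)) stop("count table contains negative counts")
  if (any(x != round(x))) stop("count table contains non-integer counts")
  storage.mode(x) <- "integer"
  attr(x, "empty_species") <- rownames(x)[rowSums(x) == 0]
  invisible(x)
}

#' Read a count table from TSV or BIOM
#'
#' The canonical on-disk format is a UTF-8 tab-separated table whose first
#' column holds species ids (header cell `species_id`) and whose remaining
#' columns are samples.  BIOM files are read through the \pkg{biomformat}
#' package when it is installed.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return an integer species-by-sample matrix (see [validate_count_table()]).
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(validate_count_table(m))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table must have at least one sample column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- ids
  validate_count_table(m)
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]; integer tables round-trip bit-identically.
#'
#' @param x count table matrix.
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  x <- validate_count_table(x)
  df <- data.frame(species_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Library sizes (per-sample sequence totals)
#'
#' @param x count table matrix.
#' @return named integer vector of column totals.
#' @export
library_sizes <- function(x) colSums(x)

#' Drop samples with low sequence totals
#'
#' Samples whose library size falls below `min_total` are removed before any
#' rarefaction-based analysis; the default of 100 sequences reflects common
#' practice for low-biomass saliva samples.  The species set is never
#' changed by this filter.
#'
#' @param x count table matrix.
#' @param min_total minimum library size to retain a sample.
#' @return list with elements `table` (the filtered count table) and
#'   `removed` (character vector of removed sample ids).
#' @export
filter_low_count_samples <- function(x, min_total = 100) {
  x <- validate_count_table(x)
  if (min_total < 0) stop("min_total must be >= 0")
  keep <- library_sizes(x) >= min_total
  if (!any(keep)) warning("all samples fall below min_total")
  list(table = x[, keep, drop = FALSE], removed = colnames(x)[!keep])
}

#' Convert counts to (square-root-adjusted) relative abundances
#'
#' @param x count table matrix; every column total must be positive.
#' @param sqrt_adjust if `TRUE`, return the element-wise square root of the
#'   proportions (a variance-stabilizing display transform for abundance
#'   boxplots).
#' @return real matrix, same shape as `x`; columns sum to 1 when
#'   `sqrt_adjust = FALSE`.
#' @export
relative_abundance <- function(x, sqrt_adjust = FALSE) {
  totals <- colSums(x)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(colnames(x)[totals == 0], collapse = ", "))
  p <- sweep(x, 2, totals, "/")
  if (sqrt_adjust) p <- sqrt(p)
  p
}

#' Sum count columns within (subject, group) units
#'
#' Repeatedly sampled subjects are collapsed to one column per subject and
#' group by element-wise addition, so that per-subject analyses are not
#' biased by unequal sampling frequency.
#'
#' @param x count table matrix.
#' @param grouping data frame with columns `sample_id`, `subject_id`,
#'   `group`; every column of `x` must appear exactly once.
#' @return count table with one column per (subject, group) unit, named
#'   `<subject>.<group>`, carrying a `"units"` attribute (data frame with
#'   columns `unit`, `subject_id`, `group`).
#' @export
combine_subject_samples <- function(x, grouping) {
  need <- c("sample_id", "subject_id", "group")
  if (!all(need %in% names(grouping)))
    stop("grouping needs columns: ", paste(need, collapse = ", "))
  idx <- match(colnames(x), grouping$sample_id)
  if (any(is.na(idx)))
    stop("unmapped samples: ",
         paste(colnames(x)[is.na(idx)], collapse = ", "))
  unit <- paste(grouping$subject_id[idx], grouping$group[idx], sep = ".")
  units <- unique(data.frame(unit = unit,
                             subject_id = grouping$subject_id[idx],
                             group = grouping$group[idx],
                             stringsAsFactors = FALSE))
  combined <- t(rowsum(t(x), group = unit, reorder = FALSE))
  storage.mode(combined) <- "integer"
  units <- units[match(colnames(combined), units$unit), ]
  rownames(units) <- NULL
  attr(combined, "units") <- units
  combined
}
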
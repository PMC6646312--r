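#' Read and validate sample metadata
#'
#' Metadata is a CSV with header
#' `sample_id,subject_id,role,age_months,solid_food_start_months,tooth_eruption_months`;
#' empty cells encode missing values.  `role` is `"child"` or `"mother"`.
#' Child ages must lie in `[0, 13)` months; event ages, when recorded, must
#' be positive.  Mothers contribute a single baseline sample each, and their
#' `age_months` field is not used for grouping.
#'
#' @param path CSV path.
#' @return validated metadata data frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- read.csv(path, stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta metadata data frame.
#' @param table optional count table; when given, every sample id in the
#'   table must have exactly one metadata row.
#' @export
validate_sample_metadata <- function(meta, table = NULL) {
  need <- c("sample_id", "subject_id", "role", "age_months")
  if (!all(need %in% names(meta)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  if (!all(meta$role %in% c("child", "mother")))
    stop("role must be 'child' or 'mother'")
  child <- meta$role == "child"
  if (any(is.na(meta$age_months[child])))
    stop("child samples must carry age_months")
  if (any(meta$age_months[child] < 0 | meta$age_months[child] >= 13))
    stop("child age_months must lie in [0, 13)")
  for (ev in c("solid_food_start_months", "tooth_eruption_months")) {
    if (ev %in% names(meta)) {
      bad <- !is.na(meta[[ev]]) & meta[[ev]] <= 0
      if (any(bad)) stop(ev, " must be positive when present")
    }
  }
  if (!is.null(table)) {
    missing <- setdiff(colnames(table), meta$sample_id)
    if (length(missing))
      stop("samples without metadata: ", paste(missing, collapse = ", "))
  }
  meta
}

#' Write sample metadata as CSV
#' @param meta metadata data frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(meta, path) {
  write.csv(meta, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assign samples to infant / toddler / mother age groups
#'
#' Children aged 0--2 months (inclusive on both ends) are infants, children
#' aged 10--12 months are toddlers, mothers form their own group, and all
#' remaining child samples are labeled `"other"`.  The partition is
#' exhaustive and mutually exclusive.
#'
#' @param meta metadata data frame.
#' @return data frame with columns `sample_id`, `subject_id`, `group`.
#' @export
assign_age_groups <- function(meta) {
  meta <- validate_sample_metadata(meta)
  group <- ifelse(meta$role == "mother", "mother",
           ifelse(meta$age_months >= 0 & meta$age_months <= 2, "infant",
           ifelse(meta$age_months >= 10 & meta$age_months <= 12, "toddler",
                  "other")))
  data.frame(sample_id = meta$sample_id, subject_id = meta$subject_id,
             group = group, stringsAsFactors = FALSE)
}
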
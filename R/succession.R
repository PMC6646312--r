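child_interval_labels <- c("[0,3)", "[3,6)", "[6,9)", "[9,12]")

# interval index of an age in months: half-open 3-month bins, the last
# closed at 12 so month-12 samples land in [9,12]
interval_of <- function(age, window = 3) {
  pmin(floor(age / window), (12 %/% window) - 1) + 1L
}

#' Pool monthly child samples into 3-month intervals
#'
#' Counts are summed within each (subject, interval); intervals are
#' half-open except the last, which is closed at 12 months so that
#' month-12 samples fall in `[9,12]`.  Subject-intervals with no collected
#' samples are simply absent, and are later excluded from the prevalence
#' denominator of that interval.
#'
#' @param x count table matrix.
#' @param meta sample metadata (child samples of `x` are used).
#' @param window interval width in months.
#' @return count table with one column per subject-interval, carrying a
#'   `"pools"` attribute (data frame: `pool`, `subject_id`, `interval`).
#' @export
pool_intervals <- function(x, meta, window = 3) {
  meta <- validate_sample_metadata(meta, x)
  child <- meta[meta$role == "child" & meta$sample_id %in% colnames(x), ]
  if (!nrow(child)) stop("no child samples to pool")
  xs <- x[, child$sample_id, drop = FALSE]
  iv <- interval_of(child$age_months, window)
  pool <- paste(child$subject_id, child_interval_labels[iv], sep = ".")
  pooled <- t(rowsum(t(xs), group = pool, reorder = FALSE))
  storage.mode(pooled) <- "integer"
  info <- unique(data.frame(pool = pool, subject_id = child$subject_id,
                            interval = child_interval_labels[iv],
                            stringsAsFactors = FALSE))
  info <- info[match(colnames(pooled), info$pool), ]
  rownames(info) <- NULL
  attr(pooled, "pools") <- info
  pooled
}

#' One pooled column per mother
#'
#' All sequences of each mother are pooled into a single column labeled
#' with the `"mother"` interval, for display alongside the child intervals.
#'
#' @inheritParams pool_intervals
#' @export
pool_mothers <- function(x, meta) {
  meta <- validate_sample_metadata(meta, x)
  mom <- meta[meta$role == "mother" & meta$sample_id %in% colnames(x), ]
  if (!nrow(mom)) stop("no mother samples to pool")
  xs <- x[, mom$sample_id, drop = FALSE]
  pool <- paste(mom$subject_id, "mother", sep = ".")
  pooled <- t(rowsum(t(xs), group = pool, reorder = FALSE))
  storage.mode(pooled) <- "integer"
  info <- unique(data.frame(pool = pool, subject_id = mom$subject_id,
                            interval = "mother", stringsAsFactors = FALSE))
  info <- info[match(colnames(pooled), info$pool), ]
  rownames(info) <- NULL
  attr(pooled, "pools") <- info
  pooled
}

#' Presence/absence after rarefying pooled counts to a common depth
#'
#' Each pool is rarefied once to `depth` (a single realization, as for a
#' presence heatmap); pools whose total falls below `depth` are dropped and
#' reported in the `"excluded"` attribute.  With `n_reps > 1` the
#' across-draw presence frequency is returned instead of a single boolean
#' realization, for sensitivity analysis.
#'
#' @param pools output of [pool_intervals()] (optionally cbind-ed with
#'   [pool_mothers()]; the `"pools"` attribute must describe all columns).
#' @param depth rarefaction depth (> 0).
#' @param seed optional integer seed.
#' @param n_reps number of rarefaction draws per pool.
#' @return species x pool logical matrix (`n_reps = 1`) or frequency
#'   matrix, with the `"pools"` attribute subset to retained pools and an
#'   `"excluded"` attribute naming dropped pools.
#' @export
pooled_presence <- function(pools, depth = 498, seed = NULL, n_reps = 1) {
  if (depth <= 0) stop("depth must be positive")
  totals <- colSums(pools)
  drop <- totals < depth
  if (any(drop))
    message("dropping ", sum(drop), " pool(s) below depth ", depth, ": ",
            paste(colnames(pools)[drop], collapse = ", "))
  kept <- pools[, !drop, drop = FALSE]
  if (!ncol(kept)) stop("no pools at or above depth ", depth)
  pres <- with_seed(seed, {
    acc <- matrix(0, nrow(kept), ncol(kept), dimnames = dimnames(kept))
    for (r in seq_len(n_reps))
      acc <- acc + (rarefy_columns(kept, depth) > 0)
    acc / n_reps
  })
  if (n_reps == 1) pres <- pres > 0
  info <- attr(pools, "pools")
  attr(pres, "pools") <- info[match(colnames(kept), info$pool), ]
  attr(pres, "excluded") <- colnames(pools)[drop]
  pres
}

#' Prevalence of species across subjects per age interval
#'
#' Prevalence in an interval is the fraction of that interval's subjects in
#' which the species is present (after pooled rarefaction).  Species are
#' retained only when present in at least `min_subject_fraction` of child
#' subjects overall (in any interval), and rows are sorted by decreasing
#' overall prevalence, ties broken by earlier acquisition interval and then
#' species id.
#'
#' @param presence species x pool presence matrix from [pooled_presence()].
#' @param min_subject_fraction overall-subject prevalence filter.
#' @param acquisition_threshold threshold used for the tie-breaking
#'   acquisition interval (see [acquisition_intervals()]).
#' @return object of class `prevalence_matrix`: list with `prevalence`
#'   (species x interval matrix, possibly including a `"mother"` column),
#'   `denominators` (subjects per interval), `overall` (per-species overall
#'   subject prevalence).
#' @export
prevalence_matrix <- function(presence, min_subject_fraction = 0.5,
                              acquisition_threshold = 0.75) {
  info <- attr(presence, "pools")
  if (is.null(info)) stop("presence matrix lacks its 'pools' attribute")
  intervals <- c(child_interval_labels[child_interval_labels %in%
                                         info$interval],
                 if ("mother" %in% info$interval) "mother")
  prev <- sapply(intervals, function(iv) {
    cols <- info$interval == iv
    rowMeans(presence[, cols, drop = FALSE] > 0)
  })
  denom <- vapply(intervals,
                  function(iv) length(unique(info$subject_id[info$interval == iv])),
                  0L)
  child_iv <- setdiff(intervals, "mother")
  child_info <- info[info$interval != "mother", ]
  subjects <- unique(child_info$subject_id)
  # overall prevalence: fraction of child subjects positive in >= 1 interval
  by_subj <- vapply(subjects, function(s) {
    cols <- child_info$pool[child_info$subject_id == s]
    rowSums(presence[, cols, drop = FALSE] > 0) > 0
  }, logical(nrow(presence)))
  overall <- rowMeans(by_subj)
  keep <- overall >= min_subject_fraction
  prev <- prev[keep, , drop = FALSE]
  overall <- overall[keep]
  # sort: overall prevalence desc, then earlier acquisition, then id
  first_iv <- apply(prev[, child_iv, drop = FALSE] >= acquisition_threshold,
                    1, function(z) if (any(z)) which(z)[1] else Inf)
  ord <- order(-overall, first_iv, rownames(prev))
  structure(list(prevalence = prev[ord, , drop = FALSE],
                 denominators = denom, overall = overall[ord],
                 intervals = intervals),
            class = "prevalence_matrix")
}

#' @export
print.prevalence_matrix <- function(x, ...) {
  cat(sprintf("Prevalence matrix: %d species x %d intervals\n",
              nrow(x$prevalence), length(x$intervals)))
  cat("  subjects per interval: ",
      paste(sprintf("%s=%d", x$intervals, x$denominators), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.prevalence_matrix <- function(x, threshold = 0.75, ...) {
  m <- x$prevalence[rev(seq_len(nrow(x$prevalence))), , drop = FALSE]
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Species prevalence by age interval", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 1)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2,
                 cex.axis = 0.5)
  invisible(x)
}

#' First age interval of high prevalence (acquisition call)
#'
#' The acquisition interval of a species is the first child age interval
#' (in age order, never the mother column) in which its prevalence reaches
#' `threshold`.  A species whose prevalence later falls back below the
#' threshold keeps its first-crossing call but is flagged.
#'
#' @param pm a [prevalence_matrix()].
#' @param threshold prevalence required for detection across children.
#' @return data frame of class `acquisition_calls` with columns
#'   `species_id`, `acquisition_interval` (`NA` if never reached),
#'   `overall_prevalence`, `drops_below_after`.
#' @export
acquisition_intervals <- function(pm, threshold = 0.75) {
  child_iv <- setdiff(pm$intervals, "mother")
  prev <- pm$prevalence[, child_iv, drop = FALSE]
  hits <- prev >= threshold
  first <- apply(hits, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  drops <- vapply(seq_len(nrow(prev)), function(i) {
    if (is.na(first[i])) return(FALSE)
    later <- prev[i, seq(first[i], ncol(prev)), drop = TRUE]
    any(later < threshold)
  }, logical(1))
  structure(data.frame(
    species_id = rownames(prev),
    acquisition_interval = ifelse(is.na(first), NA_character_,
                                  child_iv[first]),
    overall_prevalence = unname(pm$overall),
    drops_below_after = drops,
    stringsAsFactors = FALSE, row.names = NULL),
    class = c("acquisition_calls", "data.frame"), threshold = threshold)
}
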
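#' Rarefy a count vector to a fixed depth
#'
#' Random subsampling without replacement (multivariate hypergeometric):
#' the output sums to `depth` and never exceeds the input element-wise.
#' Matches the behaviour of `vegan::rrarefy`, which this package uses as an
#' independent cross-check in its test suite.
#'
#' @param counts non-negative integer vector.
#' @param depth target total, `0 <= depth <= sum(counts)`.
#' @param seed optional integer seed.
#' @return integer vector of subsampled counts.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  if (depth < 0) stop("depth must be >= 0")
  if (depth > sum(counts))
    stop("depth (", depth, ") exceeds total count (", sum(counts), ")")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  with_seed(seed, {
    out <- rarefy_vector_cpp(as.integer(counts), as.integer(depth))
    names(out) <- names(counts)
    out
  })
}

#' Rarefy every column of a count table
#'
#' @param x count table matrix (species x samples).
#' @param depths single depth recycled to all columns, or one per column.
#' @param seed optional integer seed.
#' @return integer matrix of the same shape.
#' @export
rarefy_columns <- function(x, depths, seed = NULL) {
  depths <- as.integer(rep_len(depths, ncol(x)))
  if (any(depths > colSums(x)))
    stop("depth exceeds library size for sample(s): ",
         paste(colnames(x)[depths > colSums(x)], collapse = ", "))
  with_seed(seed, {
    out <- rarefy_columns_cpp(x, depths)
    dimnames(out) <- dimnames(x)
    out
  })
}

#' Double-rarefaction empirical inclusion probabilities
#'
#' Determines core community membership per group while correcting for two
#' biases at once: unequal library sizes and unequal per-subject sampling
#' frequency.  Each iteration (a) rarefies every sample to the smallest
#' library size in the analysis set, (b) sums the rarefied counts within
#' each (subject, group) unit, (c) rarefies every combined unit to the
#' smallest combined total, and (d) records, for each group, which species
#' are observed (count > 0) in at least one of that group's units.  The
#' empirical inclusion probability of a species in a group is the fraction
#' of iterations in which it was observed there; species at or above
#' `threshold` are called included.
#'
#' Samples below the intended stage-1 depth must be removed beforehand
#' (see [filter_low_count_samples()]).
#'
#' @param x count table matrix.
#' @param grouping data frame with columns `sample_id`, `subject_id`,
#'   `group`; samples of `x` absent from `grouping` (or with group `NA` or
#'   `"other"`) are excluded from the analysis set.
#' @param n_iterations number of resampling iterations.
#' @param threshold inclusion threshold on the empirical probability.
#' @param seed optional integer seed.
#' @return object of class `inclusion_result`: data frame with columns
#'   `group`, `species_id`, `empirical_probability`, `included`, plus
#'   attributes `n_iterations`, `threshold`, `stage1_depth`.
#' @export
double_rarefaction_inclusion <- function(x, grouping, n_iterations = 1000,
                                         threshold = 0.95, seed = NULL) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  keep <- grouping$sample_id[!is.na(grouping$group) &
                               grouping$group != "other"]
  keep <- intersect(colnames(x), keep)
  if (!length(keep)) stop("no samples in the analysis set")
  x <- x[, keep, drop = FALSE]
  idx <- match(keep, grouping$sample_id)
  unit <- paste(grouping$subject_id[idx], grouping$group[idx], sep = ".")
  unit_group <- vapply(split(grouping$group[idx], unit), `[`, "", 1)
  groups <- sort(unique(unname(unit_group)))
  if (any(tabulate(factor(unit_group, groups)) < 1))
    stop("every group needs at least one unit")
  d1 <- min(colSums(x))
  if (d1 < 1) stop("empty sample in the analysis set")
  unit_f <- factor(unit)
  # indicator: samples x units, for summing rarefied counts within units
  M <- outer(unit, levels(unit_f), "==") * 1L
  group_units <- lapply(groups,
                        function(g) which(unit_group[levels(unit_f)] == g))
  names(group_units) <- groups
  obs <- matrix(0L, nrow(x), length(groups),
                dimnames = list(rownames(x), groups))
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      r1 <- rarefy_columns_cpp(x, rep.int(as.integer(d1), ncol(x)))
      combined <- r1 %*% M
      storage.mode(combined) <- "integer"
      d2 <- min(colSums(combined))
      r2 <- rarefy_columns_cpp(combined, rep.int(as.integer(d2),
                                                 ncol(combined)))
      for (g in groups) {
        seen <- rowSums(r2[, group_units[[g]], drop = FALSE] > 0L) > 0L
        obs[, g] <- obs[, g] + seen
      }
    }
  })
  prob <- obs / n_iterations
  res <- data.frame(
    group = rep(groups, each = nrow(x)),
    species_id = rep(rownames(x), length(groups)),
    empirical_probability = as.vector(prob),
    stringsAsFactors = FALSE)
  res$included <- res$empirical_probability >= threshold
  structure(res, class = c("inclusion_result", "data.frame"),
            n_iterations = n_iterations, threshold = threshold,
            stage1_depth = d1)
}

#' @export
print.inclusion_result <- function(x, ...) {
  cat(sprintf(
    "Double-rarefaction inclusion: %d species x %d group(s), %d iterations\n",
    length(unique(x$species_id)), length(unique(x$group)),
    attr(x, "n_iterations")))
  cat(sprintf("  stage-1 depth %d, threshold %.2f\n",
              attr(x, "stage1_depth"), attr(x, "threshold")))
  tab <- table(x$group[x$included])
  for (g in names(tab))
    cat(sprintf("  %s: %d species included\n", g, tab[[g]]))
  invisible(x)
}

#' Average a statistic over repeated rarefactions
#'
#' Rarefies `counts` to `depth` `n_reps` times independently and returns
#' the mean of `statistic` over the replicates; used for rarefied Shannon
#' diversity and richness so that unequal library sizes do not bias
#' comparisons.
#'
#' @param counts non-negative integer vector.
#' @param depth rarefaction depth.
#' @param statistic function of a count vector returning a scalar.
#' @param n_reps number of independent rarefactions.
#' @param seed optional integer seed.
#' @return mean of the statistic across replicates.
#' @export
rarefy_mean_statistic <- function(counts, depth, statistic, n_reps = 10,
                                  seed = NULL) {
  with_seed(seed, {
    mean(vapply(seq_len(n_reps),
                function(i) statistic(rarefy(counts, depth)), 0))
  })
}
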
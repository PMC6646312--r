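#' Venn-region membership from group inclusion calls
#'
#' Assigns every species included in at least one of the infant, toddler
#' and mother groups to exactly one of the 7 Venn regions (the nonempty
#' subsets of the three groups).
#'
#' @param inclusions an `inclusion_result` from
#'   [double_rarefaction_inclusion()] covering the three groups.
#' @param groups the three region-defining groups, in display order.
#' @return object of class `venn_membership`: named list of character
#'   vectors, one per region (names like `"infant+toddler+mother"`).
#' @export
venn_membership <- function(inclusions,
                            groups = c("infant", "toddler", "mother")) {
  missing <- setdiff(groups, unique(inclusions$group))
  if (length(missing))
    stop("inclusion results lack group(s): ",
         paste(missing, collapse = ", "))
  inc <- inclusions[inclusions$included & inclusions$group %in% groups, ]
  regions <- list()
  for (sp in unique(inc$species_id)) {
    members <- groups[groups %in% inc$group[inc$species_id == sp]]
    key <- paste(members, collapse = "+")
    regions[[key]] <- c(regions[[key]], sp)
  }
  all_keys <- unlist(lapply(seq_along(groups), function(m) {
    apply(utils::combn(groups, m), 2, paste, collapse = "+")
  }))
  out <- setNames(vector("list", length(all_keys)), all_keys)
  for (key in all_keys)
    out[[key]] <- sort(regions[[key]] %||% character())
  structure(out, class = "venn_membership")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.venn_membership <- function(x, ...) {
  cat("Venn membership (", sum(lengths(x)), " species included):\n",
      sep = "")
  for (key in names(x))
    cat(sprintf("  %-22s %d\n", key, length(x[[key]])))
  invisible(x)
}

#' Relative-abundance contribution of a shared core set
#'
#' For each sample, the summed relative abundance of the given species
#' set; group summaries report median and quartiles.
#'
#' @param x count table matrix with positive library sizes.
#' @param core_set character vector of species ids (must all be rows of
#'   `x`).
#' @param grouping optional data frame (`sample_id`, `group`) for the
#'   per-group summaries.
#' @return object of class `core_contribution`: list with `per_sample`
#'   (named numeric in `[0,1]`) and `by_group` (data frame of group
#'   median/quartiles, when grouping is given).
#' @export
shared_core_contribution <- function(x, core_set, grouping = NULL) {
  unknown <- setdiff(core_set, rownames(x))
  if (length(unknown))
    stop("unknown species id(s): ", paste(unknown, collapse = ", "))
  p <- relative_abundance(x)
  frac <- if (length(core_set)) {
    colSums(p[core_set, , drop = FALSE])
  } else {
    setNames(numeric(ncol(x)), colnames(x))
  }
  by_group <- NULL
  if (!is.null(grouping)) {
    g <- grouping$group[match(names(frac), grouping$sample_id)]
    keep <- !is.na(g)
    qs <- tapply(frac[keep], g[keep], quantile, probs = c(0.25, 0.5, 0.75))
    by_group <- data.frame(
      group = names(qs),
      q1 = vapply(qs, `[`, 0, 1), median = vapply(qs, `[`, 0, 2),
      q3 = vapply(qs, `[`, 0, 3), row.names = NULL,
      stringsAsFactors = FALSE)
  }
  structure(list(per_sample = frac, by_group = by_group),
            class = "core_contribution")
}

#' @export
print.core_contribution <- function(x, ...) {
  cat(sprintf("Shared-core contribution: mean %.3f over %d samples\n",
              mean(x$per_sample), length(x$per_sample)))
  if (!is.null(x$by_group)) {
    for (i in seq_len(nrow(x$by_group)))
      cat(sprintf("  %-8s median %.3f (IQR %.3f-%.3f)\n",
                  x$by_group$group[i], x$by_group$median[i],
                  x$by_group$q1[i], x$by_group$q3[i]))
  }
  invisible(x)
}
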
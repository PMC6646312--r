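#' Non-metric multidimensional scaling of a distance matrix
#'
#' Rank-based embedding minimizing Kruskal stress-1, via
#' [vegan::metaMDS()] with random restarts.  Non-convergence is flagged,
#' not raised.
#'
#' @param d a `dist` object (e.g. from [bray_curtis_dist()]).
#' @param k embedding dimension.
#' @param n_starts number of random starts (`trymax`).
#' @param groups optional group label per sample, for centroids.
#' @param seed optional integer seed.
#' @return object of class `nmds_ordination`: list with `points`
#'   (samples x k), `stress` (Kruskal stress-1, fraction), `converged`,
#'   and `centroids` (group x k) when `groups` is given.
#' @export
nmds <- function(d, k = 2, n_starts = 20, groups = NULL, seed = NULL) {
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 samples")
  fit <- with_seed(seed, {
    vegan::metaMDS(d, k = k, trymax = n_starts, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  })
  pts <- fit$points
  colnames(pts) <- paste0("NMDS", seq_len(k))
  centroids <- NULL
  if (!is.null(groups)) {
    if (length(groups) != n) stop("one group label per sample required")
    centroids <- apply(pts, 2, function(col) tapply(col, groups, mean))
    if (is.null(dim(centroids)))
      centroids <- matrix(centroids, nrow = 1,
                          dimnames = list(unique(groups), colnames(pts)))
  }
  structure(list(points = pts, stress = fit$stress,
                 converged = isTRUE(fit$converged) || fit$stress < 1e-6,
                 centroids = centroids, engine = fit),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples in %d dimensions\n",
              nrow(x$points), ncol(x$points)))
  cat(sprintf("  stress = %.4f (%s)\n", x$stress,
              if (x$converged) "converged" else "no convergent solution"))
  invisible(x)
}

#' @export
plot.nmds_ordination <- function(x, groups = NULL, ...) {
  plot(x$points[, 1], x$points[, 2],
       col = if (is.null(groups)) 1 else as.integer(factor(groups)),
       xlab = "NMDS1", ylab = "NMDS2", pch = 16, ...)
  if (!is.null(x$centroids))
    graphics::points(x$centroids[, 1], x$centroids[, 2], pch = 15,
                     cex = 1.6,
                     col = seq_len(nrow(x$centroids)))
  invisible(x)
}

#' Per-sample distance to the all-children centroid over time
#'
#' Ordinates all child samples by NMDS of Bray-Curtis dissimilarities and
#' returns each sample's distance to the centroid, either along the first
#' ordination dimension only (`mode = "dim1"`, the default: the dominant
#' axis of community variation) or in the full k-dimensional space.  A
#' declining distance with age indicates convergence of children toward a
#' shared community profile; pair with [lme_trend()] for inference.
#'
#' @param x count table matrix.
#' @param meta sample metadata; child samples of `x` are used.
#' @param mode `"dim1"` or `"full"`.
#' @param k,n_starts,seed passed to [nmds()].
#' @return data frame with columns `sample_id`, `subject_id`,
#'   `age_months`, `distance`, plus attribute `ordination`.
#' @export
distance_to_centroid_profile <- function(x, meta, mode = c("dim1", "full"),
                                         k = 2, n_starts = 20, seed = NULL) {
  mode <- match.arg(mode)
  meta <- validate_sample_metadata(meta, x)
  child <- meta[meta$role == "child" & meta$sample_id %in% colnames(x), ]
  if (nrow(child) < k + 2) stop("too few child samples for NMDS")
  xs <- x[, child$sample_id, drop = FALSE]
  ord <- nmds(bray_curtis_dist(xs), k = k, n_starts = n_starts, seed = seed)
  pts <- ord$points
  centroid <- colMeans(pts)
  distance <- if (mode == "dim1") {
    abs(pts[, 1] - centroid[1])
  } else {
    sqrt(rowSums(sweep(pts, 2, centroid)^2))
  }
  out <- data.frame(sample_id = child$sample_id,
                    subject_id = child$subject_id,
                    age_months = child$age_months,
                    distance = unname(distance),
                    stringsAsFactors = FALSE)
  attr(out, "ordination") <- ord
  out
}
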
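#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`: 0 for identical vectors, 1 for disjoint
#' supports.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  s <- sum(x) + sum(y)
  if (s == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / s
}

#' Bray-Curtis distance matrix for a count table
#'
#' Computed on per-sample relative abundances by default, so unequal
#' library sizes do not masquerade as compositional differences.  Delegates
#' to [vegan::vegdist()].
#'
#' @param x count table matrix (species x samples).
#' @param relative convert columns to proportions first.
#' @return a `dist` object over samples.
#' @export
bray_curtis_dist <- function(x, relative = TRUE) {
  m <- if (relative) relative_abundance(x) else x
  vegan::vegdist(t(m), method = "bray")
}

#' Shannon diversity (natural log)
#'
#' @param counts non-negative abundance vector with positive total.
#' @return `-sum(p * log(p))` over nonzero proportions.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("total count must be positive")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Species richness (number of nonzero entries)
#'
#' @param counts abundance vector.
#' @return integer count of taxa present.
#' @export
richness <- function(counts) sum(counts > 0)
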
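# Independent brute-force oracles used to check the resampling machinery.
# These enumerate outcome spaces directly and never call the package's
# rarefaction code paths.

# All multivariate-hypergeometric outcomes of drawing `depth` from `counts`,
# with exact probabilities.
enum_hyper <- function(counts, depth) {
  grids <- lapply(counts, function(ci) 0:ci)
  G <- as.matrix(expand.grid(grids))
  G <- G[rowSums(G) == depth, , drop = FALSE]
  p <- apply(G, 1, function(k) prod(choose(counts, k))) /
    choose(sum(counts), depth)
  list(outcomes = G, probs = p)
}

# P(a species' count is zero after rarefying a vector holding k copies of it
# among total reads down to d): hypergeometric zero class.
p_zero_after_rarefy <- function(k, total, d) {
  if (k == 0) return(1)
  if (total - k < d) return(0)
  choose(total - k, d) / choose(total, d)
}

# Exact double-rarefaction inclusion probability of `species` in `group`,
# by full enumeration of joint stage-1 outcomes.  `tab` is species x
# samples; `grouping` maps samples to (subject, group).  Stage-1 depth is
# the minimum library size; stage-2 depth is the per-outcome minimum
# combined unit total (here constant = d1 * min unit size).
exact_double_inclusion <- function(tab, grouping, species, group) {
  d1 <- min(colSums(tab))
  idx <- match(colnames(tab), grouping$sample_id)
  unit <- paste(grouping$subject_id[idx], grouping$group[idx], sep = ".")
  per_sample <- lapply(seq_len(ncol(tab)),
                       function(j) enum_hyper(tab[, j], d1))
  # cartesian product over samples
  combos <- expand.grid(lapply(per_sample,
                               function(e) seq_along(e$probs)))
  total_p <- 0
  for (r in seq_len(nrow(combos))) {
    p_joint <- 1
    combined <- list()
    for (j in seq_len(ncol(tab))) {
      pick <- combos[r, j]
      p_joint <- p_joint * per_sample[[j]]$probs[pick]
      vec <- per_sample[[j]]$outcomes[pick, ]
      u <- unit[j]
      combined[[u]] <- if (is.null(combined[[u]])) vec else combined[[u]] + vec
    }
    d2 <- min(vapply(combined, sum, 0))
    units_in_group <- names(combined)[endsWith(names(combined),
                                               paste0(".", group))]
    sp_i <- match(species, rownames(tab))
    p_absent_everywhere <- prod(vapply(units_in_group, function(u) {
      p_zero_after_rarefy(combined[[u]][sp_i], sum(combined[[u]]), d2)
    }, 0))
    total_p <- total_p + p_joint * (1 - p_absent_everywhere)
  }
  total_p
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
enum_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(x, y)
  m <- length(pooled)
  center <- n * (m - n) / 2
  sets <- utils::combn(m, n)
  us <- apply(sets, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  mean(abs(us - center) >= abs(obs - center) - 1e-12)
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all sign vectors.
enum_signed_rank_p <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  rk <- rank(abs(diffs))
  obs <- sum(rk[diffs > 0])
  center <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% rk
  mean(abs(ws - center) >= abs(obs - center) - 1e-12)
}

# small deterministic toy table used across tests: species rows (1,2) and
# (3,4), so library sizes are (4, 6)
toy_table <- function() {
  matrix(c(1L, 2L, 3L, 4L), nrow = 2, byrow = TRUE,
         dimnames = list(c("spA", "spB"), c("s1", "s2")))
}
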
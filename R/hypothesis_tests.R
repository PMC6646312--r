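#' Permutational multivariate analysis of variance (one factor)
#'
#' Anderson's pseudo-F computed directly from a distance matrix: total and
#' within-group sums of squared dissimilarities give
#' `F = (SS_between / (k-1)) / (SS_within / (n-k))`, and significance comes
#' from permuting group labels.  With `exact = TRUE` (or `"auto"` with few
#' samples) every distinct label assignment is enumerated and the p-value
#' is the exact permutation probability; otherwise `n_permutations` random
#' permutations are drawn and the `+1`-corrected estimator
#' `p = (1 + #{F* >= F}) / (1 + n_permutations)` is used.
#'
#' @param d a `dist` object.
#' @param labels group label per sample; every group needs >= 2 members.
#' @param n_permutations random permutations when not enumerating.
#' @param exact `TRUE`, `FALSE`, or `"auto"` (enumerate when there are at
#'   most 5000 distinct assignments).
#' @param seed optional integer seed.
#' @return object of class `permanova_result`: list with `pseudo_F`,
#'   `p_value`, `n_permutations`, `exact`, `ss` (between/within/total).
#' @export
permanova <- function(d, labels, n_permutations = 9999, exact = "auto",
                      seed = NULL) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per sample required")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least 2 members")
  k <- length(sizes)
  pseudo_f <- function(lab) {
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
    }
    sst <- sum(D2) / (2 * n)
    ssa <- sst - ssw
    c(F = (ssa / (k - 1)) / (ssw / (n - k)), ssa = ssa, ssw = ssw,
      sst = sst)
  }
  obs <- pseudo_f(labels)
  n_distinct <- factorial(n) / prod(factorial(sizes))
  do_exact <- isTRUE(exact) ||
    (identical(exact, "auto") && n_distinct <= 5000)
  if (do_exact) {
    perms <- multiset_permutations(labels)
    f_perm <- vapply(perms, function(p) pseudo_f(p)[["F"]], 0)
    p <- mean(f_perm >= obs[["F"]] - 1e-12)
    n_used <- length(perms)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(i) pseudo_f(sample(labels))[["F"]], 0)
    })
    p <- (1 + sum(f_perm >= obs[["F"]] - 1e-12)) / (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(pseudo_F = unname(obs[["F"]]), p_value = p,
                 n_permutations = n_used, exact = do_exact,
                 ss = c(between = unname(obs[["ssa"]]),
                        within = unname(obs[["ssw"]]),
                        total = unname(obs[["sst"]]))),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%s, %d permutations)\n",
              x$pseudo_F, x$p_value,
              if (x$exact) "exact enumeration" else "random permutations",
              x$n_permutations))
  invisible(x)
}

# all distinct orderings of a multiset of labels
multiset_permutations <- function(x, limit = 100000) {
  ux <- unique(x)
  counts <- as.integer(table(factor(x, ux)))
  total <- factorial(length(x)) / prod(factorial(counts))
  if (total > limit) stop("too many distinct assignments to enumerate")
  rec <- function(counts) {
    if (sum(counts) == 0) return(list(character(0)))
    out <- list()
    for (i in seq_along(ux)) {
      if (counts[i] > 0) {
        counts[i] <- counts[i] - 1L
        for (tail in rec(counts))
          out[[length(out) + 1L]] <- c(ux[i], tail)
        counts[i] <- counts[i] + 1L
      }
    }
    out
  }
  rec(counts)
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square p on k-1 degrees of freedom).  When all values
#' are identical the statistic is 0 and p is 1.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `H` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(!lengths(groups))) stop("empty group")
  values <- unlist(groups)
  if (length(unique(values)) == 1) return(list(H = 0, p_value = 1))
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p by enumeration for small tie-free samples (combined n <= 12),
#' normal approximation with tie correction otherwise; delegates to
#' [stats::wilcox.test()].
#'
#' @param x,y numeric vectors.
#' @param exact_when_small use the exact distribution when admissible.
#' @return list with `U` and `p_value`.
#' @export
mann_whitney <- function(x, y, exact_when_small = TRUE) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- exact_when_small && !ties && (length(x) + length(y) <= 12)
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact,
                                     correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Differences `post - pre` are ranked after dropping exact zeros; the p
#' value is exact (sign enumeration) for n <= 15 without rank ties, else a
#' tie-corrected normal approximation.  All-zero differences are degenerate
#' and raise an error.
#'
#' @param pre,post paired numeric vectors.
#' @return list with `W` (sum of positive ranks) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  diffs <- post - pre
  diffs <- diffs[diffs != 0]
  if (!length(diffs)) stop("degenerate pairs: all differences are zero")
  if (length(diffs) < 5)
    warning("fewer than 5 nonzero differences; test has little power")
  ties <- anyDuplicated(abs(diffs)) > 0
  use_exact <- !ties && length(diffs) <= 15
  wt <- suppressWarnings(wilcox.test(post, pre, paired = TRUE,
                                     exact = use_exact, correct = TRUE))
  list(W = unname(wt$statistic), p_value = wt$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, order-preserving with
#' the input; delegates to [stats::p.adjust()].
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @return adjusted p values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Linear mixed-effects age trend
#'
#' Fits `value ~ age + (1 | subject)` — a fixed linear age effect with a
#' random intercept per subject — and returns the fixed slope with its
#' Satterthwaite t-test p value (via \pkg{lmerTest}).  When the random
#' effect variance is estimated as zero (singular fit) the model falls
#' back to ordinary least squares with cluster-robust (CR) standard errors
#' by subject, noted in the `method` field.
#'
#' @param values numeric response per sample.
#' @param age_months age covariate per sample.
#' @param subject_ids subject identifier per sample (>= 3 subjects).
#' @return list with `slope`, `p_value`, `method`.
#' @export
lme_trend <- function(values, age_months, subject_ids) {
  df <- data.frame(value = values, age = age_months,
                   subject = factor(subject_ids))
  df <- df[complete.cases(df), ]
  if (nlevels(droplevels(df$subject)) < 3) stop("need at least 3 subjects")
  if (length(unique(df$age)) < 2) stop("need at least 2 distinct ages")
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(value ~ age + (1 | subject),
                                    data = df)),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit)) {
    co <- summary(fit)$coefficients
    return(list(slope = unname(co["age", "Estimate"]),
                p_value = unname(co["age", "Pr(>|t|)"]),
                method = "lmm_satterthwaite"))
  }
  ols <- lm(value ~ age, data = df)
  vc <- sandwich::vcovCL(ols, cluster = df$subject)
  ct <- lmtest::coeftest(ols, vcov. = vc)
  list(slope = unname(ct["age", "Estimate"]),
       p_value = unname(ct["age", "Pr(>|t|)"]),
       method = "ols_cluster_robust")
}
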
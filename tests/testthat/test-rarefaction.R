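test_that("rarefy handles boundary depths exactly", {
  expect_equal(unname(rarefy(c(5, 3, 2), 10)), c(5, 3, 2))
  expect_equal(unname(rarefy(c(7, 0, 0), 3)), c(3, 0, 0))
  expect_equal(sum(rarefy(c(4, 9, 2), 6, seed = 1)), 6)
  expect_error(rarefy(c(1, 1), 3), "exceeds")
  expect_error(rarefy(c(-1, 2), 1), "non-negative")
})

test_that("rarefy matches multivariate hypergeometric moments and marginals", {
  set.seed(71)
  reps <- replicate(20000, rarefy(c(50, 50), 10)[1])
  # hypergeometric: mean n*K/N = 5, var = n*(K/N)(1-K/N)(N-n)/(N-1)
  v <- 10 * 0.5 * 0.5 * 90 / 99
  expect_lt(abs(mean(reps) - 5), 3 * sqrt(v / 20000))
  expect_lt(abs(var(reps) - v) / v, 0.1)
  # chi-square goodness of fit against dhyper on a 2-cell toy
  counts <- table(factor(reps, 0:10))
  expected <- dhyper(0:10, 50, 50, 10) * 20000
  keep <- expected > 5
  chi <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 1e-4)
})

test_that("rarefy agrees with vegan::rrarefy in distribution", {
  set.seed(5)
  ours <- replicate(4000, rarefy(c(30, 70), 20)[1])
  veg <- suppressWarnings(
    replicate(4000, vegan::rrarefy(matrix(c(30L, 70L), 1), 20)[1]))
  expect_lt(abs(mean(ours) - mean(veg)), 4 * sqrt(2 * var(veg) / 4000))
  expect_gt(ks.test(ours, veg)$p.value, 1e-4)
})

test_that("rarefy_columns applies per-column depths", {
  m <- toy_table()
  r <- rarefy_columns(m, c(2, 3), seed = 1)
  expect_equal(unname(colSums(r)), c(2, 3))
  expect_true(all(r <= m))
  expect_error(rarefy_columns(m, 10), "exceeds library size")
})

make_grouping <- function(samples, subjects, groups) {
  data.frame(sample_id = samples, subject_id = subjects, group = groups,
             stringsAsFactors = FALSE)
}

test_that("inclusion probabilities hit the exact hypergeometric case", {
  # one 10-read sample {A:9, B:1} in group g1; a 5-read sample elsewhere
  # sets the stage-1 depth to 5, so P(B observed) = 1 - C(9,5)/C(10,5) = 0.5
  tab <- matrix(c(9L, 1L, 5L, 0L), 2,
                dimnames = list(c("A", "B"), c("s1", "s2")))
  g <- make_grouping(c("s1", "s2"), c("c1", "c2"), c("g1", "g2"))
  inc <- double_rarefaction_inclusion(tab, g, n_iterations = 1000, seed = 42)
  pB <- inc$empirical_probability[inc$species_id == "B" & inc$group == "g1"]
  expect_lt(abs(pB - 0.5), 3 * sqrt(0.25 / 1000))
  expect_false(inc$included[inc$species_id == "B" & inc$group == "g1"])
  # degenerate rows: absent everywhere -> 0, monoculture -> 1
  expect_equal(inc$empirical_probability[inc$species_id == "B" &
                                           inc$group == "g2"], 0)
  expect_equal(inc$empirical_probability[inc$species_id == "A" &
                                           inc$group == "g2"], 1)
  expect_equal(inc$empirical_probability[inc$species_id == "A" &
                                           inc$group == "g1"], 1)
})

test_that("empirical inclusion matches the enumeration oracle on small toys", {
  # unequal library sizes so both rarefaction stages genuinely subsample
  tab <- matrix(c(3L, 1L, 4L, 2L, 5L, 0L), 2,
                dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  g <- make_grouping(c("s1", "s2", "s3"), c("c1", "c1", "c2"),
                     c("g1", "g1", "g1"))
  p_exact <- exact_double_inclusion(tab, g, "B", "g1")
  expect_lt(p_exact, 1) # the toy must be non-degenerate
  inc <- double_rarefaction_inclusion(tab, g, n_iterations = 2000, seed = 9)
  pB <- inc$empirical_probability[inc$species_id == "B"]
  expect_lt(abs(pB - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 2000))
})

test_that("exact inclusion probability is monotone in species counts", {
  g <- make_grouping(c("s1", "s2"), c("c1", "c2"), c("g1", "g1"))
  base <- matrix(c(5L, 1L, 4L, 2L), 2,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
  p0 <- exact_double_inclusion(base, g, "B", "g1")
  more <- base; more["B", "s1"] <- 3L
  p1 <- exact_double_inclusion(more, g, "B", "g1")
  expect_gte(p1, p0)
  # and the empirical estimate tracks the increase
  inc0 <- double_rarefaction_inclusion(base, g, n_iterations = 1500, seed = 2)
  inc1 <- double_rarefaction_inclusion(more, g, n_iterations = 1500, seed = 2)
  expect_gt(inc1$empirical_probability[inc1$species_id == "B"] + 0.05,
            inc0$empirical_probability[inc0$species_id == "B"])
})

test_that("inclusion runs are deterministic given a seed and reject bad input", {
  tab <- matrix(c(4L, 2L, 3L, 3L), 2,
                dimnames = list(c("A", "B"), c("s1", "s2")))
  g <- make_grouping(c("s1", "s2"), c("c1", "c2"), c("g1", "g1"))
  i1 <- double_rarefaction_inclusion(tab, g, n_iterations = 200, seed = 3)
  i2 <- double_rarefaction_inclusion(tab, g, n_iterations = 200, seed = 3)
  expect_identical(i1$empirical_probability, i2$empirical_probability)
  expect_error(double_rarefaction_inclusion(tab, g, n_iterations = 0),
               "n_iterations")
  expect_error(double_rarefaction_inclusion(tab, g[0, ]), "no samples")
})

test_that("rarefied mean statistics conserve depth and match closed forms", {
  expect_equal(rarefy_mean_statistic(c(10, 20), 7, sum, seed = 1), 7)
  expect_equal(rarefy_mean_statistic(c(1000, 1000), 2000, richness), 2)
  # richness of [999, 1] at depth 500: 1 + P(the singleton is drawn) = 1.5
  m <- rarefy_mean_statistic(c(999, 1), 500, richness, n_reps = 10,
                             seed = 11)
  expect_lt(abs(m - 1.5), 3 * sqrt(0.25 / 10))
})
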
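interval_meta <- function(ages, subjects = "c1") {
  n <- length(ages)
  data.frame(sample_id = paste0("s", seq_len(n)),
             subject_id = rep_len(subjects, n), role = "child",
             age_months = ages, stringsAsFactors = FALSE)
}

test_that("interval pooling sums counts and applies the boundary rule", {
  meta <- interval_meta(c(0, 1, 2, 12))
  m <- matrix(100L, 2, 4,
              dimnames = list(c("a", "b"), meta$sample_id))
  pools <- pool_intervals(m, meta)
  info <- attr(pools, "pools")
  expect_setequal(info$interval, c("[0,3)", "[9,12]"))
  expect_equal(sum(pools[, info$interval == "[0,3)"]), 600)
  expect_equal(sum(pools[, info$interval == "[9,12]"]), 200)
  # subject with no samples in [3,6): that column simply does not exist
  expect_false("[3,6)" %in% info$interval)
})

test_that("pooled presence is a rarefied realization with pool exclusions", {
  m <- matrix(c(1000L, 0L, 400L, 50L), 2,
              dimnames = list(c("mono", "absent"), c("s1", "s2")))
  meta <- interval_meta(c(0, 4), subjects = c("c1", "c2"))
  pools <- pool_intervals(m, meta)
  expect_message(pres <- pooled_presence(pools, depth = 498, seed = 1),
                 "dropping 1 pool")
  expect_true(pres["mono", 1])
  expect_false(pres["absent", 1])
  expect_equal(length(attr(pres, "excluded")), 1)
  expect_error(pooled_presence(pools, depth = 0), "positive")
})

test_that("single-copy presence probability equals depth over total", {
  # pool of 1000 reads holding one copy: P(present at depth 498) = 0.498
  m <- matrix(c(999L, 1L), 2, dimnames = list(c("filler", "single"), "s1"))
  meta <- interval_meta(0)
  pools <- pool_intervals(m, meta)
  freq <- pooled_presence(pools, depth = 498, seed = 8, n_reps = 4000)
  expect_lt(abs(freq["single", 1] - 0.498), 3 * sqrt(0.25 / 4000))
  # raising the depth raises the presence probability (d/N oracle)
  freq2 <- pooled_presence(pools, depth = 900, seed = 8, n_reps = 4000)
  expect_gt(freq2["single", 1], freq["single", 1])
  expect_lt(abs(freq2["single", 1] - 0.9), 3 * sqrt(0.09 / 4000))
})

presence_fixture <- function() {
  # 3 subjects x 4 intervals, hand-built presence patterns
  subjects <- rep(paste0("c", 1:3), each = 4)
  intervals <- rep(c("[0,3)", "[3,6)", "[6,9)", "[9,12]"), 3)
  pools <- paste(subjects, intervals, sep = ".")
  pres <- rbind(
    everywhere = rep(TRUE, 12),
    late = intervals %in% c("[6,9)", "[9,12]"),
    one_subject = subjects == "c1",
    never = rep(FALSE, 12))
  colnames(pres) <- pools
  attr(pres, "pools") <- data.frame(pool = pools, subject_id = subjects,
                                    interval = intervals,
                                    stringsAsFactors = FALSE)
  pres
}

test_that("prevalence matrix filters by overall subject prevalence and sorts", {
  pres <- presence_fixture()
  pm <- prevalence_matrix(pres, min_subject_fraction = 0.5)
  expect_equal(rownames(pm$prevalence)[1], "everywhere")
  expect_false("one_subject" %in% rownames(pm$prevalence)) # 1/3 < 0.5
  expect_false("never" %in% rownames(pm$prevalence))
  expect_equal(unname(pm$prevalence["late", "[6,9)"]), 1)
  expect_equal(unname(pm$prevalence["late", "[0,3)"]), 0)
  expect_equal(unname(pm$denominators), rep(3L, 4))
})

test_that("prevalence values are invariant to row and column permutations", {
  pres <- presence_fixture()
  pm <- prevalence_matrix(pres)
  shuffled <- pres[c(3, 1, 4, 2), sample(ncol(pres))]
  attr(shuffled, "pools") <-
    attr(pres, "pools")[match(colnames(shuffled), colnames(pres)), ]
  pm2 <- prevalence_matrix(shuffled)
  expect_equal(pm2$prevalence[rownames(pm$prevalence), ], pm$prevalence)
})

test_that("fractional prevalence reflects the subjects present", {
  pres <- presence_fixture()[, 1:8] # subjects c1, c2 only
  info <- attr(presence_fixture(), "pools")[1:8, ]
  two_of_three <- rbind(pres, partial = c(rep(TRUE, 4), rep(FALSE, 4)))
  attr(two_of_three, "pools") <- info
  pm <- prevalence_matrix(two_of_three, min_subject_fraction = 0.5)
  expect_equal(unname(pm$prevalence["partial", "[0,3)"]), 0.5)
})

test_that("acquisition calls are first crossings with drop-back flags", {
  prev <- rbind(a = c(1, 1, 1, 1), b = c(0.3, 0.5, 0.8, 0.9),
                c = c(0.5, 0.5, 0.5, 0.5), d = c(0.8, 0.4, 0.9, 0.9))
  colnames(prev) <- c("[0,3)", "[3,6)", "[6,9)", "[9,12]")
  pm <- structure(list(prevalence = prev,
                       overall = c(a = 1, b = 0.9, c = 0.5, d = 0.9),
                       intervals = colnames(prev),
                       denominators = rep(9L, 4)),
                  class = "prevalence_matrix")
  calls <- acquisition_intervals(pm, threshold = 0.75)
  expect_equal(calls$acquisition_interval[calls$species_id == "a"], "[0,3)")
  expect_equal(calls$acquisition_interval[calls$species_id == "b"], "[6,9)")
  expect_true(is.na(calls$acquisition_interval[calls$species_id == "c"]))
  expect_equal(calls$acquisition_interval[calls$species_id == "d"], "[0,3)")
  expect_true(calls$drops_below_after[calls$species_id == "d"])
  expect_false(calls$drops_below_after[calls$species_id == "a"])
})

test_that("planted acquisition order is recovered on a synthetic cohort", {
  co <- simulate_cohort(cohort_config(missingness = 0),
                        default_truth(n_background = 60), seed = 31)
  pools <- pool_intervals(co$counts, co$metadata)
  pres <- pooled_presence(pools, depth = 1000, seed = 31)
  pm <- prevalence_matrix(pres)
  calls <- acquisition_intervals(pm)
  onset_iv <- c("[0,3)", "[3,6)", "[6,9)", "[9,12]")
  waves <- co$truth$waves
  planted <- rep(seq_along(waves), lengths(waves))
  called <- match(calls$acquisition_interval[
    match(unlist(waves), calls$species_id)], onset_iv)
  ok <- !is.na(called) & called >= planted
  expect_gte(mean(ok), 0.9)
  expect_gte(cor(planted, called, method = "spearman",
                 use = "complete.obs"), 0.8)
})
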
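fake_inclusion <- function(calls) {
  # calls: named list species -> character vector of groups included
  groups <- c("infant", "toddler", "mother")
  df <- expand.grid(group = groups, species_id = names(calls),
                    stringsAsFactors = FALSE)
  df$empirical_probability <- mapply(function(g, s)
    if (g %in% calls[[s]]) 1 else 0, df$group, df$species_id)
  df$included <- df$empirical_probability >= 0.95
  structure(df, class = c("inclusion_result", "data.frame"),
            n_iterations = 1000, threshold = 0.95, stage1_depth = 100)
}

test_that("Venn regions partition the included species", {
  inc <- fake_inclusion(list(
    shared = c("infant", "toddler", "mother"),
    adult = "mother",
    kids = c("infant", "toddler"),
    nowhere = character()))
  v <- venn_membership(inc)
  expect_equal(v[["infant+toddler+mother"]], "shared")
  expect_equal(v[["mother"]], "adult")
  expect_equal(v[["infant+toddler"]], "kids")
  expect_equal(sum(lengths(v)), 3) # 'nowhere' belongs to no region
  expect_equal(length(v), 7)
  expect_error(venn_membership(inc[inc$group != "mother", ]), "lack")
})

test_that("shared-core contribution is the summed core fraction per sample", {
  m <- matrix(c(70L, 30L, 50L, 50L), 2,
              dimnames = list(c("core1", "other"), c("s1", "s2")))
  cc <- shared_core_contribution(m, "core1")
  expect_equal(unname(cc$per_sample), c(0.7, 0.5))
  expect_equal(unname(shared_core_contribution(m,
    c("core1", "other"))$per_sample), c(1, 1))
  expect_equal(unname(shared_core_contribution(m, character())$per_sample),
               c(0, 0))
  expect_error(shared_core_contribution(m, "ghost"), "unknown")
  g <- data.frame(sample_id = c("s1", "s2"), group = c("a", "a"))
  cc2 <- shared_core_contribution(m, "core1", g)
  expect_equal(cc2$by_group$median, 0.6)
})

event_meta <- function(ages, event_age, subject = "c1") {
  data.frame(sample_id = paste0(subject, "_m", ages),
             subject_id = subject, role = "child", age_months = ages,
             solid_food_start_months = event_age,
             tooth_eruption_months = NA_real_, stringsAsFactors = FALSE)
}

test_that("event pairs take the nearest samples around the event age", {
  meta <- event_meta(c(5, 6, 8), 6.5)
  pairs <- select_event_pairs(meta, "solid_food")
  expect_equal(pairs$pre_age, 6)
  expect_equal(pairs$post_age, 8)
  # all samples before the event: excluded with a reason
  meta2 <- rbind(meta, event_meta(c(1, 2), 6.5, subject = "c2"))
  pairs2 <- select_event_pairs(meta2, "solid_food")
  expect_equal(nrow(pairs2), 1)
  expect_equal(attr(pairs2, "excluded")$subject_id, "c2")
  # missing event age: excluded
  meta3 <- rbind(meta, {
    x <- event_meta(c(5, 8), NA_real_, subject = "c3"); x
  })
  expect_equal(nrow(select_event_pairs(meta3, "solid_food")), 1)
  expect_error(select_event_pairs(event_meta(1:3, NA_real_), "solid_food"),
               "no subjects")
})

build_event_cohort <- function(n_extra_by_subject) {
  # 5 subjects, one pre and one post sample each; post gains a
  # subject-specific number of new species so richness differences are
  # positive and distinct (exact Wilcoxon branch applies)
  n_subj <- length(n_extra_by_subject)
  base_sp <- paste0("base", 1:12)
  extra_sp <- paste0("extra", 1:max(n_extra_by_subject))
  cols <- list(); meta <- list()
  for (s in seq_len(n_subj)) {
    pre_id <- sprintf("c%d_pre", s); post_id <- sprintf("c%d_post", s)
    pre <- setNames(rep(100L, 12), base_sp)
    extras <- setNames(rep(0L, length(extra_sp)), extra_sp)
    cols[[pre_id]] <- c(pre, extras)
    post_extras <- extras
    if (n_extra_by_subject[s] > 0)
      post_extras[seq_len(n_extra_by_subject[s])] <- 300L
    cols[[post_id]] <- c(pre, post_extras)
    meta[[s]] <- data.frame(
      sample_id = c(pre_id, post_id), subject_id = sprintf("c%d", s),
      role = "child", age_months = c(5, 7),
      solid_food_start_months = 6, tooth_eruption_months = NA_real_,
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- c(base_sp, extra_sp)
  storage.mode(counts) <- "integer"
  list(counts = counts, meta = do.call(rbind, meta))
}

test_that("a planted all-positive richness effect hits the exact minimum p", {
  ec <- build_event_cohort(c(6, 7, 8, 9, 10))
  res <- event_analysis(ec$counts, ec$meta, "solid_food",
                        include_ordination = FALSE, seed = 3)
  rich <- res$metrics[res$metrics$metric == "richness", ]
  expect_equal(rich$p_value, 2 / 32) # n = 5, all differences positive
  expect_gt(rich$mean_post, rich$mean_pre)
})

test_that("identical pre and post tables exercise the degenerate p = 1 path", {
  ec <- build_event_cohort(rep(0, 5))
  res <- event_analysis(ec$counts, ec$meta, "solid_food",
                        include_ordination = FALSE, seed = 3)
  expect_true(all(res$metrics$p_value == 1))
  # species-level tests on identical pairs are degenerate too
  expect_true(all(res$species$p_value == 1))
})

test_that("event ordination labels pre and post groups", {
  ec <- build_event_cohort(c(6, 7, 8, 9, 10))
  res <- suppressWarnings(
    event_analysis(ec$counts, ec$meta, "solid_food",
                   include_ordination = TRUE, seed = 3))
  expect_s3_class(res$ordination, "nmds_ordination")
  expect_setequal(rownames(res$ordination$centroids), c("pre", "post"))
})
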
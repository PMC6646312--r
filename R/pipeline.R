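#' Default analysis configuration
#'
#' Every tunable threshold of the pipeline in one list: the low-count
#' sample filter (100 sequences), double-rarefaction iterations (1000) and
#' inclusion threshold (0.95), pooled-presence depth (498) with the
#' overall-subject prevalence filter (0.5) and acquisition step threshold
#' (0.75), rarefied-diversity replicates (10), and PERMANOVA permutations
#' (9999).
#'
#' @param ... overrides for any named default.
#' @return named list.
#' @export
analysis_config <- function(...) {
  cfg <- list(min_total = 100, iterations = 1000, inclusion = 0.95,
              pool_depth = 498, subject_min = 0.5, step = 0.75,
              shannon_reps = 10, permutations = 9999, nmds_starts = 20)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full cohort analysis pipeline
#'
#' Executes, in order: low-count sample filtering, age-group assignment,
#' double-rarefaction inclusion with Venn membership and shared-core
#' contribution, group ordination with PERMANOVA and rarefied
#' diversity/richness comparisons, convergence-over-time analysis,
#' interval-pooled succession calls, and pre/post event comparisons.
#' Writes tidy CSVs plus a JSON manifest (file list, seed, config, package
#' version) to `out_dir`.
#'
#' @param x count table matrix.
#' @param meta sample metadata.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param config an [analysis_config()].
#' @param seed integer seed governing all randomized stages (distinct
#'   substreams are derived per stage).
#' @param skip character vector of stage names to skip, among
#'   `"events"`, `"convergence"`, `"succession"`, `"stats"`.
#' @return object of class `cohort_results`: list of per-stage results.
#' @export
run_pipeline <- function(x, meta, out_dir = NULL,
                         config = analysis_config(), seed = 1,
                         skip = character()) {
  # fixed offsets give each stage its own reproducible substream
  seeds <- as.list(seed + c(inclusion = 101, stats = 202,
                            convergence = 303, succession = 404,
                            events = 505))
  res <- list(config = config, seed = seed)

  flt <- stage("filter", filter_low_count_samples(x, config$min_total))
  xs <- flt$table
  meta <- validate_sample_metadata(meta, xs)
  res$filtered <- list(removed = flt$removed,
                       n_samples = ncol(xs), n_species = nrow(xs))

  grouping <- stage("age_groups", assign_age_groups(meta))

  res$inclusion <- stage("inclusion", double_rarefaction_inclusion(
    xs, grouping, n_iterations = config$iterations,
    threshold = config$inclusion, seed = seeds$inclusion))
  res$venn <- stage("venn", venn_membership(res$inclusion))
  core_set <- res$venn[["infant+toddler+mother"]]
  res$core_contribution <- stage("core_contribution",
    shared_core_contribution(xs, core_set, grouping))

  if (!"stats" %in% skip) {
    res$stats <- stage("stats", group_stats(xs, meta, grouping, config,
                                            seeds$stats))
  }
  if (!"convergence" %in% skip) {
    res$convergence <- stage("convergence", {
      prof <- distance_to_centroid_profile(
        xs, meta, n_starts = config$nmds_starts, seed = seeds$convergence)
      trend <- lme_trend(prof$distance, prof$age_months, prof$subject_id)
      list(profile = prof, trend = trend)
    })
  }
  if (!"succession" %in% skip) {
    res$succession <- stage("succession", {
      ch <- pool_intervals(xs, meta)
      mo <- pool_mothers(xs, meta)
      pools <- cbind(ch, mo)
      attr(pools, "pools") <- rbind(attr(ch, "pools"), attr(mo, "pools"))
      pres <- pooled_presence(pools, depth = config$pool_depth,
                              seed = seeds$succession)
      pm <- prevalence_matrix(pres, min_subject_fraction = config$subject_min,
                              acquisition_threshold = config$step)
      list(prevalence = pm,
           calls = acquisition_intervals(pm, threshold = config$step))
    })
  }
  if (!"events" %in% skip) {
    res$events <- stage("events", {
      out <- list()
      for (ev in c("solid_food", "tooth_eruption")) {
        out[[ev]] <- tryCatch(
          event_analysis(xs, meta, ev, shannon_reps = config$shannon_reps,
                         seed = seeds$events),
          error = function(e) {
            message("event '", ev, "' skipped: ", conditionMessage(e))
            NULL
          })
      }
      out
    })
  }
  class(res) <- "cohort_results"
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

# Fig 2-style group statistics: combined-per-subject ordination, PERMANOVA
# with pairwise post-hoc tests, rarefied Shannon/richness with
# Kruskal-Wallis and BH-adjusted Mann-Whitney post-hocs.
group_stats <- function(xs, meta, grouping, config, seed) {
  with_seed(seed, group_stats_impl(xs, meta, grouping, config))
}

group_stats_impl <- function(xs, meta, grouping, config) {
  sel <- grouping[grouping$group %in% c("infant", "toddler", "mother"), ]
  sub <- xs[, intersect(colnames(xs), sel$sample_id), drop = FALSE]
  combined <- combine_subject_samples(sub, sel)
  units <- attr(combined, "units")
  d <- bray_curtis_dist(combined)
  ord <- nmds(d, k = 2, n_starts = config$nmds_starts,
              groups = units$group)
  overall <- permanova(d, units$group,
                       n_permutations = config$permutations,
                       exact = FALSE)
  pw <- list()
  for (pair in utils::combn(unique(units$group), 2, simplify = FALSE)) {
    idx <- units$group %in% pair
    pw[[paste(pair, collapse = ":")]] <- permanova(
      as.dist(as.matrix(d)[idx, idx]), units$group[idx],
      n_permutations = config$permutations, exact = FALSE)
  }
  depth <- min(colSums(combined))
  rich <- vapply(seq_len(ncol(combined)), function(j)
    rarefy_mean_statistic(combined[, j], depth, richness,
                          n_reps = config$shannon_reps), 0)
  shan <- vapply(seq_len(ncol(combined)), function(j)
    rarefy_mean_statistic(combined[, j], depth, shannon,
                          n_reps = config$shannon_reps), 0)
  kw <- list(richness = kruskal_wallis(split(rich, units$group)),
             shannon = kruskal_wallis(split(shan, units$group)))
  posthoc <- list()
  for (metric in c("richness", "shannon")) {
    v <- if (metric == "richness") rich else shan
    rows <- lapply(utils::combn(unique(units$group), 2, simplify = FALSE),
                   function(pair) {
      mw <- mann_whitney(v[units$group == pair[1]],
                         v[units$group == pair[2]])
      data.frame(metric = metric,
                 comparison = paste(pair, collapse = ":"),
                 U = mw$U, p_value = mw$p_value,
                 stringsAsFactors = FALSE)
    })
    posthoc[[metric]] <- do.call(rbind, rows)
  }
  posthoc <- do.call(rbind, posthoc)
  posthoc$p_adjusted <- bh_adjust(posthoc$p_value)
  rownames(posthoc) <- NULL
  list(units = units, ordination = ord, permanova = overall,
       pairwise_permanova = pw,
       diversity = data.frame(unit = units$unit, group = units$group,
                              richness = rich, shannon = shan,
                              stringsAsFactors = FALSE),
       kruskal_wallis = kw, posthoc = posthoc,
       rarefaction_depth = depth)
}

#' @export
print.cohort_results <- function(x, ...) {
  cat("Cohort analysis results\n")
  cat(sprintf("  %d samples retained (%d removed by the <%d filter)\n",
              x$filtered$n_samples, length(x$filtered$removed),
              x$config$min_total))
  if (!is.null(x$venn)) print(x$venn)
  if (!is.null(x$stats))
    cat(sprintf("  PERMANOVA (infant/toddler/mother): F = %.2f, p = %.4g\n",
                x$stats$permanova$pseudo_F, x$stats$permanova$p_value))
  if (!is.null(x$convergence))
    cat(sprintf("  convergence: slope %.4f per month, p = %.4g (%s)\n",
                x$convergence$trend$slope, x$convergence$trend$p_value,
                x$convergence$trend$method))
  if (!is.null(x$succession))
    cat(sprintf("  succession: %d species in heatmap, %d with acquisition calls\n",
                nrow(x$succession$prevalence$prevalence),
                sum(!is.na(x$succession$calls$acquisition_interval))))
  invisible(x)
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  put(as.data.frame(res$inclusion), "inclusion.csv")
  venn_df <- data.frame(
    region = rep(names(res$venn), lengths(res$venn)),
    species_id = unlist(res$venn, use.names = FALSE),
    stringsAsFactors = FALSE)
  put(venn_df, "venn.csv")
  put(data.frame(sample_id = names(res$core_contribution$per_sample),
                 core_fraction = unname(res$core_contribution$per_sample)),
      "core_contribution.csv")
  if (!is.null(res$stats)) {
    put(data.frame(res$stats$units,
                   res$stats$ordination$points), "ordination.csv")
    perm_df <- rbind(
      data.frame(comparison = "overall",
                 pseudo_F = res$stats$permanova$pseudo_F,
                 p_value = res$stats$permanova$p_value),
      do.call(rbind, lapply(names(res$stats$pairwise_permanova), function(nm)
        data.frame(comparison = nm,
                   pseudo_F = res$stats$pairwise_permanova[[nm]]$pseudo_F,
                   p_value = res$stats$pairwise_permanova[[nm]]$p_value))))
    put(perm_df, "permanova.csv")
    put(res$stats$diversity, "diversity.csv")
    put(res$stats$posthoc, "diversity_posthoc.csv")
  }
  if (!is.null(res$convergence)) {
    put(res$convergence$profile, "convergence_profile.csv")
    put(data.frame(slope = res$convergence$trend$slope,
                   p_value = res$convergence$trend$p_value,
                   method = res$convergence$trend$method),
        "convergence_trend.csv")
  }
  if (!is.null(res$succession)) {
    pm <- res$succession$prevalence
    put(data.frame(species_id = rownames(pm$prevalence),
                   pm$prevalence, check.names = FALSE),
        "succession_prevalence.csv")
    put(as.data.frame(res$succession$calls), "succession_calls.csv")
  }
  if (!is.null(res$events)) {
    for (ev in names(res$events)) {
      if (is.null(res$events[[ev]])) next
      put(res$events[[ev]]$metrics, paste0("event_", ev, "_metrics.csv"))
      if (!is.null(res$events[[ev]]$species))
        put(res$events[[ev]]$species, paste0("event_", ev, "_species.csv"))
    }
  }
  manifest <- list(
    package = "oralsuccession",
    version = as.character(utils::packageVersion("oralsuccession")),
    seed = res$seed, config = res$config, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
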
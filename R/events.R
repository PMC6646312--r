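#' Select pre/post sample pairs around a recorded life event
#'
#' For each subject with a recorded event age, picks the latest sample
#' strictly before the event and the earliest sample at or after it
#' ("immediately pre/post").  Subjects lacking an event age or a sample on
#' either side are excluded, with the reason recorded.
#'
#' @param meta sample metadata.
#' @param event `"solid_food"` or `"tooth_eruption"`.
#' @return data frame of class `event_pairs` with columns `subject_id`,
#'   `event_age`, `pre_sample`, `pre_age`, `post_sample`, `post_age`;
#'   attribute `excluded` is a data frame of excluded subjects and
#'   reasons.
#' @export
select_event_pairs <- function(meta, event = c("solid_food",
                                               "tooth_eruption")) {
  event <- match.arg(event)
  col <- if (event == "solid_food") "solid_food_start_months"
         else "tooth_eruption_months"
  meta <- validate_sample_metadata(meta)
  child <- meta[meta$role == "child", ]
  pairs <- list(); excluded <- list()
  for (s in unique(child$subject_id)) {
    rows <- child[child$subject_id == s, ]
    ev <- unique(rows[[col]][!is.na(rows[[col]])])
    if (!length(ev)) {
      excluded[[s]] <- "no recorded event age"; next
    }
    ev <- ev[1]
    pre <- rows[rows$age_months < ev, ]
    post <- rows[rows$age_months >= ev, ]
    if (!nrow(pre)) { excluded[[s]] <- "no sample before event"; next }
    if (!nrow(post)) { excluded[[s]] <- "no sample after event"; next }
    pre <- pre[which.max(pre$age_months), ]
    post <- post[which.min(post$age_months), ]
    pairs[[s]] <- data.frame(
      subject_id = s, event_age = ev,
      pre_sample = pre$sample_id, pre_age = pre$age_months,
      post_sample = post$sample_id, post_age = post$age_months,
      stringsAsFactors = FALSE)
  }
  if (!length(pairs)) stop("no subjects with usable pre/post pairs")
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) {
    data.frame(subject_id = names(excluded),
               reason = unlist(excluded), row.names = NULL,
               stringsAsFactors = FALSE)
  } else NULL
  attr(out, "event") <- event
  class(out) <- c("event_pairs", "data.frame")
  out
}

#' Paired pre/post community comparison around a life event
#'
#' For the pre/post pairs of [select_event_pairs()], computes per-subject
#' rarefied richness and Shannon diversity (mean over `shannon_reps`
#' rarefactions to the smallest paired library) and per-species relative
#' abundances, then applies the Wilcoxon signed-rank test per metric and
#' per species (species-level p values BH-adjusted).  Species tested are
#' those with nonzero counts in at least `species_min_fraction` of the
#' paired samples.  Degenerate pairings (all differences zero) yield p = 1
#' rather than an error.  Optionally ordinates the paired samples by NMDS
#' of Bray-Curtis dissimilarities.
#'
#' @param x count table matrix.
#' @param meta sample metadata.
#' @param event `"solid_food"` or `"tooth_eruption"`.
#' @param shannon_reps rarefaction replicates for the diversity metrics.
#' @param species_min_fraction prevalence filter for species-level tests.
#' @param include_ordination compute pre/post NMDS coordinates.
#' @param seed optional integer seed.
#' @return object of class `event_comparison`: list with `pairs`,
#'   `metrics` (data frame: metric, mean_pre, mean_post, W, p),
#'   `species` (data frame with BH-adjusted p), `ordination` (or NULL).
#' @export
event_analysis <- function(x, meta, event = c("solid_food",
                                              "tooth_eruption"),
                           shannon_reps = 10, species_min_fraction = 0.25,
                           include_ordination = TRUE, seed = NULL) {
  event <- match.arg(event)
  meta <- meta[meta$sample_id %in% colnames(x), , drop = FALSE]
  pairs <- select_event_pairs(meta, event)
  if (nrow(pairs) < 5)
    warning("fewer than 5 paired subjects; tests have little power")
  samples <- c(pairs$pre_sample, pairs$post_sample)
  missing <- setdiff(samples, colnames(x))
  if (length(missing))
    stop("paired samples missing from table: ",
         paste(missing, collapse = ", "))
  xs <- x[, samples, drop = FALSE]
  depth <- min(colSums(xs))
  with_seed(seed, {
    rich <- vapply(samples, function(s)
      rarefy_mean_statistic(xs[, s], depth, richness,
                            n_reps = shannon_reps), 0)
    shan <- vapply(samples, function(s)
      rarefy_mean_statistic(xs[, s], depth, shannon,
                            n_reps = shannon_reps), 0)
    n <- nrow(pairs)
    paired_test <- function(v) {
      pre <- v[seq_len(n)]; post <- v[n + seq_len(n)]
      res <- tryCatch(wilcoxon_signed_rank(pre, post),
                      error = function(e) list(W = NA_real_, p_value = 1))
      data.frame(mean_pre = mean(pre), mean_post = mean(post),
                 W = res$W, p_value = res$p_value)
    }
    metrics <- rbind(
      cbind(metric = "richness", paired_test(rich)),
      cbind(metric = "shannon", paired_test(shan)))
    # species-level: relative abundance pre vs post
    p_rel <- relative_abundance(xs)
    tested <- rownames(xs)[rowMeans(xs > 0) >= species_min_fraction]
    species <- NULL
    if (length(tested)) {
      sp_rows <- lapply(tested, function(sp)
        cbind(species_id = sp,
              suppressWarnings(paired_test(p_rel[sp, ]))))
      species <- do.call(rbind, sp_rows)
      species$p_adjusted <- bh_adjust(species$p_value)
    }
    ord <- NULL
    if (include_ordination && length(samples) >= 4) {
      ord <- nmds(bray_curtis_dist(xs), k = 2, n_starts = 10,
                  groups = rep(c("pre", "post"), each = n))
    }
    structure(list(event = event, pairs = pairs, metrics = metrics,
                   species = species, ordination = ord,
                   rarefaction_depth = depth),
              class = "event_comparison")
  })
}

#' @export
print.event_comparison <- function(x, ...) {
  cat(sprintf("Pre/post comparison around %s (%d paired subjects)\n",
              x$event, nrow(x$pairs)))
  for (i in seq_len(nrow(x$metrics)))
    cat(sprintf("  %-9s %.2f -> %.2f  (Wilcoxon signed-rank p = %.4g)\n",
                x$metrics$metric[i], x$metrics$mean_pre[i],
                x$metrics$mean_post[i], x$metrics$p_value[i]))
  if (!is.null(x$species)) {
    sig <- sum(x$species$p_adjusted < 0.05)
    cat(sprintf("  %d of %d species significant after BH adjustment\n",
                sig, nrow(x$species)))
  }
  invisible(x)
}
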
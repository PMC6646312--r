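#' Cohort sampling-design configuration
#'
#' Describes the sampling design of a longitudinal mother-child saliva
#' cohort: number of dyads, scheduled child sampling months, the
#' probability that a scheduled child sample is missing, and the
#' library-size law.  Defaults emulate a 9-dyad cohort sampled monthly over
#' the first year with roughly 59% of scheduled child samples collected,
#' and lognormal library sizes with quartiles near 1070 / 2310 / 4850
#' sequences.
#'
#' @param n_dyads number of mother-child pairs (>= 2).
#' @param months scheduled child sampling ages, in months.
#' @param missingness probability in `[0,1]` that a scheduled child sample
#'   is not collected (uniform across months).
#' @param library_meanlog,library_sdlog lognormal parameters of the
#'   per-sample sequence total; draws are floored at 1.
#' @param theta0 Dirichlet-multinomial concentration at month 0; smaller
#'   values give stronger between-sample overdispersion.
#' @param solid_food_mean,solid_food_sd,tooth_mean,tooth_sd normal law (in
#'   months) for the per-subject event ages; draws are clipped to
#'   `[4, 10]` (solid food) and `[4, 12]` (tooth eruption).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_dyads = 9,
                          months = 0:12,
                          missingness = 0.41,
                          library_meanlog = log(2313),
                          library_sdlog = 1.122,
                          theta0 = 50,
                          solid_food_mean = 6.8, solid_food_sd = 0.9,
                          tooth_mean = 8.7, tooth_sd = 2.2) {
  if (n_dyads < 2) stop("n_dyads must be >= 2")
  if (missingness < 0 || missingness > 1) stop("missingness must be in [0,1]")
  if (library_sdlog < 0) stop("library_sdlog must be >= 0")
  if (theta0 <= 0) stop("theta0 must be positive")
  structure(list(n_dyads = n_dyads, months = sort(months),
                 missingness = missingness,
                 library_meanlog = library_meanlog,
                 library_sdlog = library_sdlog, theta0 = theta0,
                 solid_food_mean = solid_food_mean,
                 solid_food_sd = solid_food_sd,
                 tooth_mean = tooth_mean, tooth_sd = tooth_sd),
            class = "cohort_config")
}

#' Planted community structure for a synthetic cohort
#'
#' Declares which species play which ecological role in the simulated
#' community, together with the quantitative parameters of each role.  The
#' five structured sets (core, acquisition waves, early transients,
#' mother-only anaerobes, solid-food responders) must be disjoint; a pool
#' of rare background taxa absorbs whatever relative-abundance budget the
#' structured sets leave unused at each age, so expected proportions always
#' sum to one while the core stays at `target_core_fraction`.
#'
#' @param core named numeric vector of core-species relative weights;
#'   rescaled to sum to `target_core_fraction`.  Core species are present
#'   from birth in every subject and in mothers.
#' @param waves list of character vectors, one per acquisition wave, in
#'   onset order.
#' @param wave_onsets onset age (months) per wave; a wave species has
#'   weight exactly 0 before its onset and ramps logistically to
#'   `wave_plateau` after it.
#' @param wave_plateau plateau relative weight of each wave species.
#' @param ramp_rate,ramp_midpoint_offset logistic ramp steepness (per
#'   month) and midpoint offset after onset.
#' @param transients character vector of early exogenous (skin or
#'   environmental) species, present at `transient_weight` at birth and
#'   decaying as `exp(-transient_decay * t)`.
#' @param transient_weight,transient_decay see above.
#' @param mother_only character vector of species present only in mothers,
#'   each at `mother_only_weight`.
#' @param mother_only_weight see above.
#' @param solid_food character vector of species that appear in a child
#'   only after that child's solid-food start age, each at
#'   `solid_food_weight`.
#' @param solid_food_weight see above.
#' @param background character vector of rare background taxa over which
#'   the residual weight is spread equally.
#' @param target_core_fraction total relative abundance of the core set,
#'   constant across ages and hosts.
#' @param dispersion_decay ratio of month-0 to month-12 between-sample
#'   dispersion (dispersion taken as `theta^-1/2`); the concentration
#'   parameter grows geometrically as `theta0 * dispersion_decay^(2 t/12)`.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(core,
                            waves = list(),
                            wave_onsets = numeric(),
                            wave_plateau = 0.005,
                            ramp_rate = 4,
                            ramp_midpoint_offset = 0.75,
                            transients = character(),
                            transient_weight = 5e-4,
                            transient_decay = 1.5,
                            mother_only = character(),
                            mother_only_weight = 0.01,
                            solid_food = character(),
                            solid_food_weight = 0.02,
                            background = character(),
                            target_core_fraction = 0.70,
                            dispersion_decay = 3) {
  if (is.null(names(core)) || !is.numeric(core))
    stop("core must be a named numeric vector of weights")
  if (length(waves) != length(wave_onsets))
    stop("one onset per wave required")
  if (length(wave_onsets) > 1 && any(diff(wave_onsets) < 0))
    stop("wave onsets must be non-decreasing")
  if (target_core_fraction <= 0 || target_core_fraction >= 1)
    stop("target_core_fraction must lie in (0,1)")
  if (dispersion_decay < 1) stop("dispersion_decay must be >= 1")
  sets <- list(core = names(core), wave = unlist(waves),
               transient = transients, mother_only = mother_only,
               solid_food = solid_food, background = background)
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids))
    stop("species sets must be disjoint; duplicated: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  if (length(background) < 1) stop("at least one background species required")
  # worst-case structured non-core weight must leave the background room
  worst <- length(unlist(waves)) * wave_plateau +
    length(transients) * transient_weight +
    length(solid_food) * solid_food_weight
  if (target_core_fraction + worst >= 0.99)
    stop("infeasible proportions: structured weights leave no room ",
         "for background taxa")
  structure(list(core = core / sum(core) * target_core_fraction,
                 waves = waves, wave_onsets = wave_onsets,
                 wave_plateau = wave_plateau, ramp_rate = ramp_rate,
                 ramp_midpoint_offset = ramp_midpoint_offset,
                 transients = transients,
                 transient_weight = transient_weight,
                 transient_decay = transient_decay,
                 mother_only = mother_only,
                 mother_only_weight = mother_only_weight,
                 solid_food = solid_food,
                 solid_food_weight = solid_food_weight,
                 background = background,
                 target_core_fraction = target_core_fraction,
                 dispersion_decay = dispersion_decay),
            class = "synthetic_truth")
}

#' Default planted truth
#'
#' The stock community structure: 13 core species holding 70% of relative
#' abundance at all ages, acquisition waves of 6/1/7/4 species with onsets
#' at months 0/3/6/9, four decaying skin/environmental transients, four
#' mother-only anaerobes, eight solid-food responders, and a 600-taxon rare
#' background.  Individual roles can be switched off for mechanism-isolation
#' experiments (e.g. a stationary community for convergence calibration).
#'
#' @param include_waves,include_transients,include_events include the
#'   corresponding planted structure.
#' @param n_background number of rare background taxa.
#' @param dispersion_decay passed to [synthetic_truth()].
#' @return object of class `synthetic_truth`.
#' @export
default_truth <- function(include_waves = TRUE,
                          include_transients = TRUE,
                          include_events = TRUE,
                          n_background = 600,
                          dispersion_decay = 3) {
  core <- c(Streptococcus_mitis_group = 0.18,
            Streptococcus_salivarius = 0.09,
            Streptococcus_parasanguinis = 0.08,
            Streptococcus_australis = 0.06,
            Gemella_haemolysans = 0.06,
            Gemella_sanguinis = 0.05,
            Granulicatella_adiacens = 0.05,
            Rothia_mucilaginosa = 0.04,
            Veillonella_parvula = 0.03,
            Veillonella_atypica = 0.02,
            Haemophilus_parainfluenzae = 0.02,
            Actinomyces_odontolyticus = 0.01,
            Prevotella_melaninogenica = 0.01)
  waves <- list(
    c("Streptococcus_peroris", "Neisseria_mucosa", "Granulicatella_elegans",
      "Veillonella_dispar", "Actinomyces_graevenitzii",
      "Haemophilus_haemolyticus"),
    "Porphyromonas_sp_HF001",
    c("Alloprevotella_sp_HOT_473", "Leptotrichia_sp_Arg_j44",
      "Fusobacterium_periodonticum", "Capnocytophaga_granulosa",
      "Campylobacter_concisus", "Lachnoanaerobaculum_saburreum",
      "Streptococcus_cristatus"),
    c("Prevotella_nanceiensis", "Porphyromonas_catoniae",
      "Neisseria_flavescens", "Bergeyella_sp_HOT_322"))
  synthetic_truth(
    core = core,
    waves = if (include_waves) waves else list(),
    wave_onsets = if (include_waves) c(0, 3, 6, 9) else numeric(),
    transients = if (include_transients)
      c("Staphylococcus_epidermidis", "Cutibacterium_acnes",
        "Corynebacterium_tuberculostearicum", "Enterobacter_sp")
      else character(),
    mother_only = c("Porphyromonas_gingivalis", "Tannerella_forsythia",
                    "Treponema_denticola", "Filifactor_alocis"),
    solid_food = if (include_events)
      c("Prevotella_histicola", "Veillonella_rogosae",
        "Streptococcus_mutans", "Rothia_dentocariosa",
        "Actinomyces_naeslundii", "Gemella_morbillorum",
        "Leptotrichia_wadei", "Oribacterium_sinus")
      else character(),
    background = sprintf("rare_taxon_%03d", seq_len(n_background)),
    dispersion_decay = dispersion_decay)
}

truth_species <- function(truth) {
  c(names(truth$core), unlist(truth$waves), truth$transients,
    truth$mother_only, truth$solid_food, truth$background)
}

# Expected relative-abundance profile of a child sample at age t months
# (solid_food_age is that child's event age), or of a mother sample
# (t = NULL).  Returns a named vector summing to 1.
expected_profile <- function(truth, t = NULL, solid_food_age = NULL) {
  ids <- truth_species(truth)
  w <- setNames(numeric(length(ids)), ids)
  w[names(truth$core)] <- truth$core
  if (is.null(t)) { # mother
    w[unlist(truth$waves)] <- truth$wave_plateau
    w[truth$mother_only] <- truth$mother_only_weight
  } else {
    for (i in seq_along(truth$waves)) {
      onset <- truth$wave_onsets[i]
      if (t >= onset) {
        ramp <- stats::plogis(truth$ramp_rate *
                                (t - onset - truth$ramp_midpoint_offset))
        w[truth$waves[[i]]] <- truth$wave_plateau * ramp
      }
    }
    w[truth$transients] <-
      truth$transient_weight * exp(-truth$transient_decay * t)
    if (length(truth$solid_food) && !is.null(solid_food_age) &&
        !is.na(solid_food_age) && t >= solid_food_age)
      w[truth$solid_food] <- truth$solid_food_weight
  }
  residual <- 1 - sum(w)
  if (residual <= 0)
    stop("infeasible proportions: structured weights exceed 1")
  w[truth$background] <- residual / length(truth$background)
  w
}

#' Draw library sizes from the configured lognormal law
#'
#' @param config a [cohort_config()].
#' @param n number of draws.
#' @param seed optional integer seed (global RNG state is restored).
#' @return integer vector of sequence totals, floored at 1.
#' @export
sample_library_sizes <- function(config, n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    pmax(1L, as.integer(round(rlnorm(n, config$library_meanlog,
                                     config$library_sdlog))))
  })
}

# One Dirichlet-multinomial draw.  Species in `fixed` keep their expected
# proportion exactly (multinomial noise only): used for exogenous transient
# inflow, which is not part of the host community equilibrium and therefore
# does not share its between-sample overdispersion.
rdirmult <- function(n_reads, weights, theta, fixed = integer()) {
  p <- weights
  free <- setdiff(seq_along(weights), fixed)
  alpha <- theta * weights[free]
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  p[free] <- (1 - sum(weights[fixed])) * g / sum(g)
  as.integer(rmultinom(1, size = n_reads, prob = p))
}

#' Simulate a longitudinal mother-child cohort with planted truth
#'
#' Generates a species-by-sample count table and matching metadata for
#' `n_dyads` mother-child pairs.  Children are sampled at the scheduled
#' months (subject to missingness); each mother contributes one baseline
#' sample.  Counts are drawn from a Dirichlet-multinomial whose mean
#' profile encodes the planted structure in `truth` and whose concentration
#' grows with age according to `truth$dispersion_decay`, so between-sample
#' dispersion shrinks over the first year.
#'
#' @param config a [cohort_config()].
#' @param truth a [synthetic_truth()]; defaults to [default_truth()].
#' @param seed optional integer seed; a fixed seed makes the cohort fully
#'   reproducible.
#' @return object of class `synthetic_cohort`: list with elements `counts`
#'   (count table matrix), `metadata` (data frame), `truth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            truth = default_truth(),
                            seed = NULL) {
  with_seed(seed, {
    ids <- truth_species(truth)
    n <- config$n_dyads
    solid <- pmin(10, pmax(4, rnorm(n, config$solid_food_mean,
                                    config$solid_food_sd)))
    tooth <- pmin(12, pmax(4, rnorm(n, config$tooth_mean, config$tooth_sd)))
    rows <- list(); cols <- list(); meta <- list()
    for (d in seq_len(n)) {
      subj <- sprintf("dyad%02d", d)
      kept <- config$months[runif(length(config$months)) >= config$missingness]
      for (m in kept) {
        sid <- sprintf("%s_child_m%02d", subj, m)
        N <- sample_library_sizes(config, 1)
        w <- expected_profile(truth, t = m, solid_food_age = solid[d])
        theta <- config$theta0 * truth$dispersion_decay^(2 * m / 12)
        cols[[sid]] <- rdirmult(N, w, theta,
                                fixed = match(truth$transients, ids))
        meta[[sid]] <- data.frame(
          sample_id = sid, subject_id = subj, role = "child",
          age_months = m, solid_food_start_months = round(solid[d], 2),
          tooth_eruption_months = round(tooth[d], 2),
          stringsAsFactors = FALSE)
      }
      sid <- sprintf("%s_mother", subj)
      N <- sample_library_sizes(config, 1)
      w <- expected_profile(truth, t = NULL)
      theta <- config$theta0 * truth$dispersion_decay^2
      cols[[sid]] <- rdirmult(N, w, theta)
      meta[[sid]] <- data.frame(
        sample_id = sid, subject_id = subj, role = "mother",
        age_months = NA_real_, solid_food_start_months = NA_real_,
        tooth_eruption_months = NA_real_, stringsAsFactors = FALSE)
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- ids
    colnames(counts) <- names(cols)
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    counts <- validate_count_table(counts)
    structure(list(counts = counts, metadata = metadata, truth = truth,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  nchild <- sum(x$metadata$role == "child")
  cat("Synthetic mother-child cohort\n")
  cat(sprintf("  %d dyads; %d child samples (of %d scheduled), %d mothers\n",
              x$config$n_dyads, nchild,
              x$config$n_dyads * length(x$config$months),
              sum(x$metadata$role == "mother")))
  cat(sprintf("  %d species; library sizes %d-%d (median %d)\n",
              nrow(x$counts), min(library_sizes(x$counts)),
              max(library_sizes(x$counts)),
              as.integer(median(library_sizes(x$counts)))))
  cat(sprintf("  planted: %d core, %d wave, %d transient, %d mother-only, %d solid-food\n",
              length(x$truth$core), length(unlist(x$truth$waves)),
              length(x$truth$transients), length(x$truth$mother_only),
              length(x$truth$solid_food)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `counts.tsv`, `meta.csv` and `truth.json` (the planted structure,
#' with a note that abundance trajectories are modeling choices).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_sample_metadata(cohort$metadata, file.path(dir, "meta.csv"))
  truth <- unclass(cohort$truth)
  truth$core <- as.list(truth$core) # keep species names in the JSON
  truth$note <- paste("Ramp shapes and decay rates are modeling choices;",
                      "set membership and onset order are the planted truth.")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
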
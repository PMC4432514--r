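#' Configuration for the synthetic peak-list generator
#'
#' Collects every generative parameter of the simulator in one object.
#' Defaults mirror the study design the pipeline is built for: species
#' with ~40 biomarker masses between 3 and 20 kDa, 5 specimens per
#' species with 4 technical replicates (quadruplicates), mild
#' within-species mass jitter relative to the 800 ppm matching
#' tolerance, occasional peak dropout, a handful of non-biomarker noise
#' peaks per spectrum, and an exponential storage-degradation model that
#' removes high-mass peaks above a 10 kDa onset.
#'
#' @param n_species Number of species profiles.
#' @param biomarkers_per_species Biomarkers per species (default 40).
#' @param mass_low,mass_high Biomarker mass window in Da (default
#'   3000--20000).
#' @param jitter_ppm SD of the relative mass jitter per detected peak
#'   (default 200 ppm).
#' @param detect_prob Baseline per-replicate detection probability of a
#'   biomarker (default 0.95).
#' @param noise_peaks_mean Poisson mean of uniform noise peaks per
#'   replicate (default 5).
#' @param degradation_rate Exponential decay rate per kDa above the
#'   onset (default 0.4; at storage severity 1 a 15 kDa peak keeps
#'   `exp(-0.4 * 5) = 14%` of its detectability).
#' @param degradation_onset Mass (Da) above which storage degradation
#'   acts (default 10000).
#' @param calibration_offset_ppm Systematic instrument calibration
#'   offset applied to every detected mass (default 0).
#' @param n_specimens_per_species Specimens per species in a default
#'   design (default 5).
#' @param n_replicates Technical replicates per specimen (default 4).
#' @param tolerance_ppm Matching tolerance the profiles must respect:
#'   generated biomarkers are separated by more than twice this
#'   tolerance (default 800).
#' @param congener_pairs Optional data.frame
#'   `(species_a, species_b, share)` forcing `share` of `species_b`'s
#'   biomarkers to coincide with `species_a`'s (congeneric species with
#'   overlapping fingerprints).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 8L, biomarkers_per_species = 40L,
                             mass_low = 3000, mass_high = 20000,
                             jitter_ppm = 200, detect_prob = 0.95,
                             noise_peaks_mean = 5, degradation_rate = 0.4,
                             degradation_onset = 10000,
                             calibration_offset_ppm = 0,
                             n_specimens_per_species = 5L,
                             n_replicates = 4L, tolerance_ppm = 800,
                             congener_pairs = NULL, seed = 1L) {
  stopifnot(n_species >= 1, biomarkers_per_species >= 1,
            0 < mass_low, mass_low < mass_high,
            jitter_ppm >= 0, detect_prob >= 0, detect_prob <= 1,
            noise_peaks_mean >= 0, degradation_rate >= 0,
            n_replicates >= 1, tolerance_ppm > 0)
  if (!is.null(congener_pairs)) {
    stopifnot(is.data.frame(congener_pairs),
              all(c("species_a", "species_b", "share") %in%
                    names(congener_pairs)),
              all(congener_pairs$share >= 0 & congener_pairs$share <= 1))
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# Draw species profiles from the current RNG stream (no reseeding).
draw_profiles <- function(cfg) {
  needed <- cfg$n_species * cfg$biomarkers_per_species
  # minimum relative gap between biomarkers: resolvable under jitter.
  # Two jittered peak clouds (width ~3 sd each side) must stay more than
  # the matching tolerance apart, or single-linkage binning would chain
  # them into one bin; 2 * (tolerance + 3 * jitter) guarantees that and
  # implies the bare > 2 * tolerance separation invariant.
  gap <- 2 * (cfg$tolerance_ppm + 3 * cfg$jitter_ppm) * 1e-6
  capacity <- floor(log(cfg$mass_high / cfg$mass_low) / log1p(gap))
  if (needed > 0.8 * capacity) {
    stop(sprintf(
      "infeasible packing: %d biomarkers requested but only ~%d masses fit in [%g, %g] Da at 2 x %g ppm separation",
      needed, capacity, cfg$mass_low, cfg$mass_high, cfg$tolerance_ppm))
  }
  pool <- numeric(0)
  for (attempt in 1:50) {
    cand <- sort(stats::runif(4 * needed, cfg$mass_low, cfg$mass_high))
    keep <- numeric(0); last <- -Inf
    for (m in cand) {
      if (m - last > gap * (m + last) / 2) { keep <- c(keep, m); last <- m }
    }
    pool <- keep
    if (length(pool) >= needed) break
  }
  if (length(pool) < needed) stop("infeasible packing: could not place biomarkers")
  pool <- sort(sample(pool, needed))
  assign_to <- sample(rep(seq_len(cfg$n_species), cfg$biomarkers_per_species))
  species_names <- sprintf("species_%02d", seq_len(cfg$n_species))
  profiles <- lapply(seq_len(cfg$n_species), function(i) {
    structure(list(species = species_names[i],
                   true_biomarkers = sort(pool[assign_to == i]),
                   shared_with = list()),
              class = "species_profile")
  })
  names(profiles) <- species_names
  if (!is.null(cfg$congener_pairs)) {
    for (k in seq_len(nrow(cfg$congener_pairs))) {
      pa <- cfg$congener_pairs$species_a[k]
      pb <- cfg$congener_pairs$species_b[k]
      share <- cfg$congener_pairs$share[k]
      if (!pa %in% names(profiles) || !pb %in% names(profiles)) {
        stop(sprintf("unknown congener species '%s'/'%s'", pa, pb))
      }
      n_share <- round(share * cfg$biomarkers_per_species)
      if (n_share > 0) {
        donor <- sort(sample(profiles[[pa]]$true_biomarkers, n_share))
        keep <- sort(sample(profiles[[pb]]$true_biomarkers,
                            cfg$biomarkers_per_species - n_share))
        profiles[[pb]]$true_biomarkers <- sort(c(donor, keep))
        profiles[[pb]]$shared_with[[pa]] <- donor
        profiles[[pa]]$shared_with[[pb]] <- donor
      }
    }
  }
  profiles
}

#' Simulate species biomarker profiles
#'
#' Draws `n_species` disjoint biomarker mass sets inside the configured
#' window, every pair of masses (within and across species) separated by
#' more than twice the matching tolerance so that distinct biomarkers
#' can never collide under jitter at the default settings. Optional
#' congener pairs share an exact subset of biomarkers. Seeds the RNG
#' from `cfg$seed`, so the same configuration always yields the same
#' profiles.
#'
#' @param cfg A [synthetic_config()].
#' @return A named list of `species_profile` objects (`species`,
#'   `true_biomarkers`, `shared_with`).
#' @export
simulate_species_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  draw_profiles(cfg)
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s: %d biomarkers in [%.0f, %.0f] Da\n",
              x$species, length(x$true_biomarkers),
              min(x$true_biomarkers), max(x$true_biomarkers)))
  invisible(x)
}

#' Simulate one specimen's replicate peak lists
#'
#' For each replicate, each biomarker of the species profile is detected
#' with probability
#' `detect_prob * exp(-storage_severity * degradation_rate * max(0, m - onset) / 1000)`,
#' so storage damage removes high-mass peaks first while sub-onset
#' biomarkers stay detectable — fresh specimens (`storage_severity = 0`)
#' keep the full profile. A detected mass is reported as
#' `m * (1 + jitter + offset)` with Gaussian relative jitter and the
#' instrument's calibration offset; Poisson-many uniform noise peaks are
#' added and the list is clipped to the instrument's mass range.
#' Replicates are independent draws from the current RNG stream (seed at
#' the cohort level for reproducibility).
#'
#' @param profile A `species_profile`.
#' @param cfg A [synthetic_config()].
#' @param storage_severity Nonnegative degradation severity (0 = fresh).
#' @param instrument An [instrument_profile()].
#' @param specimen_id Identifier for the specimen.
#' @param storage Storage label recorded in the metadata.
#' @param origin Origin label recorded in the metadata.
#' @return A [specimen_record()] with `cfg$n_replicates` replicates.
#' @export
simulate_specimen <- function(profile, cfg, storage_severity = 0,
                              instrument = instrument_profiles()$shimadzu,
                              specimen_id = paste0(profile$species, "_s1"),
                              storage = "fresh", origin = "colony") {
  stopifnot(inherits(profile, "species_profile"),
            inherits(cfg, "synthetic_config"), storage_severity >= 0)
  m <- profile$true_biomarkers
  p_detect <- cfg$detect_prob *
    exp(-storage_severity * cfg$degradation_rate *
          pmax(0, m - cfg$degradation_onset) / 1000)
  reps <- lapply(seq_len(cfg$n_replicates), function(r) {
    detected <- stats::runif(length(m)) < p_detect
    obs <- m[detected] *
      (1 + stats::rnorm(sum(detected), 0, cfg$jitter_ppm * 1e-6) +
         cfg$calibration_offset_ppm * 1e-6)
    n_noise <- stats::rpois(1, cfg$noise_peaks_mean)
    noise <- stats::runif(n_noise, instrument$mass_min, instrument$mass_max)
    pl <- peak_list(specimen_id, r, c(obs, noise), instrument = instrument)
    clip_to_range(pl, instrument)
  })
  specimen_record(specimen_id, profile$species, origin = origin,
                  storage = storage, collection_year = 2014L,
                  replicates = reps)
}

#' Simulate a cohort of specimens with known ground truth
#'
#' Seeds the RNG once from `cfg$seed`, draws the species profiles, then
#' generates specimens row by row from a design table; the result is
#' fully reproducible and suitable to drive the whole
#' build-identify-validate pipeline with a known answer key.
#'
#' @param cfg A [synthetic_config()].
#' @param design A data.frame with columns `species` (profile name),
#'   `n_specimens`, and optionally `storage_severity` (default 0),
#'   `storage` label, and `instrument` (`"bruker"`, `"shimadzu"`, or an
#'   entry of `instruments`). Defaults to
#'   `n_specimens_per_species` fresh specimens of every species.
#' @param profiles Optional pre-drawn profiles (to share one reference
#'   truth across cohorts); when supplied the RNG is still seeded from
#'   `cfg$seed` for the specimen draws.
#' @param instruments Named list of [instrument_profile()] objects used
#'   to resolve `design$instrument`; defaults to
#'   [instrument_profiles()].
#' @param id_prefix Prefix for specimen ids (default `"syn"`), so that
#'   cohorts drawn for different purposes get distinct ids.
#' @return A list with `specimens` (list of [specimen_record()]),
#'   `truth` (data.frame: specimen_id, species, storage_severity,
#'   storage, instrument) and `profiles`.
#' @export
simulate_cohort <- function(cfg, design = NULL, profiles = NULL,
                            instruments = instrument_profiles(),
                            id_prefix = "syn") {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  if (is.null(profiles)) profiles <- draw_profiles(cfg)
  if (is.null(design)) {
    design <- data.frame(species = names(profiles),
                         n_specimens = cfg$n_specimens_per_species,
                         stringsAsFactors = FALSE)
  }
  if (!nrow(design)) {
    return(list(specimens = list(),
                truth = data.frame(specimen_id = character(0),
                                   species = character(0),
                                   storage_severity = numeric(0),
                                   storage = character(0),
                                   instrument = character(0),
                                   stringsAsFactors = FALSE),
                profiles = profiles))
  }
  if (!"storage_severity" %in% names(design)) design$storage_severity <- 0
  if (!"storage" %in% names(design)) {
    design$storage <- ifelse(design$storage_severity == 0, "fresh", "ethanol")
  }
  if (!"instrument" %in% names(design)) design$instrument <- "shimadzu"
  unknown <- setdiff(design$species, names(profiles))
  if (length(unknown)) {
    stop(sprintf("unknown species in design: %s",
                 paste(unknown, collapse = ", ")))
  }
  specimens <- list(); truth <- NULL; counter <- 0L
  for (i in seq_len(nrow(design))) {
    inst <- instruments[[design$instrument[i]]]
    if (is.null(inst)) stop(sprintf("unknown instrument '%s'",
                                    design$instrument[i]))
    for (s in seq_len(design$n_specimens[i])) {
      counter <- counter + 1L
      sid <- sprintf("%s_%04d", id_prefix, counter)
      rec <- simulate_specimen(profiles[[design$species[i]]], cfg,
                               storage_severity = design$storage_severity[i],
                               instrument = inst, specimen_id = sid,
                               storage = design$storage[i])
      specimens[[sid]] <- rec
      truth <- rbind(truth, data.frame(
        specimen_id = sid, species = design$species[i],
        storage_severity = design$storage_severity[i],
        storage = design$storage[i], instrument = inst$name,
        stringsAsFactors = FALSE))
    }
  }
  list(specimens = specimens, truth = truth, profiles = profiles)
}
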
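#' Fit a superspectrum reference database
#'
#' The central fitting function of the package: groups specimens by
#' their species label and builds one consensus superspectrum per
#' species ([build_superspectrum()]). The returned object behaves like a
#' fitted model — `print`, `summary`, `coef` (the biomarker mass sets),
#' `predict` (identification of new peak lists or specimens), `plot`
#' (UPGMA dendrogram of the reference entries) and `simulate`
#' (synthetic replicates drawn from the reference) are available.
#'
#' Specimens containing any low-quality replicate (data count below
#' `min_count`) are excluded before building and listed in the report; a
#' species left with fewer than `min_specimens` qualifying specimens is
#' dropped and reported. Fitting fails only when no species qualifies.
#'
#' @param specimens List of [specimen_record()] objects with species
#'   labels.
#' @param tolerance_ppm Relative mass tolerance in ppm (default 800).
#' @param consensus_fraction Minimum support fraction for a biomarker
#'   (default 0.75, inclusive).
#' @param mass_window Biomarker window in Da (default `c(4000, 20000)`).
#' @param min_count Spectrum quality gate (default 30).
#' @param min_specimens Minimum qualifying specimens per species
#'   (default 1).
#' @return An object of class `superspectra_db`: `superspectra` (named
#'   list of [super_spectrum()]), `params`, and `report` (excluded
#'   specimens/species and reasons).
#' @examples
#' cfg <- synthetic_config(n_species = 2, seed = 42)
#' cohort <- simulate_cohort(cfg)
#' db <- build_reference(cohort$specimens)
#' db
#' @export
build_reference <- function(specimens, tolerance_ppm = 800,
                            consensus_fraction = 0.75,
                            mass_window = c(4000, 20000),
                            min_count = 30L, min_specimens = 1L) {
  stopifnot(length(specimens) >= 1)
  labels <- vapply(specimens, `[[`, character(1), "species_label")
  excluded <- character(0); dropped_species <- character(0)
  qualifies <- vapply(specimens, function(sp) {
    all(vapply(sp$replicates, function(p)
      qc_flag(p, min_count)$flag == "high", logical(1)))
  }, logical(1))
  excluded <- vapply(specimens[!qualifies], `[[`, character(1),
                     "specimen_id")
  superspectra <- list()
  for (species in sort(unique(labels))) {
    sel <- labels == species & qualifies
    if (sum(sel) < min_specimens) {
      dropped_species <- c(dropped_species, species)
      next
    }
    superspectra[[species]] <- build_superspectrum(
      species, specimens[sel], tolerance_ppm = tolerance_ppm,
      consensus_fraction = consensus_fraction, mass_window = mass_window,
      min_count = min_count)
  }
  if (!length(superspectra)) {
    stop("no species with enough qualifying specimens; nothing to fit")
  }
  structure(list(
    superspectra = superspectra,
    params = list(tolerance_ppm = tolerance_ppm,
                  consensus_fraction = consensus_fraction,
                  mass_window = mass_window, min_count = min_count,
                  min_specimens = min_specimens),
    report = list(excluded_specimens = excluded,
                  dropped_species = dropped_species)
  ), class = "superspectra_db")
}

#' @export
print.superspectra_db <- function(x, ...) {
  cat(sprintf("Superspectrum reference database: %d species (tol %g ppm, consensus >= %g, window [%g, %g] Da)\n",
              length(x$superspectra), x$params$tolerance_ppm,
              x$params$consensus_fraction, x$params$mass_window[1],
              x$params$mass_window[2]))
  for (ss in x$superspectra) {
    cat(sprintf("  %-24s %3d biomarkers  [%s]\n", ss$species,
                length(ss$biomarker_masses),
                if (length(ss$biomarker_masses)) {
                  sprintf("%.0f-%.0f Da", min(ss$biomarker_masses),
                          max(ss$biomarker_masses))
                } else "empty"))
  }
  if (length(x$report$excluded_specimens)) {
    cat(sprintf("  excluded specimens (low-quality replicates): %s\n",
                paste(x$report$excluded_specimens, collapse = ", ")))
  }
  if (length(x$report$dropped_species)) {
    cat(sprintf("  dropped species (too few qualifying specimens): %s\n",
                paste(x$report$dropped_species, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.superspectra_db <- function(object, ...) {
  tab <- data.frame(
    species = vapply(object$superspectra, `[[`, character(1), "species"),
    n_biomarkers = vapply(object$superspectra, function(s)
      length(s$biomarker_masses), integer(1)),
    mass_min = vapply(object$superspectra, function(s)
      if (length(s$biomarker_masses)) min(s$biomarker_masses) else NA_real_,
      numeric(1)),
    mass_max = vapply(object$superspectra, function(s)
      if (length(s$biomarker_masses)) max(s$biomarker_masses) else NA_real_,
      numeric(1)),
    n_specimens = vapply(object$superspectra, `[[`, integer(1),
                         "n_specimens"),
    n_replicates = vapply(object$superspectra, `[[`, integer(1),
                          "n_replicates_per_specimen"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, params = object$params,
                 report = object$report),
            class = "summary.superspectra_db")
}

#' @export
print.summary.superspectra_db <- function(x, ...) {
  cat("Superspectrum reference database\n")
  cat(sprintf("  tolerance %g ppm, consensus fraction %g, mass window [%g, %g] Da, min count %d\n",
              x$params$tolerance_ppm, x$params$consensus_fraction,
              x$params$mass_window[1], x$params$mass_window[2],
              x$params$min_count))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.superspectra_db <- function(object, ...) {
  lapply(object$superspectra, `[[`, "biomarker_masses")
}

#' Identify peak lists or specimens against a fitted reference
#'
#' @param object A `superspectra_db` from [build_reference()].
#' @param newdata A [peak_list()], a [specimen_record()], or a list of
#'   either.
#' @param threshold Identification threshold (default 0.75).
#' @param ... Unused.
#' @return For a single peak list, a replicate-level `id_result`; for a
#'   specimen record, its specimen-level `id_result` (replicate results
#'   in `attr(, "replicates")`); for a list, a list of results.
#' @export
predict.superspectra_db <- function(object, newdata, threshold = 0.75,
                                    ...) {
  p <- object$params
  one <- function(x) {
    if (inherits(x, "peak_list")) {
      identify_replicate(x, object, threshold = threshold,
                         min_count = p$min_count,
                         tolerance_ppm = p$tolerance_ppm)
    } else if (inherits(x, "specimen_record")) {
      reps <- lapply(x$replicates, one)
      out <- identify_specimen(reps)
      attr(out, "replicates") <- reps
      out
    } else {
      stop("newdata must be peak_list or specimen_record objects")
    }
  }
  if (inherits(newdata, "peak_list") || inherits(newdata, "specimen_record")) {
    one(newdata)
  } else {
    lapply(newdata, one)
  }
}

#' Dendrogram of the reference entries
#'
#' Clusters the superspectra themselves by Dice distance of their
#' biomarker sets and plots the UPGMA dendrogram.
#'
#' @param x A `superspectra_db`.
#' @param ... Passed to [plot.mass_dendrogram()].
#' @return The dendrogram, invisibly.
#' @export
plot.superspectra_db <- function(x, ...) {
  if (length(x$superspectra) < 2) stop("need >= 2 species to cluster")
  pls <- lapply(x$superspectra, function(ss) {
    peak_list(ss$species, 1, ss$biomarker_masses)
  })
  cl <- cluster_peaklists(pls, tolerance_ppm = x$params$tolerance_ppm,
                          labels = names(x$superspectra))
  plot(cl$dendrogram, ...)
  invisible(cl$dendrogram)
}

#' Simulate replicate peak lists from a fitted reference
#'
#' Draws synthetic technical replicates whose true peaks are the
#' reference biomarkers, using the synthetic generator's jitter/dropout
#' model — useful for power checks of the identification threshold.
#'
#' @param object A `superspectra_db`.
#' @param nsim Replicates per species (default 4).
#' @param seed Integer seed.
#' @param cfg A [synthetic_config()] providing jitter, dropout and noise
#'   settings.
#' @param ... Unused.
#' @return Named list (per species) of lists of [peak_list()] objects.
#' @export
simulate.superspectra_db <- function(object, nsim = 4, seed = 1L,
                                     cfg = synthetic_config(seed = seed),
                                     ...) {
  set.seed(seed)
  cfg$n_replicates <- as.integer(nsim)
  lapply(object$superspectra, function(ss) {
    profile <- structure(list(species = ss$species,
                              true_biomarkers = ss$biomarker_masses,
                              shared_with = list()),
                         class = "species_profile")
    rec <- simulate_specimen(profile, cfg,
                             specimen_id = paste0(ss$species, "_sim"))
    rec$replicates
  })
}
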
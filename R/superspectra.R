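#' Single-linkage mass binning across replicate peak lists
#'
#' Pools the masses of all peak lists, sorts them, and joins consecutive
#' pooled masses into the same bin whenever their gap is at most
#' `tolerance_ppm * 1e-6 * mean(pair)`. This single-linkage agglomeration
#' is deterministic and independent of input list order, and avoids the
#' boundary-splitting artefacts of fixed-width grids. Each bin's `support`
#' counts the number of distinct contributing spectra (not masses), so a
#' spectrum with two masses in one bin supports it once.
#'
#' @param peaklists List of [peak_list()] objects.
#' @param tolerance_ppm Relative tolerance in parts per million, > 0.
#' @return A list of `mass_bin` objects, ascending by representative mass.
#'   Each has `representative_mass` (arithmetic mean of members),
#'   `member_masses`, and `support`.
#' @export
bin_masses <- function(peaklists, tolerance_ppm) {
  stopifnot(tolerance_ppm > 0)
  masses <- unlist(lapply(peaklists, `[[`, "masses"), use.names = FALSE)
  if (is.null(masses) || !length(masses)) return(list())
  spectrum <- rep(seq_along(peaklists),
                  vapply(peaklists, function(p) length(p$masses), integer(1)))
  ord <- order(masses, spectrum)  # stable, order-free
  masses <- masses[ord]; spectrum <- spectrum[ord]
  gaps <- diff(masses)
  midp <- (masses[-1] + masses[-length(masses)]) / 2
  newbin <- c(TRUE, gaps > tolerance_ppm * 1e-6 * midp)
  bin_id <- cumsum(newbin)
  lapply(split(seq_along(masses), bin_id), function(idx) {
    structure(list(representative_mass = mean(masses[idx]),
                   member_masses = masses[idx],
                   support = length(unique(spectrum[idx]))),
              class = "mass_bin")
  })
}

#' Species-level consensus biomarker mass set
#'
#' Low-level constructor for a superspectrum: the consensus set of
#' biomarker masses of one species, with the tolerance used to build it
#' and provenance counts. Usually produced by [build_superspectrum()] or
#' [build_reference()].
#'
#' @param species Species name.
#' @param biomarker_masses Strictly ascending masses (Da) inside
#'   `mass_window`.
#' @param tolerance_ppm Relative mass tolerance (ppm) of the build.
#' @param n_specimens,n_replicates_per_specimen Provenance counts.
#' @param mass_window Numeric `c(low, high)` window in Da.
#' @return An object of class `super_spectrum`.
#' @export
super_spectrum <- function(species, biomarker_masses, tolerance_ppm,
                           n_specimens, n_replicates_per_specimen,
                           mass_window) {
  biomarker_masses <- as.numeric(biomarker_masses)
  if (is.unsorted(biomarker_masses, strictly = TRUE)) {
    stop("biomarker_masses must be strictly ascending")
  }
  if (length(biomarker_masses) &&
      (min(biomarker_masses) < mass_window[1] ||
       max(biomarker_masses) > mass_window[2])) {
    stop("biomarker_masses must lie inside mass_window")
  }
  if (length(biomarker_masses) > 1) {
    gaps <- diff(biomarker_masses)
    midp <- (biomarker_masses[-1] +
             biomarker_masses[-length(biomarker_masses)]) / 2
    if (any(gaps <= tolerance_ppm * 1e-6 * midp)) {
      stop("consecutive biomarkers must be separated by more than the tolerance")
    }
  }
  structure(list(species = as.character(species),
                 biomarker_masses = biomarker_masses,
                 tolerance_ppm = tolerance_ppm,
                 n_specimens = as.integer(n_specimens),
                 n_replicates_per_specimen = as.integer(n_replicates_per_specimen),
                 mass_window = as.numeric(mass_window)),
            class = "super_spectrum")
}

#' @export
print.super_spectrum <- function(x, ...) {
  cat(sprintf(
    "<super_spectrum> %s: %d biomarkers%s (tol %g ppm, %d specimens x %d replicates)\n",
    x$species, length(x$biomarker_masses),
    if (length(x$biomarker_masses)) {
      sprintf(" in [%.0f, %.0f] Da", min(x$biomarker_masses),
              max(x$biomarker_masses))
    } else "",
    x$tolerance_ppm, x$n_specimens, x$n_replicates_per_specimen))
  invisible(x)
}

#' Build a species' superspectrum from replicate peak lists
#'
#' Pools all replicate spectra of the supplied specimens, bins their
#' masses by single-linkage within the ppm tolerance ([bin_masses()]),
#' and retains a bin as a biomarker when its support fraction over all
#' replicate spectra reaches `consensus_fraction` (inclusive) and its
#' representative mass lies inside `mass_window`. The builder refuses
#' low-quality replicates (data count below `min_count`) rather than
#' silently dropping them: a reference database should only ever be
#' built from spectra that pass the quality gate.
#'
#' @param species Species name for the result.
#' @param specimens List of [specimen_record()] objects (>= 1, each with
#'   >= 1 replicate).
#' @param tolerance_ppm Relative tolerance in ppm (default 800, typical
#'   linear-mode accuracy).
#' @param consensus_fraction Minimum fraction of replicate spectra that
#'   must support a bin (default 0.75, inclusive).
#' @param mass_window Biomarker mass window in Da, default
#'   `c(4000, 20000)`.
#' @param min_count Quality gate on each replicate (default 30).
#' @return A [super_spectrum()].
#' @examples
#' reps <- lapply(1:4, function(r) peak_list("s1", r, seq(5000, 9000, by = 100)))
#' sp <- specimen_record("s1", "A", replicates = reps)
#' build_superspectrum("A", list(sp))
#' @export
build_superspectrum <- function(species, specimens, tolerance_ppm = 800,
                                consensus_fraction = 0.75,
                                mass_window = c(4000, 20000),
                                min_count = 30L) {
  if (!length(specimens)) stop("need at least one specimen")
  peaklists <- unlist(lapply(specimens, `[[`, "replicates"),
                      recursive = FALSE)
  if (!length(peaklists)) stop("specimens carry no replicates")
  low <- vapply(peaklists, function(p) qc_flag(p, min_count)$flag == "low",
                logical(1))
  if (any(low)) {
    bad <- vapply(peaklists[low], function(p) {
      sprintf("%s/r%d (count %d)", p$specimen_id, p$replicate_index,
              data_count(p))
    }, character(1))
    stop(sprintf("low-quality replicates refused: %s",
                 paste(bad, collapse = ", ")))
  }
  bins <- bin_masses(peaklists, tolerance_ppm)
  total <- length(peaklists)
  keep <- vapply(bins, function(b) {
    b$support / total >= consensus_fraction &&
      b$representative_mass >= mass_window[1] &&
      b$representative_mass <= mass_window[2]
  }, logical(1))
  biomarkers <- vapply(bins[keep], `[[`, numeric(1), "representative_mass")
  n_reps <- lengths(lapply(specimens, `[[`, "replicates"))
  super_spectrum(species, biomarkers, tolerance_ppm,
                 n_specimens = length(specimens),
                 n_replicates_per_specimen = as.integer(round(mean(n_reps))),
                 mass_window = mass_window)
}

#' Check that two builds of a species' superspectrum agree
#'
#' Two reference builds of the same species (e.g. from colony versus
#' field specimens) are considered to reproduce each other when their
#' biomarker lists match 1:1 within tolerance: equal length, and each
#' sorted pair within `tolerance_ppm` of its counterpart.
#'
#' @param db_a,db_b Two [super_spectrum()] objects with the same species
#'   label.
#' @param tolerance_ppm Relative tolerance in ppm; defaults to the
#'   tolerance recorded in `db_a`.
#' @return `TRUE` or `FALSE`.
#' @export
rebuild_check <- function(db_a, db_b, tolerance_ppm = db_a$tolerance_ppm) {
  stopifnot(inherits(db_a, "super_spectrum"), inherits(db_b, "super_spectrum"))
  if (db_a$species != db_b$species) stop("species labels differ")
  a <- db_a$biomarker_masses; b <- db_b$biomarker_masses
  if (length(a) != length(b)) return(FALSE)
  if (!length(a)) return(TRUE)
  all(abs(a - b) <= tolerance_ppm * 1e-6 * (a + b) / 2)
}

#' Write / read a superspectrum reference database (JSON)
#'
#' The reference database is serialized as a JSON array of superspectra,
#' masses written to 4 decimal places (0.1 mDa, beyond linear-TOF
#' accuracy) so that the round trip is lossless at the stored precision.
#'
#' @param db A list of [super_spectrum()] objects (or a `superspectra_db`
#'   fit) with unique species names.
#' @param path File path.
#' @return `write_database()` returns `path` invisibly;
#'   `read_database()` returns a list of [super_spectrum()] objects.
#' @export
write_database <- function(db, path) {
  db <- as_superspectrum_list(db)
  species <- vapply(db, `[[`, character(1), "species")
  if (anyDuplicated(species)) {
    stop(sprintf("duplicate species names in database: %s",
                 paste(unique(species[duplicated(species)]), collapse = ", ")))
  }
  entries <- lapply(db, function(ss) {
    list(species = ss$species,
         biomarker_masses = round(ss$biomarker_masses, 4),
         tolerance_ppm = ss$tolerance_ppm,
         n_specimens = ss$n_specimens,
         n_replicates_per_specimen = ss$n_replicates_per_specimen,
         mass_window = ss$mass_window)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  entries <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(entries, function(e) {
    super_spectrum(e$species, as.numeric(e$biomarker_masses),
                   e$tolerance_ppm, e$n_specimens,
                   e$n_replicates_per_specimen, as.numeric(e$mass_window))
  })
}

# Accept either a bare list of super_spectrum objects or a fitted
# superspectra_db, returning the list.
as_superspectrum_list <- function(db) {
  if (inherits(db, "superspectra_db")) return(db$superspectra)
  if (inherits(db, "super_spectrum")) return(list(db))
  stopifnot(is.list(db))
  for (ss in db) stopifnot(inherits(ss, "super_spectrum"))
  db
}
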
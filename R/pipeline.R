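#' Build a reference database from files and write it out
#'
#' Orchestrates the reference-building stage: reads a specimen metadata
#' CSV and the referenced peak-list files, fits the reference
#' ([build_reference()]) and writes the JSON database plus a build
#' report and the serialized run configuration next to it.
#'
#' @param config A named list of parameters as produced by
#'   [run_config()]; missing entries take the defaults.
#' @param metadata Data.frame of specimen metadata (see
#'   [read_specimen_metadata()]) with an extra `path` column naming each
#'   specimen's peak-list file (tabular: one file per replicate,
#'   semicolon-separated; mzXML: one file holding all replicates), or a
#'   list of ready [specimen_record()] objects.
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   writing.
#' @return The fitted `superspectra_db`, invisibly when writing.
#' @export
run_build_db <- function(config = run_config(), metadata, out_dir = NULL) {
  config <- run_config_fill(config)
  specimens <- if (is.data.frame(metadata)) {
    load_specimens(metadata, config)
  } else metadata
  db <- build_reference(specimens,
                        tolerance_ppm = config$tolerance_ppm,
                        consensus_fraction = config$consensus_fraction,
                        mass_window = config$mass_window,
                        min_count = config$min_count,
                        min_specimens = config$min_specimens)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_database(db, file.path(out_dir, "reference_db.json"))
    jsonlite::write_json(db$report, file.path(out_dir, "build_report.json"),
                         auto_unbox = TRUE)
    write_run_config(config, file.path(out_dir, "run_config.json"))
    return(invisible(db))
  }
  db
}

#' Validate a reference database against a cohort with known truth
#'
#' Runs replicate-level identification for every specimen, combines the
#' replicates into specimen-level calls, joins the calls to the truth
#' table into a [validation_ledger()], and summarizes sensitivity and
#' specificity.
#'
#' @param config As in [run_build_db()].
#' @param db A `superspectra_db` or list of [super_spectrum()] objects.
#' @param cohort List of [specimen_record()] objects to identify.
#' @param truth Data.frame with `specimen_id` and `species` (the true
#'   label); optionally `storage`.
#' @param out_dir Optional output directory for the ledger CSV, summary
#'   JSON and run configuration.
#' @return A list with `ledger` ([validation_ledger()]), `summary`
#'   ([summary.validation_ledger()]), and `calls` (specimen-level
#'   `id_result` objects).
#' @export
run_validation <- function(config = run_config(), db, cohort, truth,
                           out_dir = NULL) {
  config <- run_config_fill(config)
  db_list <- as_superspectrum_list(db)
  if (!length(db_list)) stop("reference database is empty")
  if (!length(cohort)) stop("empty cohort")
  ids <- vapply(cohort, `[[`, character(1), "specimen_id")
  missing_truth <- setdiff(ids, truth$specimen_id)
  if (length(missing_truth)) {
    stop(sprintf("truth table missing specimens: %s",
                 paste(utils::head(missing_truth, 5), collapse = ", ")))
  }
  db_species <- vapply(db_list, `[[`, character(1), "species")
  calls <- lapply(cohort, function(sp) {
    reps <- lapply(sp$replicates, function(pl) {
      identify_replicate(pl, db_list, threshold = config$threshold,
                         min_count = config$min_count,
                         tolerance_ppm = config$tolerance_ppm)
    })
    identify_specimen(reps)
  })
  names(calls) <- ids
  truth_idx <- match(ids, truth$specimen_id)
  storage <- if ("storage" %in% names(truth)) {
    truth$storage[truth_idx]
  } else {
    vapply(cohort, `[[`, character(1), "storage")
  }
  ledger <- validation_ledger(data.frame(
    specimen_id = ids,
    true_species = truth$species[truth_idx],
    in_database = truth$species[truth_idx] %in% db_species,
    storage = storage,
    quality = vapply(calls, function(cc) cc$quality$flag, character(1)),
    call_status = vapply(calls, `[[`, character(1), "status"),
    species_call = vapply(calls, `[[`, character(1), "species_call"),
    stringsAsFactors = FALSE
  ))
  summ <- summary(ledger)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(ledger),
                     file.path(out_dir, "validation_ledger.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(summ),
                         file.path(out_dir, "diagnostic_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_run_config(config, file.path(out_dir, "run_config.json"))
  }
  list(ledger = ledger, summary = summ, calls = calls)
}

#' Run configuration for the pipeline stages
#'
#' Gathers every tunable parameter with the package-wide defaults, so a
#' run's configuration can be serialized alongside its outputs and a
#' rerun from the serialized file reproduces them exactly.
#'
#' @param tolerance_ppm Matching tolerance (default 800 ppm).
#' @param threshold Identification threshold (default 0.75).
#' @param min_count Quality gate (default 30).
#' @param consensus_fraction Consensus support fraction (default 0.75).
#' @param mass_window Biomarker window (default `c(4000, 20000)` Da).
#' @param min_specimens Minimum qualifying specimens per species
#'   (default 1).
#' @param seed Seed for stages that draw random numbers (default 1).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(tolerance_ppm = 800, threshold = 0.75,
                       min_count = 30L, consensus_fraction = 0.75,
                       mass_window = c(4000, 20000), min_specimens = 1L,
                       seed = 1L) {
  structure(list(tolerance_ppm = tolerance_ppm, threshold = threshold,
                 min_count = min_count,
                 consensus_fraction = consensus_fraction,
                 mass_window = mass_window, min_specimens = min_specimens,
                 seed = seed),
            class = "run_config")
}

run_config_fill <- function(config) {
  defaults <- run_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

#' @rdname run_config
#' @param config A `run_config` (or plain named list).
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(run_config_fill(config)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$mass_window <- as.numeric(cfg$mass_window)
  do.call(run_config, cfg)
}

# Load specimen records from a metadata table with a `path` column.
load_specimens <- function(metadata, config) {
  stopifnot("path" %in% names(metadata))
  lapply(seq_len(nrow(metadata)), function(i) {
    md <- metadata[i, ]
    paths <- strsplit(md$path, ";")[[1]]
    reps <- if (length(paths) == 1 && grepl("\\.mzxml$", paths,
                                            ignore.case = TRUE)) {
      read_mzxml_masslist(paths, specimen_id = md$specimen_id)
    } else {
      lapply(seq_along(paths), function(r) {
        read_peaklist_table(paths[r], md$specimen_id, r)
      })
    }
    specimen_record(md$specimen_id, md$species_label, md$origin,
                    md$storage, md$collection_year, reps)
  })
}
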
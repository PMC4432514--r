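# Injective matching between two sorted mass lists. A pair (a_i, b_j)
# is admissible when |a_i - b_j| <= tol * 1e-6 * mean(a_i, b_j); the
# admissible b-range of each a_i is a contiguous run whose endpoints are
# nondecreasing in i (a staircase / convex bipartite structure), so the
# classical sweep -- walk a ascending, pair each a_i with the smallest
# still-unused admissible b -- attains maximum cardinality: no single
# broad peak can satisfy two close biomarkers, and the count equals the
# optimal bipartite matching (verified by brute force in the tests).
match_masses <- function(a, b, tolerance_ppm) {
  if (!length(a) || !length(b)) {
    return(list(n = 0L, a_idx = integer(0), b_idx = integer(0)))
  }
  t <- tolerance_ppm * 1e-6
  admissible <- function(x, y) abs(x - y) <= t * (x + y) / 2
  keep_a <- integer(0); keep_b <- integer(0)
  j <- 1L; nb <- length(b)
  for (i in seq_along(a)) {
    # skip b's below the admissible window of a_i
    while (j <= nb && b[j] < a[i] && !admissible(a[i], b[j])) j <- j + 1L
    if (j > nb) break
    if (admissible(a[i], b[j])) {
      keep_a <- c(keep_a, i); keep_b <- c(keep_b, j)
      j <- j + 1L
    }
  }
  list(n = length(keep_a), a_idx = keep_a, b_idx = keep_b)
}

#' Biomarker match fraction of a query against one superspectrum
#'
#' Counts the superspectrum biomarkers for which the query peak list has
#' a mass within the ppm tolerance. Matching is injective: each biomarker
#' is counted at most once and a single query mass can satisfy at most
#' one biomarker (greedy sweep over the sorted lists, attaining the
#' maximum injective match), so one broad
#' peak cannot match two close biomarkers. The fraction denominates by
#' the superspectrum's biomarker count — identification asks how much of
#' the reference pattern the query reproduces.
#'
#' @param query A [peak_list()].
#' @param ss A [super_spectrum()] with >= 1 biomarker.
#' @param tolerance_ppm Relative tolerance in ppm; defaults to the
#'   superspectrum's build tolerance.
#' @return An object of class `match_report`: `species`, `matched`,
#'   `total_biomarkers`, `fraction`.
#' @export
match_fraction <- function(query, ss, tolerance_ppm = ss$tolerance_ppm) {
  stopifnot(inherits(query, "peak_list"), inherits(ss, "super_spectrum"))
  total <- length(ss$biomarker_masses)
  if (!total) stop("superspectrum has no biomarkers")
  m <- match_masses(ss$biomarker_masses, query$masses, tolerance_ppm)
  structure(list(species = ss$species, matched = m$n,
                 total_biomarkers = total, fraction = m$n / total),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %s: %d/%d biomarkers (%.1f%%)\n",
              x$species, x$matched, x$total_biomarkers, 100 * x$fraction))
  invisible(x)
}

#' Identify one replicate peak list against the reference database
#'
#' Applies the quality gate first: a low-quality spectrum (data count
#' below `min_count`) is never identified, regardless of its matches.
#' Otherwise the match fraction against every superspectrum is computed
#' and sorted (descending fraction, ties by more matched biomarkers, then
#' species name); the replicate is identified when the best fraction
#' reaches `threshold` (inclusive). All match reports are retained for
#' audit, so sub-threshold best matches and exact ties remain visible.
#'
#' @param query A [peak_list()].
#' @param db A `superspectra_db` fit or list of [super_spectrum()]
#'   objects (nonempty).
#' @param threshold Identification threshold on the biomarker match
#'   fraction, default 0.75, inclusive.
#' @param min_count Quality gate, default 30.
#' @param tolerance_ppm Relative tolerance in ppm, default 800.
#' @return An object of class `id_result` with `query_id`, `level`
#'   (`"replicate"`), `status` (`"identified"`, `"no_id_low_quality"` or
#'   `"no_id_below_threshold"`), `species_call`, `best_matches`
#'   (data.frame) and `quality`.
#' @export
identify_replicate <- function(query, db, threshold = 0.75,
                               min_count = 30L, tolerance_ppm = 800) {
  db <- as_superspectrum_list(db)
  if (!length(db)) stop("reference database is empty")
  q <- qc_flag(query, min_count)
  qid <- sprintf("%s/r%d", query$specimen_id, query$replicate_index)
  if (q$flag == "low") {
    return(new_id_result(qid, "replicate", "no_id_low_quality", NA_character_,
                         empty_match_table(), q))
  }
  reports <- lapply(db, function(ss) match_fraction(query, ss, tolerance_ppm))
  tab <- data.frame(
    species = vapply(reports, `[[`, character(1), "species"),
    matched = vapply(reports, `[[`, integer(1), "matched"),
    total_biomarkers = vapply(reports, `[[`, integer(1), "total_biomarkers"),
    fraction = vapply(reports, `[[`, numeric(1), "fraction"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$fraction, -tab$matched, tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  if (tab$fraction[1] >= threshold) {
    new_id_result(qid, "replicate", "identified", tab$species[1], tab, q)
  } else {
    new_id_result(qid, "replicate", "no_id_below_threshold", NA_character_,
                  tab, q)
  }
}

#' Combine replicate calls into a specimen-level identification
#'
#' Let S be the set of species called among the replicates with status
#' `identified`. The specimen is `identified` when S has exactly one
#' species — even when other replicates failed the quality gate or the
#' threshold, since an identification was still produced; `discrepant`
#' when two or more species were called; `no_id_low_quality` when no
#' replicate was identified and all were low quality; and
#' `no_id_below_threshold` otherwise.
#'
#' @param replicates List of replicate-level `id_result` objects for one
#'   specimen (>= 1).
#' @return A specimen-level `id_result`.
#' @export
identify_specimen <- function(replicates) {
  stopifnot(length(replicates) >= 1)
  for (r in replicates) {
    stopifnot(inherits(r, "id_result"))
    if (r$level != "replicate") stop("inputs must be replicate-level results")
  }
  sid <- unique(sub("/r[0-9]+$", "", vapply(replicates, `[[`, character(1),
                                            "query_id")))
  if (length(sid) != 1) {
    stop(sprintf("mixed specimen ids: %s", paste(sid, collapse = ", ")))
  }
  calls <- unlist(lapply(replicates, function(r) {
    if (r$status == "identified") r$species_call else NULL
  }))
  species_set <- sort(unique(calls))
  statuses <- vapply(replicates, `[[`, character(1), "status")
  counts <- vapply(replicates, function(r) r$quality$data_count, integer(1))
  quality <- structure(list(data_count = max(counts),
                            flag = if (any(vapply(replicates, function(r)
                              r$quality$flag == "high", logical(1))))
                              "high" else "low"),
                       class = "quality_flag")
  best <- do.call(rbind, lapply(replicates, `[[`, "best_matches"))
  if (length(species_set) == 1L) {
    status <- "identified"; call <- species_set
  } else if (length(species_set) >= 2L) {
    status <- "discrepant"; call <- NA_character_
  } else if (all(statuses == "no_id_low_quality")) {
    status <- "no_id_low_quality"; call <- NA_character_
  } else {
    status <- "no_id_below_threshold"; call <- NA_character_
  }
  new_id_result(sid, "specimen", status, call, best, quality)
}

new_id_result <- function(query_id, level, status, species_call,
                          best_matches, quality) {
  stopifnot(status %in% c("identified", "no_id_low_quality",
                          "no_id_below_threshold", "discrepant"))
  if (status == "discrepant" && level != "specimen") {
    stop("discrepant status only arises at specimen level")
  }
  structure(list(query_id = query_id, level = level, status = status,
                 species_call = species_call, best_matches = best_matches,
                 quality = quality),
            class = "id_result")
}

empty_match_table <- function() {
  data.frame(species = character(0), matched = integer(0),
             total_biomarkers = integer(0), fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.id_result <- function(x, ...) {
  cat(sprintf("<id_result> %s [%s] %s%s (quality %s, data count %d)\n",
              x$query_id, x$level, x$status,
              if (!is.na(x$species_call)) paste0(": ", x$species_call) else "",
              x$quality$flag, x$quality$data_count))
  if (nrow(x$best_matches)) {
    top <- utils::head(x$best_matches, 3)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s %d/%d (%.1f%%)\n", top$species[i], top$matched[i],
                  top$total_biomarkers[i], 100 * top$fraction[i]))
    }
  }
  invisible(x)
}
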
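# Round half away from zero at the given number of decimals; the printed
# percentages use commercial rounding, not banker's rounding.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Truth-versus-call validation ledger
#'
#' One row per specimen: what the specimen truly is (morphological /
#' genetic identification), whether its species is represented in the
#' reference database, spectrum quality, and what the automated
#' identification called. Sensitivity and specificity are computed from
#' this table.
#'
#' @param df A data.frame with columns `specimen_id`, `true_species`,
#'   `in_database` (logical), `storage`, `quality` (`"high"`/`"low"`),
#'   `call_status` (`"identified"`, `"no_id_low_quality"`,
#'   `"no_id_below_threshold"`, `"discrepant"`) and `species_call`
#'   (character, `NA` when no call). A missing `storage` column defaults
#'   to `"fresh"`.
#' @return The validated data.frame with class `validation_ledger`.
#' @export
validation_ledger <- function(df) {
  if (!"storage" %in% names(df)) df$storage <- "fresh"
  need <- c("specimen_id", "true_species", "in_database", "storage",
            "quality", "call_status", "species_call")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("ledger missing columns: %s", paste(miss, collapse = ", ")))
  }
  stopifnot(all(df$quality %in% c("high", "low")),
            all(df$call_status %in% c("identified", "no_id_low_quality",
                                      "no_id_below_threshold", "discrepant")),
            is.logical(df$in_database))
  bad <- df$call_status == "identified" & is.na(df$species_call)
  if (any(bad)) stop("identified rows must carry a species_call")
  structure(df[need], class = c("validation_ledger", "data.frame"))
}

#' Expand aggregate outcome counts into a validation ledger
#'
#' Published validation studies report aggregate counts (n correct, n
#' wrong, n without result, ...) rather than per-specimen tables. This
#' helper reconstructs a row-level ledger with exactly those counts, so
#' the diagnostic percentages can be recomputed from the printed numbers.
#' Correct rows call the true species; wrong rows call `"__other__"`.
#'
#' @param n_correct Correctly identified, high-quality spectra.
#' @param n_wrong_high Wrong identifications from high-quality spectra.
#' @param n_wrong_low Wrong identifications from low-quality spectra.
#' @param n_no_id_low Low-quality spectra without any identification.
#' @param n_no_id_high_in_db High-quality spectra of database species
#'   that stayed below the identification threshold.
#' @param n_no_id_high_not_in_db High-quality spectra of species absent
#'   from the database (correctly not identified).
#' @param mislabelled Number of the `n_wrong_high` rows that are
#'   suspected label errors (call agrees with an independent genetic
#'   identification); marked so [correct_mislabels()] can rewrite their
#'   truth.
#' @return A [validation_ledger()].
#' @export
ledger_from_counts <- function(n_correct, n_wrong_high = 0, n_wrong_low = 0,
                               n_no_id_low = 0, n_no_id_high_in_db = 0,
                               n_no_id_high_not_in_db = 0,
                               mislabelled = 0) {
  stopifnot(mislabelled <= n_wrong_high)
  row <- function(n, true, in_db, quality, status, call, tag) {
    if (n <= 0) return(NULL)
    data.frame(specimen_id = sprintf("%s_%03d", tag, seq_len(n)),
               true_species = true, in_database = in_db,
               storage = "fresh", quality = quality, call_status = status,
               species_call = call, mislabel = FALSE,
               stringsAsFactors = FALSE)
  }
  parts <- list(
    row(n_correct, "target_species", TRUE, "high", "identified",
        "target_species", "ok"),
    row(n_wrong_high, "target_species", TRUE, "high", "identified",
        "__other__", "wr_hi"),
    row(n_wrong_low, "target_species", TRUE, "low", "identified",
        "__other__", "wr_lo"),
    row(n_no_id_low, "target_species", TRUE, "low", "no_id_low_quality",
        NA_character_, "lo"),
    row(n_no_id_high_in_db, "target_species", TRUE, "high",
        "no_id_below_threshold", NA_character_, "sub"),
    row(n_no_id_high_not_in_db, "novel_species", FALSE, "high",
        "no_id_below_threshold", NA_character_, "nov")
  )
  df <- do.call(rbind, parts)
  if (mislabelled > 0) {
    idx <- which(grepl("^wr_hi", df$specimen_id))[seq_len(mislabelled)]
    df$mislabel[idx] <- TRUE
  }
  out <- validation_ledger(df[setdiff(names(df), "mislabel")])
  out$mislabel <- df$mislabel
  out
}

#' Rewrite the truth of suspected mislabelled specimens
#'
#' When mass spectrometry and independent DNA sequencing agree against
#' the original morphological label, the specimen was probably
#' mislabelled: the ledger correction rewrites `true_species` to the
#' (agreeing) call and records an audit note.
#'
#' @param ledger A [validation_ledger()].
#' @param ids Specimen ids to correct; defaults to rows flagged in a
#'   `mislabel` column if present.
#' @return The corrected ledger; corrected ids in
#'   `attr(, "mislabel_corrected")`.
#' @export
correct_mislabels <- function(ledger, ids = NULL) {
  stopifnot(inherits(ledger, "validation_ledger"))
  if (is.null(ids)) {
    if (!"mislabel" %in% names(ledger)) return(ledger)
    ids <- ledger$specimen_id[ledger$mislabel]
  }
  sel <- ledger$specimen_id %in% ids
  if (any(sel & is.na(ledger$species_call))) {
    stop("cannot correct a specimen without a species call")
  }
  ledger$true_species[sel] <- ledger$species_call[sel]
  attr(ledger, "mislabel_corrected") <- ids
  ledger
}

ledger_filter <- function(ledger, high_quality_only, exclude_not_in_db) {
  if (high_quality_only) ledger <- ledger[ledger$quality == "high", , drop = FALSE]
  if (exclude_not_in_db) ledger <- ledger[ledger$in_database, , drop = FALSE]
  ledger
}

#' Sensitivity: percent of specimens correctly identified
#'
#' `100 * n(species_call == true_species) / n(rows surviving filters)`,
#' rounded half-up. Published studies mix precisions: an integer percent
#' for an overall figure, one decimal for per-quality breakdowns —
#' control with `digits`.
#'
#' @param ledger A [validation_ledger()].
#' @param high_quality_only Restrict the denominator to high-quality
#'   spectra.
#' @param exclude_not_in_db Drop specimens whose species is absent from
#'   the reference database.
#' @param digits Decimals of the returned percent (default: 0 overall,
#'   1 when `high_quality_only`).
#' @return Percent in `[0, 100]`.
#' @export
sensitivity <- function(ledger, high_quality_only = FALSE,
                        exclude_not_in_db = FALSE,
                        digits = if (high_quality_only) 1 else 0) {
  stopifnot(inherits(ledger, "validation_ledger"))
  led <- ledger_filter(ledger, high_quality_only, exclude_not_in_db)
  if (!nrow(led)) stop("no rows survive the filters (empty denominator)")
  correct <- !is.na(led$species_call) & led$species_call == led$true_species
  round_half_up(100 * sum(correct) / nrow(led), digits)
}

#' Specificity: 100 minus the percent of wrong identifications
#'
#' The complement of the wrong-identification rate: `100 - 100 * wrong /
#' denominator`, where a wrong identification is a species call that
#' disagrees with the specimen's truth. The `denominator` is either the
#' specimens that yielded an identification (`"identified"`, the stated
#' definition) or all high-quality spectra (`"high_quality"`, the
#' division some published field-cohort figures use). With zero wrong
#' calls the value is exactly 100 regardless of denominator.
#'
#' @inheritParams sensitivity
#' @param denominator `"identified"` or `"high_quality"`.
#' @return Percent in `[0, 100]`.
#' @export
specificity <- function(ledger, high_quality_only = FALSE,
                        denominator = c("identified", "high_quality"),
                        digits = if (high_quality_only) 1 else 0) {
  stopifnot(inherits(ledger, "validation_ledger"))
  denominator <- match.arg(denominator)
  led <- ledger_filter(ledger, high_quality_only, exclude_not_in_db = FALSE)
  denom <- switch(denominator,
                  identified = sum(!is.na(led$species_call)),
                  high_quality = sum(led$quality == "high"))
  if (!denom) stop("empty denominator for specificity")
  wrong <- sum(!is.na(led$species_call) &
                 led$species_call != led$true_species)
  if (wrong == 0) return(100)
  round_half_up(100 - 100 * wrong / denom, digits)
}

#' Diagnostic summary of a validation ledger
#'
#' @param object A [validation_ledger()].
#' @param ... Unused.
#' @return An object of class `diagnostic_summary`: counts (`n_total`,
#'   `n_identified`, `n_correct`, `n_wrong`, `n_no_result`) and the
#'   percentages (`sensitivity_overall`, `sensitivity_high_quality`,
#'   `specificity`), with percentages `NA` where the denominator is
#'   empty.
#' @export
summary.validation_ledger <- function(object, ...) {
  led <- object
  has_call <- !is.na(led$species_call)
  correct <- has_call & led$species_call == led$true_species
  pct_or_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  structure(list(
    n_total = nrow(led),
    n_identified = sum(has_call),
    n_correct = sum(correct),
    n_wrong = sum(has_call & !correct),
    n_no_result = sum(!has_call),
    sensitivity_overall = pct_or_na(sensitivity(led)),
    sensitivity_high_quality = pct_or_na(sensitivity(led, TRUE)),
    specificity = pct_or_na(specificity(led))
  ), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat("Diagnostic summary\n")
  cat(sprintf("  specimens: %d (identified %d: %d correct, %d wrong; no result %d)\n",
              x$n_total, x$n_identified, x$n_correct, x$n_wrong,
              x$n_no_result))
  cat(sprintf("  sensitivity: %s %%  (high-quality spectra only: %s %%)\n",
              format(x$sensitivity_overall), format(x$sensitivity_high_quality)))
  cat(sprintf("  specificity: %s %%\n", format(x$specificity)))
  invisible(x)
}

#' Per-category breakdown of a validation ledger
#'
#' Cross-tabulates identification outcomes by storage condition and
#' spectrum quality.
#'
#' @param ledger A [validation_ledger()].
#' @return A data.frame with one row per storage-by-quality cell and
#'   counts per call status.
#' @export
ledger_breakdown <- function(ledger) {
  stopifnot(inherits(ledger, "validation_ledger"))
  has_call <- !is.na(ledger$species_call)
  correct <- has_call & ledger$species_call == ledger$true_species
  agg <- function(sel) {
    c(n = sum(sel), correct = sum(correct & sel),
      wrong = sum(has_call & !correct & sel),
      no_result = sum(!has_call & sel))
  }
  cells <- unique(ledger[c("storage", "quality")])
  cells <- cells[order(cells$storage, cells$quality), , drop = FALSE]
  out <- cbind(cells, t(vapply(seq_len(nrow(cells)), function(i) {
    agg(ledger$storage == cells$storage[i] &
          ledger$quality == cells$quality[i])
  }, numeric(4))))
  rownames(out) <- NULL
  out
}
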
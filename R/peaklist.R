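#' Peak list: one replicate spectrum reduced to its biomarker masses
#'
#' A MALDI-TOF spectrum enters the pipeline as a *peak list*: the m/z values
#' (singly charged protein ions, in Da) picked from one technical replicate,
#' optionally with intensities. Masses are stored strictly ascending; exact
#' duplicate masses are collapsed to a single entry keeping the maximum
#' intensity. Intensities are carried through I/O but ignored by all
#' downstream matching, which is presence/absence only.
#'
#' @param specimen_id Specimen identifier (character scalar).
#' @param replicate_index Technical replicate number, integer >= 1.
#' @param masses Numeric vector of m/z values in Da, all > 0. Sorted on
#'   construction.
#' @param intensities Optional numeric vector of nonnegative intensities,
#'   same length as `masses`.
#' @param instrument An [instrument_profile()] or `NULL`.
#' @param source_format `"table"` or `"mzxml"`.
#' @return An object of class `peak_list`.
#' @examples
#' pl <- peak_list("sp1", 1, c(5200.1, 4123.4, 9871.0))
#' data_count(pl)
#' @export
peak_list <- function(specimen_id, replicate_index, masses,
                      intensities = NULL, instrument = NULL,
                      source_format = c("table", "mzxml")) {
  source_format <- match.arg(source_format)
  masses <- as.numeric(masses)
  if (anyNA(masses)) stop("masses must be numeric and non-missing")
  if (length(masses) && any(masses <= 0)) stop("masses must all be > 0")
  replicate_index <- as.integer(replicate_index)
  if (is.na(replicate_index) || replicate_index < 1L) {
    stop("replicate_index must be an integer >= 1")
  }
  if (!is.null(intensities)) {
    intensities <- as.numeric(intensities)
    if (length(intensities) != length(masses)) {
      stop("intensities must have the same length as masses")
    }
    if (length(intensities) && any(intensities < 0)) {
      stop("intensities must be nonnegative")
    }
  }
  ord <- order(masses)
  masses <- masses[ord]
  if (!is.null(intensities)) intensities <- intensities[ord]
  # collapse exact duplicates, keeping the max intensity (order-independent)
  if (anyDuplicated(masses)) {
    keep <- !duplicated(masses)
    if (!is.null(intensities)) {
      grp <- factor(match(masses, unique(masses)),
                    levels = seq_along(unique(masses)))
      intensities <- as.numeric(tapply(intensities, grp, max))
    }
    masses <- masses[keep]
  }
  if (!is.null(instrument)) stopifnot(inherits(instrument, "instrument_profile"))
  structure(
    list(
      specimen_id = as.character(specimen_id),
      replicate_index = replicate_index,
      masses = masses,
      intensities = intensities,
      instrument = instrument,
      source_format = source_format
    ),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf(
    "<peak_list> %s replicate %d: %d masses%s\n",
    x$specimen_id, x$replicate_index, length(x$masses),
    if (length(x$masses)) {
      sprintf(" [%.1f, %.1f] Da", min(x$masses), max(x$masses))
    } else ""
  ))
  invisible(x)
}

#' Instrument mass-range profile
#'
#' Mass spectrometers record peak lists over instrument-specific mass
#' windows (e.g. Bruker Ultraflex III: 2--25 kDa; Shimadzu Axima
#' Confidence: 3--20 kDa). Cross-instrument comparison requires clipping
#' peak lists to a common window.
#'
#' @param name Instrument name.
#' @param mass_min,mass_max Window bounds in Da, `0 < mass_min < mass_max`.
#' @return An object of class `instrument_profile`.
#' @seealso [clip_to_range()]
#' @export
instrument_profile <- function(name, mass_min, mass_max) {
  mass_min <- as.numeric(mass_min); mass_max <- as.numeric(mass_max)
  if (!(is.finite(mass_min) && is.finite(mass_max) &&
        mass_min > 0 && mass_min < mass_max)) {
    stop("require 0 < mass_min < mass_max")
  }
  structure(list(name = as.character(name), mass_min = mass_min,
                 mass_max = mass_max),
            class = "instrument_profile")
}

#' @export
print.instrument_profile <- function(x, ...) {
  cat(sprintf("<instrument_profile> %s [%g, %g] Da\n",
              x$name, x$mass_min, x$mass_max))
  invisible(x)
}

#' Built-in instrument profiles
#'
#' The two widely used linear-TOF platforms and their acquisition windows.
#' @return A named list of [instrument_profile()] objects
#'   (`bruker`: 2--25 kDa, `shimadzu`: 3--20 kDa).
#' @export
instrument_profiles <- function() {
  list(
    bruker = instrument_profile("bruker", 2000, 25000),
    shimadzu = instrument_profile("shimadzu", 3000, 20000)
  )
}

#' Specimen record: a specimen's metadata plus its replicate peak lists
#'
#' @param specimen_id Specimen identifier shared by all replicates.
#' @param species_label Morphological species label (may be `"unknown"`).
#' @param origin `"colony"` or `"field"`.
#' @param storage `"fresh"`, `"deep_frozen"` or `"ethanol"`.
#' @param collection_year Integer year.
#' @param replicates List of [peak_list()] objects with this
#'   `specimen_id` and unique `replicate_index` values.
#' @return An object of class `specimen_record`.
#' @export
specimen_record <- function(specimen_id, species_label = "unknown",
                            origin = c("colony", "field"),
                            storage = c("fresh", "deep_frozen", "ethanol"),
                            collection_year = NA_integer_,
                            replicates = list()) {
  origin <- match.arg(origin)
  storage <- match.arg(storage)
  stopifnot(is.list(replicates))
  for (pl in replicates) {
    if (!inherits(pl, "peak_list")) stop("replicates must be peak_list objects")
    if (pl$specimen_id != specimen_id) {
      stop(sprintf("replicate specimen_id '%s' does not match '%s'",
                   pl$specimen_id, specimen_id))
    }
  }
  idx <- vapply(replicates, `[[`, integer(1), "replicate_index")
  if (anyDuplicated(idx)) stop("replicate_index values must be unique")
  structure(
    list(specimen_id = as.character(specimen_id),
         species_label = as.character(species_label),
         origin = origin, storage = storage,
         collection_year = as.integer(collection_year),
         replicates = replicates),
    class = "specimen_record"
  )
}

#' @export
print.specimen_record <- function(x, ...) {
  cat(sprintf("<specimen_record> %s (%s, %s, %s): %d replicates\n",
              x$specimen_id, x$species_label, x$origin, x$storage,
              length(x$replicates)))
  invisible(x)
}

#' Read a tabular peak list
#'
#' Parses a 1- or 2-column whitespace- or comma-delimited text file of
#' `mass[, intensity]` rows. A single non-numeric header line is allowed.
#' Exact duplicate masses are collapsed keeping the maximum intensity.
#'
#' @inheritParams peak_list
#' @param path Path to the text file.
#' @return A [peak_list()] with masses sorted ascending.
#' @export
read_peaklist_table <- function(path, specimen_id, replicate_index,
                                instrument = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    return(peak_list(specimen_id, replicate_index, numeric(0),
                     instrument = instrument))
  }
  parse_row <- function(line) {
    fields <- strsplit(trimws(line), "[,[:space:]]+")[[1]]
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_row(lines[nonblank[1]])
  start <- if (anyNA(first)) 2L else 1L  # header line tolerated
  rows <- nonblank[seq(start, length(nonblank))]
  if (start > length(nonblank)) rows <- integer(0)
  masses <- numeric(0); intensities <- NULL
  vals <- lapply(rows, function(i) {
    v <- parse_row(lines[i])
    if (anyNA(v) || !(length(v) %in% 1:2)) {
      stop(sprintf("line %d of %s: expected 1-2 numeric fields, got '%s'",
                   i, path, trimws(lines[i])))
    }
    if (v[1] <= 0) {
      stop(sprintf("line %d of %s: mass must be positive, got %g", i, path, v[1]))
    }
    v
  })
  if (length(vals)) {
    masses <- vapply(vals, `[`, numeric(1), 1)
    if (all(lengths(vals) == 2L)) {
      intensities <- vapply(vals, `[`, numeric(1), 2)
    }
  }
  peak_list(specimen_id, replicate_index, masses, intensities,
            instrument = instrument)
}

#' Write a peak list as a tabular text file
#'
#' Inverse of [read_peaklist_table()]; masses (and intensities if present)
#' are written to 4 decimal places, one peak per line.
#'
#' @param pl A [peak_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist_table <- function(pl, path) {
  stopifnot(inherits(pl, "peak_list"))
  if (is.null(pl$intensities)) {
    lines <- sprintf("%.4f", pl$masses)
  } else {
    lines <- sprintf("%.4f\t%.4f", pl$masses, pl$intensities)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an mzXML mass-list export
#'
#' Supports the mass-list dialect used for exported peak lists (not raw
#' profile spectra): an `msRun` of `scan` elements, one scan per technical
#' replicate, each holding a `peaks` element of mass/intensity pairs either
#' as plain whitespace-separated text or as uncompressed base64
#' (network byte order, 32- or 64-bit floats). Scan document order defines
#' `replicate_index` 1, 2, ...
#'
#' @param path Path to the mzXML file.
#' @param instrument Optional [instrument_profile()] attached to the
#'   resulting peak lists.
#' @param specimen_id Specimen id for the resulting peak lists; defaults to
#'   the file name without extension.
#' @return A list of [peak_list()] objects, one per scan.
#' @export
read_mzxml_masslist <- function(path, instrument = NULL,
                                specimen_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(specimen_id)) {
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  }
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("malformed XML in %s: %s",
                                                   path, conditionMessage(e))))
  # namespace-agnostic: exported mass lists come with and without the
  # mzXML schema namespace
  scans <- xml2::xml_find_all(doc, ".//*[local-name()='scan']")
  if (!length(scans)) stop(sprintf("no <scan> elements in %s", path))
  out <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    peaks <- xml2::xml_find_first(scans[[i]], ".//*[local-name()='peaks']")
    if (inherits(peaks, "xml_missing")) {
      stop(sprintf("scan %d in %s has no <peaks> element", i, path))
    }
    comp <- xml2::xml_attr(peaks, "compressionType")
    if (!is.na(comp) && !comp %in% c("none", "")) {
      stop(sprintf("unsupported compressionType '%s' in %s", comp, path))
    }
    txt <- trimws(xml2::xml_text(peaks))
    vals <- decode_peaks_text(txt, xml2::xml_attr(peaks, "precision"), path)
    if (length(vals) %% 2L != 0L) {
      stop(sprintf("scan %d in %s: odd number of peak values", i, path))
    }
    m <- vals[seq(1, length(vals), by = 2)]
    inten <- vals[seq(2, length(vals), by = 2)]
    out[[i]] <- peak_list(specimen_id, i, m, inten,
                          instrument = instrument, source_format = "mzxml")
  }
  out
}

# Decode a <peaks> payload: whitespace-separated numbers, or base64 of
# big-endian IEEE floats (mzXML network byte order).
decode_peaks_text <- function(txt, precision, path) {
  if (!nzchar(txt)) return(numeric(0))
  if (grepl("^[-0-9.eE+[:space:],]+$", txt)) {
    vals <- suppressWarnings(as.numeric(strsplit(txt, "[,[:space:]]+")[[1]]))
    if (anyNA(vals)) stop(sprintf("non-numeric peak text in %s", path))
    return(vals)
  }
  raw <- tryCatch(jsonlite::base64_dec(gsub("[[:space:]]", "", txt)),
                  error = function(e) stop(sprintf("invalid base64 peaks in %s", path)))
  size <- if (is.na(precision) || precision == "32") 4L else 8L
  if (!is.na(precision) && !precision %in% c("32", "64")) {
    stop(sprintf("unsupported precision '%s' in %s", precision, path))
  }
  readBin(raw, what = "double", n = length(raw) %/% size,
          size = size, endian = "big")
}

#' Write peak lists as an mzXML mass list
#'
#' One `scan` per peak list, peaks encoded as base64 big-endian 64-bit
#' floats; the counterpart of [read_mzxml_masslist()].
#'
#' @param peaklists A list of [peak_list()] objects (one specimen's
#'   replicates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzxml_masslist <- function(peaklists, path) {
  stopifnot(length(peaklists) >= 1)
  scans <- vapply(seq_along(peaklists), function(i) {
    pl <- peaklists[[i]]
    inten <- if (is.null(pl$intensities)) rep(1, length(pl$masses)) else pl$intensities
    vals <- as.numeric(rbind(pl$masses, inten))
    b64 <- jsonlite::base64_enc(writeBin(vals, raw(), size = 8L, endian = "big"))
    paste0(
      sprintf('  <scan num="%d" peaksCount="%d">\n', i, length(pl$masses)),
      sprintf('   <peaks precision="64" byteOrder="network" compressionType="none">%s</peaks>\n',
              gsub("\n", "", b64)),
      "  </scan>"
    )
  }, character(1))
  writeLines(c('<?xml version="1.0" encoding="ISO-8859-1"?>',
               "<mzXML>", " <msRun>", scans, " </msRun>", "</mzXML>"), path)
  invisible(path)
}

#' Clip a peak list to an instrument's mass range
#'
#' Keeps exactly the masses `m` with `mass_min <= m <= mass_max` of the
#' target instrument, preserving order, and stamps the target instrument on
#' the result. Used to harmonize peak lists acquired on instruments with
#' different acquisition windows before matching or clustering.
#'
#' @param pl A [peak_list()].
#' @param target An [instrument_profile()].
#' @return The clipped [peak_list()].
#' @export
clip_to_range <- function(pl, target) {
  stopifnot(inherits(pl, "peak_list"), inherits(target, "instrument_profile"))
  keep <- pl$masses >= target$mass_min & pl$masses <= target$mass_max
  peak_list(pl$specimen_id, pl$replicate_index, pl$masses[keep],
            if (is.null(pl$intensities)) NULL else pl$intensities[keep],
            instrument = target, source_format = pl$source_format)
}

#' Apply a calibration offset to a peak list
#'
#' Shifts every mass by a relative offset in parts per million,
#' `m * (1 + offset_ppm * 1e-6)`; models a systematic cross-instrument
#' calibration difference.
#'
#' @param pl A [peak_list()].
#' @param offset_ppm Relative offset in ppm.
#' @return The shifted [peak_list()].
#' @export
apply_calibration_offset <- function(pl, offset_ppm) {
  stopifnot(inherits(pl, "peak_list"))
  peak_list(pl$specimen_id, pl$replicate_index,
            pl$masses * (1 + offset_ppm * 1e-6), pl$intensities,
            instrument = pl$instrument, source_format = pl$source_format)
}

#' Read specimen metadata
#'
#' Reads a CSV with columns `specimen_id, species_label, origin, storage,
#' collection_year` describing the cohort; peak lists are attached
#' separately.
#'
#' @param path CSV path.
#' @return A data.frame with the five metadata columns.
#' @export
read_specimen_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species_label", "origin", "storage",
            "collection_year")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop(sprintf("metadata missing columns: %s", paste(miss, collapse = ", ")))
  }
  md
}
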
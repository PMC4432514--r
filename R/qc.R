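#' Number of evaluable masses in a peak list
#'
#' The "data count" of a spectrum: how many picked masses its peak list
#' contains. Drives the quality gate ([qc_flag()]): reference building and
#' automated identification only accept spectra with enough evaluable
#' masses.
#'
#' @param pl A [peak_list()].
#' @return Integer count of masses.
#' @export
data_count <- function(pl) {
  stopifnot(inherits(pl, "peak_list"))
  length(pl$masses)
}

#' Spectrum quality gate on data counts
#'
#' Spectra with fewer than `min_count` evaluable masses are flagged low
#' quality; the boundary itself (exactly `min_count` masses) is high
#' quality. The default gate of 30 counts reflects routine practice for
#' whole-insect protein profiles, where degraded specimens lose peaks.
#'
#' @param pl A [peak_list()].
#' @param min_count Minimum data count for high quality; integer >= 1,
#'   default 30.
#' @return An object of class `quality_flag`: a list with `data_count`
#'   and `flag` (`"high"` or `"low"`).
#' @examples
#' qc_flag(peak_list("s", 1, seq(4000, 4029)))  # 30 masses -> high
#' @export
qc_flag <- function(pl, min_count = 30L) {
  stopifnot(min_count >= 1)
  n <- data_count(pl)
  structure(list(data_count = n,
                 flag = if (n >= min_count) "high" else "low"),
            class = "quality_flag")
}

#' @export
print.quality_flag <- function(x, ...) {
  cat(sprintf("<quality_flag> %s (data count %d)\n", x$flag, x$data_count))
  invisible(x)
}

#' Fraction of masses in the high mass range
#'
#' Storage degradation (notably in ethanol) preferentially destroys the
#' high-mass part of a protein profile; the fraction of masses at or above
#' `cutoff` tracks that loss without affecting the low-mass biomarkers
#' used for identification.
#'
#' @param pl A [peak_list()].
#' @param cutoff Mass cutoff in Da, default 10000.
#' @return Fraction in `[0, 1]`; 0 for an empty list.
#' @export
high_mass_fraction <- function(pl, cutoff = 10000) {
  stopifnot(inherits(pl, "peak_list"))
  if (!length(pl$masses)) return(0)
  mean(pl$masses >= cutoff)
}
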
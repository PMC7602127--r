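#' Construct a single mass spectrum
#'
#' A scan is the atomic unit of an LC-MS(/MS) run: one centroided mass
#' spectrum acquired at a given retention time. Peaks are stored as two
#' parallel numeric vectors sorted by ascending m/z.
#'
#' @param scan_index 0-based integer position of the scan in its run.
#' @param ms_level integer, 1 for a survey (MS1) spectrum, 2 for a
#'   fragmentation (MS2) spectrum.
#' @param rt retention time, in the unit of the enclosing run's
#'   `rt_variant` (minutes by default).
#' @param mz numeric vector of m/z values (Thomson), strictly ascending.
#' @param intensity numeric vector of non-negative intensities, same
#'   length as `mz`.
#' @param precursor_mz m/z of the selected precursor ion; required when
#'   `ms_level == 2`, must be `NA` otherwise.
#' @param precursor_intensity optional non-negative precursor intensity.
#'
#' @return An object of class `ms_scan`.
#' @export
ms_scan <- function(scan_index, ms_level, rt, mz, intensity,
                    precursor_mz = NA_real_,
                    precursor_intensity = NA_real_) {
  x <- structure(
    list(
      scan_index = as.integer(scan_index),
      ms_level = as.integer(ms_level),
      rt = as.numeric(rt),
      mz = as.numeric(mz),
      intensity = as.numeric(intensity),
      precursor_mz = as.numeric(precursor_mz),
      precursor_intensity = as.numeric(precursor_intensity)
    ),
    class = "ms_scan"
  )
  validate_scan(x)
  x
}

validate_scan <- function(x) {
  if (!x$ms_level %in% c(1L, 2L))
    stop_validation("ms_level must be 1 or 2")
  if (length(x$mz) != length(x$intensity))
    stop_validation("mz and intensity must have the same length")
  if (length(x$mz) > 1 && any(diff(x$mz) <= 0))
    stop_validation("mz values must be strictly ascending")
  if (any(x$intensity < 0))
    stop_validation("intensities must be non-negative")
  if (x$ms_level == 2L && (is.na(x$precursor_mz) || x$precursor_mz <= 0))
    stop_validation("an MS2 scan requires a positive precursor_mz")
  invisible(x)
}

#' Construct an LC-MS(/MS) run
#'
#' Bundles an ordered list of scans with the sample identifier and the
#' retention-time convention in force. Scans must be in non-decreasing
#' retention-time order.
#'
#' @param sample_id non-empty string identifying the sample.
#' @param scans list of [ms_scan()] objects, ordered by retention time.
#' @param rt_variant retention-time convention: `"minutes"` (default),
#'   `"seconds"`, or `"scan_index"` (rt equals the 0-based scan index).
#'
#' @return An object of class `ms_run`.
#' @export
ms_run <- function(sample_id, scans, rt_variant = c("minutes", "seconds",
                                                    "scan_index")) {
  rt_variant <- match.arg(rt_variant)
  x <- structure(
    list(sample_id = as.character(sample_id), rt_variant = rt_variant,
         scans = scans),
    class = "ms_run"
  )
  validate_run(x)
  x
}

validate_run <- function(x) {
  if (!nzchar(x$sample_id)) stop_validation("sample_id must be non-empty")
  lapply(x$scans, validate_scan)
  rts <- vapply(x$scans, `[[`, numeric(1), "rt")
  if (length(rts) > 1 && any(diff(rts) < 0))
    stop_validation(sprintf(
      "scan retention times must be non-decreasing in run '%s'", x$sample_id))
  invisible(x)
}

#' @export
print.ms_run <- function(x, ...) {
  lv <- vapply(x$scans, `[[`, integer(1), "ms_level")
  cat(sprintf("<ms_run> sample '%s': %d scans (%d MS1, %d MS2), rt in %s\n",
              x$sample_id, length(x$scans), sum(lv == 1L), sum(lv == 2L),
              x$rt_variant))
  invisible(x)
}

run_ms_levels <- function(run) {
  vapply(run$scans, `[[`, integer(1), "ms_level")
}

run_scans_at_level <- function(run, level) {
  run$scans[run_ms_levels(run) == level]
}
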
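#' Read an LC-MS(/MS) run from an mzXML or mzML file
#'
#' Parses a centroided raw-data file and returns the scans at the
#' requested MS levels, with retention time converted to the requested
#' convention. Scans are returned sorted by retention time (ties broken
#' by the original scan index) and peaks sorted by ascending m/z.
#'
#' @param path path to a readable mzXML or mzML file.
#' @param rt_variant retention-time convention for the returned run:
#'   `"minutes"` (default), `"seconds"`, or `"scan_index"` in which case
#'   rt is the 0-based position of the scan among the returned scans.
#' @param ms_levels integer vector of MS levels to retain (default `1`).
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#'
#' @return An [ms_run()] object.
#' @export
read_run <- function(path, rt_variant = c("minutes", "seconds", "scan_index"),
                     ms_levels = 1L, sample_id = NULL) {
  rt_variant <- match.arg(rt_variant)
  if (!file.exists(path)) stop_data(sprintf("file not found: '%s'", path))
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))

  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop_data(sprintf(
                   "cannot parse '%s' as mzXML/mzML: %s", path,
                   conditionMessage(e))))
  on.exit(try(mzR::close(fh), silent = TRUE), add = TRUE)
  hdr <- tryCatch(mzR::header(fh),
                  error = function(e) stop_data(sprintf(
                    "cannot read scan headers from '%s': %s", path,
                    conditionMessage(e))))

  keep <- which(hdr$msLevel %in% as.integer(ms_levels))
  if (length(keep) == 0)
    stop_data(sprintf("'%s' contains no scans at MS level(s) %s", path,
                      paste(ms_levels, collapse = ",")))

  # sort by rt, ties by original acquisition order
  keep <- keep[order(hdr$retentionTime[keep], keep)]
  scans <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    pk <- mzR::peaks(fh, k)
    if (is.null(dim(pk))) pk <- matrix(pk, ncol = 2)
    o <- order(pk[, 1])
    pk <- pk[o, , drop = FALSE]
    lvl <- as.integer(hdr$msLevel[k])
    rt_sec <- hdr$retentionTime[k]
    rt <- switch(rt_variant,
                 minutes = rt_sec / 60,
                 seconds = rt_sec,
                 scan_index = i - 1)
    prec <- if (lvl == 2L) hdr$precursorMZ[k] else NA_real_
    prec_int <- if (lvl == 2L) hdr$precursorIntensity[k] else NA_real_
    if (lvl == 2L && (is.na(prec) || prec <= 0))
      stop_data(sprintf("MS2 scan %d in '%s' lacks a precursor m/z", k, path))
    scans[[i]] <- ms_scan(scan_index = i - 1L, ms_level = lvl, rt = rt,
                          mz = pk[, 1], intensity = pk[, 2],
                          precursor_mz = prec, precursor_intensity = prec_int)
  }
  ms_run(sample_id, scans, rt_variant)
}

#' Write a run to an mzXML file
#'
#' Serializes an [ms_run()] to a standards-conformant mzXML file (via the
#' ProteoWizard writer). Retention times are stored in seconds; a run
#' whose `rt_variant` is `"minutes"` is converted, and one using
#' `"scan_index"` stores the index value as seconds so that reading the
#' file back with `rt_variant = "scan_index"` reproduces it.
#'
#' @param run an [ms_run()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  validate_run(run)
  if (!dir.exists(dirname(path)))
    stop_data(sprintf("output directory does not exist: '%s'", dirname(path)))
  n <- length(run$scans)
  rt_sec <- vapply(run$scans, `[[`, numeric(1), "rt")
  rt_sec <- switch(run$rt_variant,
                   minutes = rt_sec * 60,
                   seconds = rt_sec,
                   scan_index = rt_sec)
  lv <- run_ms_levels(run)
  pks <- lapply(run$scans, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  prec_mz <- vapply(run$scans, `[[`, numeric(1), "precursor_mz")
  prec_int <- vapply(run$scans, `[[`, numeric(1), "precursor_intensity")
  npk <- vapply(pks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lv,
    polarity = 1L, peaksCount = npk,
    totIonCurrent = vapply(pks, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = rt_sec,
    basePeakMZ = vapply(pks, function(p)
      if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pks, function(p)
      if (nrow(p)) max(p[, 2]) else 0, numeric(1)),
    collisionEnergy = ifelse(lv == 2L, 35, 0), ionisationEnergy = 0,
    lowMZ = vapply(pks, function(p) if (nrow(p)) min(p[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(pks, function(p) if (nrow(p)) max(p[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(lv == 2L, prec_mz, 0),
    precursorCharge = ifelse(lv == 2L, 1L, 0L),
    precursorIntensity = ifelse(lv == 2L & !is.na(prec_int), prec_int, 0),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(lv == 2L, prec_mz, NA_real_),
    isolationWindowLowerOffset = ifelse(lv == 2L, 1, NA_real_),
    isolationWindowUpperOffset = ifelse(lv == 2L, 1, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  tryCatch(
    mzR::writeMSData(pks, path, header = hdr, outformat = "mzxml"),
    error = function(e) stop_data(sprintf(
      "cannot write mzXML to '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

#' Construct a samples-by-features bucket table
#'
#' The bucket table is the central exchange object of the pipeline: a
#' numeric matrix with one row per sample and one column per consolidated
#' feature, each cell holding the feature's integration value (peak area)
#' in that sample, 0 meaning "not detected".
#'
#' @param values numeric matrix (samples x features), non-negative.
#' @param sample_ids character vector of unique row names.
#' @param feature_keys character vector of column names, conventionally
#'   `"mz@rt"` strings such as `"457.7850@12.40"`.
#' @param feature_mz,feature_rt optional numeric vectors with the feature
#'   coordinates; parsed from `feature_keys` when omitted.
#' @param transform_tag which transformation has been applied: one of
#'   `"raw"`, `"log10p1"`, `"tic"`, `"presence_absence"`.
#'
#' @return An object of class `bucket_table` (a numeric matrix with
#'   attributes).
#' @export
bucket_table <- function(values, sample_ids = rownames(values),
                         feature_keys = colnames(values),
                         feature_mz = NULL, feature_rt = NULL,
                         transform_tag = "raw") {
  values <- as.matrix(values)
  mode(values) <- "numeric"
  if (is.null(sample_ids) || anyDuplicated(sample_ids))
    stop_validation("sample ids must be present and unique")
  if (length(sample_ids) != nrow(values) ||
      length(feature_keys) != ncol(values))
    stop_validation("dimension mismatch between values and names")
  if (anyNA(values)) stop_validation("bucket table must not contain NA")
  if (any(values < 0)) stop_validation("bucket values must be non-negative")
  if (transform_tag == "presence_absence" && !all(values %in% c(0, 1)))
    stop_validation("presence_absence table must be 0/1")
  rownames(values) <- as.character(sample_ids)
  colnames(values) <- as.character(feature_keys)
  if (is.null(feature_mz) && ncol(values) > 0) {
    parsed <- parse_feature_keys(colnames(values))
    feature_mz <- parsed$mz
    feature_rt <- parsed$rt
  }
  structure(values, feature_mz = feature_mz, feature_rt = feature_rt,
            transform_tag = transform_tag,
            class = c("bucket_table", "matrix", "array"))
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("<bucket_table> %d samples x %d features (%s)\n",
              nrow(x), ncol(x), attr(x, "transform_tag")))
  invisible(x)
}

# "457.7850@12.40" -> list(mz=457.785, rt=12.4); non-conforming keys get NA
parse_feature_keys <- function(keys) {
  parts <- strsplit(keys, "@", fixed = TRUE)
  mz <- vapply(parts, function(p)
    suppressWarnings(as.numeric(p[1])), numeric(1))
  rt <- vapply(parts, function(p)
    if (length(p) >= 2) suppressWarnings(as.numeric(p[2])) else NA_real_,
    numeric(1))
  list(mz = mz, rt = rt)
}

format_feature_key <- function(mz, rt) sprintf("%.4f@%.2f", mz, rt)

#' Read a bucket table from CSV
#'
#' Accepts any externally produced samples-by-features table (for example
#' a presence/absence table of molecular-network nodes): first column is
#' the sample id, remaining columns are feature keys, cells are numeric.
#' Blank cells are imputed as 0 (feature absent).
#'
#' @param path CSV file path.
#' @param transform_tag tag recorded on the returned table (default
#'   `"raw"`; use `"presence_absence"` when reading a 0/1 node table).
#' @return A [bucket_table()].
#' @export
read_bucket_table <- function(path, transform_tag = "raw") {
  if (!file.exists(path)) stop_data(sprintf("file not found: '%s'", path))
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop_data(sprintf(
      "cannot parse CSV '%s': %s", path, conditionMessage(e))))
  if (ncol(df) < 1) stop_data(sprintf("'%s' has no columns", path))
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop_validation(sprintf(
      "duplicate sample id(s) in '%s': %s", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals == ""] <- "0"
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_data(sprintf(
      "non-numeric cell in '%s' at row %d, column '%s'", path, bad[1],
      colnames(vals)[bad[2]]))
  }
  bucket_table(num, sample_ids = ids, feature_keys = colnames(num),
               transform_tag = transform_tag)
}

#' Write a bucket table to CSV
#'
#' @param table a [bucket_table()].
#' @param path output CSV path.
#' @param id_column name of the first (sample id) column.
#' @return `path`, invisibly.
#' @export
write_bucket_table <- function(table, path, id_column = "sample_id") {
  df <- data.frame(rownames(table), unclass(table), check.names = FALSE,
                   row.names = NULL)
  names(df)[1] <- id_column
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group mapping from CSV
#'
#' @param path CSV with columns `sample_id,group` (header required).
#' @return Named character vector mapping sample id to group label.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(df)))
    stop_data(sprintf("'%s' must have columns sample_id,group", path))
  if (anyDuplicated(df$sample_id))
    stop_validation(sprintf("duplicate sample id(s) in '%s'", path))
  stats::setNames(df$group, df$sample_id)
}
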
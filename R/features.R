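#' Parameters controlling MS1 feature detection
#'
#' @param mz_tol m/z tolerance (Da) for associating a peak with an open
#'   extracted-ion trace. The trace centroid is a running
#'   intensity-weighted mean, so slow m/z drift is followed.
#' @param rt_tol retention-time tolerance (run rt units) used when
#'   consolidating features across samples.
#' @param min_height minimum apex intensity for a chromatographic peak.
#' @param min_scans minimum number of scan points a peak must span
#'   (peak-size criterion; rejects one-scan spikes).
#' @param max_gap_scans number of consecutive scans a trace may go
#'   without a member peak before it is closed.
#' @param edge_frac peak-shape criterion: integration boundaries extend
#'   outward from the apex until intensity drops below
#'   `edge_frac * apex_height` (or a local minimum separating two apices,
#'   or the trace end).
#'
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(mz_tol = 0.01, rt_tol = 0.2, min_height = 0,
                             min_scans = 3L, max_gap_scans = 1L,
                             edge_frac = 0.01) {
  if (mz_tol <= 0) stop_validation("mz_tol must be > 0")
  if (rt_tol < 0) stop_validation("rt_tol must be >= 0")
  if (min_height < 0) stop_validation("min_height must be >= 0")
  if (min_scans < 1) stop_validation("min_scans must be >= 1")
  if (max_gap_scans < 0) stop_validation("max_gap_scans must be >= 0")
  if (edge_frac <= 0 || edge_frac > 1)
    stop_validation("edge_frac must be in (0, 1]")
  structure(list(mz_tol = mz_tol, rt_tol = rt_tol, min_height = min_height,
                 min_scans = as.integer(min_scans),
                 max_gap_scans = as.integer(max_gap_scans),
                 edge_frac = edge_frac),
            class = "detection_params")
}

#' Extract ion chromatogram traces from a run
#'
#' Greedy trace building over the MS1 scans in retention-time order:
#' every peak joins the open trace whose running intensity-weighted mean
#' m/z lies within `mz_tol` (nearest centroid wins; ties go to the
#' lower-m/z trace), otherwise it opens a new trace. A trace accepts at
#' most one peak per scan, so a trace is a proper chromatogram (one
#' intensity per scan); a second same-scan peak within tolerance takes
#' the next eligible trace or opens a new one. A trace is closed after
#' `max_gap_scans` consecutive scans without a member. Every input peak
#' belongs to exactly one trace.
#'
#' @param run an [ms_run()] with MS1 scans.
#' @param params a [detection_params()] object.
#' @return List of traces; each trace is a data frame with columns
#'   `scan_index`, `rt`, `mz`, `intensity`, ordered by scan.
#' @export
extract_eics <- function(run, params) {
  stopifnot(inherits(params, "detection_params"))
  scans <- run_scans_at_level(run, 1L)
  if (length(scans) == 0)
    stop_data(sprintf("run '%s' has no MS1 scans", run$sample_id))

  # open-trace state, kept in parallel vectors for speed
  cap <- 256L
  t_wmz <- numeric(cap)    # sum(intensity * mz)
  t_w <- numeric(cap)      # sum(intensity)
  t_last <- integer(cap)   # scan position of last member
  t_pts <- vector("list", cap)
  t_open <- logical(cap)
  t_id <- integer(cap)     # creation order, for stable output
  n_tr <- 0L
  closed <- list()

  grow <- function() {
    cap2 <- cap * 2L
    t_wmz <<- c(t_wmz, numeric(cap)); t_w <<- c(t_w, numeric(cap))
    t_last <<- c(t_last, integer(cap)); t_pts <<- c(t_pts, vector("list", cap))
    t_open <<- c(t_open, logical(cap)); t_id <<- c(t_id, integer(cap))
    cap <<- cap2
  }

  for (p in seq_along(scans)) {
    s <- scans[[p]]
    if (length(s$mz)) {
      open_idx <- which(t_open[seq_len(n_tr)])
      cents <- if (length(open_idx)) t_wmz[open_idx] / t_w[open_idx]
               else numeric(0)
      for (j in seq_along(s$mz)) {
        mzj <- s$mz[j]; intj <- s$intensity[j]
        tr <- 0L
        if (length(open_idx)) {
          dd <- abs(cents - mzj)
          ok <- which(dd <= params$mz_tol & t_last[open_idx] != p)
          if (length(ok)) {
            best <- ok[order(dd[ok], cents[ok])][1]  # nearest, tie: lower m/z
            tr <- open_idx[best]
            cents[best] <- (t_wmz[tr] + intj * mzj) / (t_w[tr] + intj)
          }
        }
        if (tr == 0L) {
          if (n_tr == cap) grow()
          n_tr <- n_tr + 1L
          tr <- n_tr
          t_open[tr] <- TRUE; t_id[tr] <- n_tr
          t_wmz[tr] <- 0; t_w[tr] <- 0; t_pts[tr] <- list(NULL)
          open_idx <- c(open_idx, tr)
          cents <- c(cents, mzj)
        }
        t_wmz[tr] <- t_wmz[tr] + intj * mzj
        t_w[tr] <- t_w[tr] + intj
        t_last[tr] <- p
        t_pts[[tr]] <- c(t_pts[[tr]],
                         list(c(s$scan_index, s$rt, mzj, intj)))
      }
    }
    # close traces that have been silent for more than max_gap_scans scans
    stale <- which(t_open[seq_len(n_tr)] &
                     (p - t_last[seq_len(n_tr)]) > params$max_gap_scans)
    if (length(stale)) t_open[stale] <- FALSE
  }

  out <- lapply(seq_len(n_tr), function(i) {
    m <- do.call(rbind, t_pts[[i]])
    data.frame(scan_index = as.integer(m[, 1]), rt = m[, 2], mz = m[, 3],
               intensity = m[, 4])
  })
  out
}

#' Detect and integrate MS1 chromatographic features
#'
#' Within each extracted-ion trace, local intensity maxima with height at
#' least `min_height` become peak apices. Integration boundaries extend
#' outward from each apex until the intensity falls below
#' `edge_frac * apex_height`, a local minimum separating two apices is
#' reached (the trace is split at the minimum), or the trace ends. Peaks
#' spanning fewer than `min_scans` points are discarded. The integration
#' value is the trapezoidal area of intensity over retention time; the
#' feature m/z is the intensity-weighted mean over the peak's points.
#'
#' @inheritParams extract_eics
#' @return Data frame with one row per feature: `sample_id`, `mz`,
#'   `rt_apex`, `rt_start`, `rt_end`, `height`, `area`.
#' @export
detect_features <- function(run, params) {
  traces <- extract_eics(run, params)
  res <- list()
  for (tr in traces) {
    y <- tr$intensity
    n <- length(y)
    # apices: rising edge of every local maximum (plateau -> first point)
    prev <- c(-Inf, y[-n])
    nxt <- c(y[-1], -Inf)
    apices <- which(y > prev & y >= nxt & y >= params$min_height)
    if (length(apices) == 0) next
    # valley between adjacent apices: leftmost minimum strictly between
    valleys <- integer(0)
    if (length(apices) > 1) {
      valleys <- vapply(seq_len(length(apices) - 1), function(k) {
        lo <- apices[k] + 1L; hi <- apices[k + 1] - 1L
        if (lo > hi) return(apices[k])       # adjacent apices: split at left
        seg <- lo:hi
        seg[which.min(y[seg])]
      }, integer(1))
    }
    for (k in seq_along(apices)) {
      a <- apices[k]
      thr <- params$edge_frac * y[a]
      left_lim <- if (k > 1) valleys[k - 1] else 1L
      right_lim <- if (k < length(apices)) valleys[k] else n
      L <- a
      while (L > left_lim && y[L - 1] >= thr) L <- L - 1L
      R <- a
      while (R < right_lim && y[R + 1] >= thr) R <- R + 1L
      if ((R - L + 1L) < params$min_scans) next
      idx <- L:R
      rts <- tr$rt[idx]; ys <- y[idx]
      area <- trapezoid(rts, ys)
      if (area <= 0) next
      res[[length(res) + 1L]] <- data.frame(
        sample_id = run$sample_id,
        mz = stats::weighted.mean(tr$mz[idx], ys),
        rt_apex = tr$rt[a], rt_start = rts[1], rt_end = rts[length(rts)],
        height = y[a], area = area)
    }
  }
  if (length(res) == 0)
    return(data.frame(sample_id = character(0), mz = numeric(0),
                      rt_apex = numeric(0), rt_start = numeric(0),
                      rt_end = numeric(0), height = numeric(0),
                      area = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$mz, out$rt_apex), , drop = FALSE]
}

trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Consolidate per-sample features into a bucket table
#'
#' Greedy clustering of the pooled features: features are sorted by area
#' (descending; ties by lower m/z, then lower rt), the highest-area
#' unassigned feature seeds a consolidated feature, and from each sample
#' the highest-area unassigned feature within `mz_tol` and `rt_tol` of
#' the seed is absorbed (at most one per sample, so a bucket cell holds a
#' single integration value). The consolidated key is the area-weighted
#' mean (m/z, rt) of the members, rendered as `"mz@rt"`. Every feature is
#' assigned exactly once.
#'
#' @param features_by_sample named list mapping sample id to a feature
#'   data frame as returned by [detect_features()], or a single pooled
#'   data frame with a `sample_id` column.
#' @param mz_tol,rt_tol consolidation tolerances (> 0), in Da and run rt
#'   units.
#' @return A [bucket_table()] with one row per sample (samples with no
#'   features get all-zero rows) and columns sorted by m/z then rt.
#' @export
consolidate <- function(features_by_sample, mz_tol, rt_tol) {
  if (mz_tol <= 0 || rt_tol <= 0)
    stop_validation("consolidation tolerances must be > 0")
  if (is.data.frame(features_by_sample)) {
    pool <- features_by_sample
    sample_ids <- unique(pool$sample_id)
  } else {
    sample_ids <- names(features_by_sample)
    if (is.null(sample_ids))
      stop_validation("features_by_sample must be a named list")
    pool <- do.call(rbind, c(features_by_sample, list(make.row.names = FALSE)))
  }
  if (is.null(pool) || nrow(pool) == 0) {
    warning("no features to consolidate; returning an empty bucket table")
    return(bucket_table(matrix(numeric(0), nrow = length(sample_ids),
                               ncol = 0,
                               dimnames = list(sample_ids, NULL))))
  }
  ord <- order(-pool$area, pool$mz, pool$rt_apex)
  assigned <- logical(nrow(pool))
  cols <- list()
  for (i in ord) {
    if (assigned[i]) next
    near <- which(!assigned &
                    abs(pool$mz - pool$mz[i]) <= mz_tol &
                    abs(pool$rt_apex - pool$rt_apex[i]) <= rt_tol)
    # at most one member per sample: highest area, ties lower mz then rt
    members <- integer(0)
    for (sid in unique(pool$sample_id[near])) {
      cand <- near[pool$sample_id[near] == sid]
      cand <- cand[order(-pool$area[cand], pool$mz[cand],
                         pool$rt_apex[cand])]
      members <- c(members, cand[1])
    }
    assigned[members] <- TRUE
    w <- pool$area[members]
    cols[[length(cols) + 1L]] <- list(
      mz = stats::weighted.mean(pool$mz[members], w),
      rt = stats::weighted.mean(pool$rt_apex[members], w),
      sample_id = pool$sample_id[members], area = pool$area[members])
  }
  mzc <- vapply(cols, `[[`, numeric(1), "mz")
  rtc <- vapply(cols, `[[`, numeric(1), "rt")
  o <- order(mzc, rtc)
  cols <- cols[o]; mzc <- mzc[o]; rtc <- rtc[o]
  vals <- matrix(0, nrow = length(sample_ids), ncol = length(cols),
                 dimnames = list(sample_ids,
                                 format_feature_key(mzc, rtc)))
  for (j in seq_along(cols)) {
    vals[cols[[j]]$sample_id, j] <- cols[[j]]$area
  }
  bucket_table(vals, feature_mz = mzc, feature_rt = rtc)
}

#' Transform a bucket table
#'
#' @param table a [bucket_table()].
#' @param method `"raw"` (identity), `"log10p1"` (`log10(x + 1)`),
#'   `"tic"` (each row divided by its sum; all-zero rows stay zero), or
#'   `"presence_absence"` (1 where x > 0).
#' @return The transformed [bucket_table()] with its `transform_tag`
#'   updated.
#' @export
transform_bucket <- function(table, method = c("raw", "log10p1", "tic",
                                               "presence_absence")) {
  if (length(method) == 1 && !method %in% c("raw", "log10p1", "tic",
                                            "presence_absence"))
    stop_usage(sprintf("unknown transform method '%s'", method))
  method <- match.arg(method)
  vals <- unclass(table)
  attrs <- attributes(table)
  vals <- switch(method,
    raw = vals,
    log10p1 = log10(vals + 1),
    tic = {
      rs <- rowSums(vals)
      rs[rs == 0] <- 1
      vals / rs
    },
    presence_absence = (vals > 0) + 0)
  bucket_table(vals, feature_mz = attrs$feature_mz,
               feature_rt = attrs$feature_rt, transform_tag = method)
}

#' Write detected features to CSV
#'
#' @param features data frame from [detect_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a detected-features CSV
#'
#' @param path CSV written by [write_features()].
#' @return Feature data frame.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, colClasses = c(sample_id = "character"))
  need <- c("sample_id", "mz", "rt_apex", "rt_start", "rt_end", "height",
            "area")
  if (!all(need %in% names(df)))
    stop_data(sprintf("'%s' is not a feature table (missing columns %s)",
                      path, paste(setdiff(need, names(df)), collapse = ",")))
  df
}
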
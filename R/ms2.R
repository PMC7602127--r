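#' Parameters for the MS2 analog-family workflow
#'
#' @param bin_oom number of decimal places to which precursor m/z is
#'   rounded when binning (0 = unit-mass bins, matching low-resolution
#'   ion-trap data; 1 = 0.1-Da bins, and so on).
#' @param fragment_filter_mz m/z of the diagnostic fragment ion that
#'   defines the analog family (e.g. 168 for a shared core fragment).
#' @param fragment_tol tolerance (Da) when searching scans for the
#'   diagnostic fragment; default 0.5 Da suits unit-resolution data.
#' @param cluster_cutoff cosine-distance height at which the within-bin
#'   scan dendrogram is cut (default 0.15).
#' @param fragment_bin_width width (Da) of the fixed m/z grid, anchored
#'   at 0, onto which fragment spectra are accumulated before cosine
#'   comparison (default 1.0 Da).
#' @param consensus_min_fraction minimum fraction of a cluster's scans in
#'   which a fragment bin must appear to be retained in the consensus
#'   spectrum (default 0.5).
#' @return An object of class `ms2_params`.
#' @export
ms2_params <- function(bin_oom = 0L, fragment_filter_mz = 168,
                       fragment_tol = 0.5, cluster_cutoff = 0.15,
                       fragment_bin_width = 1.0,
                       consensus_min_fraction = 0.5) {
  if (fragment_tol <= 0) stop_validation("fragment_tol must be > 0")
  if (cluster_cutoff < 0 || cluster_cutoff > 1)
    stop_validation("cluster_cutoff must be in [0, 1]")
  if (fragment_bin_width <= 0)
    stop_validation("fragment_bin_width must be > 0")
  if (consensus_min_fraction <= 0 || consensus_min_fraction > 1)
    stop_validation("consensus_min_fraction must be in (0, 1]")
  structure(list(bin_oom = as.integer(bin_oom),
                 fragment_filter_mz = fragment_filter_mz,
                 fragment_tol = fragment_tol,
                 cluster_cutoff = cluster_cutoff,
                 fragment_bin_width = fragment_bin_width,
                 consensus_min_fraction = consensus_min_fraction),
            class = "ms2_params")
}

# round half up (not banker's rounding) to d decimal places
round_half_up <- function(x, d = 0L) floor(x * 10^d + 0.5) / 10^d

#' Bin MS2 scans by precursor mass
#'
#' Each scan is assigned to the bin whose key is its precursor m/z
#' rounded half-up to `bin_oom` decimal places; the bins partition the
#' input.
#'
#' @param scans list of MS2 [ms_scan()] objects.
#' @param bin_oom decimal places for rounding (0 = integer bins).
#' @return List of precursor bins, ordered by key; each is a list with
#'   `bin_key` (numeric) and `scans`.
#' @export
bin_by_precursor <- function(scans, bin_oom = 0L) {
  lv <- vapply(scans, `[[`, integer(1), "ms_level")
  if (any(lv != 2L))
    stop_validation("bin_by_precursor expects MS2 scans only")
  prec <- vapply(scans, `[[`, numeric(1), "precursor_mz")
  key <- round_half_up(prec, bin_oom)
  uk <- sort(unique(key))
  lapply(uk, function(k)
    list(bin_key = k, scans = scans[key == k]))
}

#' Keep only precursor bins containing a diagnostic fragment
#'
#' A bin is retained iff at least one member scan has a fragment peak
#' within `[fragment_mz - tol, fragment_mz + tol]`. Bins and scans are
#' otherwise unmodified, so the output is a subset of the input.
#'
#' @param bins list of precursor bins from [bin_by_precursor()].
#' @param fragment_mz diagnostic fragment m/z.
#' @param tol search tolerance in Da (> 0).
#' @return Filtered list of bins.
#' @export
filter_bins_by_fragment <- function(bins, fragment_mz, tol) {
  if (tol <= 0) stop_validation("tol must be > 0")
  keep <- vapply(bins, function(b)
    any(vapply(b$scans, function(s)
      any(abs(s$mz - fragment_mz) <= tol), logical(1))), logical(1))
  bins[keep]
}

# accumulate a fragment spectrum onto the fixed bin grid anchored at 0;
# returns named vector (names = integer bin indices)
bin_spectrum <- function(scan, width) {
  idx <- floor(scan$mz / width)
  v <- tapply(scan$intensity, idx, sum)
  stats::setNames(as.numeric(v), names(v))
}

#' Cosine distance between two fragment spectra
#'
#' Fragment peaks are accumulated into fixed m/z bins of width
#' `fragment_bin_width` anchored at 0, and the distance is 1 minus the
#' cosine similarity of the binned intensity vectors.
#'
#' @param a,b MS2 [ms_scan()] objects with at least one peak each.
#' @param fragment_bin_width bin width in Da.
#' @return Distance in `[0, 1]`.
#' @export
scan_cosine_distance <- function(a, b, fragment_bin_width = 1.0) {
  if (length(a$mz) == 0 || length(b$mz) == 0)
    stop_validation("cannot compute cosine distance for an empty scan")
  va <- bin_spectrum(a, fragment_bin_width)
  vb <- bin_spectrum(b, fragment_bin_width)
  bins <- union(names(va), names(vb))
  xa <- stats::setNames(numeric(length(bins)), bins)
  xb <- xa
  xa[names(va)] <- va
  xb[names(vb)] <- vb
  d <- 1 - sum(xa * xb) / (sqrt(sum(xa^2)) * sqrt(sum(xb^2)))
  min(max(d, 0), 1)
}

#' Cluster the scans of one precursor bin
#'
#' Average-linkage hierarchical clustering on pairwise fragment-spectrum
#' cosine distances, cut at height `cutoff`. A singleton bin yields one
#' singleton cluster; the clusters partition the bin.
#'
#' @param bin a precursor bin (list with `scans`).
#' @param cutoff cosine-distance cut height.
#' @param fragment_bin_width bin width passed to
#'   [scan_cosine_distance()].
#' @return List of clusters, each a list of scans.
#' @export
cluster_scans <- function(bin, cutoff = 0.15, fragment_bin_width = 1.0) {
  scans <- bin$scans
  n <- length(scans)
  if (n == 0) stop_validation("cannot cluster an empty precursor bin")
  if (n == 1) return(list(scans))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- scan_cosine_distance(scans[[i]], scans[[j]],
                                                 fragment_bin_width)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, h = cutoff)
  lapply(sort(unique(grp)), function(g) scans[grp == g])
}

#' Consensus spectrum of a scan cluster
#'
#' Fragment bins present in at least `min_fraction` of the member scans
#' are retained; the consensus peak m/z is the intensity-weighted mean
#' of the contributing peaks and its intensity the mean of the per-scan
#' relative intensities (each scan normalized to max 1), re-normalized so
#' the strongest consensus peak is 1.
#'
#' @param cluster non-empty list of MS2 scans.
#' @param fragment_bin_width bin width in Da.
#' @param min_fraction minimum member fraction for a bin (in (0, 1]).
#' @return An object of class `consensus_spectrum`: list with
#'   `n_members` and `peaks` (data frame `mz`, `intensity`, `fraction`).
#' @export
consensus_spectrum <- function(cluster, fragment_bin_width = 1.0,
                               min_fraction = 0.5) {
  n <- length(cluster)
  if (n == 0) stop_validation("cannot build a consensus of zero scans")
  # per scan: bin -> (sum intensity, sum mz*intensity, relative intensity)
  acc_w <- acc_wm <- acc_rel <- acc_n <- list()
  for (s in cluster) {
    if (length(s$mz) == 0)
      stop_validation("cannot build a consensus from an empty scan")
    idx <- as.character(floor(s$mz / fragment_bin_width))
    w <- tapply(s$intensity, idx, sum)
    wm <- tapply(s$intensity * s$mz, idx, sum)
    rel <- w / max(w)
    for (b in names(w)) {
      acc_w[[b]] <- c(acc_w[[b]], w[[b]])
      acc_wm[[b]] <- c(acc_wm[[b]], wm[[b]])
      acc_rel[[b]] <- c(acc_rel[[b]], rel[[b]])
    }
  }
  bins <- names(acc_w)
  frac <- vapply(bins, function(b) length(acc_w[[b]]) / n, numeric(1))
  keep <- bins[frac >= min_fraction]
  if (length(keep) == 0) {
    peaks <- data.frame(mz = numeric(0), intensity = numeric(0),
                        fraction = numeric(0))
  } else {
    mz <- vapply(keep, function(b) sum(acc_wm[[b]]) / sum(acc_w[[b]]),
                 numeric(1))
    it <- vapply(keep, function(b) mean(acc_rel[[b]]), numeric(1))
    it <- it / max(it)
    o <- order(mz)
    peaks <- data.frame(mz = unname(mz[o]), intensity = unname(it[o]),
                        fraction = unname(frac[keep][o]))
  }
  structure(list(n_members = n, peaks = peaks),
            class = "consensus_spectrum")
}

#' Run the full MS2 analog-family workflow
#'
#' Pools the MS2 scans of the input runs, bins them by precursor mass,
#' keeps the bins containing the diagnostic fragment, clusters each
#' retained bin's scans by cosine distance, and emits one consensus
#' spectrum per cluster together with a summary report.
#'
#' @param runs a single [ms_run()] or a list of runs containing MS2
#'   scans.
#' @param params an [ms2_params()] object.
#' @return List with `consensus` (list of `consensus_spectrum` objects,
#'   each carrying `bin_key` and `cluster_id`), `report` (data frame:
#'   `bin_key`, `n_scans`, `n_clusters`, `n_consensus_peaks` -- one row
#'   per retained bin), and `n_bins_total` (bin count before the
#'   diagnostic-fragment filter).
#' @export
run_ms2_pipeline <- function(runs, params = ms2_params()) {
  stopifnot(inherits(params, "ms2_params"))
  if (inherits(runs, "ms_run")) runs <- list(runs)
  scans <- unlist(lapply(runs, run_scans_at_level, 2L), recursive = FALSE)
  if (length(scans) == 0)
    stop_data("no MS2 scans in the input run(s)")
  bins <- bin_by_precursor(scans, params$bin_oom)
  kept <- filter_bins_by_fragment(bins, params$fragment_filter_mz,
                                  params$fragment_tol)
  consensus <- list()
  rep_rows <- list()
  for (b in kept) {
    clusters <- cluster_scans(b, params$cluster_cutoff,
                              params$fragment_bin_width)
    npk <- integer(length(clusters))
    for (ci in seq_along(clusters)) {
      cs <- consensus_spectrum(clusters[[ci]], params$fragment_bin_width,
                               params$consensus_min_fraction)
      cs$bin_key <- b$bin_key
      cs$cluster_id <- ci
      npk[ci] <- nrow(cs$peaks)
      consensus[[length(consensus) + 1L]] <- cs
    }
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      bin_key = b$bin_key, n_scans = length(b$scans),
      n_clusters = length(clusters), n_consensus_peaks = sum(npk))
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows)
    else data.frame(bin_key = numeric(0), n_scans = integer(0),
                    n_clusters = integer(0), n_consensus_peaks = integer(0))
  list(consensus = consensus, report = report, n_bins_total = length(bins))
}

#' Write consensus spectra as MGF
#'
#' One `BEGIN IONS`/`END IONS` entry per consensus spectrum, with
#' `PEPMASS` set to the precursor bin key.
#'
#' @param consensus list of `consensus_spectrum` objects (as produced by
#'   [run_ms2_pipeline()]).
#' @param path output MGF path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(consensus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cs in consensus) {
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE=bin_%s_cluster_%d",
                         format(cs$bin_key, trim = TRUE), cs$cluster_id),
                 sprintf("PEPMASS=%s", format(cs$bin_key, trim = TRUE)),
                 "CHARGE=1+",
                 sprintf("%.4f %.6f", cs$peaks$mz, cs$peaks$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}
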
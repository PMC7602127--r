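#' Configuration for the synthetic LC-MS(/MS) generator
#'
#' The generator emulates a chemogeographic study design: several sample
#' groups (collection regions), metabolites shared by every group plus
#' group-specific metabolites, Gaussian chromatographic elution profiles
#' with additive baseline noise, and -- for MS2 -- a family of structural
#' analogs whose fragment spectra share a diagnostic core fragment among
#' unrelated decoy precursors.
#'
#' @param seed integer seed; a fixed seed makes the generator fully
#'   deterministic.
#' @param n_groups number of sample groups (default 5 regions).
#' @param samples_per_group samples per group (default 3).
#' @param shared_features metabolites present in every group (default 30).
#' @param specific_features_per_group metabolites unique to each group
#'   (default 10).
#' @param mz_range,rt_range m/z (Th) and retention-time (minutes)
#'   intervals features are drawn from.
#' @param peak_sigma_scans chromatographic peak width (Gaussian sigma) in
#'   scan intervals (default 3).
#' @param apex_intensity_range apex intensity interval; with the default
#'   noise level the minimum gives a signal-to-baseline ratio of 100.
#' @param baseline_noise_sd standard deviation of the additive baseline
#'   noise (half-normal, floored at 0).
#' @param dropout_prob probability that a planted feature is missing from
#'   a given sample (default 0.05).
#' @param scans_per_run number of MS1 scans per run (default 240).
#' @param noise_peaks_per_scan random noise peaks added to each scan.
#' @param mz_jitter_sd per-point mass jitter (Da) around the true feature
#'   m/z, exercising the running-centroid trace builder.
#' @param min_mz_sep,min_rt_sep resolvability constraint: two features
#'   may not be closer than `min_mz_sep` in m/z while also closer than
#'   `min_rt_sep` in rt. A configuration that cannot be placed is
#'   rejected.
#' @param ms2_family optional list configuring the MS2 dataset:
#'   `n_analogs`, `core_fragments` (shared fragment m/z values, the first
#'   being the diagnostic one), `side_fragments_per_analog`,
#'   `n_decoy_precursors`, `scans_per_precursor`, `intensity_jitter`
#'   (relative sd), `decoy_fragments`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_groups = 5L, samples_per_group = 3L,
                       shared_features = 30L,
                       specific_features_per_group = 10L,
                       mz_range = c(200, 800), rt_range = c(1, 20),
                       peak_sigma_scans = 3,
                       apex_intensity_range = c(1e5, 1e6),
                       baseline_noise_sd = 1e3, dropout_prob = 0.05,
                       scans_per_run = 240L, noise_peaks_per_scan = 10L,
                       mz_jitter_sd = 0.002,
                       min_mz_sep = 0.05, min_rt_sep = 1.0,
                       ms2_family = NULL) {
  if (n_groups < 1 || samples_per_group < 1)
    stop_validation("n_groups and samples_per_group must be >= 1")
  if (shared_features < 0 || specific_features_per_group < 0)
    stop_validation("feature counts must be >= 0")
  if (diff(mz_range) <= 0 || diff(rt_range) <= 0)
    stop_validation("mz_range and rt_range must be non-degenerate")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop_validation("dropout_prob must be in [0, 1)")
  if (scans_per_run < 10) stop_validation("scans_per_run must be >= 10")
  if (!is.null(ms2_family)) {
    defaults <- list(n_analogs = 5L, core_fragments = c(168.102, 96.081),
                     side_fragments_per_analog = 3L,
                     n_decoy_precursors = 20L, scans_per_precursor = 4L,
                     intensity_jitter = 0.1, decoy_fragments = 6L)
    ms2_family <- utils::modifyList(defaults, ms2_family)
  }
  structure(list(seed = as.integer(seed), n_groups = as.integer(n_groups),
                 samples_per_group = as.integer(samples_per_group),
                 shared_features = as.integer(shared_features),
                 specific_features_per_group =
                   as.integer(specific_features_per_group),
                 mz_range = mz_range, rt_range = rt_range,
                 peak_sigma_scans = peak_sigma_scans,
                 apex_intensity_range = apex_intensity_range,
                 baseline_noise_sd = baseline_noise_sd,
                 dropout_prob = dropout_prob,
                 scans_per_run = as.integer(scans_per_run),
                 noise_peaks_per_scan = as.integer(noise_peaks_per_scan),
                 mz_jitter_sd = mz_jitter_sd, min_mz_sep = min_mz_sep,
                 min_rt_sep = min_rt_sep, ms2_family = ms2_family),
            class = "sim_config")
}

# draw feature (mz, rt) positions subject to the resolvability constraint
place_features <- function(n, config, existing_mz = numeric(0),
                           existing_rt = numeric(0)) {
  mz <- existing_mz; rt <- existing_rt
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:1000) {
      m <- stats::runif(1, config$mz_range[1], config$mz_range[2])
      r <- stats::runif(1, config$rt_range[1] + 1,
                        config$rt_range[2] - 1)
      conflict <- any(abs(mz - m) < config$min_mz_sep &
                        abs(rt - r) < config$min_rt_sep)
      if (!conflict) { mz <- c(mz, m); rt <- c(rt, r); placed <- TRUE; break }
    }
    if (!placed)
      stop_validation(
        "infeasible configuration: cannot place features at the requested density")
  }
  keep <- setdiff(seq_along(mz), seq_along(existing_mz))
  list(mz = mz[keep], rt = rt[keep])
}

#' Simulate a chemogeographic MS1 dataset with ground truth
#'
#' Each sample's chromatogram contains the shared features, its own
#' group's specific features (both as Gaussian elution profiles with
#' per-point mass jitter), and random baseline-noise peaks. Features are
#' independently dropped per sample with probability `dropout_prob`.
#' The ground truth records every emitted peak instance, with the true
#' area computed by trapezoidal integration of the exact emitted
#' intensity points.
#'
#' Draw order (fixed, so outputs are stable): feature positions (shared
#' then per group), then per sample in group-major order: per-feature
#' dropout, apex intensities, profile mass jitter, then per-scan noise
#' peaks.
#'
#' @param config a [sim_config()].
#' @return List with `runs` (list of [ms_run()], sample ids
#'   `g<group>_s<replicate>`), `truth` (list: `peaks` -- one row per
#'   planted peak instance with `sample_id`, `group`, `feature_id`,
#'   `mz`, `rt`, `height`, `area`; `features` -- the feature catalogue;
#'   `groups` -- named vector sample id -> group), and `config`.
#' @export
simulate_ms1_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_feat <- config$shared_features +
    config$n_groups * config$specific_features_per_group
  shared <- place_features(config$shared_features, config)
  feat_mz <- shared$mz; feat_rt <- shared$rt
  feat_group <- rep(NA_character_, config$shared_features)
  for (g in seq_len(config$n_groups)) {
    sp <- place_features(config$specific_features_per_group, config,
                         feat_mz, feat_rt)
    feat_mz <- c(feat_mz, sp$mz); feat_rt <- c(feat_rt, sp$rt)
    feat_group <- c(feat_group,
                    rep(paste0("g", g), config$specific_features_per_group))
  }
  features <- data.frame(
    feature_id = sprintf("F%03d", seq_len(n_feat)),
    kind = ifelse(is.na(feat_group), "shared", "specific"),
    group = feat_group, mz = feat_mz, rt = feat_rt)

  rts <- seq(config$rt_range[1], config$rt_range[2],
             length.out = config$scans_per_run)
  sigma_rt <- config$peak_sigma_scans * (rts[2] - rts[1])

  runs <- list()
  truth_rows <- list()
  groups <- character(0)
  for (g in seq_len(config$n_groups)) {
    glab <- paste0("g", g)
    active_kind <- features$kind == "shared" |
      (!is.na(features$group) & features$group == glab)
    for (s in seq_len(config$samples_per_group)) {
      sid <- sprintf("g%d_s%d", g, s)
      groups[sid] <- glab
      drop <- stats::runif(n_feat) < config$dropout_prob
      apex <- stats::runif(n_feat, config$apex_intensity_range[1],
                           config$apex_intensity_range[2])
      present <- which(active_kind & !drop)
      # per-scan peak pools
      scan_mz <- vector("list", config$scans_per_run)
      scan_int <- vector("list", config$scans_per_run)
      for (f in present) {
        prof <- apex[f] *
          exp(-(rts - features$rt[f])^2 / (2 * sigma_rt^2))
        sel <- which(abs(rts - features$rt[f]) <= 4 * sigma_rt &
                       prof > 0)
        if (length(sel) == 0) next
        jit <- stats::rnorm(length(sel), 0, config$mz_jitter_sd)
        for (ii in seq_along(sel)) {
          p <- sel[ii]
          scan_mz[[p]] <- c(scan_mz[[p]], features$mz[f] + jit[ii])
          scan_int[[p]] <- c(scan_int[[p]], prof[p])
        }
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          sample_id = sid, group = glab,
          feature_id = features$feature_id[f],
          mz = features$mz[f], rt = features$rt[f],
          height = max(prof[sel]), area = trapezoid(rts[sel], prof[sel]))
      }
      scans <- vector("list", config$scans_per_run)
      for (p in seq_len(config$scans_per_run)) {
        nmz <- stats::runif(config$noise_peaks_per_scan,
                            config$mz_range[1], config$mz_range[2])
        nint <- abs(stats::rnorm(config$noise_peaks_per_scan, 0,
                                 config$baseline_noise_sd))
        mzv <- c(scan_mz[[p]], nmz)
        inv <- c(scan_int[[p]], nint)
        o <- order(mzv)
        mzv <- mzv[o]; inv <- inv[o]
        # coincident m/z values (vanishingly rare) are merged
        if (anyDuplicated(mzv)) {
          inv <- as.numeric(tapply(inv, mzv, sum))
          mzv <- sort(unique(mzv))
        }
        scans[[p]] <- ms_scan(scan_index = p - 1L, ms_level = 1L,
                              rt = rts[p], mz = mzv, intensity = inv)
      }
      runs[[sid]] <- ms_run(sid, scans, "minutes")
    }
  }
  truth_peaks <- if (length(truth_rows)) do.call(rbind, truth_rows)
    else data.frame(sample_id = character(0), group = character(0),
                    feature_id = character(0), mz = numeric(0),
                    rt = numeric(0), height = numeric(0), area = numeric(0))
  list(runs = runs,
       truth = list(peaks = truth_peaks, features = features,
                    groups = groups),
       config = config)
}

#' Simulate an MS2 analog-family dataset with ground truth
#'
#' Emits replicate MS2 scans for `n_analogs` precursors that all contain
#' the shared core fragments (including the diagnostic one) plus
#' analog-specific side-chain fragments, and for `n_decoy_precursors`
#' precursors that lack the diagnostic fragment. Precursor bins (at unit
#' resolution) are all distinct, and replicate scans differ only by
#' multiplicative intensity jitter.
#'
#' @param config a [sim_config()] with a non-NULL `ms2_family`.
#' @return List with `runs` (a single-element list holding one
#'   [ms_run()] of MS2 scans), `truth` (list: `precursors` -- data frame
#'   with `precursor_mz`, `bin_key`, `kind` ("analog"/"decoy"),
#'   `analog_id`; `fragments` -- one row per planted fragment with
#'   `analog_id`, `role`, `mz`), and `config`.
#' @export
simulate_ms2_dataset <- function(config = sim_config(ms2_family = list())) {
  stopifnot(inherits(config, "sim_config"))
  fam <- config$ms2_family
  if (is.null(fam))
    stop_validation("config$ms2_family must be set for an MS2 simulation")
  set.seed(config$seed)
  n_prec <- fam$n_analogs + fam$n_decoy_precursors
  # distinct unit-mass bins, fractional offset away from the .5 boundary
  bins <- sample(seq(300L, 700L), n_prec)
  offs <- stats::runif(n_prec, -0.3, 0.3)
  prec_mz <- bins + offs
  kind <- rep(c("analog", "decoy"),
              c(fam$n_analogs, fam$n_decoy_precursors))
  analog_id <- ifelse(kind == "analog",
                      sprintf("A%02d", cumsum(kind == "analog")),
                      NA_character_)
  diag_mz <- fam$core_fragments[1]
  # fragment m/z values, kept out of the diagnostic fragment's unit bin
  draw_fragments <- function(n, lo, hi, forbid_diag = TRUE) {
    out <- numeric(0)
    while (length(out) < n) {
      f <- stats::runif(1, lo, hi)
      if (forbid_diag && abs(f - diag_mz) < 2) next
      if (any(abs(out - f) < 2)) next
      out <- c(out, f)
    }
    out
  }
  frag_rows <- list()
  spectra <- vector("list", n_prec)
  for (i in seq_len(n_prec)) {
    if (kind[i] == "analog") {
      side <- draw_fragments(fam$side_fragments_per_analog, 180,
                             prec_mz[i] - 20)
      fr <- c(fam$core_fragments, side)
      role <- c(rep("core", length(fam$core_fragments)),
                rep("side", length(side)))
    } else {
      fr <- draw_fragments(fam$decoy_fragments, 80, prec_mz[i] - 20)
      role <- rep("decoy", length(fr))
    }
    base <- stats::runif(length(fr), 0.2, 1) * 1e4
    o <- order(fr)
    spectra[[i]] <- list(mz = fr[o], base = base[o])
    frag_rows[[i]] <- data.frame(
      precursor_mz = prec_mz[i], analog_id = analog_id[i],
      role = role[o], mz = fr[o])
  }
  scans <- list()
  idx <- 0L
  for (i in seq_len(n_prec)) {
    for (r in seq_len(fam$scans_per_precursor)) {
      jit <- if (fam$intensity_jitter > 0)
        pmax(1 + stats::rnorm(length(spectra[[i]]$mz), 0,
                              fam$intensity_jitter), 0.05)
        else rep(1, length(spectra[[i]]$mz))
      scans[[length(scans) + 1L]] <- ms_scan(
        scan_index = idx, ms_level = 2L, rt = (idx + 1) * 0.02,
        mz = spectra[[i]]$mz, intensity = spectra[[i]]$base * jit,
        precursor_mz = prec_mz[i], precursor_intensity = 1e5)
      idx <- idx + 1L
    }
  }
  run <- ms_run("ms2_sim", scans, "minutes")
  list(runs = list(ms2_sim = run),
       truth = list(
         precursors = data.frame(precursor_mz = prec_mz,
                                 bin_key = round_half_up(prec_mz, 0),
                                 kind = kind, analog_id = analog_id),
         fragments = do.call(rbind, frag_rows)),
       config = config)
}
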
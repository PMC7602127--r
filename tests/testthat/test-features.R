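test_that("a single persistent ion gives exactly one trace", {
  scans <- lapply(1:10, function(i)
    ms_scan(i - 1L, 1L, i * 0.1, 457.31, 1000))
  run <- ms_run("one", scans)
  eics <- extract_eics(run, detection_params(mz_tol = 0.01))
  expect_length(eics, 1)
  expect_equal(nrow(eics[[1]]), 10)
})

test_that("co-eluting ions separated by >> mz_tol give disjoint traces", {
  scans <- lapply(1:10, function(i)
    ms_scan(i - 1L, 1L, i * 0.1, c(457.31, 458.31), c(1000, 800)))
  run <- ms_run("two", scans)
  eics <- extract_eics(run, detection_params(mz_tol = 0.01))
  expect_length(eics, 2)
  expect_true(all(vapply(eics, nrow, integer(1)) == 10))
  # each trace holds a single ion species
  expect_lt(max(vapply(eics, function(e) diff(range(e$mz)), numeric(1))),
            0.01)
})

test_that("running-centroid chaining follows a drifting ion", {
  # m/z drifts 457.310 -> 457.316 in steps of 0.0012 while the peak
  # rises x4 per scan, so the intensity-weighted centroid tracks the
  # newest points and each step stays within mz_tol = 0.002 of it, even
  # though the total drift (0.006) exceeds the tolerance (hand-simulated
  # against the greedy rule)
  mzs <- 457.310 + 0.0012 * (0:5)
  scans <- lapply(1:6, function(i)
    ms_scan(i - 1L, 1L, i * 0.1, mzs[i], 10 * 4^(i - 1)))
  run <- ms_run("drift", scans)
  eics <- extract_eics(run, detection_params(mz_tol = 0.002))
  expect_length(eics, 1)
  expect_equal(eics[[1]]$mz, mzs)
  # at equal intensities the running mean lags the drift: by scan 4 the
  # newest point is 0.0024 from the centroid and a second trace opens
  flat <- ms_run("flat", lapply(1:6, function(i)
    ms_scan(i - 1L, 1L, i * 0.1, mzs[i], 1000)))
  expect_length(extract_eics(flat, detection_params(mz_tol = 0.002)), 2)
})

test_that("traces close after max_gap_scans and a peak is one per scan", {
  # same ion present in scans 1-3 and 7-9 with a 3-scan silence
  present <- c(1:3, 7:9)
  scans <- lapply(1:9, function(i) {
    if (i %in% present) ms_scan(i - 1L, 1L, i * 0.1, 300.2, 500)
    else ms_scan(i - 1L, 1L, i * 0.1, numeric(0), numeric(0))
  })
  run <- ms_run("gap", scans)
  eics <- extract_eics(run, detection_params(max_gap_scans = 1L))
  expect_length(eics, 2)
  eics <- extract_eics(run, detection_params(max_gap_scans = 3L))
  expect_length(eics, 1)
  # two same-scan peaks within tolerance cannot share a trace
  twin <- ms_run("twin", lapply(1:5, function(i)
    ms_scan(i - 1L, 1L, i * 0.1, c(500.000, 500.004), c(900, 800))))
  eics <- extract_eics(twin, detection_params(mz_tol = 0.01))
  expect_length(eics, 2)
  expect_true(all(vapply(eics, function(e) !anyDuplicated(e$scan_index),
                         logical(1))))
})

test_that("every input peak lands in exactly one trace", {
  set.seed(42)
  scans <- lapply(1:30, function(i) {
    mz <- sort(runif(8, 100, 110))
    ms_scan(i - 1L, 1L, i * 0.1, mz, runif(8, 10, 1000))
  })
  run <- ms_run("cons", scans)
  eics <- extract_eics(run, detection_params(mz_tol = 0.05))
  expect_equal(sum(vapply(eics, nrow, integer(1))), 30 * 8)
})

test_that("a planted Gaussian peak is integrated to its trapezoid area", {
  fx <- gaussian_run(apex = 1e6, sigma_scans = 3)
  params <- detection_params(min_height = 1e4, edge_frac = 0.01)
  feats <- detect_features(fx$run, params)
  expect_equal(nrow(feats), 1)
  expect_equal(feats$height, 1e6)
  expect_equal(feats$rt_apex, fx$centre)
  # brute-force trapezoid over the planted intensities
  direct <- sum(diff(fx$rts) * (fx$prof[-1] + fx$prof[-length(fx$prof)]) / 2)
  expect_lt(abs(feats$area - direct) / direct, 0.05)
  expect_equal(feats$mz, fx$mz0, tolerance = 1e-9)
})

test_that("min_height and min_scans filter peaks", {
  fx <- gaussian_run(apex = 1e3)
  expect_equal(nrow(detect_features(fx$run,
                                    detection_params(min_height = 1e4))), 0)
  # a 2-scan blip is rejected when min_scans = 4
  scans <- lapply(1:6, function(i)
    ms_scan(i - 1L, 1L, i * 0.1,
            if (i %in% 3:4) 300.1 else numeric(0),
            if (i %in% 3:4) 5000 else numeric(0)))
  run <- ms_run("blip", scans)
  expect_equal(nrow(detect_features(run,
                                    detection_params(min_scans = 4L,
                                                     max_gap_scans = 0L))), 0)
  expect_equal(nrow(detect_features(run,
                                    detection_params(min_scans = 2L,
                                                     max_gap_scans = 0L))), 1)
})

test_that("overlapping peaks are split at the local minimum", {
  rts <- (0:40) * 0.1
  p1 <- 1e5 * exp(-(rts - 1.2)^2 / (2 * 0.3^2))
  p2 <- 8e4 * exp(-(rts - 2.6)^2 / (2 * 0.3^2))
  prof <- p1 + p2
  scans <- lapply(seq_along(rts), function(i)
    ms_scan(i - 1L, 1L, rts[i], 400.5, prof[i]))
  run <- ms_run("twopeak", scans)
  feats <- detect_features(run, detection_params(min_height = 1e4))
  expect_equal(nrow(feats), 2)
  expect_equal(sort(feats$rt_apex), c(1.2, 2.6), tolerance = 0.05)
  valley <- rts[which.min(prof[rts > 1.2 & rts < 2.6]) + sum(rts <= 1.2)]
  expect_lte(feats$rt_end[which.min(feats$rt_apex)], valley + 0.11)
})

test_that("scaling all intensities scales every detected area", {
  fx <- gaussian_run(apex = 2e5)
  params <- detection_params(min_height = 1e4)
  f1 <- detect_features(fx$run, params)
  scaled <- ms_run("scaled", lapply(fx$run$scans, function(s)
    ms_scan(s$scan_index, 1L, s$rt, s$mz, s$intensity * 3)))
  f2 <- detect_features(scaled, params)
  expect_equal(f2$area, 3 * f1$area, tolerance = 1e-10)
  expect_equal(f2$rt_apex, f1$rt_apex)
})

test_that("consolidation merges within tolerance and separates outside", {
  f <- function(sid, mz, rt, area)
    data.frame(sample_id = sid, mz = mz, rt_apex = rt, rt_start = rt - 0.1,
               rt_end = rt + 0.1, height = area, area = area)
  three <- list(s1 = f("s1", 457.310, 5.0, 100),
                s2 = f("s2", 457.312, 5.05, 90),
                s3 = f("s3", 457.309, 4.95, 80))
  tab <- consolidate(three, mz_tol = 0.01, rt_tol = 0.2)
  expect_equal(ncol(tab), 1)
  expect_equal(sum(tab > 0), 3)

  apart <- list(s1 = rbind(f("s1", 457.310, 5.0, 100),
                           f("s1", 457.360, 5.0, 50)))
  tab <- consolidate(apart, mz_tol = 0.01, rt_tol = 0.2)
  expect_equal(ncol(tab), 2)
})

test_that("greedy chain A-B-C with A-C out of tolerance gives 2 columns", {
  f <- function(sid, mz, area)
    data.frame(sample_id = sid, mz = mz, rt_apex = 5, rt_start = 4.9,
               rt_end = 5.1, height = area, area = area)
  # A(s1)=300.000, B(s2)=300.008, C(s3)=300.016; tol 0.01
  chain <- list(s1 = f("s1", 300.000, 100), s2 = f("s2", 300.008, 90),
                s3 = f("s3", 300.016, 80))
  tab <- consolidate(chain, mz_tol = 0.01, rt_tol = 0.5)
  expect_equal(ncol(tab), 2)
  # A seeds and absorbs B; C is its own column
  expect_equal(sum(tab[, 1] > 0), 2)
  expect_equal(sum(tab[, 2] > 0), 1)
  expect_gt(tab["s3", 2], 0)
})

test_that("consolidation conserves features and is idempotent", {
  set.seed(99)
  for (trial in 1:5) {
    # resolvable features: true positions >= 4x the tolerance apart, each
    # sample observing them with sub-tolerance scatter
    true_mz <- 100 + (1:8) * 2
    true_rt <- 1 + (1:8) %% 4 * 4
    pool <- do.call(rbind, lapply(1:3, function(s) data.frame(
      sample_id = paste0("s", s),
      mz = true_mz + runif(8, -0.1, 0.1),
      rt_apex = true_rt + runif(8, -0.3, 0.3),
      rt_start = 0, rt_end = 0, height = 1,
      area = round(runif(8, 1, 1000), 1))))
    tab <- consolidate(pool, mz_tol = 0.5, rt_tol = 1.0)
    expect_equal(sum(tab > 0), nrow(pool))
    expect_lte(ncol(tab), nrow(pool))
    # re-consolidating the consolidated cells reproduces the columns
    redo <- do.call(rbind, lapply(rownames(tab), function(sid) {
      nz <- which(tab[sid, ] > 0)
      if (length(nz) == 0) return(NULL)
      data.frame(sample_id = sid, mz = attr(tab, "feature_mz")[nz],
                 rt_apex = attr(tab, "feature_rt")[nz],
                 rt_start = 0, rt_end = 0, height = 1,
                 area = unname(tab[sid, nz]))
    }))
    tab2 <- consolidate(redo, mz_tol = 0.5, rt_tol = 1.0)
    expect_equal(ncol(tab2), ncol(tab))
    expect_equal(unname(unclass(tab2) > 0), unname(unclass(tab) > 0))
  }
})

test_that("bucket transformations follow their definitions", {
  vals <- matrix(c(0, 3.5, 1e6, 2, 2, 4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("f1", "f2", "f3")))
  tab <- bucket_table(vals)
  pa <- transform_bucket(tab, "presence_absence")
  expect_equal(unname(pa["a", ]), c(0, 1, 1), ignore_attr = TRUE)
  tic <- transform_bucket(tab, "tic")
  expect_equal(unname(tic["b", ]), c(0.25, 0.25, 0.5), ignore_attr = TRUE)
  lg <- transform_bucket(tab, "log10p1")
  expect_equal(unname(lg["a", 1]), 0)
  expect_equal(unname(lg["b", 3]), log10(5))
  expect_identical(attr(pa, "transform_tag"), "presence_absence")
  expect_error(transform_bucket(tab, "sqrt"),
               class = "chemocomp_usage_error")
  # all-zero rows survive tic untouched
  z <- bucket_table(matrix(c(0, 0, 1, 3), nrow = 2, byrow = TRUE,
                           dimnames = list(c("z", "y"), c("f1", "f2"))))
  expect_equal(unname(transform_bucket(z, "tic")["z", ]), c(0, 0),
               ignore_attr = TRUE)
})
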
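# In-code fixtures shared across test files.

# a small MS1 run with one Gaussian peak planted on a flat trace
gaussian_run <- function(apex = 1e6, sigma_scans = 3, n_scans = 41,
                         mz0 = 457.31, rt_step = 0.1, sample_id = "fix") {
  rts <- (seq_len(n_scans) - 1) * rt_step
  centre <- rts[(n_scans + 1) / 2]
  prof <- apex * exp(-(rts - centre)^2 / (2 * (sigma_scans * rt_step)^2))
  scans <- lapply(seq_len(n_scans), function(i)
    ms_scan(i - 1L, 1L, rts[i], mz0, prof[i]))
  list(run = ms_run(sample_id, scans), rts = rts, prof = prof,
       centre = centre, mz0 = mz0)
}

# an MS2 scan with the given fragment peaks
frag_scan <- function(mz, intensity = rep(1, length(mz)), precursor = 400,
                      idx = 0L, rt = 0.1) {
  o <- order(mz)
  ms_scan(idx, 2L, rt, mz[o], intensity[o], precursor_mz = precursor)
}

# mixed-level 10-scan run for round-trip tests
mixed_run <- function() {
  scans <- list()
  for (i in 1:10) {
    if (i %% 2 == 1) {
      scans[[i]] <- ms_scan(i - 1L, 1L, i * 0.5,
                            c(150.1, 250.25, 350.333),
                            c(1000, 2500.5, 10))
    } else {
      scans[[i]] <- ms_scan(i - 1L, 2L, i * 0.5, c(81.07, 168.102),
                            c(5.5, 99.9), precursor_mz = 457.31,
                            precursor_intensity = 1e4)
    }
  }
  ms_run("mixed", scans)
}
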
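# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from first principles and do
# not call the package functions they are checking.

# Cophenetic correlation: explicit pairwise merge-height lookup plus the
# Pearson formula, from an hclust merge table.
oracle_cophenetic <- function(hc, dist_matrix) {
  n <- length(hc$labels)
  members <- lapply(seq_len(n), identity)      # leaves by index
  coph <- matrix(NA_real_, n, n)
  clusters <- list()
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(k) if (k < 0) -k else clusters[[k]]
    a <- get(hc$merge[i, 1]); b <- get(hc$merge[i, 2])
    for (x in a) for (y in b) coph[x, y] <- coph[y, x] <- hc$height[i]
    clusters[[i]] <- c(a, b)
  }
  dm <- as.matrix(dist_matrix)[hc$labels, hc$labels]
  iu <- upper.tri(coph)
  x <- dm[iu]; y <- coph[iu]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Precursor binning: independent rounding (string-free half-up via
# truncation) and set partition.
oracle_bin_keys <- function(precursors, d = 0) {
  f <- 10^d
  scaled <- precursors * f
  key <- (trunc(scaled) + as.integer(scaled - trunc(scaled) >= 0.5)) / f
  sort(unique(key))
}

# Consolidation: naive re-execution of the greedy rule with explicit
# loops over a pooled feature data frame (sample_id, mz, rt_apex, area).
oracle_consolidate <- function(pool, mz_tol, rt_tol) {
  pool <- pool[order(-pool$area, pool$mz, pool$rt_apex), , drop = FALSE]
  taken <- rep(FALSE, nrow(pool))
  cols <- list()
  repeat {
    seed <- which(!taken)[1]
    if (is.na(seed)) break
    members <- integer(0)
    for (sid in unique(pool$sample_id)) {
      best <- NA_integer_
      for (i in seq_len(nrow(pool))) {
        if (taken[i] || pool$sample_id[i] != sid) next
        if (abs(pool$mz[i] - pool$mz[seed]) > mz_tol) next
        if (abs(pool$rt_apex[i] - pool$rt_apex[seed]) > rt_tol) next
        if (is.na(best) ||
            pool$area[i] > pool$area[best] ||
            (pool$area[i] == pool$area[best] &&
             (pool$mz[i] < pool$mz[best] ||
              (pool$mz[i] == pool$mz[best] &&
               pool$rt_apex[i] < pool$rt_apex[best]))))
          best <- i
      }
      if (!is.na(best)) members <- c(members, best)
    }
    taken[members] <- TRUE
    w <- pool$area[members]
    cols[[length(cols) + 1L]] <- data.frame(
      mz = sum(pool$mz[members] * w) / sum(w),
      rt = sum(pool$rt_apex[members] * w) / sum(w),
      n = length(members))
  }
  out <- do.call(rbind, cols)
  out[order(out$mz, out$rt), , drop = FALSE]
}

# random small pooled feature table for consolidation trials
random_feature_pool <- function(n_samples, n_features) {
  pool <- expand.grid(s = seq_len(n_samples), f = seq_len(n_features))
  data.frame(
    sample_id = paste0("s", pool$s),
    mz = round(stats::runif(nrow(pool), 100, 110), 3),
    rt_apex = round(stats::runif(nrow(pool), 1, 10), 2),
    rt_start = 0, rt_end = 0, height = 1,
    area = round(stats::runif(nrow(pool), 1, 1000), 1))
}
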
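#' Pairwise cosine distances between samples
#'
#' `d(i, j) = 1 - (x_i . x_j) / (||x_i|| ||x_j||)` over the feature
#' vectors of a bucket table. Cosine distance ignores total signal scale,
#' which suits LC-MS profiles whose absolute intensities vary with sample
#' amount; for non-negative data it lies in `[0, 1]`.
#'
#' @param table a [bucket_table()] with at least 2 samples and no
#'   all-zero sample rows.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = sample
#'   ids.
#' @export
cosine_distance_matrix <- function(table) {
  x <- unclass(table)
  if (nrow(x) < 2) stop_validation("need at least 2 samples")
  nrm <- sqrt(rowSums(x^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop_validation(sprintf("sample(s) with all-zero feature vector: %s",
                            paste(rownames(x)[zero], collapse = ", ")))
  d <- 1 - tcrossprod(x / nrm)
  d[d < 0] <- 0
  d[d > 1 & d < 1 + 1e-12] <- 1
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of samples
#'
#' Average linkage (UPGMA) by default, the customary partner of
#' cophenetic validation; single and complete linkage are also offered.
#' The dendrogram is exported as a Newick string in which node heights
#' are half the merge distance, so the leaf-to-leaf path length through a
#' merge equals the merge distance.
#'
#' @param dist symmetric distance matrix with zero diagonal (for example
#'   from [cosine_distance_matrix()]).
#' @param linkage `"average"` (default), `"single"`, or `"complete"`.
#' @return An object of class `linkage_result`: list with elements
#'   `hclust` (the [stats::hclust] tree), `merge_table` (data frame with
#'   `node_a`, `node_b`, `merge_distance`, `cluster_size`), `leaf_labels`,
#'   `linkage`, and `newick`.
#' @export
hierarchical_cluster <- function(dist, linkage = c("average", "single",
                                                   "complete")) {
  linkage <- match.arg(linkage)
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist) || !isTRUE(all.equal(dist, t(dist),
                                                    tolerance = 1e-8)))
    stop_validation("distance matrix must be symmetric")
  if (any(abs(diag(dist)) > 1e-12))
    stop_validation("distance matrix must have a zero diagonal")
  if (nrow(dist) < 2) stop_validation("need at least 2 samples")
  if (is.null(rownames(dist)))
    rownames(dist) <- colnames(dist) <- paste0("S", seq_len(nrow(dist)))
  hc <- stats::hclust(stats::as.dist(dist), method = linkage)
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sz <- function(k) if (k < 0) 1L else sizes[k]
    sizes[i] <- sz(hc$merge[i, 1]) + sz(hc$merge[i, 2])
  }
  merge_table <- data.frame(node_a = hc$merge[, 1], node_b = hc$merge[, 2],
                            merge_distance = hc$height,
                            cluster_size = sizes)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, merge_table = merge_table,
                 leaf_labels = hc$labels, linkage = linkage,
                 newick = ape::write.tree(phy)),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("<linkage_result> %d leaves, %s linkage, max height %.4f\n",
              length(x$leaf_labels), x$linkage,
              max(x$merge_table$merge_distance)))
  invisible(x)
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (the merge height at which each pair of samples
#' first joins the same cluster). Values near 1 indicate that the
#' dendrogram faithfully represents the distance matrix; the coefficient
#' is exactly 1 iff the distances are ultrametric with respect to the
#' tree.
#'
#' @param linkage a `linkage_result` built from `dist`.
#' @param dist the distance matrix the tree was built from; at least 3
#'   samples (with 2 the correlation is undefined).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(linkage, dist) {
  stopifnot(inherits(linkage, "linkage_result"))
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 3)
    stop_validation("cophenetic correlation is undefined for fewer than 3 samples")
  dv <- stats::as.dist(dist)
  cv <- stats::cophenetic(linkage$hclust)
  # align on the tree's label order
  cv <- as.matrix(cv)[labels(dv), labels(dv)]
  cv <- stats::as.dist(cv)
  if (stats::sd(dv) == 0 || stats::sd(cv) == 0)
    stop_validation("cophenetic correlation is undefined: zero variance")
  stats::cor(as.vector(dv), as.vector(cv))
}

#' Rank features by between-group difference
#'
#' Per feature, a Kruskal-Wallis rank-sum test across the sample groups
#' (equivalent to a Wilcoxon rank-sum test for two groups); p-values are
#' corrected with Benjamini-Hochberg. Robust to the non-normal,
#' zero-inflated intensity distributions typical of untargeted
#' metabolomics. An ordinary one-way ANOVA F test is offered as an
#' alternative.
#'
#' @param table a [bucket_table()].
#' @param groups named character vector mapping every sample id of
#'   `table` to a group label; at least 2 groups with at least 2 samples
#'   each.
#' @param alpha nominal FDR level recorded on the result (default 0.05).
#' @param method `"kruskal"` (default) or `"anova"`.
#' @return An object of class `feature_ranking`: data frame with columns
#'   `feature_key`, `statistic`, `p_value`, `q_value`, `direction` (the
#'   group with the largest mean), sorted by statistic descending.
#' @export
select_features <- function(table, groups, alpha = 0.05,
                            method = c("kruskal", "anova")) {
  method <- match.arg(method)
  x <- unclass(table)
  if (is.null(names(groups)) || !all(rownames(x) %in% names(groups)))
    stop_validation("groups must be a named vector covering every sample")
  g <- factor(groups[rownames(x)])
  if (nlevels(g) < 2)
    stop_validation("need at least 2 groups")
  if (any(table(g) < 2))
    stop_validation(sprintf(
      "every group needs at least 2 samples (offending: %s)",
      paste(names(which(table(g) < 2)), collapse = ", ")))
  nfeat <- ncol(x)
  stat <- p <- numeric(nfeat)
  dirn <- character(nfeat)
  for (j in seq_len(nfeat)) {
    v <- x[, j]
    gm <- tapply(v, g, mean)
    dirn[j] <- names(gm)[which.max(gm)]
    if (length(unique(v)) == 1) {        # constant feature: exact null
      stat[j] <- 0; p[j] <- 1
    } else if (method == "kruskal") {
      kt <- stats::kruskal.test(v, g)
      stat[j] <- unname(kt$statistic); p[j] <- kt$p.value
    } else {
      ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
      stat[j] <- unname(ft$statistic)
      p[j] <- ft$p.value
      if (is.na(stat[j])) { stat[j] <- 0; p[j] <- 1 }
    }
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature_key = colnames(x), statistic = stat,
                    p_value = p, q_value = q, direction = dirn,
                    row.names = NULL)
  out <- out[order(-out$statistic, out$feature_key), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, alpha = alpha, method = method,
            class = c("feature_ranking", "data.frame"))
}

#' List the most prominent features
#'
#' Features ranked by their summed integration value across samples (or
#' within each group when `per_group` is given) -- the natural notion of
#' prominence when bucket cells hold peak areas. Ties are broken by
#' lower m/z. A ranking by per-sample maximum is available as an option.
#'
#' @param table a [bucket_table()].
#' @param n number of features to return (>= 1); when `n` exceeds the
#'   feature count all features are returned with a warning.
#' @param per_group optional named vector mapping sample id to group; if
#'   given, a separate ranking is produced within each group.
#' @param rank_by `"sum"` (default) or `"max"`.
#' @return A data frame with columns `feature_key`, `value`, and one
#'   column per sample with the underlying values; with `per_group`, a
#'   named list of such data frames.
#' @export
prominent_features <- function(table, n, per_group = NULL,
                               rank_by = c("sum", "max")) {
  rank_by <- match.arg(rank_by)
  if (n < 1) stop_usage("n must be >= 1")
  x <- unclass(table)
  mzs <- attr(table, "feature_mz")
  if (is.null(mzs)) mzs <- parse_feature_keys(colnames(x))$mz
  rank_one <- function(xm) {
    v <- if (rank_by == "sum") colSums(xm) else apply(xm, 2, max)
    o <- order(-v, mzs, colnames(xm))
    k <- min(n, ncol(xm))
    if (n > ncol(xm))
      warning(sprintf("n = %d exceeds the %d available features", n,
                      ncol(xm)))
    top <- o[seq_len(k)]
    data.frame(feature_key = colnames(xm)[top], value = unname(v[top]),
               t(xm[, top, drop = FALSE]), check.names = FALSE,
               row.names = NULL)
  }
  if (is.null(per_group)) return(rank_one(x))
  g <- factor(per_group[rownames(x)])
  out <- lapply(levels(g), function(lv) rank_one(x[g == lv, , drop = FALSE]))
  names(out) <- levels(g)
  out
}

#' Heat-map matrix in dendrogram leaf order
#'
#' Reorders the bucket table rows to the dendrogram leaf order (and
#' optionally the columns by feature m/z) for external plotting.
#'
#' @param table a [bucket_table()].
#' @param linkage a `linkage_result` over the same samples.
#' @return Numeric matrix.
#' @export
heatmap_matrix <- function(table, linkage) {
  stopifnot(inherits(linkage, "linkage_result"))
  x <- unclass(table)
  ord <- linkage$leaf_labels[linkage$hclust$order]
  x[ord, , drop = FALSE]
}
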
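# Clustering of differential-expression fold-change trajectories:
# Spearman-correlation distance with complete linkage for the dendrogram,
# k-means plus the gap statistic to choose the number of clusters, and
# per-cluster mean profiles for the downstream correlation stage.

#' Log2 fold-change profiles of differentially expressed features
#'
#' @param de result of [de_mirna()] or [de_mrna()].
#' @param features features to keep (default: the `de_any` set).
#' @return numeric matrix, features x contrasts (T2..T6, each vs T1).
#' @export
fold_change_profiles <- function(de, features = de$de_features) {
  de$profiles[features, , drop = FALSE]
}

#' Spearman correlation distance matrix
#'
#' `d(i, j) = 1 - rho_s(i, j)` where `rho_s` is the Pearson correlation of
#' within-profile ranks (average ranks on ties); `d` lies in `[0, 2]` with
#' a zero diagonal.
#'
#' @param profiles numeric matrix, features x timepoints (>= 2 rows).
#' @return symmetric distance matrix with the feature names.
#' @export
spearman_distance <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 profiles")
  constant <- apply(profiles, 1, function(x) length(unique(x)) == 1L)
  if (any(constant)) {
    stop("constant profile(s): rank correlation undefined for ",
         paste(rownames(profiles)[constant], collapse = ", "))
  }
  d <- 1 - stats::cor(t(profiles), method = "spearman")
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering merging, at each step, the two clusters with
#' the smallest maximum inter-point distance (via `stats::hclust`,
#' method `"complete"`; merge heights are non-decreasing and the result is
#' deterministic for a given distance matrix).
#'
#' @param d symmetric distance matrix (zero diagonal) or `dist` object.
#' @return an `hclust` object.
#' @export
complete_linkage_cluster <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) {
      stop("distance matrix must be symmetric")
    }
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix needs a zero diagonal")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "complete")
}

#' Choose the number of clusters by the gap statistic
#'
#' For `k = 1..k_max`, `Gap(k) = mean_b log(W*_kb) - log(W_k)` where `W_k`
#' is the within-cluster sum of squared distances from k-means (best of
#' `nstart` restarts) and the `B` reference data sets are drawn uniformly
#' over the per-dimension range of the data.  The chosen `k` is the
#' smallest `k` with `Gap(k) >= Gap(k+1) - s_{k+1}` (the original
#' one-standard-error rule).
#'
#' @param profiles numeric matrix, features x dimensions.
#' @param k_max largest number of clusters to evaluate (must be < nrow).
#' @param B number of reference data sets (>= 10).
#' @param rng_seed optional integer seed making the choice reproducible.
#' @param nstart k-means restarts per fit (default 25).
#' @return list with `k` (chosen number of clusters), `table` (the gap
#'   curve: `logW`, `E.logW`, `gap`, `SE.sim` per k) and `kmeans`
#'   (the k-means fit at the chosen k).
#' @export
gap_statistic_k <- function(profiles, k_max = 6L, B = 50L, rng_seed = NULL,
                            nstart = 25L) {
  profiles <- as.matrix(profiles)
  if (k_max >= nrow(profiles)) stop("k_max must be smaller than the number of profiles")
  if (B < 10L) stop("B must be at least 10")
  km <- function(x, k) suppressWarnings(stats::kmeans(x, k, nstart = nstart,
                                                      iter.max = 50L))
  run <- function() {
    gs <- cluster::clusGap(profiles, FUNcluster = km, K.max = k_max, B = B,
                           d.power = 2, spaceH0 = "original", verbose = FALSE)
    k <- cluster::maxSE(gs$Tab[, "gap"], gs$Tab[, "SE.sim"],
                        method = "Tibs2001SEmax")
    list(k = k, table = gs$Tab, kmeans = km(profiles, k))
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}

#' Cut the dendrogram and summarize clusters
#'
#' Cuts the complete-linkage tree into `k` groups, renumbers clusters in
#' order of first appearance along the dendrogram leaf order, and computes
#' the per-cluster arithmetic mean profile.
#'
#' @param hc an `hclust` object from [complete_linkage_cluster()].
#' @param profiles the profile matrix the tree was built from.
#' @param k number of clusters (`1 <= k <= nrow(profiles)`).
#' @return object of class `cluster_set`: list with `labels` (named integer
#'   vector in `1..k`), `k`, `means` (k x timepoints matrix) and
#'   `leaf_order` (permutation of features for heatmap display).
#' @export
cut_and_summarize <- function(hc, profiles, k) {
  profiles <- as.matrix(profiles)
  stopifnot(k >= 1L, k <= nrow(profiles))
  raw <- stats::cutree(hc, k = k)
  leaf <- hc$order
  relabel <- stats::setNames(seq_len(k), unique(raw[leaf]))
  labels <- stats::setNames(as.integer(relabel[as.character(raw)]), names(raw))
  means <- t(vapply(seq_len(k), function(cl) {
    colMeans(profiles[labels == cl, , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(means) <- as.character(seq_len(k))
  structure(list(labels = labels, k = k, means = means, leaf_order = leaf),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$labels), "features in", x$k, "clusters\n")
  print(table(x$labels))
  cat("mean profiles:\n")
  print(round(x$means, 2))
  invisible(x)
}

#' Heatmap of fold-change profiles ordered by the dendrogram
#'
#' Rows are features in dendrogram leaf order, annotated by cluster;
#' columns are the T2..T6 contrasts.  Requires the pheatmap package.
#'
#' @param profiles profile matrix.
#' @param cs `cluster_set` from [cut_and_summarize()].
#' @param file optional output path (PNG/PDF chosen from the extension).
#' @return the pheatmap object, invisibly.
#' @export
plot_profile_heatmap <- function(profiles, cs, file = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("pheatmap is required for heatmaps")
  }
  ord <- rownames(profiles)[cs$leaf_order]
  ann <- data.frame(cluster = factor(cs$labels[ord]), row.names = ord)
  ph <- pheatmap::pheatmap(profiles[ord, , drop = FALSE],
                           cluster_rows = FALSE, cluster_cols = FALSE,
                           annotation_row = ann, silent = !is.null(file),
                           filename = if (is.null(file)) NA else file)
  invisible(ph)
}
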
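# Integration of mRNA and miRNA expression: genes are annotated as
# positively or negatively correlated to each miRNA cluster's mean
# fold-change profile, with the +/-0.67 threshold applied strictly.

#' Expressed-miRNA filter
#'
#' Keeps features with a raw count strictly greater than `min_count` in at
#' least `ceiling(min_fraction * n_samples)` samples.
#'
#' @param counts integer count matrix, features x samples (raw counts).
#' @param min_count count threshold, strict (default 10).
#' @param min_fraction required fraction of samples (default 2/3).
#' @return character vector of retained feature names.
#' @export
expressed_filter <- function(counts, min_count = 10, min_fraction = 2 / 3) {
  counts <- as.matrix(counts)
  need <- ceiling(min_fraction * ncol(counts))
  rownames(counts)[rowSums(counts > min_count) >= need]
}

#' Correlation of gene profiles with cluster mean profiles
#'
#' @param gene_profiles numeric matrix, genes x timepoints (log2FC vs T1).
#' @param cluster_means numeric matrix, clusters x timepoints (same
#'   contrasts).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return numeric matrix of correlation coefficients, genes x clusters.
#'   Zero-variance gene profiles give `NA` with a warning.
#' @export
gene_cluster_correlation <- function(gene_profiles, cluster_means,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  gene_profiles <- as.matrix(gene_profiles)
  cluster_means <- as.matrix(cluster_means)
  if (ncol(gene_profiles) != ncol(cluster_means)) {
    stop("gene and cluster profiles must cover the same contrasts")
  }
  zv <- apply(gene_profiles, 1, stats::sd) == 0
  if (any(zv)) {
    warning("zero-variance gene profile(s): ",
            paste(utils::head(rownames(gene_profiles)[zv], 5), collapse = ", "))
  }
  r <- suppressWarnings(
    stats::cor(t(gene_profiles), t(cluster_means), method = method))
  rownames(r) <- rownames(gene_profiles)
  colnames(r) <- rownames(cluster_means)
  r
}

#' Annotate correlation directions per gene and cluster
#'
#' A gene is `negative` to a cluster iff `r < -threshold` and `positive`
#' iff `r > threshold` (strict inequalities); otherwise `none`.  Genes
#' negative to at least one cluster form the negatively correlated set and
#' are assigned to the negative cluster with the largest `|r|`;
#' `best_cluster` records the overall `argmax |r|`.
#'
#' @param r correlation matrix from [gene_cluster_correlation()].
#' @param threshold correlation magnitude threshold (default 0.67).
#' @return data.frame with one row per gene: `gene`, the per-cluster
#'   coefficients (`r_<cluster>`), per-cluster directions
#'   (`dir_<cluster>`), `best_cluster`, `assigned_cluster` (NA when not
#'   negative to any cluster) and `negative` (logical).  The
#'   per-cluster partition of negative genes is attached as
#'   `attr(, "negative_groups")`.
#' @export
annotate_directions <- function(r, threshold = 0.67) {
  r <- as.matrix(r)
  cl <- colnames(r)
  dirs <- matrix("none", nrow = nrow(r), ncol = ncol(r),
                 dimnames = dimnames(r))
  dirs[!is.na(r) & r > threshold] <- "positive"
  dirs[!is.na(r) & r < -threshold] <- "negative"
  absr <- abs(r)
  best <- cl[apply(absr, 1, function(x) {
    if (all(is.na(x))) NA_integer_ else which.max(x)
  })]
  assigned <- vapply(seq_len(nrow(r)), function(g) {
    neg <- which(dirs[g, ] == "negative")
    if (length(neg) == 0L) return(NA_character_)
    cl[neg[which.max(absr[g, neg])]]
  }, character(1))
  out <- data.frame(gene = rownames(r), stringsAsFactors = FALSE)
  for (c1 in cl) out[[paste0("r_", c1)]] <- r[, c1]
  for (c1 in cl) out[[paste0("dir_", c1)]] <- dirs[, c1]
  out$best_cluster <- best
  out$assigned_cluster <- assigned
  out$negative <- !is.na(assigned)
  attr(out, "negative_groups") <-
    split(out$gene[out$negative], out$assigned_cluster[out$negative])
  out
}
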
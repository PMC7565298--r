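# Final miRNA-target pair table: flag major expressed matures, join duplex
# hits with correlation annotations and cluster labels, and summarize the
# table (distinct genes and miRNAs, degree distributions, major-expressed
# coverage, per-cluster breakdowns).

#' Flag the major expressed mature miRNA of each family
#'
#' Within each miRNA gene family, the mature with the highest mean
#' normalized count across all samples is flagged; ties flag all tied
#' members.  Families with zero total counts get no flag (with a warning).
#'
#' @param counts raw count matrix, features x samples.
#' @param reference reference data.frame with `mature_id` and `family_id`.
#' @param sf size factors (computed with [size_factors()] when `NULL`).
#' @return named logical vector over `mature_id`.
#' @export
flag_major_expressed <- function(counts, reference, sf = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(rownames(counts) %in% reference$mature_id))
  if (is.null(sf)) sf <- size_factors(counts)
  means <- rowMeans(sweep(counts, 2, sf, "/"))
  fam <- reference$family_id[match(rownames(counts), reference$mature_id)]
  flag <- stats::setNames(logical(nrow(counts)), rownames(counts))
  for (f in unique(fam)) {
    idx <- which(fam == f)
    mx <- max(means[idx])
    if (mx == 0) {
      warning("family ", f, " has zero counts; no major expressed mature")
      next
    }
    flag[idx[means[idx] == mx]] <- TRUE
  }
  flag
}

#' Build the final miRNA-target pair table
#'
#' Retains duplex hits whose gene is annotated as negatively correlated to
#' the cluster of the targeting miRNA, joining the cluster label and the
#' major-expressed flag.  Multiple sites of one (miRNA, gene) pair are
#' collapsed to the lowest-MFE site, giving one row per pair.
#'
#' @param hits data.frame from [predict_targets()] (`mirna`, `utr`,
#'   `site_start`, `mfe`, ...); `utr` names are gene ids.
#' @param annotations data.frame from [annotate_directions()].
#' @param cluster_labels named vector of cluster labels per miRNA (e.g.
#'   `cluster_set$labels`); names must cover every miRNA in `hits`.
#' @param major_flags named logical vector from [flag_major_expressed()]
#'   (missing miRNAs default to `NA`).
#' @return data.frame with one row per retained pair: `gene`, `mirna`,
#'   `cluster`, `direction` (always "negative"), `major_expressed`,
#'   `site_start`, `mfe`.
#' @export
build_pair_table <- function(hits, annotations, cluster_labels,
                             major_flags = NULL) {
  if (nrow(hits) == 0L) {
    return(data.frame(gene = character(0), mirna = character(0),
                      cluster = character(0), direction = character(0),
                      major_expressed = logical(0), site_start = integer(0),
                      mfe = numeric(0)))
  }
  miss_m <- setdiff(unique(hits$mirna), names(cluster_labels))
  if (length(miss_m) > 0L) {
    stop("miRNAs in hits without a cluster label: ",
         paste(utils::head(miss_m, 10), collapse = ", "))
  }
  dir_cols <- grep("^dir_", names(annotations), value = TRUE)
  clusters_known <- sub("^dir_", "", dir_cols)
  rows <- list()
  for (r in seq_len(nrow(hits))) {
    gene <- hits$utr[r]
    mi <- hits$mirna[r]
    cl <- as.character(cluster_labels[[mi]])
    if (!(cl %in% clusters_known)) {
      stop("cluster ", cl, " of ", mi, " missing from the annotations")
    }
    a <- annotations[annotations$gene == gene, , drop = FALSE]
    if (nrow(a) == 0L) next        # gene was not annotated (not a DE gene)
    if (a[[paste0("dir_", cl)]][1] != "negative") next
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, mirna = mi, cluster = cl, direction = "negative",
      major_expressed = if (is.null(major_flags)) NA else
        unname(major_flags[mi]),
      site_start = hits$site_start[r], mfe = hits$mfe[r],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(0), mirna = character(0),
                      cluster = character(0), direction = character(0),
                      major_expressed = logical(0), site_start = integer(0),
                      mfe = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mfe), , drop = FALSE]
  out <- out[!duplicated(out[c("gene", "mirna")]), , drop = FALSE]
  out <- out[order(out$gene, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a miRNA-target pair table
#'
#' @param pairs data.frame with at least `gene`, `mirna`, `cluster` and
#'   `major_expressed` columns (one row per pair), e.g. from
#'   [build_pair_table()] or [load_table4_fixture()].
#' @return list with `n_pairs`, `n_target_genes`, `n_targeting_mirnas`,
#'   `per_mirna_degree` and `per_gene_degree` (named, decreasing),
#'   `major_coverage` (fraction of target genes hit by at least one major
#'   expressed mature miRNA), and `per_cluster` (data.frame `cluster`,
#'   `n_genes`, `n_mirnas`, `n_pairs`).
#' @export
summarize_pair_table <- function(pairs) {
  if (nrow(pairs) == 0L) stop("empty pair table")
  per_mirna <- sort(table(pairs$mirna), decreasing = TRUE)
  per_gene <- sort(table(pairs$gene), decreasing = TRUE)
  major_by_gene <- tapply(pairs$major_expressed, pairs$gene,
                          function(x) any(x %in% TRUE))
  per_cluster <- do.call(rbind, lapply(
    sort(unique(as.character(pairs$cluster))), function(cl) {
      p <- pairs[pairs$cluster == cl, , drop = FALSE]
      data.frame(cluster = cl, n_genes = length(unique(p$gene)),
                 n_mirnas = length(unique(p$mirna)), n_pairs = nrow(p),
                 stringsAsFactors = FALSE)
    }))
  list(n_pairs = nrow(pairs),
       n_target_genes = length(unique(pairs$gene)),
       n_targeting_mirnas = length(unique(pairs$mirna)),
       per_mirna_degree = per_mirna,
       per_gene_degree = per_gene,
       major_coverage = mean(major_by_gene),
       per_cluster = per_cluster)
}

#' Load the published pair-table transcription
#'
#' The package ships, as a plain-text fixture, the published table of
#' differentially expressed miRNAs in Clusters I and III with their
#' negatively correlated predicted target genes (one row per (gene,
#' miRNA) pair, with the bold major-expressed markers of the original
#' table as a logical column).
#'
#' @return data.frame with `no` (gene row number in the original table),
#'   `gene`, `cluster` ("I" or "III"), `mirna`, `major_expressed`.
#' @export
load_table4_fixture <- function() {
  path <- system.file("extdata", "pair_table_published.tsv",
                      package = "smoltmiR", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(no = "integer", gene = "character",
                                   cluster = "character", mirna = "character",
                                   major_expressed = "logical"))
}

#' Load the published cluster fold-change tables
#'
#' Transcriptions of the published relative-expression tables of the major
#' expressed family members in Clusters I/II and Cluster III: log2 fold
#' changes at T2..T6 relative to T1, with the significance asterisks as
#' logical columns.
#'
#' @return data.frame with `no`, `mirna`, `cluster`, `lfc_T2`..`lfc_T6`,
#'   `sig_T2`..`sig_T6`.
#' @export
load_cluster_profile_fixture <- function() {
  path <- system.file("extdata", "cluster_profiles_published.tsv",
                      package = "smoltmiR", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
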
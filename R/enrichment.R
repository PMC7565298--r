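# Overrepresentation analysis of a study gene set against a background:
# one-sided Fisher's exact test (equivalently the hypergeometric upper
# tail), Benjamini-Hochberg adjustment, FDR < 0.05, and an optional
# hierarchical rollup of significant terms under their most general
# significant ancestor.

#' Fisher's exact overrepresentation test per annotation term
#'
#' For each term with at least one annotated background gene, computes the
#' 2x2 overlap counts and the one-sided (overrepresentation) p-value
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` — identical to the
#' one-sided Fisher's exact test on the table.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param annotation data.frame with columns `gene`, `term` and optionally
#'   `name` (human-readable term name).
#' @return data.frame with one row per term: `term`, `name`, `k` (study
#'   genes with the term), `K` (background genes with the term), `n`
#'   (study size), `N` (background size), `fold_enrichment`
#'   (`(k/n)/(K/N)`), `pvalue`, `fdr` (BH-adjusted).  Sorted by `pvalue`.
#' @export
fisher_enrich <- function(study, background, annotation) {
  study <- unique(study)
  background <- unique(background)
  missing <- setdiff(study, background)
  if (length(missing) > 0L) {
    stop("study genes absent from the background: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no background gene is annotated")
  N <- length(background)
  n <- length(study)
  bg_by_term <- split(unique(ann[c("gene", "term")])$gene,
                      unique(ann[c("gene", "term")])$term)
  terms <- names(bg_by_term)
  K <- lengths(bg_by_term)
  k <- vapply(bg_by_term, function(g) sum(g %in% study), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p[k == 0L] <- 1
  nm <- if ("name" %in% names(ann)) {
    ann$name[match(terms, ann$term)]
  } else terms
  out <- data.frame(term = terms, name = nm, k = k, K = K, n = n, N = N,
                    fold_enrichment = (k / n) / (K / N),
                    pvalue = p, row.names = NULL, stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$pvalue)
  out[order(out$pvalue, -out$fold_enrichment), , drop = FALSE]
}

#' Filter enrichment results at an FDR threshold
#'
#' Retains terms with `fdr < fdr_threshold` (strict), sorted by `fdr` then
#' decreasing fold enrichment.
#'
#' @param results data.frame from [fisher_enrich()].
#' @param fdr_threshold strict FDR cutoff (default 0.05).
#' @return the retained rows.
#' @export
filter_significant <- function(results, fdr_threshold = 0.05) {
  out <- results[results$fdr < fdr_threshold, , drop = FALSE]
  out[order(out$fdr, -out$fold_enrichment), , drop = FALSE]
}

#' Group significant terms under their most general significant ancestor
#'
#' Using user-supplied parent links (a directed acyclic graph), every
#' significant term is grouped under each of its maximal significant
#' ancestors (significant terms, possibly itself, none of whose proper
#' ancestors are significant).  A term below a diamond may appear in two
#' groups, and a gene may appear in several groups.
#'
#' @param significant data.frame of significant terms (needs a `term`
#'   column; e.g. from [filter_significant()]).
#' @param parents data.frame with columns `term`, `parent` (one row per
#'   link; terms without rows are roots).
#' @param annotation optional annotation data.frame (`gene`, `term`); when
#'   given together with `study`, per-group gene lists are included.
#' @param study optional study gene set to restrict the gene lists.
#' @return list of groups, each a list with `root`, `terms` (member terms)
#'   and `genes` (possibly empty character vector).
#' @export
hierarchical_rollup <- function(significant, parents = NULL,
                                annotation = NULL, study = NULL) {
  terms <- significant$term
  if (is.null(parents) || nrow(parents) == 0L) {
    groups <- lapply(terms, function(t) list(root = t, terms = t,
                                             genes = character(0)))
  } else {
    if (any(parents$term == parents$parent)) {
      stop("self-loop in parent links")
    }
    par_of <- split(parents$parent, parents$term)
    ancestors <- function(t) {
      seen <- character(0)
      frontier <- t
      while (length(frontier) > 0L) {
        nxt <- unique(unlist(par_of[frontier], use.names = FALSE))
        nxt <- setdiff(nxt, seen)
        if (t %in% nxt) stop("cycle detected in parent links at term: ", t)
        seen <- c(seen, nxt)
        if (length(seen) > length(unique(c(parents$term, parents$parent)))) {
          stop("cycle detected in parent links")
        }
        frontier <- nxt
      }
      seen
    }
    anc <- lapply(stats::setNames(terms, terms), ancestors)
    # roots: significant terms with no significant proper ancestor
    roots <- terms[vapply(terms, function(t) {
      !any(anc[[t]] %in% terms)
    }, logical(1))]
    groups <- lapply(roots, function(rt) {
      members <- terms[vapply(terms, function(t) {
        t == rt || rt %in% anc[[t]]
      }, logical(1))]
      list(root = rt, terms = members, genes = character(0))
    })
  }
  if (!is.null(annotation)) {
    for (i in seq_along(groups)) {
      g <- unique(annotation$gene[annotation$term %in% groups[[i]]$terms])
      if (!is.null(study)) g <- intersect(g, study)
      groups[[i]]$genes <- sort(g)
    }
  }
  groups
}
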
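# Differential expression: negative binomial Wald tests for miRNA counts
# (each of T2..T6 against the pre-smolt baseline T1) and Welch t-tests for
# log2 microarray intensities, with Benjamini-Hochberg adjustment and the
# branch-specific significance filters.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over features with all-positive
#' counts of the ratio count / geometric-mean-count, rescaled so the factors
#' have geometric mean 1.
#'
#' @param counts integer matrix, features x samples.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    stop("no feature with all-positive counts; supply a pseudo-reference ",
         "or filter samples")
  }
  lg <- log(counts[allpos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(exp(lg - ref), 2, stats::median)
  sf / exp(mean(log(sf)))
}

#' Negative binomial Wald test for a two-group contrast
#'
#' Per-feature NB model with a moment-based dispersion estimate
#' `max(0, (s^2 - m) / m^2)` from the pooled within-group variance of
#' normalized counts, shrunk halfway (on log scale) toward a fitted
#' mean-dispersion trend `a0 + a1 / mean`.  The log2 fold change is the
#' ratio of normalized group means with pseudocount 0.5; the Wald statistic
#' `log2FC / SE` is referred to a standard normal.
#'
#' @param counts integer matrix, features x samples (raw counts).
#' @param groupA,groupB column names (or indices) of the two groups; the
#'   fold change is B relative to A (A is the baseline).
#' @param sf size factors for the columns of `counts`; computed by
#'   [size_factors()] when `NULL`.
#' @return data.frame with one row per feature: `feature`, `baseMean`
#'   (mean normalized count over the two groups), `log2FC`, `SE`, `stat`,
#'   `pvalue`, `allzero` (flag; such features get `log2FC = 0`,
#'   `pvalue = 1`).
#' @export
nb_wald_test <- function(counts, groupA, groupB, sf = NULL) {
  counts <- as.matrix(counts)
  if (length(groupA) < 2L || length(groupB) < 2L) {
    stop("at least 2 samples per group required")
  }
  if (is.null(sf)) sf <- size_factors(counts[, c(groupA, groupB), drop = FALSE])
  if (is.null(names(sf))) names(sf) <- colnames(counts)
  norm <- sweep(counts, 2, sf[colnames(counts)], "/")
  A <- norm[, groupA, drop = FALSE]
  B <- norm[, groupB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  m <- rowMeans(cbind(A, B))
  s2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  alpha_mom <- pmax(0, (s2 - m) / m^2)
  alpha_mom[!is.finite(alpha_mom)] <- 0
  # mean-dispersion trend alpha(m) = a0 + a1/m, fitted on features with a
  # positive moment estimate, then halfway log-scale shrinkage toward it
  pos <- alpha_mom > 0 & m > 0
  if (sum(pos) >= 10L) {
    fit <- stats::lm(alpha_mom[pos] ~ I(1 / m[pos]))
    a0 <- max(coef(fit)[1], 1e-4)
    a1 <- max(coef(fit)[2], 0)
  } else {
    a0 <- if (any(pos)) max(mean(alpha_mom[pos]), 1e-4) else 1e-4
    a1 <- 0
  }
  alpha_tr <- a0 + a1 / pmax(m, 0.5)
  eps <- 1e-8
  alpha <- exp((log(alpha_mom + eps) + log(alpha_tr + eps)) / 2)
  log2fc <- log2((mB + 0.5) / (mA + 0.5))
  se <- sqrt((1 / nA) * (1 / (mA + 0.5) + alpha) +
             (1 / nB) * (1 / (mB + 0.5) + alpha)) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  allzero <- rowSums(counts[, c(groupA, groupB), drop = FALSE]) == 0
  log2fc[allzero] <- 0
  p[allzero] <- 1
  stat[allzero] <- 0
  data.frame(feature = rownames(counts), baseMean = m, log2FC = log2fc,
             SE = se, stat = stat, pvalue = p, allzero = allzero,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch t-test per gene on log2 intensities
#'
#' @param expr numeric matrix of log2-scale intensities, genes x samples.
#' @param groupA,groupB column names (or indices) of the two groups; the
#'   fold change is `mean(B) - mean(A)`.
#' @return data.frame with `feature`, `log2FC`, `stat`, `df`, `pvalue`.
#'   Genes with zero variance in both groups get `pvalue = 1` when the
#'   means are equal and `pvalue = 0` otherwise.
#' @export
ttest_expr <- function(expr, groupA, groupB) {
  expr <- as.matrix(expr)
  if (length(groupA) < 2L || length(groupB) < 2L) {
    stop("at least 2 samples per group required")
  }
  A <- expr[, groupA, drop = FALSE]
  B <- expr[, groupB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  lfc <- mB - mA
  sed2 <- vA / nA + vB / nB
  t <- lfc / sqrt(sed2)
  df <- sed2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zerovar <- sed2 == 0
  p[zerovar] <- ifelse(lfc[zerovar] == 0, 1, 0)
  t[zerovar & lfc == 0] <- 0
  data.frame(feature = rownames(expr), log2FC = lfc, stat = t, df = df,
             pvalue = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement,
#' order-preserving on the input indexing (a thin, validating wrapper
#' around `stats::p.adjust(method = "BH")`).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`; `NA` is an error.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals)) stop("NA p-values not allowed")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Apply the branch-specific differential expression filters
#'
#' miRNA branch: a contrast is significant iff `padj <= alpha`,
#' `|log2FC| >= lfc` and `baseMean >= min_basemean` (all bounds inclusive).
#' mRNA branch: `pvalue <= alpha` and `|log2FC| >= lfc` (no baseMean floor,
#' raw p-values).  A feature is differentially expressed (`de_any`) when
#' any contrast passes.
#'
#' @param results named list of per-contrast data.frames (as returned by
#'   [nb_wald_test()] or [ttest_expr()], with a `padj` column added for the
#'   miRNA branch).
#' @param branch `"mirna"` or `"mrna"`.
#' @param alpha significance level (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 1 for miRNA,
#'   0.8 for mRNA when `NULL`).
#' @param min_basemean baseMean floor for the miRNA branch (default 10).
#' @return list with `de_flag` (logical matrix, features x contrasts),
#'   `de_any` (named logical) and `de_features` (character vector).
#' @export
apply_de_filters <- function(results, branch = c("mirna", "mrna"),
                             alpha = 0.05, lfc = NULL, min_basemean = 10) {
  branch <- match.arg(branch)
  if (is.null(lfc)) lfc <- if (branch == "mirna") 1.0 else 0.8
  feats <- results[[1]]$feature
  flags <- sapply(results, function(r) {
    stopifnot(identical(r$feature, feats))
    if (branch == "mirna") {
      if (is.null(r$padj)) stop("miRNA branch requires a padj column")
      r$padj <= alpha & abs(r$log2FC) >= lfc & r$baseMean >= min_basemean
    } else {
      r$pvalue <= alpha & abs(r$log2FC) >= lfc
    }
  })
  flags <- matrix(flags, nrow = length(feats),
                  dimnames = list(feats, names(results)))
  de_any <- apply(flags, 1, any)
  list(de_flag = flags, de_any = de_any,
       de_features = feats[de_any])
}

# Build the named sample groups for the five T2..T6 vs T1 contrasts.
contrast_groups <- function(timepoints) {
  tps <- sort(unique(timepoints))
  stopifnot("T1" %in% tps)
  lapply(stats::setNames(setdiff(tps, "T1"), setdiff(tps, "T1")),
         function(tp) list(A = names(timepoints)[timepoints == "T1"],
                           B = names(timepoints)[timepoints == tp]))
}

#' Differential expression of miRNA counts against the T1 baseline
#'
#' Runs [nb_wald_test()] for each timepoint T2..T6 against T1 (size factors
#' estimated once from all samples), adjusts p-values with
#' [bh_adjust()] within each contrast, and applies the miRNA significance
#' filters.
#'
#' @param counts integer count matrix, features x samples.
#' @param timepoints named character vector of timepoint labels per sample.
#' @param alpha,lfc,min_basemean thresholds passed to [apply_de_filters()].
#' @return list with `contrasts` (per-contrast data.frames including
#'   `padj` and `de` columns), `baseMean` (over all samples), `de_flag`,
#'   `de_any`, `de_features`, `size_factors` and `profiles` (log2FC matrix,
#'   features x contrasts).
#' @export
de_mirna <- function(counts, timepoints, alpha = 0.05, lfc = 1.0,
                     min_basemean = 10) {
  counts <- as.matrix(counts)
  if (is.null(names(timepoints))) names(timepoints) <- colnames(counts)
  sf <- size_factors(counts)
  basemean <- rowMeans(sweep(counts, 2, sf, "/"))
  res <- lapply(contrast_groups(timepoints), function(g) {
    r <- nb_wald_test(counts[, c(g$A, g$B), drop = FALSE], g$A, g$B,
                      sf = sf[c(g$A, g$B)])
    r$baseMean <- basemean           # study-wide mean of normalized counts
    r$padj <- bh_adjust(r$pvalue)
    r
  })
  filt <- apply_de_filters(res, "mirna", alpha, lfc, min_basemean)
  for (nm in names(res)) res[[nm]]$de <- unname(filt$de_flag[, nm])
  profiles <- sapply(res, function(r) r$log2FC)
  rownames(profiles) <- rownames(counts)
  list(contrasts = res, baseMean = basemean, de_flag = filt$de_flag,
       de_any = filt$de_any, de_features = filt$de_features,
       size_factors = sf, profiles = profiles)
}

#' Differential expression of log2 microarray intensities against T1
#'
#' Runs [ttest_expr()] for each timepoint T2..T6 against T1 and applies the
#' microarray significance filters (raw p-values, per the platform's
#' default reporting).  BH-adjusted p-values are included for reference.
#'
#' @param expr numeric matrix of log2 intensities, genes x samples.
#' @param timepoints named character vector of timepoint labels per sample.
#' @param alpha,lfc thresholds passed to [apply_de_filters()].
#' @return list with `contrasts`, `de_flag`, `de_any`, `de_features` and
#'   `profiles` (log2FC matrix, genes x contrasts).
#' @export
de_mrna <- function(expr, timepoints, alpha = 0.05, lfc = 0.8) {
  expr <- as.matrix(expr)
  if (is.null(names(timepoints))) names(timepoints) <- colnames(expr)
  res <- lapply(contrast_groups(timepoints), function(g) {
    r <- ttest_expr(expr[, c(g$A, g$B), drop = FALSE], g$A, g$B)
    r$padj <- bh_adjust(r$pvalue)
    r
  })
  filt <- apply_de_filters(res, "mrna", alpha, lfc)
  for (nm in names(res)) res[[nm]]$de <- unname(filt$de_flag[, nm])
  profiles <- sapply(res, function(r) r$log2FC)
  rownames(profiles) <- rownames(expr)
  list(contrasts = res, de_flag = filt$de_flag, de_any = filt$de_any,
       de_features = filt$de_features, profiles = profiles)
}
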
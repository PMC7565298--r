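# Seed-constrained miRNA:3'UTR duplex prediction.
#
# The screen mirrors the classic intermolecular hybridization approach:
# candidate sites require perfect Watson-Crick complementarity to the miRNA
# seed (positions 2-8 from the 5' end, G:U wobble disallowed), the duplex is
# then extended by a dynamic program over intermolecular pairings only
# (neither strand folds on itself) with bulges and internal loops capped at
# 9 nt per side, and sites are reported when the minimum free energy is at
# or below the threshold (-18 kcal/mol by default).

#' Find perfect seed-complementary sites in a 3'UTR
#'
#' Scans the UTR (5'->3') for exact Watson-Crick reverse complements of the
#' miRNA seed, positions `seed_start`..`seed_end` (1-based from the miRNA
#' 5' end; the canonical seed is 2-8).  G:U wobble pairs are explicitly not
#' matches.
#'
#' @param utr,mirna nucleotide strings (RNA or DNA; U/T normalized).
#' @param seed_start,seed_end seed span on the miRNA (defaults 2 and 8).
#' @return Integer vector of 1-based start positions of the seed site on the
#'   UTR sense strand (the position pairing the *last* seed base, i.e. the
#'   5'-most UTR base of the site).  The site spans
#'   `start .. start + (seed_end - seed_start)`.
#' @examples
#' find_seed_sites(paste0("AAAA", "CUACCUC", "AAAA"), "UGAGGUAGUAGGUUGUAUAGUU")
#' @export
find_seed_sites <- function(utr, mirna, seed_start = 2L, seed_end = 8L) {
  utr <- as_rna(utr)
  mirna <- as_rna(mirna)
  if (nchar(mirna) < seed_end) {
    stop("miRNA shorter than the seed span (", seed_end, " nt): ", mirna)
  }
  seed <- substr(mirna, seed_start, seed_end)
  site <- rna_revcomp(seed)
  if (nchar(utr) < nchar(site)) return(integer(0))
  m <- Biostrings::matchPattern(site, Biostrings::RNAString(utr), fixed = TRUE)
  as.integer(Biostrings::start(m))
}

# Terminal AU/GU penalty for one duplex-end pair type (0 for CG/GC).
.term_pen <- function(pt, model) {
  if (is.na(pt)) return(Inf)
  if (pt %in% c("AU", "UA", "GU", "UG")) model$terminal_au else 0
}

# Core DP: minimum free energy of a duplex anchored so that miRNA positions
# seed_start..seed_end are contiguously Watson-Crick paired at target
# position s (s pairs miRNA position seed_end).  Window coordinates.
# Returns list(mfe, pairs) with pairs ordered by increasing target position.
duplex_mfe_at_site <- function(tb, mb, s, model,
                               max_bulge = 9L, max_internal = 9L,
                               seed_start = 2L, seed_end = 8L) {
  n <- length(tb); L <- length(mb)
  sl <- seed_end - seed_start + 1L
  e0 <- s + sl - 1L                       # target position pairing seed_start
  stopifnot(s >= 1L, e0 <= n)
  seed_i <- s:e0
  seed_j <- seed_end:seed_start
  if (!all(is_wc_pair(tb[seed_i], mb[seed_j]))) {
    return(list(mfe = Inf, pairs = NULL))
  }
  e_seed <- 0
  if (sl > 1L) {
    for (r in seq_len(sl - 1L)) {
      e_seed <- e_seed + step_energy(seed_i[r], seed_j[r],
                                     seed_i[r + 1L], seed_j[r + 1L],
                                     tb, mb, model, max_bulge, max_internal)
    }
  }

  gap <- max(max_bulge, max_internal)

  # --- 3' arm: miRNA j > seed_end pairs target i < s -----------------------
  js3 <- if (seed_end < L) (seed_end + 1L):L else integer(0)
  is3 <- if (s > 1L) seq_len(s - 1L) else integer(0)
  D3 <- matrix(Inf, nrow = length(js3), ncol = length(is3))
  B3 <- matrix(NA_integer_, nrow = length(js3), ncol = length(is3))  # backptr
  best3 <- .term_pen(pair_type(tb[s], mb[seed_end]), model)
  best3_end <- NULL
  for (aj in seq_along(js3)) {
    j <- js3[aj]
    for (ai in rev(seq_along(is3))) {
      i <- is3[ai]
      if (is.na(pair_type(tb[i], mb[j]))) next
      best <- Inf; bp <- NA_integer_
      # inner neighbour: the seed end (s, seed_end) or a previous DP cell
      if (j - seed_end - 1L <= gap && s - i - 1L <= gap) {
        cst <- step_energy(i, j, s, seed_end, tb, mb, model,
                           max_bulge, max_internal)
        if (cst < best) { best <- cst; bp <- 0L }
      }
      if (ai < length(is3)) {
        for (ajp in seq_len(aj - 1L)) {
          jp <- js3[ajp]
          if (j - jp - 1L > gap) next
          for (aip in (ai + 1L):length(is3)) {
            ip <- is3[aip]
            if (ip - i - 1L > gap) break
            if (!is.finite(D3[ajp, aip])) next
            cst <- D3[ajp, aip] +
              step_energy(i, j, ip, jp, tb, mb, model, max_bulge, max_internal)
            if (cst < best) { best <- cst; bp <- (ajp - 1L) * length(is3) + aip }
          }
        }
      }
      D3[aj, ai] <- best
      B3[aj, ai] <- bp
      tot <- best + .term_pen(pair_type(tb[i], mb[j]), model)
      if (tot < best3) { best3 <- tot; best3_end <- c(aj, ai) }
    }
  }

  # --- 5' arm: miRNA j < seed_start pairs target i > e0 --------------------
  js5 <- if (seed_start > 1L) (seed_start - 1L):1L else integer(0)
  is5 <- if (e0 < n) (e0 + 1L):n else integer(0)
  D5 <- matrix(Inf, nrow = length(js5), ncol = length(is5))
  B5 <- matrix(NA_integer_, nrow = length(js5), ncol = length(is5))
  best5 <- .term_pen(pair_type(tb[e0], mb[seed_start]), model)
  best5_end <- NULL
  for (aj in seq_along(js5)) {
    j <- js5[aj]
    for (ai in seq_along(is5)) {
      i <- is5[ai]
      if (is.na(pair_type(tb[i], mb[j]))) next
      best <- Inf; bp <- NA_integer_
      if (seed_start - j - 1L <= gap && i - e0 - 1L <= gap) {
        cst <- step_energy(e0, seed_start, i, j, tb, mb, model,
                           max_bulge, max_internal)
        if (cst < best) { best <- cst; bp <- 0L }
      }
      for (ajp in seq_len(aj - 1L)) {
        jp <- js5[ajp]
        if (jp - j - 1L > gap) next
        for (aip in seq_len(ai - 1L)) {
          ip <- is5[aip]
          if (i - ip - 1L > gap) next
          if (!is.finite(D5[ajp, aip])) next
          cst <- D5[ajp, aip] +
            step_energy(ip, jp, i, j, tb, mb, model, max_bulge, max_internal)
          if (cst < best) { best <- cst; bp <- (ajp - 1L) * length(is5) + aip }
        }
      }
      D5[aj, ai] <- best
      B5[aj, ai] <- bp
      tot <- best + .term_pen(pair_type(tb[i], mb[j]), model)
      if (tot < best5) { best5 <- tot; best5_end <- c(aj, ai) }
    }
  }

  mfe <- model$init + e_seed + best3 + best5
  if (!is.finite(mfe)) return(list(mfe = Inf, pairs = NULL))

  pairs <- data.frame(i = seed_i, j = seed_j)
  if (!is.null(best3_end)) {
    aj <- best3_end[1L]; ai <- best3_end[2L]
    repeat {
      pairs <- rbind(data.frame(i = is3[ai], j = js3[aj]), pairs)
      bp <- B3[aj, ai]
      if (is.na(bp) || bp == 0L) break
      aj <- (bp - 1L) %/% length(is3) + 1L
      ai <- (bp - 1L) %%  length(is3) + 1L
    }
  }
  if (!is.null(best5_end)) {
    aj <- best5_end[1L]; ai <- best5_end[2L]
    ext <- NULL
    repeat {
      ext <- rbind(data.frame(i = is5[ai], j = js5[aj]), ext)
      bp <- B5[aj, ai]
      if (is.na(bp) || bp == 0L) break
      aj <- (bp - 1L) %/% length(is5) + 1L
      ai <- (bp - 1L) %%  length(is5) + 1L
    }
    pairs <- rbind(pairs, ext)
  }
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  list(mfe = mfe, pairs = pairs)
}

# Dot-bracket-style pairing string over both strands: "target&miRNA" with
# "(" / ")" at paired positions.
pairing_string <- function(pairs, n_target, n_mirna) {
  tl <- rep(".", n_target); ml <- rep(".", n_mirna)
  tl[pairs$i] <- "("
  ml[pairs$j] <- ")"
  paste0(paste(tl, collapse = ""), "&", paste(ml, collapse = ""))
}

#' Minimum free energy of a seed-anchored miRNA:target duplex
#'
#' Dynamic program over intermolecular pairings only: miRNA seed positions
#' (`seed_start`..`seed_end`, default 2-8) must be contiguously Watson-Crick
#' paired at a seed-complementary site of the window; the 3' part of the
#' miRNA and position 1 are then extended freely under the loop constraints
#' (bulges at most `max_bulge` nt, internal loops at most `max_internal` nt
#' per side).  G:U pairs are allowed outside the seed.  The energy is
#' initiation + stacking terms + loop penalties + terminal-AU/GU
#' corrections under [energy_model()].
#'
#' @param window target subsequence (5'->3') containing at least one seed
#'   site.
#' @param mirna mature miRNA sequence (5'->3').
#' @param model an [energy_model()].
#' @param max_bulge,max_internal loop constraints in nt.
#' @param seed_start,seed_end forced helix span on the miRNA.
#' @return list with `mfe` (kcal/mol; `Inf` if no structure satisfies the
#'   helix constraint), `pairs` (data.frame of paired positions `i` on the
#'   window, `j` on the miRNA), `pairing` (dot-bracket style string
#'   "window&miRNA"), `site_start`/`site_end` (seed site span on the
#'   window), and `span_start`/`span_end` (outermost paired window
#'   positions).
#' @export
duplex_mfe <- function(window, mirna, model = energy_model(),
                       max_bulge = 9L, max_internal = 9L,
                       seed_start = 2L, seed_end = 8L) {
  window <- as_rna(window)
  mirna <- as_rna(mirna)
  sites <- find_seed_sites(window, mirna, seed_start, seed_end)
  empty <- list(mfe = Inf, pairs = NULL, pairing = NULL,
                site_start = NA_integer_, site_end = NA_integer_,
                span_start = NA_integer_, span_end = NA_integer_)
  if (length(sites) == 0L) return(empty)
  tb <- strsplit(window, "", fixed = TRUE)[[1]]
  mb <- strsplit(mirna, "", fixed = TRUE)[[1]]
  best <- empty
  for (s in sites) {
    res <- duplex_mfe_at_site(tb, mb, s, model, max_bulge, max_internal,
                              seed_start, seed_end)
    if (res$mfe < best$mfe) {
      best <- list(mfe = res$mfe, pairs = res$pairs,
                   pairing = pairing_string(res$pairs, length(tb), length(mb)),
                   site_start = s,
                   site_end = s + (seed_end - seed_start),
                   span_start = min(res$pairs$i),
                   span_end = max(res$pairs$i))
    }
  }
  best
}

#' Predict miRNA targets by seed match and duplex minimum free energy
#'
#' For every (miRNA, UTR) combination, every perfect seed-complementary site
#' is extended by [duplex_mfe()] within a local window (seed site plus
#' miRNA length + 9 nt of flank on each side, which is sufficient for any
#' loop-legal structure) and retained when the minimum free energy is at or
#' below `mfe_threshold` (inclusive).  Overlapping retained sites of the
#' same (miRNA, UTR) pair are collapsed to the lowest-energy site.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param utrs named character vector (or `Biostrings::XStringSet`) of
#'   3'UTR sequences, 5'->3' sense strand.
#' @param model an [energy_model()].
#' @param mfe_threshold report sites with MFE <= this value (kcal/mol).
#' @param max_bulge,max_internal,seed_start,seed_end see [duplex_mfe()].
#' @return data.frame with one row per retained (miRNA, UTR, site):
#'   `mirna`, `utr`, `site_start`, `site_end` (seed site, 1-based inclusive
#'   on the UTR sense strand), `span_start`, `span_end` (full paired span),
#'   `mfe`, `pairing` (over the scan window), `seed_anchored` (always TRUE).
#' @export
predict_targets <- function(mirnas, utrs, model = energy_model(),
                            mfe_threshold = -18, max_bulge = 9L,
                            max_internal = 9L, seed_start = 2L,
                            seed_end = 8L) {
  if (length(mirnas) == 0L || length(utrs) == 0L) {
    stop("mirnas and utrs must be non-empty")
  }
  if (methods::is(utrs, "XStringSet")) {
    utrs <- stats::setNames(as.character(utrs), names(utrs))
  }
  if (is.null(names(mirnas)) || is.null(names(utrs))) {
    stop("mirnas and utrs must be named")
  }
  mirnas <- vapply(mirnas, as_rna, character(1))
  sl <- seed_end - seed_start
  rows <- list()
  for (g in names(utrs)) {
    utr <- as_rna(utrs[[g]])
    if (nchar(utr) < sl + 1L) {
      message("skipping UTR shorter than the seed: ", g)
      next
    }
    for (mi in names(mirnas)) {
      mseq <- mirnas[[mi]]
      L <- nchar(mseq)
      sites <- find_seed_sites(utr, mseq, seed_start, seed_end)
      if (length(sites) == 0L) next
      hits <- list()
      for (s in sites) {
        left <- max(1L, s - (L + 9L))
        right <- min(nchar(utr), s + sl + 10L)
        win <- substr(utr, left, right)
        res <- duplex_mfe_at_site(strsplit(win, "", fixed = TRUE)[[1]],
                                  strsplit(mseq, "", fixed = TRUE)[[1]],
                                  s - left + 1L, model,
                                  max_bulge, max_internal,
                                  seed_start, seed_end)
        if (res$mfe <= mfe_threshold) {
          hits[[length(hits) + 1L]] <- data.frame(
            mirna = mi, utr = g,
            site_start = s, site_end = s + sl,
            span_start = min(res$pairs$i) + left - 1L,
            span_end = max(res$pairs$i) + left - 1L,
            mfe = res$mfe,
            pairing = pairing_string(res$pairs, nchar(win), L),
            seed_anchored = TRUE,
            stringsAsFactors = FALSE)
        }
      }
      if (length(hits) == 0L) next
      hits <- do.call(rbind, hits)
      # collapse overlapping seed sites to the lowest-MFE one
      hits <- hits[order(hits$mfe, hits$site_start), , drop = FALSE]
      keep <- rep(TRUE, nrow(hits))
      for (r in seq_len(nrow(hits))) {
        if (!keep[r]) next
        if (r < nrow(hits)) {
          for (r2 in (r + 1L):nrow(hits)) {
            if (keep[r2] &&
                hits$site_start[r2] <= hits$site_end[r] &&
                hits$site_end[r2] >= hits$site_start[r]) {
              keep[r2] <- FALSE
            }
          }
        }
      }
      rows[[length(rows) + 1L]] <- hits[keep, , drop = FALSE]
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mirna = character(0), utr = character(0),
                      site_start = integer(0), site_end = integer(0),
                      span_start = integer(0), span_end = integer(0),
                      mfe = numeric(0), pairing = character(0),
                      seed_anchored = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$utr, out$mirna, out$site_start), , drop = FALSE]
}
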
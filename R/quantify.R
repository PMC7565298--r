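# Small-RNA FASTQ -> miRNA count matrix: 3' adapter trimming, 18-25 nt size
# selection, unique end-to-end mapping against mature miRNA references.

#' The 3' sequencing adapter of the small-RNA libraries
#' @export
SMOLT_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"

#' Trim the 3' adapter from reads
#'
#' A read is truncated at the leftmost position where either the full
#' adapter occurs, or a prefix of the adapter of length at least
#' `min_overlap` runs to the end of the read.  Matching is exact (no
#' error-tolerant alignment): synthetic reads are error-free, and real-data
#' users should pre-trim with an error-tolerant tool if needed.  Reads with
#' no such match are returned as `NA` (untrimmed marker; discard downstream).
#'
#' @param reads character vector of read sequences (DNA, 5'->3').
#' @param adapter adapter sequence; default [SMOLT_ADAPTER].
#' @param min_overlap minimum adapter prefix length at the read 3' end
#'   (default 3; must satisfy `nchar(adapter) >= min_overlap >= 3`).
#' @return character vector: trimmed inserts (possibly empty strings), `NA`
#'   where no adapter match was found.
#' @export
trim_adapter <- function(reads, adapter = SMOLT_ADAPTER, min_overlap = 3L) {
  nc <- nchar(adapter)
  if (!(nc >= min_overlap && min_overlap >= 3L)) {
    stop("need nchar(adapter) >= min_overlap >= 3")
  }
  if (length(reads) == 0L) return(character(0))
  if (any(!nzchar(reads)) || anyNA(reads)) stop("empty read in input")
  n <- nchar(reads)
  # leftmost full-adapter occurrence
  p <- regexpr(adapter, reads, fixed = TRUE)
  p[p < 0L] <- NA_integer_
  # adapter prefix running to the read end; longest prefix = leftmost start,
  # and any such start is right of every possible full match
  unresolved <- is.na(p)
  for (k in seq(nc - 1L, min_overlap)) {
    if (!any(unresolved)) break
    idx <- which(unresolved & n >= k)
    if (length(idx) == 0L) next
    hit <- substr(reads[idx], n[idx] - k + 1L, n[idx]) == substr(adapter, 1L, k)
    p[idx[hit]] <- n[idx[hit]] - k + 1L
    unresolved[idx[hit]] <- FALSE
  }
  out <- rep(NA_character_, length(reads))
  ok <- !is.na(p)
  out[ok] <- substr(reads[ok], 1L, p[ok] - 1L)
  out
}

#' Size-select trimmed reads
#'
#' Retains reads whose trimmed length is between `min_len` and `max_len`
#' nucleotides, bounds inclusive.
#'
#' @param reads character vector of trimmed reads (no `NA`).
#' @param min_len,max_len inclusive length bounds (defaults 18 and 25 nt).
#' @return list with `kept` (character vector) and `discarded`
#'   (named integer tally: `short`, `long`).
#' @export
filter_by_length <- function(reads, min_len = 18L, max_len = 25L) {
  if (length(reads) == 0L) {
    return(list(kept = character(0), discarded = c(short = 0L, long = 0L)))
  }
  n <- nchar(reads)
  list(kept = reads[n >= min_len & n <= max_len],
       discarded = c(short = sum(n < min_len), long = sum(n > max_len)))
}

#' Map size-selected reads to mature miRNAs and count unique hits
#'
#' A read increments a reference feature if and only if it matches
#' end-to-end (equal length) within `max_mismatches` substitutions to
#' exactly one reference entry, after U/T normalization and uppercasing.
#' Reads hitting several entries (e.g. identical paralogs) are tallied as
#' multi-mapped and counted for no feature; reads hitting none are tallied
#' as unmapped.
#'
#' @param reads character vector of size-selected reads.
#' @param reference mature miRNA reference: data.frame with columns
#'   `mature_id`, `family_id`, `sequence` (see [read_mirna_reference()]).
#' @param max_mismatches maximum substitutions for an end-to-end match
#'   (default 0).
#' @return list with `counts` (named integer vector, one per `mature_id`)
#'   and `stats` (named integers `mapped`, `multimapped`, `unmapped`).
#' @export
map_and_count <- function(reads, reference, max_mismatches = 0L) {
  validate_reference(reference)
  refseq <- chartr("uU", "tT", toupper(reference$sequence))
  refseq <- toupper(refseq)
  counts <- stats::setNames(integer(nrow(reference)), reference$mature_id)
  stats_out <- c(mapped = 0L, multimapped = 0L, unmapped = 0L)
  if (length(reads) == 0L) return(list(counts = counts, stats = stats_out))
  reads <- toupper(chartr("uU", "tT", reads))
  tab <- table(reads)
  useq <- names(tab)
  nhit <- integer(length(useq))
  firsthit <- integer(length(useq))
  if (max_mismatches == 0L) {
    dup <- duplicated(refseq) | duplicated(refseq, fromLast = TRUE)
    idx <- match(useq, refseq)
    nhit[!is.na(idx)] <- 1L
    nhit[!is.na(idx) & dup[replace(idx, is.na(idx), 1L)]] <- 2L
    firsthit <- idx
  } else {
    rl <- nchar(refseq)
    for (u in seq_along(useq)) {
      cand <- which(rl == nchar(useq[u]))
      if (length(cand) == 0L) next
      rb <- strsplit(refseq[cand], "", fixed = TRUE)
      ub <- strsplit(useq[u], "", fixed = TRUE)[[1]]
      mm <- vapply(rb, function(x) sum(x != ub), integer(1))
      hits <- cand[mm <= max_mismatches]
      nhit[u] <- length(hits)
      if (length(hits) >= 1L) firsthit[u] <- hits[1L]
    }
  }
  nread <- as.integer(tab)
  uni <- nhit == 1L
  add <- tapply(nread[uni], firsthit[uni], sum)
  counts[as.integer(names(add))] <- counts[as.integer(names(add))] +
    as.integer(add)
  stats_out["mapped"] <- sum(nread[uni])
  stats_out["multimapped"] <- sum(nread[nhit > 1L])
  stats_out["unmapped"] <- sum(nread[nhit == 0L])
  list(counts = counts, stats = stats_out)
}

validate_reference <- function(reference) {
  stopifnot(is.data.frame(reference),
            all(c("mature_id", "family_id", "sequence") %in% names(reference)))
  if (nrow(reference) == 0L) stop("empty miRNA reference")
  if (anyDuplicated(reference$mature_id)) {
    stop("duplicate mature ids in reference: ",
         paste(unique(reference$mature_id[duplicated(reference$mature_id)]),
               collapse = ", "))
  }
  nc <- nchar(reference$sequence)
  if (any(nc < 16L | nc > 30L)) {
    stop("reference sequences must be 16-30 nt")
  }
  if (any(!nzchar(reference$family_id))) stop("empty family_id in reference")
  invisible(TRUE)
}

#' Derive a miRNA family id from a mature miRNA name
#'
#' Strips the species prefix, the -5p/-3p arm suffix and letter/paralog
#' variants, keeping the family stem (e.g. `ssa-miR-146a-3-3p` ->
#' `miR-146`, `ssa-let-7b-3p` -> `let-7`, `ssa-miR-novel-12-5p` ->
#' `miR-novel-12`).
#'
#' @param ids character vector of mature miRNA names.
#' @return character vector of family ids (the input id itself when no
#'   family stem is recognized).
#' @export
mirna_family <- function(ids) {
  x <- sub("-[35]p$", "", ids)
  x <- sub("^[a-z]{3}-", "", x)
  m <- regmatches(x, regexpr("^(let|miR)-(novel-)?[0-9]+", x))
  out <- ids
  has <- lengths(regmatches(x, gregexpr("^(let|miR)-(novel-)?[0-9]+", x))) > 0
  out[has] <- m
  out
}

#' Read a mature miRNA reference FASTA
#'
#' @param path FASTA file of mature miRNA sequences (RNA or DNA alphabet).
#' @param family_ids optional named character vector mapping mature id to
#'   family id; by default families are derived with [mirna_family()].
#' @return data.frame with columns `mature_id`, `family_id`, `sequence`
#'   (RNA alphabet).
#' @export
read_mirna_reference <- function(path, family_ids = NULL) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  ref <- data.frame(mature_id = ids,
                    family_id = if (is.null(family_ids)) mirna_family(ids)
                                else unname(family_ids[ids]),
                    sequence = as_rna(as.character(x)),
                    stringsAsFactors = FALSE)
  validate_reference(ref)
  ref
}

#' Quantify small-RNA samples into a miRNA count matrix
#'
#' Runs the full per-sample chain: adapter trimming ([trim_adapter()]),
#' size selection ([filter_by_length()]) and unique end-to-end mapping
#' ([map_and_count()]).
#'
#' @param samples either a named list of character vectors of raw read
#'   sequences (one element per sample) or a named character vector of
#'   FASTQ file paths (gzip allowed).
#' @param reference mature miRNA reference data.frame.
#' @param timepoints character/factor of timepoint labels, one per sample
#'   (`T1`..`T6`).
#' @param adapter,min_overlap see [trim_adapter()].
#' @param min_len,max_len see [filter_by_length()].
#' @param max_mismatches see [map_and_count()].
#' @return list with `counts` (integer matrix, features x samples),
#'   `timepoints` (named character vector) and `stats` (data.frame of
#'   per-sample tallies: `raw`, `untrimmed`, `short`, `long`, `mapped`,
#'   `multimapped`, `unmapped`, `mean_retained_len`).  The tallies satisfy
#'   raw = untrimmed + short + long + mapped + multimapped + unmapped.
#' @export
quantify_smallrna <- function(samples, reference, timepoints,
                              adapter = SMOLT_ADAPTER, min_overlap = 3L,
                              min_len = 18L, max_len = 25L,
                              max_mismatches = 0L) {
  if (is.character(samples)) {
    paths <- samples
    samples <- lapply(paths, function(p) {
      as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
    })
    names(samples) <- names(paths)
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be named")
  }
  if (length(timepoints) != length(samples)) {
    stop("one timepoint label per sample required")
  }
  counts <- matrix(0L, nrow = nrow(reference), ncol = length(samples),
                   dimnames = list(reference$mature_id, names(samples)))
  stats_df <- data.frame()
  for (s in names(samples)) {
    raw <- samples[[s]]
    trimmed <- trim_adapter(raw, adapter, min_overlap)
    untrimmed <- sum(is.na(trimmed))
    flt <- filter_by_length(trimmed[!is.na(trimmed)], min_len, max_len)
    mc <- map_and_count(flt$kept, reference, max_mismatches)
    counts[, s] <- mc$counts
    stats_df <- rbind(stats_df, data.frame(
      sample = s, raw = length(raw), untrimmed = untrimmed,
      short = unname(flt$discarded["short"]),
      long = unname(flt$discarded["long"]),
      mapped = unname(mc$stats["mapped"]),
      multimapped = unname(mc$stats["multimapped"]),
      unmapped = unname(mc$stats["unmapped"]),
      mean_retained_len = if (length(flt$kept)) mean(nchar(flt$kept)) else NA_real_,
      stringsAsFactors = FALSE))
  }
  list(counts = counts,
       timepoints = stats::setNames(as.character(timepoints), names(samples)),
       stats = stats_df)
}
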
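# Independent oracles used across the test suite.  Each re-implements the
# checked operation from first principles (naive scans, brute-force
# enumeration, closed forms) without sharing code with the package paths
# it validates.

# --- adapter trimming: naive scan over all suffixes -------------------------
oracle_trim <- function(read, adapter, min_overlap = 3L) {
  n <- nchar(read)
  nc <- nchar(adapter)
  for (p in seq_len(n)) {
    k <- min(n - p + 1L, nc)
    if (k < min_overlap) break
    if (substr(read, p, p + k - 1L) == substr(adapter, 1L, k)) {
      return(substr(read, 1L, p - 1L))
    }
  }
  NA_character_
}

# --- seed sites: naive sliding-window scan ---------------------------------
oracle_seed_scan <- function(utr, mirna, seed_start = 2L, seed_end = 8L) {
  utr <- chartr("tT", "uU", toupper(utr))
  mirna <- chartr("tT", "uU", toupper(mirna))
  seed <- substr(mirna, seed_start, seed_end)
  sb <- rev(strsplit(seed, "")[[1]])
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  site <- paste(comp[sb], collapse = "")
  w <- nchar(site)
  hits <- integer(0)
  if (nchar(utr) < w) return(hits)
  for (p in seq_len(nchar(utr) - w + 1L)) {
    if (substr(utr, p, p + w - 1L) == site) hits <- c(hits, p)
  }
  hits
}

# --- duplex structures: independent scorer + exhaustive enumeration --------
# Scores with its own literal copy of the nearest-neighbor rules.
oracle_score <- function(pairs, tb, mb, model, max_bulge = 9L,
                         max_internal = 9L) {
  ord <- order(pairs$i)
  pi <- pairs$i[ord]; pj <- pairs$j[ord]
  ok_pair <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "CG", "GC", "GU", "UG")
  e <- model$init
  for (r in seq_along(pi)) {
    if (!ok_pair(tb[pi[r]], mb[pj[r]])) return(Inf)
  }
  if (length(pi) > 1L) {
    for (r in seq_len(length(pi) - 1L)) {
      if (pj[r + 1L] >= pj[r]) return(Inf)
      a <- pi[r + 1L] - pi[r] - 1L
      b <- pj[r] - pj[r + 1L] - 1L
      p1 <- paste0(tb[pi[r]], mb[pj[r]])
      p2rev <- paste0(mb[pj[r + 1L]], tb[pi[r + 1L]])
      if (a == 0L && b == 0L) {
        e <- e + model$stack[p1, p2rev]
      } else if (a == 0L || b == 0L) {
        if (a + b > max_bulge) return(Inf)
        e <- e + model$bulge[a + b] +
          if (a + b == 1L) model$stack[p1, p2rev] else 0
      } else {
        if (a > max_internal || b > max_internal) return(Inf)
        e <- e + model$internal[a + b] +
          min(model$ninio[["max"]], model$ninio[["slope"]] * abs(a - b))
      }
    }
  }
  for (r in c(1L, length(pi))) {
    if (paste0(tb[pi[r]], mb[pj[r]]) %in% c("AU", "UA", "GU", "UG")) {
      e <- e + model$terminal_au
    }
  }
  e
}

# Enumerate every structure that keeps miRNA seed positions 2..8 paired
# contiguously at target site s, with any subset of additional pairs under
# the loop constraints, and return the minimum oracle score.
oracle_duplex_mfe_at_site <- function(tb, mb, s, model, max_bulge = 9L,
                                      max_internal = 9L) {
  L <- length(mb); n <- length(tb)
  seed <- data.frame(i = s:(s + 6L), j = 8:2)
  best <- oracle_score(seed, tb, mb, model, max_bulge, max_internal)
  gap <- max(max_bulge, max_internal)
  ok_pair <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "CG", "GC", "GU", "UG")
  # enumerate 3' arm extensions (j > 8, i < s), outward from the seed
  arms3 <- list(data.frame(i = integer(0), j = integer(0)))
  grow <- function(acc, last_i, last_j) {
    res <- list(acc)
    if (last_j >= L || last_i <= 1L) return(res)
    for (j in (last_j + 1L):min(L, last_j + 1L + gap)) {
      for (i in max(1L, last_i - 1L - gap):(last_i - 1L)) {
        if (!ok_pair(tb[i], mb[j])) next
        res <- c(res, grow(rbind(acc, data.frame(i = i, j = j)), i, j))
      }
    }
    res
  }
  if (L > 8L && s > 1L) arms3 <- grow(arms3[[1L]], s, 8L)
  # enumerate 5' arm (j = 1, i > s+6)
  arms5 <- list(data.frame(i = integer(0), j = integer(0)))
  if (s + 6L < n) {
    for (i in seq(s + 7L, min(n, s + 7L + gap))) {
      if (ok_pair(tb[i], mb[1L])) {
        arms5 <- c(arms5, list(data.frame(i = i, j = 1L)))
      }
    }
  }
  for (a3 in arms3) for (a5 in arms5) {
    st <- rbind(a3, seed, a5)
    sc <- oracle_score(st, tb, mb, model, max_bulge, max_internal)
    if (sc < best) best <- sc
  }
  best
}

oracle_duplex_mfe <- function(window, mirna, model, max_bulge = 9L,
                              max_internal = 9L) {
  tb <- strsplit(chartr("tT", "uU", toupper(window)), "")[[1]]
  mb <- strsplit(chartr("tT", "uU", toupper(mirna)), "")[[1]]
  sites <- oracle_seed_scan(window, mirna)
  if (length(sites) == 0L) return(Inf)
  min(vapply(sites, function(s) {
    oracle_duplex_mfe_at_site(tb, mb, s, model, max_bulge, max_internal)
  }, numeric(1)))
}

# --- BH step-up, from the definition ---------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- hypergeometric upper tail by exhaustive enumeration (N <= 12) ---------
oracle_hyper_upper <- function(k, N, K, n) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(idx) sum(pop[idx]))
  mean(hits >= k)
}

# --- complete linkage by brute force (n <= 8) ------------------------------
# Returns the sequence of merge heights and the partition at every k.
oracle_complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition for label-free comparison
canon_partition <- function(lab) {
  match(lab, unique(lab))
}

# --- misc ------------------------------------------------------------------
random_rna_str <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

make_reference <- function(seqs, ids = NULL, families = NULL) {
  if (is.null(ids)) ids <- paste0("mir", seq_along(seqs))
  if (is.null(families)) families <- ids
  data.frame(mature_id = ids, family_id = families, sequence = seqs,
             stringsAsFactors = FALSE)
}
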
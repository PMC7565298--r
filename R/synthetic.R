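# Synthetic-data generator: produces every pipeline input with the
# statistical structure the analysis assumes (6 timepoints x 8 replicates
# of NB-distributed miRNA counts with three planted fold-change archetypes,
# microarray-like log2 intensities with genes anti-correlated to the
# archetype mean profiles, 3'UTRs with planted high-affinity seed sites,
# adapter-ligated 75 nt reads), plus a ground-truth record for recovery
# tests.

#' The three planted fold-change archetypes
#'
#' Log2 fold-change trajectories over T2..T6 (each relative to T1):
#' archetype I is a sustained, monotone decrease reaching at least -1 by
#' one month post seawater transfer; archetype II is flat except for a
#' pronounced dip at one week post transfer (T5); archetype III is a
#' sustained increase through the experimental period.
#'
#' @return 3 x 5 numeric matrix, rows `I`, `II`, `III`, columns `T2`..`T6`.
#' @export
archetype_profiles <- function() {
  matrix(c(-0.8, -1.4, -1.8, -1.8, -2.2,
           -0.4, -0.2,  0.1, -2.2,  0.4,
            0.4,  0.7,  1.0,  1.3,  1.5),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("I", "II", "III"), paste0("T", 2:6)))
}

#' Simulation configuration
#'
#' Collects and validates all generator parameters.  Defaults mirror the
#' study design at desk scale: 6 timepoints with 8 sequenced replicates
#' each, three fold-change archetypes of sizes 34/14/23, 11 and 70 genes
#' anti-correlated to archetypes I and III, and 42 planted (miRNA, gene)
#' target pairs split 6/36 between archetypes I and III.
#'
#' @param n_replicates sequenced replicates per timepoint (>= 2).
#' @param n_mirnas total mature miRNAs in the reference.
#' @param n_genes total genes on the synthetic array.
#' @param n_de_per_archetype named counts of DE miRNAs per archetype
#'   (`I`, `II`, `III`); the remainder are nulls.
#' @param archetype_effects 3 x 5 log2FC trajectory matrix (see
#'   [archetype_profiles()]).
#' @param nb_dispersion shared NB dispersion of the counts.
#' @param mean_count_range T1 baseline mean counts are drawn log-uniformly
#'   from this range.
#' @param n_anti_per_archetype genes anti-correlated to each archetype
#'   mean profile.
#' @param n_pairs_per_archetype planted (miRNA, gene) pairs per archetype;
#'   each pair plants one high-affinity site in the gene's 3'UTR.  Must not
#'   exceed `n_anti_per_archetype` (one planted site per gene).
#' @param utr_length_range 3'UTR lengths (nt).
#' @param mfe_margin planted duplexes must score at least this many
#'   kcal/mol below the -18 kcal/mol reporting threshold.
#' @param mrna_replicates arrays per timepoint.
#' @param mrna_noise_sd Gaussian noise SD of the log2 intensities.
#' @param mrna_gain anti-correlation gain: a planted gene's expected log2FC
#'   profile is `-mrna_gain` times its archetype mean profile.
#' @param contaminant_fraction expected fraction of simulated raw reads
#'   whose post-trim length falls outside 18-25 nt.
#' @param rng_seed integer seed; all outputs are reproducible given the
#'   configuration.
#' @return object of class `sim_config` (a validated list; also records
#'   `n_timepoints = 6`, `timepoints = T1..T6` and
#'   `n_planted_pairs = sum(n_pairs_per_archetype)`).
#' @export
sim_config <- function(n_replicates = 8L, n_mirnas = 120L, n_genes = 600L,
                       n_de_per_archetype = c(I = 34L, II = 14L, III = 23L),
                       archetype_effects = archetype_profiles(),
                       nb_dispersion = 0.05,
                       mean_count_range = c(100, 1000),
                       n_anti_per_archetype = c(I = 11L, II = 0L, III = 70L),
                       n_pairs_per_archetype = c(I = 6L, II = 0L, III = 36L),
                       utr_length_range = c(200L, 400L),
                       mfe_margin = 4,
                       mrna_replicates = 5L,
                       mrna_noise_sd = 0.25,
                       mrna_gain = 0.8,
                       contaminant_fraction = 0.05,
                       rng_seed = 1L) {
  cfg <- list(n_timepoints = 6L, timepoints = paste0("T", 1:6),
              n_replicates = as.integer(n_replicates),
              n_mirnas = as.integer(n_mirnas),
              n_genes = as.integer(n_genes),
              n_de_per_archetype = n_de_per_archetype,
              archetype_effects = archetype_effects,
              nb_dispersion = nb_dispersion,
              mean_count_range = mean_count_range,
              n_anti_per_archetype = n_anti_per_archetype,
              n_pairs_per_archetype = n_pairs_per_archetype,
              n_planted_pairs = sum(n_pairs_per_archetype),
              utr_length_range = utr_length_range,
              mfe_margin = mfe_margin,
              mrna_replicates = as.integer(mrna_replicates),
              mrna_noise_sd = mrna_noise_sd,
              mrna_gain = mrna_gain,
              contaminant_fraction = contaminant_fraction,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_replicates >= 2L, cfg$n_mirnas > 0L, cfg$n_genes > 0L,
            all(cfg$n_de_per_archetype >= 0L),
            cfg$nb_dispersion >= 0,
            all(cfg$mean_count_range > 0),
            diff(cfg$mean_count_range) >= 0,
            all(cfg$utr_length_range > 0),
            cfg$mfe_margin >= 0, cfg$mrna_replicates >= 2L,
            cfg$mrna_noise_sd >= 0, cfg$mrna_gain > 0,
            cfg$contaminant_fraction >= 0, cfg$contaminant_fraction < 1)
  if (sum(cfg$n_de_per_archetype) > cfg$n_mirnas) {
    stop("n_de_per_archetype must sum to at most n_mirnas")
  }
  if (sum(cfg$n_anti_per_archetype) > cfg$n_genes) {
    stop("n_anti_per_archetype must sum to at most n_genes")
  }
  if (any(cfg$n_pairs_per_archetype > cfg$n_anti_per_archetype)) {
    stop("n_pairs_per_archetype cannot exceed n_anti_per_archetype")
  }
  eff <- cfg$archetype_effects
  stopifnot(nrow(eff) == 3L, ncol(eff) == 5L)
  if (any(diff(eff["I", ]) > 1e-9) || eff["I", 5] > -1) {
    stop("archetype I must be monotone non-increasing and <= -1 by T6")
  }
  if (which.min(eff["II", ]) != 4L || abs(eff["II", 4]) < 1 ||
      any(abs(eff["II", -4]) >= 1)) {
    stop("archetype II must have its minimum at T5 with |log2FC| >= 1 at T5 only")
  }
  if (max(eff["III", ]) < 1) {
    stop("archetype III must reach +1 at some timepoint")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: 6 timepoints x", x$n_replicates, "replicates;",
      x$n_mirnas, "miRNAs (DE ",
      paste(x$n_de_per_archetype, collapse = "/"), "),",
      x$n_genes, "genes (anti ",
      paste(x$n_anti_per_archetype, collapse = "/"), "),",
      x$n_planted_pairs, "planted pairs; seed", x$rng_seed, "\n")
  invisible(x)
}

# Random RNA strings of the given lengths, drawn from a shared pool for
# speed (substring of one long random string).
random_rna <- function(lengths, alphabet = c("A", "C", "G", "U")) {
  vapply(lengths, function(L) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate the miRNA count matrix, reference and ground truth
#'
#' Counts are NB with shared dispersion: a DE miRNA of archetype `a` has
#' mean `baseline * 2^effect_a(t)` at timepoint `t` (effect 0 at T1);
#' null miRNAs keep a constant mean.  Per-sample size factors are drawn
#' log-uniformly in `[0.5, 2]` so the normalization stage matters.  The
#' generated reference groups matures into miRNA gene families of 1-4
#' members with random 20-24 nt sequences, and the ground truth fixes the
#' anti-correlated gene ids and the planted (miRNA, gene) pairs used by
#' the downstream generators.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (integer matrix, miRNAs x 48 samples),
#'   `timepoints` (named labels), `reference` (data.frame `mature_id`,
#'   `family_id`, `sequence`), and `truth` (list: `de_mirnas` per
#'   archetype, `null_mirnas`, `anti_genes` per archetype, `null_genes`,
#'   `planted_pairs` data.frame, `baselines`, `size_factors`,
#'   `archetype_effects`).
#' @export
simulate_mirna_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, {
    nmir <- config$n_mirnas
    # family structure: groups of 1-4 matures
    fam_sizes <- integer(0)
    while (sum(fam_sizes) < nmir) {
      fam_sizes <- c(fam_sizes, sample(c(1L, 1L, 1L, 2L, 2L, 3L, 4L), 1L))
    }
    fam_sizes[length(fam_sizes)] <-
      fam_sizes[length(fam_sizes)] - (sum(fam_sizes) - nmir)
    fam_sizes <- fam_sizes[fam_sizes > 0L]
    family <- rep(sprintf("sim-fam-%03d", seq_along(fam_sizes)), fam_sizes)
    member <- unlist(lapply(fam_sizes, seq_len))
    arm <- sample(c("5p", "3p"), nmir, replace = TRUE)
    ids <- sprintf("ssa-sim-miR-%03d%s-%s",
                   rep(seq_along(fam_sizes), fam_sizes),
                   letters[member], arm)
    repeat {
      seqs <- random_rna(sample(20:24, nmir, replace = TRUE))
      if (!anyDuplicated(seqs)) break
    }
    reference <- data.frame(mature_id = ids, family_id = family,
                            sequence = seqs, stringsAsFactors = FALSE)

    nde <- config$n_de_per_archetype
    de_ids <- split(ids[seq_len(sum(nde))],
                    factor(rep(c("I", "II", "III"), nde),
                           levels = c("I", "II", "III")))
    de_ids <- lapply(de_ids, as.character)
    null_ids <- ids[seq_len(nmir) > sum(nde)]

    baselines <- stats::setNames(
      exp(stats::runif(nmir, log(config$mean_count_range[1]),
                       log(config$mean_count_range[2]))), ids)
    samples <- paste0(rep(config$timepoints, each = config$n_replicates), "_",
                      rep(seq_len(config$n_replicates), config$n_timepoints))
    timepoints <- stats::setNames(
      rep(config$timepoints, each = config$n_replicates), samples)
    sf <- stats::setNames(
      exp(stats::runif(length(samples), log(0.5), log(2))), samples)

    eff <- matrix(0, nrow = nmir, ncol = 6,
                  dimnames = list(ids, config$timepoints))
    for (a in c("I", "II", "III")) {
      if (length(de_ids[[a]]) == 0L) next
      eff[de_ids[[a]], 2:6] <- matrix(config$archetype_effects[a, ],
                                      nrow = length(de_ids[[a]]),
                                      ncol = 5, byrow = TRUE)
    }
    mu <- baselines * 2^eff                    # miRNAs x timepoints
    mu_s <- mu[, timepoints] %*% diag(sf)      # scale by size factor
    counts <- matrix(
      if (config$nb_dispersion < 1e-12) {
        stats::rpois(length(mu_s), lambda = mu_s)
      } else {
        stats::rnbinom(length(mu_s), mu = mu_s,
                       size = 1 / config$nb_dispersion)
      },
      nrow = nmir, dimnames = list(ids, samples))
    storage.mode(counts) <- "integer"

    genes <- sprintf("gene%04d", seq_len(config$n_genes))
    nanti <- config$n_anti_per_archetype
    anti <- split(genes[seq_len(sum(nanti))],
                  factor(rep(c("I", "II", "III"), nanti),
                         levels = c("I", "II", "III")))
    anti <- lapply(anti, as.character)
    null_genes <- genes[seq_len(config$n_genes) > sum(nanti)]

    pairs <- do.call(rbind, lapply(c("I", "II", "III"), function(a) {
      np <- config$n_pairs_per_archetype[[a]]
      if (np == 0L) return(NULL)
      data.frame(mirna = sample(de_ids[[a]], np, replace = TRUE),
                 gene = sample(anti[[a]], np, replace = FALSE),
                 archetype = a, stringsAsFactors = FALSE)
    }))
    if (is.null(pairs)) {
      pairs <- data.frame(mirna = character(0), gene = character(0),
                          archetype = character(0))
    }

    list(counts = counts, timepoints = timepoints, reference = reference,
         truth = list(de_mirnas = de_ids, null_mirnas = null_ids,
                      anti_genes = anti, null_genes = null_genes,
                      planted_pairs = pairs, baselines = baselines,
                      size_factors = sf,
                      archetype_effects = config$archetype_effects))
  })
}

#' Simulate microarray-like log2 expression
#'
#' Genes anti-correlated to archetype `a` get per-sample log2 intensity
#' `baseline - gain * mean_a(t) + N(0, sd)` (mean 0 at T1); background
#' genes are baseline plus noise only.  Errors when the configured noise
#' makes the expected gene-vs-cluster-mean correlation weaker than -0.67,
#' since the planted truth would then be unrecoverable.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_mirna_counts()].
#' @param cluster_means 3 x 5 archetype mean profiles (defaults to the
#'   truth's trajectories).
#' @return list with `expr` (genes x samples log2 matrix) and `timepoints`.
#' @export
simulate_mrna_expression <- function(config, truth, cluster_means = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cluster_means)) cluster_means <- truth$archetype_effects
  stopifnot(nrow(cluster_means) == 3L, ncol(cluster_means) == 5L)
  m <- config$mrna_replicates
  g <- config$mrna_gain
  sdn <- config$mrna_noise_sd
  for (a in c("I", "II", "III")) {
    if (length(truth$anti_genes[[a]]) == 0L) next
    mu <- cluster_means[a, ]
    rho <- g * stats::sd(mu) /
      sqrt(g^2 * stats::var(mu) + 2 * sdn^2 / m + 1e-12)
    if (rho < 0.67) {
      stop("mrna_noise_sd too large: expected |r| = ", round(rho, 3),
           " < 0.67 for archetype ", a, " - planted truth unrecoverable")
    }
  }
  withr::with_seed(config$rng_seed + 1L, {
    genes <- c(unlist(truth$anti_genes, use.names = FALSE), truth$null_genes)
    genes <- genes[order(genes)]
    samples <- paste0(rep(config$timepoints, each = m), "_a",
                      rep(seq_len(m), config$n_timepoints))
    timepoints <- stats::setNames(rep(config$timepoints, each = m), samples)
    baseline <- stats::setNames(stats::rnorm(length(genes), 8, 1), genes)
    eff <- matrix(0, nrow = length(genes), ncol = 6,
                  dimnames = list(genes, config$timepoints))
    for (a in c("I", "II", "III")) {
      ag <- truth$anti_genes[[a]]
      if (length(ag) == 0L) next
      eff[ag, 2:6] <- matrix(-g * cluster_means[a, ], nrow = length(ag),
                             ncol = 5, byrow = TRUE)
    }
    expr <- baseline + eff[, timepoints] +
      matrix(stats::rnorm(length(genes) * length(samples), 0, sdn),
             nrow = length(genes))
    dimnames(expr) <- list(genes, samples)
    list(expr = expr, timepoints = timepoints)
  })
}

#' Simulate 3'UTR sequences with planted high-affinity sites
#'
#' Every planted (miRNA, gene) pair gets the exact Watson-Crick reverse
#' complement of the full miRNA embedded at a random position of the
#' gene's UTR, guaranteeing a perfect seed site whose duplex minimum free
#' energy is verified to be at most `-18 - mfe_margin` kcal/mol under the
#' shipped energy model.  All other UTRs are decoys, rejection-sampled to
#' contain no 7-mer seed complement of any planted miRNA.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_mirna_counts()].
#' @param mirna_seqs named character vector of mature miRNA sequences
#'   (RNA or DNA), covering at least the planted miRNAs.
#' @param model energy model used for the construction check.
#' @return list with `utrs` (named character vector, RNA alphabet) and
#'   `planted_sites` (data.frame `mirna`, `gene`, `site_start`,
#'   `site_end`, `mfe`).
#' @export
simulate_utrs <- function(config, truth, mirna_seqs, model = energy_model()) {
  stopifnot(inherits(config, "sim_config"))
  mirna_seqs <- vapply(mirna_seqs, as_rna, character(1))
  pairs <- truth$planted_pairs
  if (nrow(pairs) > 0L) {
    lens <- nchar(mirna_seqs[pairs$mirna])
    if (any(is.na(lens)) || any(lens < 8L)) {
      stop("planted miRNAs must have sequences of at least 8 nt")
    }
  }
  withr::with_seed(config$rng_seed + 2L, {
    genes <- c(unlist(truth$anti_genes, use.names = FALSE), truth$null_genes)
    genes <- genes[order(genes)]
    planted_seeds <- unique(rna_revcomp(
      substr(mirna_seqs[unique(pairs$mirna)], 2L, 8L)))
    utrs <- stats::setNames(character(length(genes)), genes)
    sites <- NULL
    for (gn in genes) {
      L_u <- sample(seq(config$utr_length_range[1],
                        config$utr_length_range[2]), 1L)
      rows <- if (nrow(pairs) > 0L) which(pairs$gene == gn) else integer(0)
      if (length(rows) > 0L) {
        # planted UTR: embed the full reverse complement of each miRNA
        utr <- random_rna(L_u)
        for (r in rows) {
          mseq <- mirna_seqs[[pairs$mirna[r]]]
          block <- rna_revcomp(mseq)
          L <- nchar(block)
          e <- sample.int(L_u - L + 1L, 1L)
          utr <- paste0(substr(utr, 1L, e - 1L), block,
                        substr(utr, e + L, L_u))
          site_start <- e + L - 8L
          res <- duplex_mfe(substr(utr, max(1L, e - 10L),
                                   min(L_u, e + L + 9L)), mseq, model)
          if (res$mfe > -18 - config$mfe_margin) {
            stop("planted site for ", pairs$mirna[r], " in ", gn,
                 " scored ", round(res$mfe, 2), " kcal/mol, above the ",
                 -18 - config$mfe_margin, " construction bound")
          }
          sites <- rbind(sites, data.frame(
            mirna = pairs$mirna[r], gene = gn,
            site_start = site_start, site_end = site_start + 6L,
            mfe = res$mfe, stringsAsFactors = FALSE))
        }
        utrs[[gn]] <- utr
      } else {
        # decoy UTR: no seed complement of any planted miRNA
        ok <- FALSE
        for (attempt in seq_len(100L)) {
          utr <- random_rna(L_u)
          hit <- any(vapply(planted_seeds, function(s) {
            grepl(s, utr, fixed = TRUE)
          }, logical(1)))
          if (!hit) { ok <- TRUE; break }
        }
        if (!ok) {
          stop("could not make a seed-free decoy UTR for ", gn,
               " in 100 attempts")
        }
        utrs[[gn]] <- utr
      }
    }
    list(utrs = utrs, planted_sites = sites)
  })
}

#' Simulate adapter-ligated small-RNA reads
#'
#' Each counted read is the mature miRNA sequence (DNA alphabet) followed
#' by the 3' adapter and random downstream bases, padded or truncated to
#' 75 nt.  A configurable fraction of contaminant reads have post-trim
#' lengths outside 18-25 nt (random inserts of 5-17 or 26-40 nt).  All
#' bases carry Phred quality 40.
#'
#' @param config a [sim_config()].
#' @param counts count matrix from [simulate_mirna_counts()] (features
#'   must match the reference).
#' @param reference miRNA reference data.frame (`mature_id`, `sequence`).
#' @param contaminant_fraction overrides the configured fraction if given.
#' @return named list, one character vector of 75 nt read sequences per
#'   sample, with the per-sample contaminant counts as attribute
#'   `"contaminants"`.
#' @export
simulate_reads <- function(config, counts, reference,
                           contaminant_fraction = config$contaminant_fraction) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed + 3L, {
    dna <- chartr("U", "T", reference$sequence)
    names(dna) <- reference$mature_id
    pool_n <- 200000L
    pool <- paste(sample(c("A", "C", "G", "T"), pool_n, replace = TRUE),
                  collapse = "")
    pad_to_75 <- function(inserts) {
      body <- paste0(inserts, SMOLT_ADAPTER)
      need <- pmax(0L, 75L - nchar(body))
      starts <- sample.int(pool_n - 80L, length(body), replace = TRUE)
      substr(paste0(body, substring(pool, starts, starts + need - 1L)),
             1L, 75L)
    }
    out <- list()
    ncont <- integer(ncol(counts))
    for (j in seq_len(ncol(counts))) {
      inserts <- rep(dna[rownames(counts)], counts[, j])
      f <- contaminant_fraction
      nc <- if (f > 0) {
        stats::rbinom(1L, length(inserts), f / (1 - f))
      } else 0L
      if (nc > 0L) {
        clen <- sample(c(5:17, 26:40), nc, replace = TRUE)
        cstart <- sample.int(pool_n - 50L, nc, replace = TRUE)
        cont <- substring(pool, cstart, cstart + clen - 1L)
        inserts <- c(inserts, cont)
      }
      reads <- pad_to_75(inserts)
      out[[colnames(counts)[j]]] <- sample(reads)   # shuffle read order
      ncont[j] <- nc
    }
    attr(out, "contaminants") <- stats::setNames(ncont, colnames(counts))
    out
  })
}

#' Write reads to a FASTQ file
#'
#' @param seqs character vector of read sequences (DNA).
#' @param path output FASTQ path.
#' @param ids read ids (defaults to `read1..readN`).
#' @param qual_char constant Phred+33 quality character (default `"I"`,
#'   Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, ids = NULL, qual_char = "I") {
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep(qual_char, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Simulate a gene-to-term annotation table
#'
#' Background terms are assigned to genes at random (about two terms per
#' gene); one planted term (`GO:PLANTED`, "planted regulatory program") is
#' concentrated in the anti-correlated gene set so the enrichment stage of
#' a synthetic run has a true positive to find.  A small hierarchy links
#' every background term to one of three broad parent terms.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_mirna_counts()].
#' @param n_terms number of background terms.
#' @return list with `annotation` (data.frame `gene`, `term`, `name`) and
#'   `parents` (data.frame `term`, `parent`).
#' @export
simulate_annotation <- function(config, truth, n_terms = 40L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed + 4L, {
    genes <- c(unlist(truth$anti_genes, use.names = FALSE), truth$null_genes)
    genes <- genes[order(genes)]
    terms <- sprintf("GO:%04d", seq_len(n_terms))
    k <- pmin(stats::rpois(length(genes), 2) + 1L, n_terms)
    ann <- data.frame(
      gene = rep(genes, k),
      term = unlist(lapply(k, function(m) sample(terms, m))),
      stringsAsFactors = FALSE)
    anti <- unlist(truth$anti_genes, use.names = FALSE)
    planted_genes <- c(anti[stats::runif(length(anti)) < 0.6],
                       truth$null_genes[
                         stats::runif(length(truth$null_genes)) < 0.02])
    if (length(planted_genes) > 0L) {
      ann <- rbind(ann, data.frame(gene = planted_genes, term = "GO:PLANTED",
                                   stringsAsFactors = FALSE))
    }
    ann$name <- ifelse(ann$term == "GO:PLANTED",
                       "planted regulatory program", ann$term)
    broad <- sprintf("GO:broad%d", 1:3)
    parents <- data.frame(term = terms,
                          parent = sample(broad, n_terms, replace = TRUE),
                          stringsAsFactors = FALSE)
    list(annotation = ann[order(ann$gene, ann$term), ], parents = parents)
  })
}
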
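# Adapter trimming, size selection, unique mapping, and the quantification
# chain.

test_that("adapter trimming truncates at the leftmost adapter occurrence", {
  insert <- "TGAGGTAGTAGGTTGTATAGTT"        # 22 nt
  read <- paste0(insert, SMOLT_ADAPTER, "ACGTACGTACGTACGTACG")
  expect_identical(trim_adapter(substr(read, 1, 75)), insert)
  # no adapter anywhere: untrimmed marker
  expect_identical(trim_adapter(strrep("C", 40)), NA_character_)
  # only the first 5 adapter bases fit at the 3' end
  read2 <- paste0(insert, substr(SMOLT_ADAPTER, 1, 5))
  expect_identical(trim_adapter(read2, min_overlap = 3), insert)
  expect_identical(trim_adapter(read2), oracle_trim(read2, SMOLT_ADAPTER))
  expect_error(trim_adapter(c("ACGT", "")), "empty read")
})

test_that("trimming matches the naive all-suffixes oracle on random reads", {
  set.seed(11)
  ad <- SMOLT_ADAPTER
  reads <- vapply(1:300, function(i) {
    ins <- paste(sample(c("A", "C", "G", "T"), sample(5:40, 1), TRUE),
                 collapse = "")
    switch(sample(3, 1),
           substr(paste0(ins, ad, ins), 1, 75),                  # full adapter
           paste0(ins, substr(ad, 1, sample(0:12, 1))),          # partial end
           ins)                                                  # none
  }, character(1))
  got <- trim_adapter(reads, ad)
  want <- vapply(reads, oracle_trim, character(1), adapter = ad,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("size selection keeps 18-25 nt inclusively", {
  reads <- vapply(c(17, 18, 22, 25, 26), function(n) strrep("A", n),
                  character(1))
  f <- filter_by_length(reads)
  expect_identical(nchar(f$kept), c(18L, 22L, 25L))
  expect_identical(f$discarded, c(short = 1L, long = 1L))
  e <- filter_by_length(character(0))
  expect_identical(e$kept, character(0))
  expect_identical(e$discarded, c(short = 0L, long = 0L))
})

test_that("mapping counts unique end-to-end hits only", {
  ref <- make_reference(c("UGAGGUAGUAGGUUGUAUAGUU",
                          "ACGUACGUACGUACGUACGU",
                          "ACGUACGUACGUACGUACGU"))   # mir2 and mir3 identical
  r1 <- map_and_count("TGAGGTAGTAGGTTGTATAGTT", ref)
  expect_identical(unname(r1$counts), c(1L, 0L, 0L))
  # a read matching the two identical paralogs is multimapped, counted nowhere
  r2 <- map_and_count("ACGTACGTACGTACGTACGT", ref)
  expect_identical(sum(r2$counts), 0L)
  expect_identical(unname(r2$stats["multimapped"]), 1L)
  expect_error(map_and_count("ACGT", make_reference(c("ACGUACGUACGUACGUAC",
                                                      "CCGUACGUACGUACGUAC"),
                                                    ids = c("a", "a"))),
               "duplicate mature ids")
})

test_that("bounded-mismatch mapping matches hand enumeration on a fixture", {
  refseq <- c("TGAGGTAGTAGGTTGTATAGTT",     # 22
              "ACGTACGTACGTACGTACGT",       # 20
              "TTTTGGGGCCCCAAAATTTTGG")     # 22
  ref <- make_reference(chartr("T", "U", refseq))
  mm1 <- paste0("A", substr(refseq[1], 2, 22))         # 1 mismatch vs ref 1
  mm1_vs3 <- paste0("A", substr(refseq[3], 2, 22))     # 1 mismatch vs ref 3
  reads <- c(rep(refseq[1], 40), rep(refseq[2], 30), rep(refseq[3], 20),
             rep(mm1, 5), rep(mm1_vs3, 4), strrep("G", 21))
  r0 <- map_and_count(reads, ref, max_mismatches = 0)
  expect_identical(unname(r0$counts), c(40L, 30L, 20L))
  expect_identical(unname(r0$stats["unmapped"]), 10L)
  r1 <- map_and_count(reads, ref, max_mismatches = 1)
  expect_identical(unname(r1$counts), c(45L, 30L, 24L))
  expect_identical(unname(r1$stats["unmapped"]), 1L)
})

test_that("quantification conserves every raw read in the tallies", {
  cfg <- sim_config(n_replicates = 2, n_mirnas = 12, n_genes = 20,
                    n_de_per_archetype = c(I = 2, II = 1, III = 1),
                    n_anti_per_archetype = c(I = 2, II = 0, III = 4),
                    n_pairs_per_archetype = c(I = 1, II = 0, III = 2),
                    mean_count_range = c(20, 60), rng_seed = 5)
  sim <- simulate_mirna_counts(cfg)
  reads <- simulate_reads(cfg, sim$counts, sim$reference,
                          contaminant_fraction = 0.1)
  q <- quantify_smallrna(reads, sim$reference, sim$timepoints)
  with(q$stats, expect_identical(
    raw, untrimmed + short + long + mapped + multimapped + unmapped))
  expect_true(all(q$stats$mean_retained_len > 18,
                  q$stats$mean_retained_len < 25))
})

test_that("zero-contaminant reads round-trip to the exact simulated counts", {
  cfg <- sim_config(n_replicates = 2, n_mirnas = 10, n_genes = 20,
                    n_de_per_archetype = c(I = 2, II = 1, III = 1),
                    n_anti_per_archetype = c(I = 2, II = 0, III = 4),
                    n_pairs_per_archetype = c(I = 1, II = 0, III = 2),
                    mean_count_range = c(20, 80), rng_seed = 8)
  sim <- simulate_mirna_counts(cfg)
  reads <- simulate_reads(cfg, sim$counts, sim$reference,
                          contaminant_fraction = 0)
  q <- quantify_smallrna(reads, sim$reference, sim$timepoints)
  expect_identical(q$counts, sim$counts)
  # mean retained read length sits near the 22 nt the protocol selects for
  expect_lt(abs(mean(q$stats$mean_retained_len) - 22), 1)
})

test_that("FASTQ round trip through files preserves reads", {
  dir <- withr::local_tempdir()
  seqs <- c("TGAGGTAGTAGGTTGTATAGTT", "ACGTACGTACGTACGTACGT")
  path <- file.path(dir, "s1.fastq")
  write_fastq(seqs, path)
  back <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  expect_identical(unname(back), seqs)
  # Phred qualities are written at or above the protocol's Q32 floor
  qline <- readLines(path)[4]
  expect_true(all(utf8ToInt(qline) - 33L >= 32L))
})

test_that("miRNA family ids are derived from mature names", {
  expect_identical(
    mirna_family(c("ssa-miR-146a-3-3p", "ssa-let-7b-3p",
                   "ssa-miR-novel-12-5p", "ssa-miR-217-5p")),
    c("miR-146", "let-7", "miR-novel-12", "miR-217"))
})
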
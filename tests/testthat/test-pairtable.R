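# Major-expressed flags, pair-table construction and summaries, and the
# published-table fixture round trip.

test_that("major expressed flags pick the top mature per family, ties share", {
  ref <- make_reference(rep("ACGUACGUACGUACGUACGU", 6),
                        ids = paste0("m", 1:6),
                        families = c("solo", "quad", "quad", "quad", "quad",
                                     "tie"))
  ref$sequence <- vapply(1:6, function(i) random_rna_str(20), character(1))
  cnt <- matrix(c(50, 100, 5, 3, 1, 80), nrow = 6,
                dimnames = list(paste0("m", 1:6), "s1"))
  cnt <- cbind(cnt, s2 = cnt[, 1])
  f <- flag_major_expressed(cnt, ref, sf = setNames(c(1, 1), colnames(cnt)))
  expect_true(f[["m1"]])                      # family of one
  expect_identical(unname(f[2:5]), c(TRUE, FALSE, FALSE, FALSE))
  ref2 <- rbind(ref, data.frame(mature_id = "m7", family_id = "tie",
                                sequence = random_rna_str(20)))
  cnt2 <- rbind(cnt, m7 = c(80, 80))
  f2 <- flag_major_expressed(cnt2, ref2,
                             sf = setNames(c(1, 1), colnames(cnt2)))
  expect_true(f2[["m6"]] && f2[["m7"]])       # tie flags both
  cnt3 <- rbind(cnt, m7 = c(0, 0))
  ref3 <- rbind(ref, data.frame(mature_id = "m7", family_id = "empty",
                                sequence = random_rna_str(20)))
  expect_warning(f3 <- flag_major_expressed(cnt3, ref3,
                                            sf = setNames(c(1, 1),
                                                          colnames(cnt3))),
                 "zero counts")
  expect_false(f3[["m7"]])
})

test_that("pair-table construction enforces the negative-to-own-cluster rule", {
  hits <- data.frame(mirna = c("mA", "mA", "mB", "mC"),
                     utr = c("g1", "g2", "g1", "g3"),
                     site_start = c(5L, 9L, 7L, 2L),
                     mfe = c(-20, -21, -19, -25))
  ann <- data.frame(gene = c("g1", "g2", "g3"),
                    r_1 = c(-0.9, 0.1, -0.2), r_2 = c(0.2, -0.8, 0.1),
                    dir_1 = c("negative", "none", "none"),
                    dir_2 = c("none", "negative", "none"))
  labels <- c(mA = 1, mB = 2, mC = 1)
  flags <- c(mA = TRUE, mB = FALSE, mC = TRUE)
  pt <- build_pair_table(hits, ann, labels, flags)
  # mA/g1: negative to cluster 1 = kept; mA/g2 negative to 2 but mA is in 1:
  # dropped; mB/g1: gene negative to 1 not 2: dropped; g3 not negative: dropped
  expect_identical(nrow(pt), 1L)
  expect_identical(pt$gene, "g1")
  expect_identical(pt$mirna, "mA")
  expect_true(pt$major_expressed)
  expect_error(build_pair_table(hits, ann, labels[-3], flags),
               "without a cluster label")
  # duplicate sites collapse to the lowest MFE
  hits2 <- data.frame(mirna = "mA", utr = "g1", site_start = c(5L, 40L),
                      mfe = c(-20, -24))
  pt2 <- build_pair_table(hits2, ann, labels, flags)
  expect_identical(nrow(pt2), 1L)
  expect_identical(pt2$mfe, -24)
  expect_identical(pt2$site_start, 40L)
})

test_that("pair summaries count a single pair trivially", {
  p <- data.frame(gene = "g", mirna = "m", cluster = "I",
                  major_expressed = TRUE)
  s <- summarize_pair_table(p)
  expect_identical(s$n_pairs, 1L)
  expect_identical(s$n_target_genes, 1L)
  expect_identical(s$n_targeting_mirnas, 1L)
  expect_equal(s$major_coverage, 1)
  expect_error(summarize_pair_table(p[0, ]), "empty")
})

test_that("the published pair table summarizes to the reported counts", {
  t4 <- load_table4_fixture()
  s <- summarize_pair_table(t4)
  expect_identical(s$n_target_genes, 42L)
  pc <- s$per_cluster
  expect_identical(pc$n_genes[pc$cluster == "I"], 6L)
  expect_identical(pc$n_genes[pc$cluster == "III"], 36L)
  expect_identical(pc$n_mirnas[pc$cluster == "I"], 8L)
  expect_identical(pc$n_mirnas[pc$cluster == "III"], 18L)
  expect_identical(unname(s$per_mirna_degree[["ssa-miR-217-5p"]]), 8L)
  expect_identical(unname(s$per_gene_degree[["nrip2"]]), 6L)
  expect_equal(round(100 * s$major_coverage), 86)
})

test_that("re-joining the published table from its components is lossless", {
  t4 <- load_table4_fixture()
  hits <- data.frame(mirna = t4$mirna, utr = t4$gene,
                     site_start = seq_len(nrow(t4)), mfe = -20)
  labels <- tapply(t4$cluster, t4$mirna, function(x) x[1])
  genes <- unique(t4$gene)
  ann <- data.frame(gene = genes,
                    r_I = ifelse(genes %in% t4$gene[t4$cluster == "I"],
                                 -0.9, 0),
                    r_III = ifelse(genes %in% t4$gene[t4$cluster == "III"],
                                   -0.9, 0))
  ann$dir_I <- ifelse(ann$r_I < -0.67, "negative", "none")
  ann$dir_III <- ifelse(ann$r_III < -0.67, "negative", "none")
  flags <- tapply(t4$major_expressed, t4$mirna, any)
  pt <- build_pair_table(hits, ann, labels, flags)
  expect_identical(nrow(pt), nrow(t4))
  expect_setequal(paste(pt$gene, pt$mirna), paste(t4$gene, t4$mirna))
  s0 <- summarize_pair_table(t4)
  s1 <- summarize_pair_table(pt)
  expect_identical(s1$n_target_genes, s0$n_target_genes)
  expect_identical(s1$n_targeting_mirnas, s0$n_targeting_mirnas)
})

test_that("published cluster profile fixtures show the archetype shapes", {
  cp <- load_cluster_profile_fixture()
  expect_identical(nrow(cp), 54L)
  lfc <- as.matrix(cp[, paste0("lfc_T", 2:6)])
  mI <- colMeans(lfc[cp$cluster == "I", ])
  mII <- colMeans(lfc[cp$cluster == "II", ])
  mIII <- colMeans(lfc[cp$cluster == "III", ])
  expect_true(all(mI <= 0))
  expect_identical(unname(which.min(mI)), 5L)       # deepest at T6
  expect_identical(unname(which.min(mII)), 4L)      # dip at T5
  expect_true(all(mIII >= 0))
  # every profile passed the |log2FC| >= 1 criterion at some timepoint
  expect_true(all(apply(abs(lfc), 1, max) >= 1))
  # every profile carries at least one significant timepoint
  sig <- as.matrix(cp[, paste0("sig_T", 2:6)])
  expect_true(all(rowSums(sig) >= 1))
})
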
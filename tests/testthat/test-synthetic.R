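# Synthetic-data generator: configuration invariants, determinism,
# distributional checks, construction guarantees.

small_cfg <- function(seed = 1, ...) {
  sim_config(n_replicates = 3, n_mirnas = 24, n_genes = 40,
             n_de_per_archetype = c(I = 4, II = 2, III = 3),
             n_anti_per_archetype = c(I = 3, II = 0, III = 6),
             n_pairs_per_archetype = c(I = 2, II = 0, III = 4),
             mean_count_range = c(50, 200), rng_seed = seed, ...)
}

test_that("configuration invariants reject malformed archetypes", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(n_de_per_archetype = c(I = 100, II = 100, III = 100)),
               "at most n_mirnas")
  bad1 <- archetype_profiles(); bad1["I", 5] <- -0.5      # not <= -1 by T6
  expect_error(sim_config(archetype_effects = bad1), "archetype I")
  bad2 <- archetype_profiles(); bad2["II", 2] <- -3       # min not at T5
  expect_error(sim_config(archetype_effects = bad2), "archetype II")
  bad3 <- archetype_profiles(); bad3["III", ] <- rep(0.5, 5)
  expect_error(sim_config(archetype_effects = bad3), "archetype III")
  expect_error(sim_config(n_pairs_per_archetype = c(I = 12, II = 0, III = 36)),
               "n_anti_per_archetype")
})

test_that("identical configurations give bit-identical outputs", {
  cfg <- small_cfg(seed = 42)
  s1 <- simulate_mirna_counts(cfg)
  s2 <- simulate_mirna_counts(cfg)
  expect_identical(s1, s2)
  e1 <- simulate_mrna_expression(cfg, s1$truth)
  e2 <- simulate_mrna_expression(cfg, s2$truth)
  expect_identical(e1, e2)
  seqs <- setNames(s1$reference$sequence, s1$reference$mature_id)
  u1 <- simulate_utrs(cfg, s1$truth, seqs)
  u2 <- simulate_utrs(cfg, s1$truth, seqs)
  expect_identical(u1, u2)
  r1 <- simulate_reads(cfg, s1$counts, s1$reference)
  r2 <- simulate_reads(cfg, s1$counts, s1$reference)
  expect_identical(r1, r2)
})

test_that("ground-truth id sets are disjoint and pairs reference them", {
  sim <- simulate_mirna_counts(sim_config(rng_seed = 2))
  tr <- sim$truth
  de <- tr$de_mirnas
  expect_length(intersect(de$I, de$II), 0)
  expect_length(intersect(de$I, de$III), 0)
  expect_length(intersect(unlist(de), tr$null_mirnas), 0)
  expect_length(intersect(unlist(tr$anti_genes), tr$null_genes), 0)
  pp <- tr$planted_pairs
  expect_identical(nrow(pp), 42L)
  for (a in c("I", "III")) {
    sel <- pp$archetype == a
    expect_true(all(pp$mirna[sel] %in% de[[a]]))
    expect_true(all(pp$gene[sel] %in% tr$anti_genes[[a]]))
  }
  expect_false(anyDuplicated(pp$gene) > 0)      # one planted site per gene
})

test_that("an all-null simulation has small empirical fold changes", {
  cfg <- sim_config(n_replicates = 8, n_mirnas = 2000, n_genes = 10,
                    n_de_per_archetype = c(I = 0, II = 0, III = 0),
                    n_anti_per_archetype = c(I = 0, II = 0, III = 0),
                    n_pairs_per_archetype = c(I = 0, II = 0, III = 0),
                    mean_count_range = c(100, 1000), rng_seed = 33)
  sim <- simulate_mirna_counts(cfg)
  norm <- sweep(sim$counts, 2, sim$truth$size_factors, "/")
  lfc <- log2((rowMeans(norm[, sim$timepoints == "T2"]) + 0.5) /
              (rowMeans(norm[, sim$timepoints == "T1"]) + 0.5))
  expect_gte(mean(abs(lfc) <= 0.5), 0.95)
})

test_that("the zero-dispersion limit is Poisson", {
  cfg <- sim_config(n_replicates = 8, n_mirnas = 20, n_genes = 10,
                    n_de_per_archetype = c(I = 0, II = 0, III = 0),
                    n_anti_per_archetype = c(I = 0, II = 0, III = 0),
                    n_pairs_per_archetype = c(I = 0, II = 0, III = 0),
                    nb_dispersion = 0, mean_count_range = c(100, 100),
                    rng_seed = 44)
  sim <- simulate_mirna_counts(cfg)
  mu <- outer(rep(100, 20), sim$truth$size_factors)
  lo <- qpois(0.0005, mu); hi <- qpois(0.9995, mu)
  inside <- sim$counts >= lo & sim$counts <= hi
  expect_gte(mean(inside), 0.995)     # 99.9% envelope, small-sample slack
})

test_that("noise levels that bury the anti-correlation are rejected", {
  cfg <- small_cfg(seed = 3, mrna_noise_sd = 5)
  sim <- simulate_mirna_counts(cfg)
  expect_error(simulate_mrna_expression(cfg, sim$truth), "unrecoverable")
})

test_that("planted UTR sites are found and decoys are seed-free", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_mirna_counts(cfg)
  seqs <- setNames(sim$reference$sequence, sim$reference$mature_id)
  us <- simulate_utrs(cfg, sim$truth, seqs)
  expect_identical(nrow(us$planted_sites), 6L)
  for (r in seq_len(nrow(us$planted_sites))) {
    ps <- us$planted_sites[r, ]
    hits <- find_seed_sites(us$utrs[[ps$gene]], seqs[[ps$mirna]])
    expect_true(ps$site_start %in% hits)
    expect_lte(ps$mfe, -18 - cfg$mfe_margin)
    # the planted site survives the end-to-end prediction threshold
    hit <- predict_targets(seqs[ps$mirna], us$utrs[ps$gene])
    expect_true(ps$site_start %in% hit$site_start)
  }
  planted_mirnas <- unique(sim$truth$planted_pairs$mirna)
  decoys <- setdiff(names(us$utrs), sim$truth$planted_pairs$gene)
  for (g in decoys) {
    for (mi in planted_mirnas) {
      expect_length(find_seed_sites(us$utrs[[g]], seqs[[mi]]), 0)
    }
  }
})

test_that("simulated reads trim back to the mature length", {
  cfg <- small_cfg(seed = 21)
  sim <- simulate_mirna_counts(cfg)
  reads <- simulate_reads(cfg, sim$counts, sim$reference,
                          contaminant_fraction = 0)
  expect_true(all(nchar(reads[[1]]) == 75))
  trimmed <- trim_adapter(reads[[1]])
  expect_false(anyNA(trimmed))
  expect_setequal(unique(nchar(trimmed)),
                  unique(nchar(sim$reference$sequence[
                    sim$counts[, 1] > 0])))
})

test_that("the contaminant fraction is discarded at the configured rate", {
  cfg <- sim_config(n_replicates = 2, n_mirnas = 10, n_genes = 10,
                    n_de_per_archetype = c(I = 0, II = 0, III = 0),
                    n_anti_per_archetype = c(I = 0, II = 0, III = 0),
                    n_pairs_per_archetype = c(I = 0, II = 0, III = 0),
                    mean_count_range = c(800, 800), rng_seed = 55)
  sim <- simulate_mirna_counts(cfg)
  reads <- simulate_reads(cfg, sim$counts, sim$reference,
                          contaminant_fraction = 0.2)
  q <- quantify_smallrna(reads[1], sim$reference, "T1")
  n <- q$stats$raw
  discarded <- (q$stats$short + q$stats$long) / n
  ci <- qbinom(c(0.005, 0.995), n, 0.2) / n
  expect_gte(discarded, ci[1])
  expect_lte(discarded, ci[2])
})
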
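# Size factors, NB Wald test, Welch tests, BH adjustment, DE filters.

test_that("median-of-ratios size factors recover known scalings", {
  m <- matrix(c(10, 10, 20, 20, 30, 30), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("f", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(a = c(10, 20, 30), b = 2 * c(10, 20, 30))
  rownames(m2) <- paste0("f", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  # 5 features x 3 samples toy: equals the hand-computed median of ratios
  m3 <- matrix(c(4, 8, 16,
                 10, 10, 10,
                 6, 12, 6,
                 20, 40, 80,
                 100, 100, 200), nrow = 5, byrow = TRUE,
               dimnames = list(paste0("f", 1:5), c("s1", "s2", "s3")))
  geo <- apply(m3, 1, function(x) exp(mean(log(x))))
  raw <- apply(m3 / geo, 2, median)
  expect_equal(unname(size_factors(m3)), unname(raw / exp(mean(log(raw)))))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "all-positive")
})

test_that("NB Wald test is symmetric and unbiased for planted effects", {
  cnt <- matrix(rep(c(30, 50, 70, 90), each = 8), nrow = 4, byrow = TRUE,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:8)))
  cnt <- cbind(cnt, cnt)
  colnames(cnt) <- paste0("s", 1:16)
  r <- nb_wald_test(cnt, paste0("s", 1:8), paste0("s", 9:16),
                    sf = setNames(rep(1, 16), colnames(cnt)))
  expect_equal(r$log2FC, rep(0, 4))
  expect_equal(r$pvalue, rep(1, 4))
  # planted log2FC = -2 at basemean 200: mean estimate within +/- 0.3
  set.seed(91)
  nf <- 500
  A <- matrix(rnbinom(nf * 8, mu = 200, size = 20), nrow = nf)
  B <- matrix(rnbinom(nf * 8, mu = 50, size = 20), nrow = nf)
  cnt2 <- cbind(A, B)
  dimnames(cnt2) <- list(paste0("g", 1:nf), paste0("s", 1:16))
  r2 <- nb_wald_test(cnt2, paste0("s", 1:8), paste0("s", 9:16),
                     sf = setNames(rep(1, 16), colnames(cnt2)))
  expect_lt(abs(mean(r2$log2FC) + 2), 0.3)
  # all-zero features are flagged with p = 1
  cnt3 <- rbind(cnt2[1:3, ], zero = 0L)
  r3 <- nb_wald_test(cnt3, paste0("s", 1:8), paste0("s", 9:16),
                     sf = setNames(rep(1, 16), colnames(cnt3)))
  expect_true(r3$allzero[4])
  expect_identical(r3$pvalue[4], 1)
  expect_identical(r3$log2FC[4], 0)
  expect_error(nb_wald_test(cnt2, "s1", paste0("s", 9:16)), "at least 2")
})

test_that("Welch test matches the closed-form computation", {
  e <- matrix(c(1, 2, 4, 6), nrow = 1,
              dimnames = list("g1", paste0("s", 1:4)))
  r <- ttest_expr(e, c("s1", "s2"), c("s3", "s4"))
  vA <- 0.5; vB <- 2; se2 <- vA / 2 + vB / 2
  t_exp <- 3.5 / sqrt(se2)
  df_exp <- se2^2 / ((vA / 2)^2 / 1 + (vB / 2)^2 / 1)
  expect_equal(r$log2FC, 3.5)
  expect_equal(r$stat, t_exp)
  expect_equal(r$df, df_exp)
  expect_equal(r$pvalue, 2 * pt(-t_exp, df_exp))
  # agreement with stats::t.test on random data
  set.seed(5)
  e2 <- matrix(rnorm(10), nrow = 1, dimnames = list("g", paste0("s", 1:10)))
  r2 <- ttest_expr(e2, paste0("s", 1:5), paste0("s", 6:10))
  tt <- t.test(e2[1, 6:10], e2[1, 1:5])
  expect_equal(r2$pvalue, tt$p.value)
  # exact shift with zero within-group variance
  e3 <- matrix(c(5, 5, 5, 6, 6, 6), nrow = 1,
               dimnames = list("g", paste0("s", 1:6)))
  r3 <- ttest_expr(e3, paste0("s", 1:3), paste0("s", 4:6))
  expect_identical(r3$log2FC, 1)
  expect_identical(r3$pvalue, 0)
  e4 <- matrix(rep(5, 6), nrow = 1, dimnames = list("g", paste0("s", 1:6)))
  r4 <- ttest_expr(e4, paste0("s", 1:3), paste0("s", 4:6))
  expect_identical(r4$pvalue, 1)
})

test_that("null Welch p-values are uniform", {
  set.seed(17)
  e <- matrix(rnorm(10000 * 10), nrow = 10000,
              dimnames = list(NULL, paste0("s", 1:10)))
  rownames(e) <- paste0("g", 1:10000)
  r <- ttest_expr(e, paste0("s", 1:5), paste0("s", 6:10))
  ks <- suppressWarnings(ks.test(r$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment equals the step-up oracle and respects bounds", {
  expect_identical(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "in \\[0, 1\\]")
  set.seed(23)
  for (rep in 1:30) {
    p <- runif(sample(c(1, 5, 50, 1000), 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  }
})

test_that("DE filters apply the published thresholds with inclusive bounds", {
  mk <- function(padj, lfc, bm) {
    data.frame(feature = "f", baseMean = bm, log2FC = lfc,
               pvalue = padj, padj = padj)
  }
  de <- function(r) apply_de_filters(list(T2 = r), "mirna")$de_any[["f"]]
  expect_true(de(mk(0.05, -1.0, 10)))        # all bounds inclusive
  expect_false(de(mk(0.04, -0.99, 100)))     # |lfc| below 1
  expect_false(de(mk(0.051, -2, 100)))       # padj above 0.05
  expect_false(de(mk(0.01, -2, 9.9)))        # baseMean below 10
  dem <- function(p, l) {
    r <- data.frame(feature = "g", log2FC = l, pvalue = p, padj = p)
    apply_de_filters(list(T2 = r), "mrna")$de_any[["g"]]
  }
  expect_true(dem(0.04, 0.80))
  expect_true(dem(0.05, -0.80))
  expect_false(dem(0.04, 0.79))
  expect_false(dem(0.06, 2))
  expect_error(apply_de_filters(list(), "proteome"))
})

test_that("log2 fold changes are invariant to rescaling one sample", {
  set.seed(31)
  nf <- 200
  cnt <- matrix(rnbinom(nf * 16, mu = 150, size = 20), nrow = nf,
                dimnames = list(paste0("f", 1:nf), paste0("s", 1:16)))
  tp <- setNames(rep(c("T1", "T2"), each = 8), colnames(cnt))
  r1 <- de_mirna(cnt, tp)
  cnt2 <- cnt
  cnt2[, "s3"] <- as.integer(round(cnt2[, "s3"] * 3))
  r2 <- de_mirna(cnt2, tp)
  expect_lt(max(abs(r1$profiles - r2$profiles)), 0.05)
})

test_that("DE calling recovers planted miRNAs with controlled FDR", {
  cfg <- sim_config(rng_seed = 3)
  sim <- simulate_mirna_counts(cfg)
  dm <- de_mirna(sim$counts, sim$timepoints)
  truth <- unlist(sim$truth$de_mirnas, use.names = FALSE)
  recall <- mean(truth %in% dm$de_features)
  fdr <- mean(!(dm$de_features %in% truth))
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.10)
})
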
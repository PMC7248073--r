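make_missing_panel <- function(miss_rows) {
  g <- tiny_gwas(beta = rep(0.1, 10), pvalue = rep(0.001, 10),
                 maf = rep(0.2, 10))
  d <- matrix(1L, nrow = length(miss_rows), ncol = 10)
  for (i in seq_along(miss_rows))
    if (miss_rows[i] > 0) d[i, seq_len(miss_rows[i])] <- NA_integer_
  tiny_panel(d, g, ploidy = rep(1L, length(miss_rows)))
}

test_that("sample missingness filter is strict ('above') at the boundary", {
  p <- make_missing_panel(c(6, 5, 0))   # 60%, 50%, 0% missing
  f <- filter_individuals(p, 0.5)
  expect_equal(f$meta$sample_id, c("s2", "s3"))  # 6/10 removed, 5/10 kept
  # no missing data: identity
  p0 <- make_missing_panel(c(0, 0))
  expect_equal(filter_individuals(p0, 0.5)$dosage, p0$dosage)
  # all removed is an error
  expect_error(filter_individuals(make_missing_panel(c(9, 9)), 0.5),
               "all samples removed")
  # idempotence
  expect_equal(filter_individuals(f, 0.5)$dosage, f$dosage)
})

test_that("variant call-rate filter is strict ('below') at the boundary", {
  g <- tiny_gwas(beta = rep(0.1, 3), pvalue = rep(0.001, 3),
                 maf = rep(0.2, 3))
  d <- matrix(1L, 10, 3)
  d[1:2, 1] <- NA  # called in 8/10 -> removed at 0.9
  d[1, 2] <- NA    # called in 9/10 -> retained (not strictly below)
  p <- tiny_panel(d, g, ploidy = rep(1L, 10))
  f <- filter_variants(p, 0.9)
  expect_equal(f$snps$snp_id, c("rs2", "rs3"))
  expect_equal(filter_variants(f, 0.9)$snps$snp_id, f$snps$snp_id)
})

test_that("GWAS p subsetting uses a strict threshold and drops absentees", {
  g <- tiny_gwas(beta = c(0.1, 0.1, 0.1), pvalue = c(0.009, 0.01, 0.5),
                 maf = c(0.2, 0.2, 0.2))
  d <- matrix(1L, 4, 3)
  p <- tiny_panel(d, g, ploidy = rep(1L, 4))
  expect_equal(subset_by_gwas_p(p, g, 0.01)$snps$snp_id, "rs1")
  expect_equal(subset_by_gwas_p(p, g, 1.0)$snps$snp_id, g$snp_id)
  # variant absent from gwas table is dropped
  p2 <- p; p2$snps$snp_id[3] <- "rs_unknown"
  expect_equal(subset_by_gwas_p(p2, g, 1.0)$snps$snp_id, c("rs1", "rs2"))
})

test_that("ld_prune removes one of two perfectly correlated variants", {
  set.seed(4)
  x <- sample(0:1, 30, replace = TRUE)
  z <- sample(0:1, 30, replace = TRUE)
  d <- cbind(x, x, z)  # rs1 == rs2
  g <- tiny_gwas(beta = rep(0.1, 3), pvalue = rep(0.001, 3),
                 maf = rep(0.2, 3))
  p <- tiny_panel(d, g, ploidy = rep(1L, 30))
  kept <- ld_prune(p, window = 3, step = 1, vif_threshold = 2)
  expect_length(intersect(kept, c("rs1", "rs2")), 1)
  expect_true("rs3" %in% kept)
  # mutually independent variants are all retained
  set.seed(5)
  d2 <- matrix(sample(0:1, 30 * 3, replace = TRUE), 30, 3)
  p2 <- tiny_panel(d2, g, ploidy = rep(1L, 30))
  expect_equal(ld_prune(p2, window = 3, step = 1, vif_threshold = 2),
               g$snp_id)
  expect_error(ld_prune(p, window = 1, step = 1), "window")
})

test_that("ld_prune matches the brute-force VIF oracle on block structure", {
  set.seed(11)
  n <- 40; m <- 20
  # 4 blocks of 5 correlated variants each
  d <- matrix(NA_integer_, n, m)
  for (b in 0:3) {
    base <- sample(0:1, n, replace = TRUE)
    for (k in 1:5) {
      col <- b * 5 + k
      flip <- runif(n) < 0.15
      d[, col] <- ifelse(flip, 1L - base, base)
    }
  }
  d[sample(length(d), 40)] <- NA_integer_
  g <- tiny_gwas(beta = rep(0.1, m), pvalue = rep(0.001, m),
                 maf = rep(0.2, m))
  p <- tiny_panel(d, g, ploidy = rep(1L, n))
  for (params in list(c(8, 3, 2), c(10, 5, 2), c(6, 2, 1.5))) {
    kept <- ld_prune(p, params[1], params[2], params[3])
    expect_equal(kept, oracle_vif_prune(d, g$snp_id, params[1],
                                        params[2], params[3]))
  }
  # invariant: no retained pair with r^2 = 1 inside one window
  kept <- ld_prune(p, 10, 5, 2)
  idx <- match(kept, g$snp_id)
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i >= j || idx[j] - idx[i] >= 10) next
    cc <- suppressWarnings(
      cor(d[, idx[i]], d[, idx[j]], use = "pairwise.complete.obs"))
    if (!is.na(cc)) expect_lt(cc^2, 1)
  }
})

test_that("qc_pipeline applies stages in order and reports counts", {
  cfg <- synth_config(n_snps = 120, samples_per_leaf = 2, missingness = 0.3,
                      seed = 21)
  gw <- make_gwas(cfg)
  anc <- make_ancient_panel(cfg, gw$gwas)
  res <- qc_pipeline(anc$panel, gw$gwas, window = 10, step = 5)
  expect_equal(res$report$stage,
               c("input", "sample_missingness", "variant_callrate",
                 "gwas_p_subset", "ld_prune"))
  expect_true(all(diff(res$report$variants) <= 0))
  expect_true(all(diff(res$report$samples) <= 0))
})

test_that("filter order matters: variants rescued by prior sample removal", {
  # 20 samples; s1 and s2 are 60% missing and go first. rs1 is missing in
  # s1, s2 and s3: call rate 17/20 = 0.85 (dropped if variants filtered
  # first) but 17/18 = 0.94 after sample filtering (kept in canonical
  # order).
  g <- tiny_gwas(beta = rep(0.1, 10), pvalue = rep(0.001, 10),
                 maf = rep(0.2, 10))
  d <- matrix(1L, 20, 10)
  d[1, 1:6] <- NA; d[2, c(1, 3:7)] <- NA   # heavy-missing samples
  d[3, 1] <- NA                      # the extra miss on rs1
  p <- tiny_panel(d, g, ploidy = rep(1L, 20))
  canonical <- filter_variants(filter_individuals(p, 0.5), 0.9)
  reversed <- filter_individuals(filter_variants(p, 0.9), 0.5)
  expect_true("rs1" %in% canonical$snps$snp_id)
  expect_false("rs1" %in% reversed$snps$snp_id)
})
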
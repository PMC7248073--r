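sds_for <- function(gwas, ref_allele, sds) {
  structure(data.frame(snp_id = gwas$snp_id, chrom = gwas$chrom,
                       pos = gwas$pos, sds_reference_allele = ref_allele,
                       sds = sds, stringsAsFactors = FALSE),
            class = c("sds_table", "data.frame"))
}

test_that("align_tsds signs scores to the risk allele", {
  g <- tiny_gwas(beta = c(0.04, -0.04, 0.02))   # risks: A, T, G
  risk <- orient_risk(g)
  s <- sds_for(g, c("A", "C", "T"), c(1.2, 1.2, 0.5))
  al <- align_tsds(s, risk)
  # rs1: ref = risk -> +1.2 ; rs2: ref C = nonrisk -> -1.2
  expect_equal(al$tsds[al$snp_id == "rs1"], 1.2)
  expect_equal(al$tsds[al$snp_id == "rs2"], -1.2)
  # rs3: ref T matches neither allele (G/A) -> dropped
  expect_false("rs3" %in% al$snp_id)
  # involution: re-labelling both files (SDS reported on the opposite
  # allele with flipped sign; GWAS effect/other swapped with negated
  # beta) leaves every tSDS unchanged — the risk allele itself and the
  # frequency change it experienced are representation-invariant
  g_fl <- gwas_table(data.frame(
    snp_id = g$snp_id, chrom = g$chrom, pos = g$pos,
    effect_allele = g$other_allele, other_allele = g$effect_allele,
    beta = -g$beta, pvalue = g$pvalue, maf = g$maf))
  other_allele_of <- function(ref) ifelse(ref == risk$risk_allele,
                                          risk$nonrisk_allele,
                                          risk$risk_allele)
  s_fl <- s
  s_fl$sds_reference_allele[1:2] <- other_allele_of(s$sds_reference_allele)[1:2]
  s_fl$sds <- -s$sds
  al2 <- align_tsds(s_fl, orient_risk(g_fl))
  expect_equal(al2$tsds[match(al$snp_id, al2$snp_id)], al$tsds)
})

test_that("binned_spearman partitions SNPs and detects coupling", {
  set.seed(3)
  n <- 4500
  p <- runif(n)
  # partial-bin rule: 4500 SNPs at bin 1000 -> 5 bins
  bs <- binned_spearman(rnorm(n), p, 1000)
  expect_equal(bs$n_bins, 5)
  bins <- paleoburden:::p_bins(p, 1000)
  expect_equal(sort(as.vector(table(bins))), c(500, 1000, 1000, 1000, 1000))
  # every SNP in exactly one bin
  expect_equal(length(bins), n)
  # coupling: most significant bin has negative mean tsds -> rho > 0
  tsds <- rnorm(n)
  tsds[order(p)[1:1000]] <- rnorm(1000, -0.3)
  expect_gt(binned_spearman(tsds, p, 1000)$rho, 0)
  expect_error(binned_spearman(rnorm(5), runif(5), 10), "at least 2")
})

test_that("block assignment groups SNPs by 1-Mb windows per chromosome", {
  g <- gwas_table(data.frame(
    snp_id = paste0("rs", 1:4), chrom = c("1", "1", "1", "2"),
    pos = c(2e5, 7e5, 1.7e6, 2e5),
    effect_allele = "A", other_allele = "G",
    beta = 0.1, pvalue = c(0.1, 0.2, 0.3, 0.4), maf = 0.2))
  block <- paste(g$chrom, floor(g$pos / 1e6), sep = ":")
  # 0.5 Mb apart: same block; 1.5 Mb apart: different; chrom separates
  expect_equal(block[1], block[2])
  expect_false(block[2] == block[3])
  expect_false(block[1] == block[4])
})

test_that("block_flip_null: determinism, symmetry, degenerate input", {
  cfg <- synth_config(n_snps = 3000, sds_coupling = 0.5,
                      sds_bin_size = 500, spacing_bp = 20000, seed = 61)
  gw <- make_gwas(cfg)
  al <- align_tsds(make_sds(cfg, gw$gwas), orient_risk(gw$gwas))
  nd <- block_flip_null(al$tsds, al$gwas_p, al$chrom, al$pos,
                        bin_size = 500, n = 400, seed = 3)
  nd2 <- block_flip_null(al$tsds, al$gwas_p, al$chrom, al$pos,
                         bin_size = 500, n = 400, seed = 3)
  expect_identical(nd$null_draws, nd2$null_draws)
  # null rho symmetric about 0
  expect_lt(abs(mean(nd$null_draws)), 4 * sd(nd$null_draws) / sqrt(400))
  # built-in coupling pushes the observed rho in the positive direction
  # (with only 6 bins the block-flip null is wide, so no p assertion here;
  # detection power is exercised in the calibration/acceptance suite)
  expect_gt(nd$observed, 0)
  expect_lt(nd$p_normal, 0.5)
  # degenerate: all-zero tsds flagged
  expect_warning(
    ndz <- block_flip_null(rep(0, 3000), al$gwas_p, al$chrom, al$pos,
                           bin_size = 500, n = 10, seed = 1),
    "degenerate")
  expect_true(ndz$degenerate)
  # fewer than 2 blocks is an error
  expect_error(block_flip_null(al$tsds, al$gwas_p, rep("1", 3000),
                               rep(100, 3000), bin_size = 500),
               "at least 2 genomic blocks")
})
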
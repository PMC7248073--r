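test_that("orient_risk points at the log-odds-increasing allele", {
  g <- tiny_gwas(beta = c(0.04, -0.04, 0))
  expect_message(r <- orient_risk(g), "beta == 0")
  expect_equal(r$snp_id, c("rs1", "rs2"))
  expect_equal(r$risk_allele, c("A", "T"))       # +beta: effect; -beta: other
  expect_equal(r$nonrisk_allele, c("G", "C"))
  expect_equal(r$risk_beta, c(0.04, 0.04))
})

test_that("burden is the plain average over called risk SNPs", {
  g <- tiny_gwas(beta = c(0.1, 0.1, 0.1), pvalue = rep(0.001, 3),
                 maf = rep(0.2, 3))
  r <- orient_risk(g)
  # diploid dosages [0, 1, 2] -> f = 1
  p <- tiny_panel(matrix(c(0L, 1L, 2L), 1), g, ploidy = 2L)
  expect_equal(f_burden(p, r)$f, 1.0)
  # pseudo-haploid with missing: [0, 1, NA] + an extra SNP
  g4 <- tiny_gwas(beta = rep(0.1, 4), pvalue = rep(0.001, 4),
                  maf = rep(0.2, 4))
  p4 <- tiny_panel(matrix(c(0L, 1L, 1L, NA), 1), g4, ploidy = 1L)
  b <- f_burden(p4, orient_risk(g4))
  expect_equal(b$J, 3L)
  expect_equal(b$f, 2 / 3)
})

test_that("burden matches the loop oracle on a 50-sample synthetic panel", {
  cfg <- synth_config(n_snps = 40, samples_per_leaf = 7, seed = 31)
  gw <- make_gwas(cfg)
  anc <- make_ancient_panel(cfg, gw$gwas)
  risk <- orient_risk(gw$gwas)
  got <- f_burden(anc$panel, risk)
  want <- oracle_burden(anc$panel, risk)
  want <- want[want$J >= 1, ]
  expect_equal(got$f, want$f)
  expect_equal(got$J, want$J)
  # normalised variant too
  expect_equal(f_burden(anc$panel, risk, normalise = TRUE)$f,
               oracle_burden(anc$panel, risk, normalise = TRUE)$f)
})

test_that("burden invariances: allele flip, reordering, monotonicity", {
  cfg <- synth_config(n_snps = 30, samples_per_leaf = 3, missingness = 0.2,
                      seed = 33)
  gw <- make_gwas(cfg)
  anc <- make_ancient_panel(cfg, gw$gwas)
  risk <- orient_risk(gw$gwas)
  b <- f_burden(anc$panel, risk)
  # flipping every risk allele maps f -> ploidy - f
  flipped <- risk
  flipped$risk_allele <- risk$nonrisk_allele
  flipped$nonrisk_allele <- risk$risk_allele
  b_fl <- f_burden(anc$panel, flipped)
  expect_equal(b_fl$f, 1 - b$f)   # pseudo-haploid: ploidy 1
  # invariance under SNP and sample reordering
  perm_v <- sample(ncol(anc$panel$dosage))
  perm_s <- sample(nrow(anc$panel$dosage))
  b_perm <- f_burden(subset_panel(anc$panel, perm_s, perm_v), risk)
  expect_equal(b_perm$f[order(b_perm$sample_id)],
               b$f[order(b$sample_id)])
  # monotonicity: adding one risk-allele copy strictly increases f
  p2 <- anc$panel
  risk_is_alt <- p2$snps$alt ==
    risk$risk_allele[match(p2$snps$snp_id, risk$snp_id)]
  j <- which(risk_is_alt & !is.na(p2$dosage[1, ]) & p2$dosage[1, ] == 0)[1]
  p2$dosage[1, j] <- 1L
  expect_gt(f_burden(p2, risk)$f[1], b$f[1])
})

test_that("sample with zero called risk SNPs is excluded with a warning", {
  g <- tiny_gwas(beta = c(0.1, 0.1, 0.1), pvalue = rep(0.001, 3),
                 maf = rep(0.2, 3))
  d <- rbind(c(1L, 0L, 1L), c(NA, NA, NA))
  p <- tiny_panel(d, g, ploidy = c(1L, 1L))
  expect_warning(b <- f_burden(p, orient_risk(g)), "zero called risk SNPs")
  expect_equal(nrow(b), 1)
})

test_that("mixed ploidy requires normalise", {
  g <- tiny_gwas(beta = rep(0.1, 3), pvalue = rep(0.001, 3),
                 maf = rep(0.2, 3))
  d <- rbind(c(1L, 0L, 1L), c(2L, 1L, 0L))
  p <- tiny_panel(d, g, ploidy = c(1L, 2L))
  expect_error(f_burden(p, orient_risk(g)), "mixed-ploidy")
  expect_silent(b <- f_burden(p, orient_risk(g), normalise = TRUE))
  expect_true(all(b$f >= 0 & b$f <= 1))
})

test_that("population burden: identical groups and frequency offsets", {
  g <- tiny_gwas(beta = rep(0.1, 2), pvalue = rep(0.001, 2),
                 maf = rep(0.2, 2))
  d <- rbind(c(2L, 2L), c(2L, 2L))
  p <- tiny_panel(d, g, ploidy = c(2L, 2L), continent = c("A", "B"))
  res <- population_f_burden(p, orient_risk(g))
  # homozygous risk everywhere -> f = 2 in both groups
  expect_equal(res$f, c(2, 2))
  expect_equal(res$group, c("A", "B"))
  # frequency-offset populations: mean difference ~ 2 * delta
  cfg <- synth_config(n_snps = 400, seed = 41)
  gw <- make_gwas(cfg)
  modern <- make_modern_panels(cfg, gw$gwas,
                               offsets = c(AFR = 0.02, EUR = 0),
                               n_per_group = 150)
  pb <- population_f_burden(modern, orient_risk(gw$gwas))
  diff_means <- mean(pb$f[pb$group == "AFR"]) - mean(pb$f[pb$group == "EUR"])
  # E[f_AFR - f_EUR] = 2 * 0.02; binomial SE at these sizes ~ 0.002
  expect_equal(diff_means, 0.04, tolerance = 0.2)
})
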
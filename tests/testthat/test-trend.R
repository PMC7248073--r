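test_that("kendall_trend uses the calendar-time sign convention", {
  # burden lower in older samples = increase toward the present: tau = +1
  kt <- kendall_trend(c(3, 2, 1), c(1000, 2000, 3000))
  expect_equal(kt$tau, 1)
  # constant burden: tau-b gives 0/0 -> NA; treat as no trend
  kt0 <- kendall_trend(c(1, 1, 1, 1), c(1, 2, 3, 4) * 1000)
  expect_true(is.na(kt0$tau) || kt0$tau == 0)
})

test_that("kendall_trend matches the pair-counting oracle with ties", {
  set.seed(7)
  f <- round(rnorm(30), 1)           # ties in f
  age <- sample(seq(500, 5000, by = 500), 30, replace = TRUE)  # ties in age
  kt <- kendall_trend(f, age)
  expect_equal(kt$tau, oracle_kendall_b(f, -age), tolerance = 1e-12)
})

test_that("flip_null_trend: determinism, add-one p, sign symmetry", {
  cfg <- synth_config(n_snps = 60, samples_per_leaf = 3, missingness = 0.2,
                      gamma = 0, d = 1e-6, seed = 51)
  gw <- make_gwas(cfg)
  anc <- make_ancient_panel(cfg, gw$gwas)
  risk <- orient_risk(gw$gwas)
  nd1 <- flip_null_trend(anc$panel, risk, n = 300, seed = 99)
  nd2 <- flip_null_trend(anc$panel, risk, n = 300, seed = 99)
  expect_identical(nd1$null_draws, nd2$null_draws)
  expect_gte(nd1$p_empirical, 1 / 301)
  expect_lte(nd1$p_empirical, 1)
  expect_equal(nd1$n_draws, 300)
  # null draws roughly symmetric about zero under exchangeability
  expect_lt(abs(mean(nd1$null_draws)), 3 * sd(nd1$null_draws) / sqrt(300))
  # flipping all risk alleles flips the observed tau
  flipped <- risk
  flipped$risk_allele <- risk$nonrisk_allele
  flipped$nonrisk_allele <- risk$risk_allele
  nd_fl <- suppressWarnings(flip_null_trend(anc$panel, flipped, n = 10,
                                            seed = 99))
  expect_equal(nd_fl$observed, -nd1$observed, tolerance = 1e-12)
  expect_warning(flip_null_trend(anc$panel, risk, n = 50, seed = 1),
                 "unstable")
})

test_that("flip_null_trend detects a strong simulated decay", {
  cfg <- synth_config(n_snps = 200, samples_per_leaf = 4, missingness = 0.2,
                      gamma = -7e-5, d = 1e-7, seed = 53)
  gw <- make_gwas(cfg)
  anc <- make_ancient_panel(cfg, gw$gwas)
  nd <- flip_null_trend(anc$panel, orient_risk(gw$gwas), n = 2000,
                        seed = 5, alternative = "less")
  expect_lt(nd$observed, 0)
  expect_lte(nd$p_empirical, 0.002)
})

test_that("continent_regression recovers a known offset", {
  set.seed(61)
  n <- 200
  age <- runif(n, 1000, 9000)
  cont <- rep(c("Africa", "Europe"), each = n / 2)
  f <- 0.5 - 1e-5 * age + 0.02 * (cont == "Europe") + rnorm(n, 0, 0.005)
  res <- continent_regression(f, age, cont)
  expect_equal(res$reference, "Africa")
  est <- res$coefficients$estimate
  expect_equal(est[3], 0.02, tolerance = 0.15)
  expect_equal(est[2], -1e-5, tolerance = 0.15)
  # identical distributions: continent slope ~ 0 (insignificant)
  f0 <- 0.5 + rnorm(n, 0, 0.01)
  res0 <- continent_regression(f0, age, cont)
  expect_gt(res0$coefficients$p[3], 0.01)
  # collinear design warns
  expect_warning(
    continent_regression(f, as.numeric(cont == "Europe") * 2 + 5, cont),
    "ill-conditioned")
})

test_that("partial_kendall shrinks a shared time confounder", {
  set.seed(71)
  n <- 150
  z <- rnorm(n)
  # x and y noisy functions of z: strong raw association, the partial
  # tau is substantially reduced (the first-order formula shrinks but
  # does not exactly annihilate confounding on the tau scale)
  x <- z + 0.5 * rnorm(n); y <- 2 * z + rnorm(n)
  raw <- cor(x, y, method = "kendall")
  pk <- partial_kendall(x, y, z)
  expect_gt(raw, 0.4)
  expect_lt(abs(pk$tau_partial), raw / 2)
  # matches an independent pair-counting implementation of the formula
  txy <- oracle_kendall_b(x, y)
  txz <- oracle_kendall_b(x, z)
  tyz <- oracle_kendall_b(y, z)
  expect_equal(pk$tau_partial,
               (txy - txz * tyz) / sqrt((1 - txz^2) * (1 - tyz^2)),
               tolerance = 1e-12)
  # exactly tied (tau = 1) control is degenerate and refused
  expect_error(partial_kendall(z, 2 * z + 1, z), "perfectly associated")
  # x and y independent of z and of each other: tau_partial ~ 0
  pk3 <- partial_kendall(rnorm(n), rnorm(n), z)
  se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 3)))
  expect_lt(abs(pk3$tau_partial), 3 * se)
})

test_that("group_compare is one-tailed in the stated direction", {
  set.seed(81)
  a <- rnorm(100); b <- rnorm(100)
  gc0 <- group_compare(a, b)
  expect_gt(gc0$p, 0.01)
  # disjoint supports: minimal attainable one-tail p
  gc1 <- group_compare(1:10 + 100, 1:10)
  expect_lt(gc1$p, 1e-3)
  gc2 <- group_compare(1:10, 1:10 + 100)
  expect_gt(gc2$p, 0.999)
})

test_that("group_compare has power at delta = 0.5 sd", {
  set.seed(91)
  rej <- replicate(200, {
    a <- rnorm(100, 0.5); b <- rnorm(100)
    group_compare(a, b)$p < 0.05
  })
  expect_gt(mean(rej), 0.9)
})

test_that("weighted_kendall reduces to tau-a and matches its oracle", {
  set.seed(101)
  a <- rnorm(20); b <- rnorm(20)
  # equal weights reduce exactly to tau-a
  tau_a <- oracle_weighted_kendall(a, b, rep(1, 20))
  expect_equal(weighted_kendall(a, b), tau_a, tolerance = 1e-12)
  # zero-weight observation drops out
  w <- c(0, rep(1, 19))
  expect_equal(weighted_kendall(a, b, w),
               weighted_kendall(a[-1], b[-1]), tolerance = 1e-12)
  # general weights match the pair-enumeration oracle
  w2 <- -log10(runif(20))
  expect_equal(weighted_kendall(a, b, w2),
               oracle_weighted_kendall(a, b, w2), tolerance = 1e-12)
})
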
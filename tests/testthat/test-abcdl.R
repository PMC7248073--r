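test_that("sample_tree validates structure and derives branch lengths", {
  tree <- default_sample_tree()
  expect_s3_class(tree, "sample_tree")
  expect_length(tree$leaves, 8)
  expect_setequal(tree$leaves,
                  c("UstIshim", "Malta1", "Kostenski14", "GoyetQ116-1",
                    "Villabruna", "Loschbour", "Vestonice16", "ElMiron"))
  # leaf ages consistent with cumulative branch lengths
  ages <- setNames(tree$nodes$age_bp, tree$nodes$name)
  for (i in seq_len(nrow(tree$edges))) {
    e <- tree$edges[i, ]
    expect_equal(ages[[e$parent]] - ages[[e$child]], e$dt * tree$gen_time)
  }
  # structural errors
  edges <- data.frame(parent = c("r", "r", "a"), child = c("a", "b", "b"))
  expect_error(sample_tree(edges, c(r = 3000, a = 2000, b = 1000)),
               "two parents")
  edges2 <- data.frame(parent = "r", child = "a")
  expect_error(sample_tree(edges2, c(r = 1000, a = 2000)), "younger")
})

test_that("newick round-trip preserves topology, ages and dt", {
  tree <- default_sample_tree()
  path <- withr::local_tempfile(fileext = ".nwk")
  write_sample_tree(tree, path)
  tree2 <- read_sample_tree(path)
  expect_setequal(tree2$leaves, tree$leaves)
  o1 <- tree$nodes[order(tree$nodes$name), ]
  o2 <- tree2$nodes[order(tree2$nodes$name), ]
  expect_equal(o2$age_bp, o1$age_bp, tolerance = 1e-8)
})

test_that("simulate_branch honours the closed-form moments", {
  # deterministic cases
  expect_equal(simulate_branch(c(0.2, 0.5), 0, 0, 10), c(0.2, 0.5))
  expect_equal(simulate_branch(0.5, 1e-4, 0, 1000), 0.6)
  # clamping at the boundary
  expect_equal(simulate_branch(0.99, 1e-4, 0, 1000), 1)
  # stochastic moments at 1e5 loci: mean ~ gamma*dt, var ~ d*dt
  set.seed(5)
  n <- 1e5
  child <- simulate_branch(rep(0.5, n), 0, 1e-6, 100)
  inc <- child - 0.5
  expect_lt(abs(mean(inc)), 3 * sqrt(1e-4 / n))
  expect_lt(abs(var(inc) - 1e-4), 3 * 1e-4 * sqrt(2 / (n - 1)))
})

test_that("simulate_dataset: drift direction, symmetry, covariance", {
  tree <- default_sample_tree()
  # d = 0, gamma < 0: every leaf mean below the root mean
  sim <- simulate_dataset(tree, -7e-5, 0, 0.6, 100)
  expect_true(all(sim$leaf_means < 0.6))
  # two sister leaves with equal path length, d = 0: identical means
  edges <- data.frame(parent = c("r", "r"), child = c("L1", "L2"))
  star <- sample_tree(edges, c(r = 5000, L1 = 1000, L2 = 1000))
  sim2 <- simulate_dataset(star, -5e-5, 0, runif(50), 50, seed = 2)
  expect_equal(sim2$leaf_means[["L1"]], sim2$leaf_means[["L2"]])
  # determinism under a fixed seed
  a <- simulate_dataset(tree, 1e-5, 1e-6, 0.5, 200, seed = 11)
  b <- simulate_dataset(tree, 1e-5, 1e-6, 0.5, 200, seed = 11)
  expect_identical(a$leaf_freqs, b$leaf_freqs)
  # Brownian covariance of leaf means reflects shared path length:
  # Cov(mean_i, mean_j) = d * t_shared / n_loci
  edges3 <- data.frame(parent = c("r", "r", "a", "a"),
                       child = c("b", "a", "L1", "L2"))
  tr3 <- sample_tree(edges3, c(r = 4000, a = 2000, b = 100,
                               L1 = 100, L2 = 100), gen_time = 1)
  set.seed(21)
  reps <- t(replicate(1000, {
    s <- simulate_dataset(tr3, 0, 1e-6, 0.5, 30)
    s$leaf_means[c("L1", "L2")]
  }))
  shared <- (4000 - 2000)  # generations from root to the L1/L2 ancestor
  expect_equal(cov(reps[, 1], reps[, 2]), 1e-6 * shared / 30,
               tolerance = 0.25)
})

test_that("reference table: prior sanity and standardisation", {
  pr <- abc_priors()
  tree <- default_sample_tree()
  expect_error(generate_reference_table(pr, tree, n_sims = 0), "n_sims")
  ref <- generate_reference_table(pr, tree, n_sims = 2000, n_loci = 300,
                                  seed = 7)
  ref_b <- generate_reference_table(pr, tree, n_sims = 2000, n_loci = 300,
                                    seed = 7)
  expect_identical(ref$raw, ref_b$raw)
  expect_equal(unname(colMeans(ref$std)), rep(0, 8), tolerance = 1e-10)
  expect_equal(unname(apply(ref$std, 2, sd)), rep(1, 8), tolerance = 1e-10)
  # gamma prior is uniform on (-1e-4, 1e-4)
  ks <- suppressWarnings(
    ks.test(ref$theta$gamma, "punif", -1e-4, 1e-4))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(ref$theta$d >= 1e-8 & ref$theta$d <= 1e-4))
})

test_that("Elliott activations and their midpoints", {
  expect_equal(elliott(0), 0)
  expect_equal(elliott_pos(0), 0.5)   # output variant midpoint
  expect_equal(elliott(10, slope = 0.1), 1 / (1 + 1) )
  expect_true(all(abs(elliott(seq(-100, 100), 0.1)) < 1))
  expect_true(all(elliott_pos(seq(-100, 100), 0.1) > 0 &
                    elliott_pos(seq(-100, 100), 0.1) < 1))
})

test_that("compiled training core matches the pure-R reference backend", {
  set.seed(1)
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- runif(200)
  for (dr in c(0, 0.1)) {
    a <- train_mlp(X, y, max_iter = 40, target_error = 0, seed = 5,
                   dropout = dr, backend = "cpp")
    b <- train_mlp(X, y, max_iter = 40, target_error = 0, seed = 5,
                   dropout = dr, backend = "r")
    expect_equal(a$W, b$W, tolerance = 1e-12)
    expect_equal(a$mse, b$mse, tolerance = 1e-12)
  }
})

test_that("training on a constant-target table predicts that constant", {
  set.seed(2)
  X <- matrix(rnorm(500 * 8), 500, 8)
  y <- rep(0.7, 500)
  net <- train_mlp(X, y, max_iter = 5000, target_error = 1e-5, seed = 9,
                   dropout = 0)
  expect_lt(net$mse, 1e-3)
  expect_equal(mean(predict(net, X)), 0.7, tolerance = 0.05)
})

test_that("ensemble summaries are informative about gamma", {
  art <- abc_artifacts()
  # fresh validation set
  set.seed(404)
  th <- paleoburden:::draw_priors(art$ref$priors, 1000)
  raw <- paleoburden:::simulate_summaries(art$ref$tree, th$gamma, th$d,
                                          art$ref$priors$f0, art$ref$n_loci)
  pred <- predict(art$ens, standardise_summary(art$ref, raw))
  expect_gt(cor(pred, th$gamma), 0.7)
  # per-net predictions available behind the consensus flag
  mat <- predict(art$ens, standardise_summary(art$ref, raw),
                 consensus = FALSE)
  expect_equal(dim(mat), c(1000, 10))
})

test_that("abc_estimate: null recovery, guardrails, prior support", {
  art <- abc_artifacts()
  obs0 <- simulate_dataset(art$ref$tree, 0, 1e-8, 0.5, art$ref$n_loci,
                           seed = 31)$leaf_means
  est <- abc_estimate(obs0, art$ens, art$ref, art$pool, n_retain = 1000)
  expect_lt(est$ci[1], 0)
  expect_gt(est$ci[2], 0)
  expect_true(all(est$posterior_draws >= -1e-4 &
                    est$posterior_draws <= 1e-4))
  expect_error(abc_estimate(obs0, art$ens, art$ref, art$pool,
                            n_retain = length(art$pool$ss) + 1),
               "exceeds the pool")
})

test_that("factor2 classifies runs as specified", {
  f <- factor2(c(1e-4, 1e-4, 1e-4, 1e-7), c(1.5e-4, 2.5e-4, -1e-4, 5e-8))
  expect_equal(f$inside[1:3], c(TRUE, FALSE, FALSE))
  expect_equal(f$n_excluded, 1)   # |true| below the 1e-6 floor
  expect_equal(f$fraction, 1 / 3)
})
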
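#' Evolve per-locus allele frequencies along one branch
#'
#' One step of the Brownian frequency model: over a branch of `dt`
#' generations, each locus frequency moves by a deterministic selection
#' trend `gamma * dt` plus Gaussian drift of variance `d * dt`,
#' \deqn{f' \sim N(f + \gamma\,dt,\; d\,dt),}
#' then is truncated to \[0, 1\] (the model is silent off the boundary;
#' truncation is the simplest defensible rule).
#'
#' @param f_parent Numeric vector of parent frequencies in \[0, 1\].
#' @param gamma Per-generation selection trend (sign = direction).
#' @param d Per-generation drift variance (>= 0).
#' @param dt Branch length in generations (> 0).
#' @return Numeric vector of child frequencies in \[0, 1\].
#' @export
simulate_branch <- function(f_parent, gamma, d, dt) {
  stopifnot(dt > 0, d >= 0, all(f_parent >= 0 & f_parent <= 1))
  child <- stats::rnorm(length(f_parent), mean = f_parent + gamma * dt,
                        sd = sqrt(d * dt))
  pmin(pmax(child, 0), 1)
}

#' Simulate per-locus frequencies at every leaf of a sample tree
#'
#' Runs [simulate_branch()] down every branch of the tree from a common
#' root frequency vector and returns, per leaf, both the full frequency
#' vector and its mean over loci (the raw summary statistic: the expected
#' burden of a sample drawn at that leaf, each locus contributing
#' equally).
#'
#' @param tree A [sample_tree()].
#' @param gamma Per-generation selection trend.
#' @param d Per-generation drift variance.
#' @param f0 Root frequencies: scalar, or vector of length `n_loci`.
#' @param n_loci Number of loci.
#' @param seed Optional RNG seed.
#' @return List with `leaf_means` (named vector, leaves in `tree$leaves`
#'   order) and `leaf_freqs` (matrix loci x leaves).
#' @export
simulate_dataset <- function(tree, gamma, d, f0, n_loci, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f0 <- rep_len(f0, n_loci)
  freqs <- list()
  freqs[[tree$root]] <- f0
  for (i in seq_len(nrow(tree$edges))) {
    e <- tree$edges[i, ]
    freqs[[e$child]] <- simulate_branch(freqs[[e$parent]], gamma, d, e$dt)
  }
  leaf_freqs <- do.call(cbind, freqs[tree$leaves])
  list(leaf_means = colMeans(leaf_freqs), leaf_freqs = leaf_freqs)
}

# Vectorised tree simulation for many parameter draws at once: one matrix
# (loci x sims) per node, one rnorm call per branch per chunk. Returns the
# sims x leaves matrix of leaf means. Order of random draws differs from
# repeated simulate_dataset() calls, but the distribution is identical.
#' @noRd
simulate_summaries <- function(tree, gamma, d, f0_range, n_loci,
                               chunk = 250L) {
  n_sims <- length(gamma)
  stopifnot(length(d) == n_sims)
  out <- matrix(NA_real_, n_sims, length(tree$leaves),
                dimnames = list(NULL, tree$leaves))
  for (lo in seq(1L, n_sims, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_sims)
    b <- hi - lo + 1L
    g <- gamma[lo:hi]; dd <- d[lo:hi]
    freqs <- list()
    freqs[[tree$root]] <- matrix(
      stats::runif(n_loci * b, f0_range[1], f0_range[2]), n_loci, b)
    for (i in seq_len(nrow(tree$edges))) {
      e <- tree$edges[i, ]
      z <- matrix(stats::rnorm(n_loci * b), n_loci, b)
      child <- sweep(freqs[[e$parent]], 2, g * e$dt, "+") +
        sweep(z, 2, sqrt(dd * e$dt), "*")
      freqs[[e$child]] <- pmin(pmax(child, 0), 1)
    }
    for (l in tree$leaves) out[lo:hi, l] <- colMeans(freqs[[l]])
  }
  out
}

#' Prior specification for the selection-trend estimator
#'
#' The trend parameter gamma takes a uniform prior symmetric about zero,
#' by default (-1e-4, 1e-4) per generation (over ~1,552 generations this
#' spans an average frequency change of roughly -0.15 to 0.15 per locus).
#' The drift variance d takes a log-uniform prior, default (1e-8, 1e-4)
#' per generation, spanning negligible to strong drift; root frequencies
#' are uniform per locus, default (0.05, 0.95).
#'
#' @param gamma Length-2 numeric: gamma prior bounds (symmetric about 0).
#' @param d Length-2 numeric: drift-variance bounds (log-uniform).
#' @param f0 Length-2 numeric: root-frequency bounds.
#' @return List of class `abc_priors`.
#' @export
abc_priors <- function(gamma = c(-1e-4, 1e-4), d = c(1e-8, 1e-4),
                       f0 = c(0.05, 0.95)) {
  stopifnot(length(gamma) == 2, gamma[1] < gamma[2],
            isTRUE(all.equal(gamma[1], -gamma[2])),
            length(d) == 2, d[1] > 0, d[1] < d[2],
            length(f0) == 2, f0[1] >= 0, f0[2] <= 1, f0[1] < f0[2])
  structure(list(gamma = gamma, d = d, f0 = f0), class = "abc_priors")
}

#' @noRd
draw_priors <- function(priors, n) {
  list(gamma = stats::runif(n, priors$gamma[1], priors$gamma[2]),
       d = exp(stats::runif(n, log(priors$d[1]), log(priors$d[2]))))
}

#' Simulate the reference table for neural-summary training
#'
#' Draws `n_sims` parameter sets from the priors, simulates each on the
#' tree, and standardises the raw leaf-mean summaries per coordinate
#' (mean 0, sd 1); the standardisation constants are stored and must be
#' reused for every later summary (observed data included).
#'
#' @param priors An [abc_priors()].
#' @param tree A [sample_tree()].
#' @param n_sims Number of simulations (default 10000).
#' @param n_loci Loci per simulation (default 3000, the order of magnitude
#'   of an LD-pruned trait-associated SNP set).
#' @param seed RNG seed.
#' @return List of class `abc_reference`: `theta` (data.frame gamma, d),
#'   `raw`, `std` (matrices sims x leaves), `center`, `scale`, `priors`,
#'   `tree`, `n_loci`.
#' @export
generate_reference_table <- function(priors, tree, n_sims = 10000,
                                     n_loci = 3000, seed = 1) {
  stopifnot(n_sims >= 1)
  set.seed(seed)
  th <- draw_priors(priors, n_sims)
  raw <- simulate_summaries(tree, th$gamma, th$d, priors$f0, n_loci)
  center <- colMeans(raw)
  scale <- apply(raw, 2, stats::sd)
  if (any(scale == 0)) stop("degenerate summary coordinate (zero variance)")
  std <- sweep(sweep(raw, 2, center, "-"), 2, scale, "/")
  structure(list(theta = data.frame(gamma = th$gamma, d = th$d),
                 raw = raw, std = std, center = center, scale = scale,
                 priors = priors, tree = tree, n_loci = n_loci),
            class = "abc_reference")
}

#' Standardise raw summaries with a reference table's constants
#' @param ref An `abc_reference`.
#' @param raw Matrix or vector of raw leaf-mean summaries.
#' @return Standardised matrix.
#' @export
standardise_summary <- function(ref, raw) {
  raw <- matrix(raw, ncol = length(ref$center),
                dimnames = list(NULL, names(ref$center)))
  sweep(sweep(raw, 2, ref$center, "-"), 2, ref$scale, "/")
}
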
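#' Simulate the ABC pool of (parameter, neural summary) pairs
#'
#' Fresh prior draws are simulated on the tree, standardised with the
#' reference table's constants, and reduced to the scalar consensus
#' neural summary. The pool can be reused across several observed
#' datasets (standard practice: the simulations do not depend on the
#' observation).
#'
#' @param ensemble A `summary_ensemble`.
#' @param ref The `abc_reference` the ensemble was trained on.
#' @param n_sims Pool size (default 1e6 at full scale; reduce for
#'   desk-scale runs).
#' @param seed RNG seed.
#' @return List of class `abc_pool`: `theta` (data.frame), `ss` (numeric
#'   vector of neural summaries).
#' @export
abc_pool <- function(ensemble, ref, n_sims = 1e6, seed = 1) {
  stopifnot(n_sims >= 1)
  set.seed(seed)
  th <- draw_priors(ref$priors, n_sims)
  raw <- simulate_summaries(ref$tree, th$gamma, th$d, ref$priors$f0,
                            ref$n_loci)
  ss <- predict(ensemble, standardise_summary(ref, raw))
  structure(list(theta = data.frame(gamma = th$gamma, d = th$d), ss = ss),
            class = "abc_pool")
}

#' ABC posterior for the selection trend with local-linear adjustment
#'
#' Rejection step: the `n_retain` pool simulations whose neural summary
#' is closest (absolute difference) to the observed one are kept. The
#' retained trend draws are then adjusted by weighted local-linear
#' regression of the parameter on the summary (Epanechnikov weights on
#' the distances), shifting each draw to the observed summary value;
#' adjusted draws are truncated to the prior support.
#'
#' @param observed_raw Raw leaf-mean summary vector of the observed data
#'   (leaves in tree order).
#' @param ensemble A `summary_ensemble`.
#' @param ref The `abc_reference` used for standardisation.
#' @param pool An [abc_pool()].
#' @param n_retain Number of accepted simulations (default 1000).
#' @param adjustment `"loclinear"` (default) or `"rejection"`.
#' @return List of class `abc_result`: `posterior_draws`,
#'   `posterior_mean`, `ci` (2.5-97.5%), `n_retained`, `adjustment`,
#'   `ss_observed`.
#' @export
abc_estimate <- function(observed_raw, ensemble, ref, pool,
                         n_retain = 1000,
                         adjustment = c("loclinear", "rejection")) {
  adjustment <- match.arg(adjustment)
  n_sims <- length(pool$ss)
  if (n_retain > n_sims) stop("n_retain exceeds the pool size")
  ss_obs <- predict(ensemble, standardise_summary(ref, observed_raw))
  dist <- abs(pool$ss - ss_obs)
  keep <- order(dist)[seq_len(n_retain)]
  gamma <- pool$theta$gamma[keep]
  if (adjustment == "loclinear") {
    dmax <- max(dist[keep])
    w <- if (dmax > 0) 1 - (dist[keep] / dmax)^2 else rep(1, n_retain)
    # guard against all-zero weights when every distance equals the max
    if (sum(w) == 0) w <- rep(1, n_retain)
    x <- pool$ss[keep] - ss_obs
    fit <- stats::lm.wfit(cbind(1, x), gamma, w)
    gamma <- gamma - fit$coefficients[2] * x
    gamma <- pmin(pmax(gamma, ref$priors$gamma[1]), ref$priors$gamma[2])
  }
  structure(list(posterior_draws = unname(gamma),
                 posterior_mean = mean(gamma),
                 ci = stats::quantile(gamma, c(0.025, 0.975), names = FALSE),
                 n_retained = n_retain,
                 adjustment = adjustment,
                 ss_observed = ss_obs),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf(
    "abc_result (%s): posterior mean %.3g, 95%% CI [%.3g, %.3g], n = %d\n",
    x$adjustment, x$posterior_mean, x$ci[1], x$ci[2], x$n_retained))
  invisible(x)
}

#' Factor-2 validation statistic
#'
#' Fraction of validation runs whose posterior-mean estimate has the same
#' sign as the true parameter and magnitude within 50-200% of it. Runs
#' with |true value| below `floor` are excluded from the fraction (a
#' ratio criterion is meaningless at zero) and counted separately.
#'
#' @param true Numeric vector of true parameter values.
#' @param estimated Numeric vector of posterior means.
#' @param floor Exclusion threshold on |true| (default 1e-6).
#' @return List: `fraction`, `n_used`, `n_excluded`, logical `inside`
#'   (NA for excluded runs).
#' @export
factor2 <- function(true, estimated, floor = 1e-6) {
  stopifnot(length(true) == length(estimated))
  usable <- abs(true) >= floor
  ratio <- abs(estimated) / abs(true)
  inside <- sign(estimated) == sign(true) & ratio >= 0.5 & ratio <= 2.0
  inside[!usable] <- NA
  list(fraction = mean(inside[usable]),
       n_used = sum(usable), n_excluded = sum(!usable), inside = inside)
}

#' Full factor-2 calibration experiment
#'
#' Draws `n_validation` pseudo-observed datasets from the priors,
#' estimates each with the trained ensemble and shared pool, and returns
#' the factor-2 statistic — the pipeline's own check that the posterior
#' mean is a usable point estimate of the selection trend.
#'
#' @param ensemble A `summary_ensemble`.
#' @param ref The `abc_reference`.
#' @param pool An [abc_pool()].
#' @param n_validation Number of pseudo-observed datasets (default 100).
#' @param n_retain Accepted simulations per estimate (default 1000).
#' @param seed RNG seed for the validation draws.
#' @return List: `factor2` (as from [factor2()]), `true`, `estimated`.
#' @export
abc_validate <- function(ensemble, ref, pool, n_validation = 100,
                         n_retain = 1000, seed = 1) {
  set.seed(seed)
  th <- draw_priors(ref$priors, n_validation)
  raw <- simulate_summaries(ref$tree, th$gamma, th$d, ref$priors$f0,
                            ref$n_loci)
  est <- vapply(seq_len(n_validation), function(i)
    abc_estimate(raw[i, ], ensemble, ref, pool,
                 n_retain = n_retain)$posterior_mean, numeric(1))
  list(factor2 = factor2(th$gamma, est), true = th$gamma, estimated = est)
}
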
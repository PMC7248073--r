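#' Kendall correlation between burden and calendar time
#'
#' Computes tie-corrected Kendall's tau-b between per-sample burden and
#' calendar time, taken as `-age_bp` so that a burden *declining toward
#' the present* gives a *negative* tau. The p-value is the usual normal
#' approximation (ties make the exact distribution unavailable).
#'
#' @param f Numeric vector of per-sample burdens.
#' @param age_bp Numeric vector of sample ages in years before present.
#' @return List with `tau` and `p` (two-sided asymptotic).
#' @export
kendall_trend <- function(f, age_bp) {
  stopifnot(length(f) == length(age_bp), length(f) >= 3)
  ct <- suppressWarnings(
    stats::cor.test(f, -age_bp, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

# Observed burdens plus the per-SNP "flip increments" needed to recompute
# burdens under any risk-allele reassignment without touching genotypes:
# flipping SNP j maps its oriented dosage g to ploidy - g at called sites,
# so f(flip set S) = f_obs - sum_{j in S} D[, j], D_ij = (2 g_ij - p_i)/J_i.
#' @noRd
flip_machine <- function(panel, risk, normalise = FALSE) {
  g <- oriented_dosage(panel, risk)
  if (normalise) g <- sweep(g, 1, panel$ploidy, "/")
  J <- rowSums(!is.na(g))
  if (any(J < 1)) stop("sample(s) with zero called risk SNPs; QC first")
  f_obs <- rowMeans(g, na.rm = TRUE)
  pl <- if (normalise) rep(1, nrow(g)) else panel$ploidy
  D <- sweep(2 * g, 1, pl, "-") / J
  D[is.na(D)] <- 0
  list(f_obs = f_obs, D = D)
}

#' Risk-allele randomization null for the temporal trend
#'
#' Null model of "no association between the examined alleles and the
#' trait": each draw reassigns every SNP's risk allele at random
#' (probability 0.5 per SNP), recomputes every sample's burden and the
#' Kendall trend tau against calendar time. This is equivalent to scoring
#' random SNP sets frequency-matched to the trait-associated set. The
#' empirical p uses the add-one rule \eqn{(1 + k)/(n + 1)}.
#'
#' With `alternative = "observed"` the tail is chosen by the sign of the
#' observed tau (the convention used when the direction is read off the
#' data); pre-specify `"less"` or `"greater"` for a calibrated directional
#' test.
#'
#' @param panel A QC'd [genotype_panel()].
#' @param risk A risk orientation from [orient_risk()].
#' @param n Number of randomizations (default 10000).
#' @param seed RNG seed.
#' @param alternative Tail: `"observed"`, `"less"` or `"greater"`.
#' @param normalise See [f_burden()].
#' @return A [null_distribution()] with `method = "flip_risk"`.
#' @export
flip_null_trend <- function(panel, risk, n = 10000, seed = 1,
                            alternative = c("observed", "less", "greater"),
                            normalise = FALSE) {
  alternative <- match.arg(alternative)
  if (n < 100) warning("n < 100 randomizations: empirical p is unstable")
  fm <- flip_machine(panel, risk, normalise)
  time_cal <- -panel$meta$age_bp
  tau_obs <- stats::cor(fm$f_obs, time_cal, method = "kendall")
  m <- ncol(fm$D)
  set.seed(seed)
  # flip indicators drawn SNP-index fastest (column-major), one stream
  S <- matrix(stats::runif(m * n) < 0.5, nrow = m, ncol = n)
  F_null <- fm$f_obs - fm$D %*% S
  tau_null <- as.vector(stats::cor(time_cal, F_null, method = "kendall"))
  upper <- switch(alternative,
                  greater = TRUE, less = FALSE, observed = tau_obs >= 0)
  k <- if (upper) sum(tau_null >= tau_obs) else sum(tau_null <= tau_obs)
  null_distribution(tau_obs, tau_null, empirical_p(k, n),
                    method = "flip_risk", seed = seed,
                    extra = list(alternative = alternative))
}

#' Burden-versus-age regression with a continental covariate
#'
#' Ordinary least squares of burden on sample age and a two-level
#' continent indicator (coded 0/1; the reference level is the first factor
#' level and is reported). Used to ask whether one continent carries a
#' systematically higher burden at matched sample ages.
#'
#' @param f Numeric burden vector.
#' @param age_bp Sample ages (years BP).
#' @param continent Two-level factor or character vector.
#' @return List with `coefficients` (data.frame: estimate, p), the
#'   `reference` level, and the fitted `model`.
#' @export
continent_regression <- function(f, age_bp, continent) {
  continent <- factor(continent)
  if (nlevels(continent) != 2)
    stop("continent must have exactly two levels")
  cont01 <- as.numeric(continent) - 1
  X <- cbind(1, age_bp, cont01)
  if (kappa(X) > 1e8)
    warning("ill-conditioned design (age and continent nearly collinear)")
  fit <- stats::lm(f ~ age_bp + cont01)
  s <- summary(fit)$coefficients
  est <- stats::coef(fit)   # keeps NA for aliased terms
  pv <- s[match(names(est), rownames(s)), 4]
  coefs <- data.frame(term = c("intercept", "age_bp", "continent"),
                      estimate = unname(est), p = unname(pv),
                      row.names = NULL)
  list(coefficients = coefs, reference = levels(continent)[1], model = fit)
}

#' Partial Kendall correlation controlling for a third variable
#'
#' The standard first-order partial tau
#' \deqn{\tau_{xy \cdot z} = \frac{\tau_{xy} - \tau_{xz}\tau_{yz}}
#'   {\sqrt{(1-\tau_{xz}^2)(1-\tau_{yz}^2)}}}
#' with tau-b marginals; the p-value uses the normal approximation with
#' variance \eqn{2(2n+5)/(9n(n-3))}. Typical use: burden versus
#' hunter-gatherer ancestry controlling for sampling age, where age
#' confounds both.
#'
#' @param x,y Numeric vectors whose association is of interest.
#' @param z Numeric control variable.
#' @return List with `tau_partial` and `p` (two-sided).
#' @export
partial_kendall <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, n >= 4)
  txy <- stats::cor(x, y, method = "kendall")
  txz <- stats::cor(x, z, method = "kendall")
  tyz <- stats::cor(y, z, method = "kendall")
  den <- sqrt(max(1 - txz^2, 0) * max(1 - tyz^2, 0))
  if (den < 1e-6) stop("control variable perfectly associated with x or y")
  tp <- (txy - txz * tyz) / den
  se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 3)))
  list(tau_partial = tp, p = 2 * stats::pnorm(-abs(tp) / se))
}

#' One-tailed rank-sum comparison of two burden distributions
#'
#' Wilcoxon rank-sum test of the hypothesis that group A is stochastically
#' greater than group B.
#'
#' @param f_a,f_b Numeric burden vectors for the two groups.
#' @return List with `W` and one-tailed `p`.
#' @export
group_compare <- function(f_a, f_b) {
  wt <- suppressWarnings(
    stats::wilcox.test(f_a, f_b, alternative = "greater", exact = FALSE))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Weighted Kendall correlation (tau-a style)
#'
#' Each pair (i, j) contributes the product of its two weights, signed by
#' concordance; the statistic is the weighted pair sum normalised by the
#' total pair weight (tie pairs contribute weight but no sign, as in
#' tau-a). With equal weights this reduces exactly to tau-a. The intended
#' weighting is `-log10(p)` of the anchor GWAS, so confidently associated
#' SNPs dominate a cross-disorder effect-size concordance.
#'
#' @param a,b Numeric vectors (e.g. effect sizes in two GWAS).
#' @param weights Non-negative per-observation weights; default
#'   equal weights.
#' @return The weighted tau (scalar).
#' @export
weighted_kendall <- function(a, b, weights = NULL) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 2)
  w <- weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w >= 0))
  sa <- sign(outer(a, a, "-"))
  sb <- sign(outer(b, b, "-"))
  ww <- outer(w, w)
  ut <- upper.tri(sa)
  tot <- sum(ww[ut])
  if (tot == 0) stop("all pair weights are zero")
  sum((sa * sb * ww)[ut]) / tot
}
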
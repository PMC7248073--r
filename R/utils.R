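#' Convert a span of calendar years to generations
#'
#' Ancient-sample ages are reported in years before present (BP); the
#' frequency simulator works in generations. The default generation time of
#' 29 years is the standard estimate for recent human populations.
#'
#' @param years Numeric vector of year spans (>= 0).
#' @param gen_time Generation time in years (default 29).
#' @param round_result Round to the nearest whole generation? Default `TRUE`.
#' @return Numeric vector of generations.
#' @examples
#' years_to_generations(45000)  # ~1552 generations
#' @export
years_to_generations <- function(years, gen_time = 29, round_result = TRUE) {
  stopifnot(is.numeric(years), all(years >= 0), gen_time > 0)
  g <- years / gen_time
  if (round_result) round(g) else g
}

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
is_valid_base <- function(x) !is.na(x) & x %in% DNA_BASES

# A/T and C/G SNPs are strand-ambiguous: the two alleles are reverse
# complements, so an outgroup allele cannot be assigned to one of them
# without strand information.
#' @noRd
is_strand_ambiguous <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(a1) & !is.na(a2) & unname(comp[a1]) == a2
}

# Deterministic per-stage seed derived from a single global seed, so the
# pipeline needs exactly one seed in its config. Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h * 7919) %% 2147483587 + 1)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Empirical p-value with the add-one rule: never exactly zero.
#' @noRd
empirical_p <- function(n_extreme, n_draws) (1 + n_extreme) / (n_draws + 1)

#' Container for resampling null distributions
#'
#' Bundles an observed statistic with its randomization null draws and the
#' add-one empirical p-value \eqn{p = (1 + \#\{\mathrm{extreme}\})/(n + 1)},
#' which is never exactly zero.
#'
#' @param observed Observed value of the statistic.
#' @param null_draws Numeric vector of null draws.
#' @param p_empirical Empirical p-value.
#' @param method Label of the randomization scheme.
#' @param seed Seed used for the draws.
#' @param extra Optional named list of diagnostics.
#' @return An object of class `null_distribution`.
#' @export
null_distribution <- function(observed, null_draws, p_empirical, method,
                              seed = NA_integer_, extra = list()) {
  stopifnot(is.numeric(null_draws), length(p_empirical) == 1L)
  structure(
    c(list(observed = observed, null_draws = null_draws,
           p_empirical = p_empirical, method = method,
           n_draws = length(null_draws), seed = seed), extra),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Resampling null [%s]: observed = %.4g, n_draws = %d, p = %.4g\n",
              x$method, x$observed, x$n_draws, x$p_empirical))
  invisible(x)
}
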
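#' Join introgression tag SNPs to the GWAS and orient effects
#'
#' Keeps tag SNPs whose archaic allele is homozygous in the
#' high-coverage Altai Neanderthal genome (the stringent definition of a
#' confidently archaic allele), joins them to the GWAS table by SNP id,
#' and orients each effect size to the archaic allele:
#' `beta_archaic = +beta` when the archaic allele is the effect allele,
#' `-beta` when it is the other allele. Tags whose archaic allele matches
#' neither GWAS allele are dropped with a warning.
#'
#' @param tags A `tag_snp_table` from [read_tag_snps()].
#' @param gwas A [gwas_table()].
#' @return data.frame `snp_id`, `archaic_allele`, `beta_archaic`.
#' @export
filter_tags <- function(tags, gwas) {
  t2 <- tags[tags$altai_homozygous, , drop = FALSE]
  idx <- match(t2$snp_id, gwas$snp_id)
  ok <- !is.na(idx)
  is_eff <- ok & t2$archaic_allele == gwas$effect_allele[idx]
  is_oth <- ok & t2$archaic_allele == gwas$other_allele[idx]
  use <- is_eff | is_oth
  use[is.na(use)] <- FALSE
  if (any(ok & !use))
    warning(sum(ok & !use),
            " tag(s) dropped: archaic allele matches neither GWAS allele")
  orientation <- ifelse(is_eff[use], 1, -1)
  data.frame(snp_id = t2$snp_id[use],
             archaic_allele = t2$archaic_allele[use],
             beta = gwas$beta[idx[use]],
             orientation = orientation,
             beta_archaic = orientation * gwas$beta[idx[use]],
             stringsAsFactors = FALSE)
}

#' Mean archaic-oriented effect size
#'
#' The arithmetic mean of the effect sizes oriented to the archaic
#' allele: positive values mean introgressed alleles tend to be risk
#' alleles for the trait.
#'
#' @param joined Output of [filter_tags()].
#' @return Scalar mean effect size.
#' @export
mean_archaic_beta <- function(joined) {
  stopifnot(nrow(joined) >= 1)
  mean(joined$beta_archaic)
}

#' Randomization null for the mean archaic effect size
#'
#' Under the null that archaic-allele identity is unrelated to the
#' trait's effect direction, the orientation of each tag's effect is
#' exchangeable. The default scheme (`"sign_flip"`) flips each
#' `beta_archaic` independently with probability 0.5 per draw; the
#' alternative (`"shuffle"`) permutes the GWAS effect sizes across tags
#' while keeping each tag's orientation sign. One-tailed in the
#' enrichment direction: `p = (1 + #\{null mean >= observed\})/(n + 1)`.
#'
#' @param joined Output of [filter_tags()].
#' @param n Number of draws (default 10000).
#' @param seed RNG seed.
#' @param scheme `"sign_flip"` (default) or `"shuffle"`.
#' @return A [null_distribution()] with `method = "permute_beta"`.
#' @export
permute_beta_null <- function(joined, n = 10000, seed = 1,
                              scheme = c("sign_flip", "shuffle")) {
  scheme <- match.arg(scheme)
  m <- nrow(joined)
  stopifnot(m >= 1)
  obs <- mean_archaic_beta(joined)
  set.seed(seed)
  if (scheme == "sign_flip") {
    S <- matrix(sample(c(-1, 1), m * n, replace = TRUE), m, n)
    null_means <- as.vector(crossprod(joined$beta_archaic, S)) / m
  } else {
    # reassign GWAS effects to tags at random, keep each tag's orientation
    null_means <- vapply(seq_len(n), function(i)
      mean(joined$orientation * sample(joined$beta)), numeric(1))
  }
  k <- sum(null_means >= obs)
  null_distribution(obs, null_means, empirical_p(k, n),
                    method = "permute_beta", seed = seed,
                    extra = list(scheme = scheme))
}
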
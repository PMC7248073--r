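#' Orient GWAS SNPs to their risk allele
#'
#' The risk allele of a SNP is the allele that increases trait log-odds:
#' the effect allele when `beta > 0`, the other allele when `beta < 0`.
#' SNPs with `beta == 0` have no defined risk orientation and are excluded
#' (deterministically, rather than oriented at random).
#'
#' @param gwas A [gwas_table()].
#' @return data.frame `snp_id`, `risk_allele`, `nonrisk_allele`,
#'   `risk_beta` (= |beta|), `pvalue`, `maf`; class `risk_orientation`.
#' @export
orient_risk <- function(gwas) {
  stopifnot(all(is.finite(gwas$beta)))
  keep <- gwas$beta != 0
  if (any(!keep))
    message(sum(!keep), " SNP(s) with beta == 0 excluded (ambiguous orientation)")
  g <- gwas[keep, , drop = FALSE]
  up <- g$beta > 0
  out <- data.frame(
    snp_id = g$snp_id,
    risk_allele = ifelse(up, g$effect_allele, g$other_allele),
    nonrisk_allele = ifelse(up, g$other_allele, g$effect_allele),
    risk_beta = abs(g$beta),
    pvalue = g$pvalue,
    maf = g$maf,
    stringsAsFactors = FALSE)
  structure(out, class = c("risk_orientation", "data.frame"))
}

# Dosage matrix oriented so entries count copies of the risk allele.
# Panel dosages count ALT copies; if the risk allele is REF the dosage is
# reflected to ploidy - g. SNPs whose alleles do not match the orientation
# table are dropped.
#' @noRd
oriented_dosage <- function(panel, risk) {
  idx <- match(panel$snps$snp_id, risk$snp_id)
  ok <- !is.na(idx)
  risk_is_alt <- panel$snps$alt == risk$risk_allele[idx]
  risk_is_ref <- panel$snps$ref == risk$risk_allele[idx] &
    panel$snps$alt == risk$nonrisk_allele[idx]
  match_alt <- ok & risk_is_alt &
    panel$snps$ref == risk$nonrisk_allele[idx]
  usable <- (match_alt | (ok & risk_is_ref))
  usable[is.na(usable)] <- FALSE
  if (!any(usable)) stop("no panel SNP matches the risk orientation table")
  g <- panel$dosage[, usable, drop = FALSE]
  flip <- which(risk_is_ref[usable])
  if (length(flip))
    g[, flip] <- sweep(-g[, flip, drop = FALSE], 1, panel$ploidy, "+")
  g
}

#' Per-individual mean risk-allele burden
#'
#' For individual *i* with genotype calls at *J_i* risk-oriented SNPs,
#' the burden is the plain average
#' \deqn{f_i = \frac{1}{J_i} \sum_{j=1}^{J_i} G_{ij}}
#' where \eqn{G_{ij}} counts copies of the risk allele (0/1 for
#' pseudo-haploid samples, 0/1/2 for diploids); missing calls are excluded
#' from both sum and count. The divisor is the number of SNPs, not
#' chromosomes, so diploid burdens live in \[0, 2\] and pseudo-haploid
#' burdens in \[0, 1\]; set `normalise = TRUE` to divide by ploidy and put
#' every sample on the \[0, 1\] scale (required when ploidies are mixed).
#'
#' @param panel A QC'd [genotype_panel()].
#' @param risk A risk orientation from [orient_risk()].
#' @param normalise Divide dosages by sample ploidy first? Default `FALSE`,
#'   faithful to the plain average.
#' @return data.frame `sample_id`, `age_bp`, `continent`, `hg_ancestry`,
#'   `J` (called risk SNPs), `f` (burden); samples with zero called risk
#'   SNPs are excluded with a warning. Class `burden_result`.
#' @export
f_burden <- function(panel, risk, normalise = FALSE) {
  if (!normalise && length(unique(panel$ploidy)) > 1L)
    stop("mixed-ploidy panel: burdens are not comparable; use normalise = TRUE")
  g <- oriented_dosage(panel, risk)
  if (normalise) g <- sweep(g, 1, panel$ploidy, "/")
  J <- rowSums(!is.na(g))
  f <- rowMeans(g, na.rm = TRUE)
  keep <- J >= 1
  if (any(!keep))
    warning(sum(!keep), " sample(s) with zero called risk SNPs excluded")
  out <- data.frame(sample_id = panel$meta$sample_id,
                    age_bp = panel$meta$age_bp,
                    continent = panel$meta$continent,
                    hg_ancestry = panel$meta$hg_ancestry,
                    J = as.integer(J), f = f,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("burden_result", "data.frame"))
}

#' Per-individual burden in modern panels, grouped by population
#'
#' Same statistic as [f_burden()], computed on a modern diploid panel and
#' returned with the grouping column, for downstream group comparisons
#' (e.g. continental contrasts of the burden of risk alleles ascertained
#' in another population).
#'
#' @param panel A diploid [genotype_panel()]; groups are taken from
#'   `panel$meta$continent`.
#' @param risk A risk orientation from [orient_risk()].
#' @param normalise See [f_burden()].
#' @return A `burden_result` data.frame with a `group` column.
#' @export
population_f_burden <- function(panel, risk, normalise = FALSE) {
  res <- f_burden(panel, risk, normalise = normalise)
  res$group <- res$continent
  res
}
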
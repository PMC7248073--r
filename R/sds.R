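#' Align singleton density scores to the trait's risk alleles
#'
#' A raw SDS is reported for one reference allele; the trait-aligned
#' score (tSDS) flips its sign so that positive values mean the *risk*
#' allele has been rising in recent generations:
#' `tSDS = +SDS` when the score's reference allele is the risk allele,
#' `-SDS` otherwise. SNPs absent from either table, or whose SDS
#' reference allele matches neither GWAS allele, are dropped.
#'
#' @param sds An `sds_table` from [read_sds_table()].
#' @param risk A risk orientation from [orient_risk()].
#' @return data.frame `snp_id`, `chrom`, `pos`, `gwas_p`, `tsds`.
#' @export
align_tsds <- function(sds, risk) {
  idx <- match(sds$snp_id, risk$snp_id)
  ok <- !is.na(idx)
  r_allele <- risk$risk_allele[idx]
  n_allele <- risk$nonrisk_allele[idx]
  match_risk <- ok & sds$sds_reference_allele == r_allele
  match_nonrisk <- ok & sds$sds_reference_allele == n_allele
  use <- match_risk | match_nonrisk
  use[is.na(use)] <- FALSE
  if (any(ok & !use))
    message(sum(ok & !use),
            " SNP(s) dropped: SDS reference allele matches neither GWAS allele")
  data.frame(snp_id = sds$snp_id[use],
             chrom = sds$chrom[use],
             pos = sds$pos[use],
             gwas_p = risk$pvalue[idx[use]],
             tsds = ifelse(match_risk[use], sds$sds[use], -sds$sds[use]),
             stringsAsFactors = FALSE)
}

# bin assignment by ascending GWAS p (ties broken by chrom, pos);
# consecutive bins of bin_size, final partial bin retained
#' @noRd
p_bins <- function(gwas_p, bin_size, chrom = NULL, pos = NULL) {
  ord <- if (is.null(chrom)) order(gwas_p) else order(gwas_p, chrom, pos)
  bin <- integer(length(gwas_p))
  bin[ord] <- ceiling(seq_along(ord) / bin_size)
  bin
}

#' Rank correlation between binned tSDS and GWAS p-value
#'
#' SNPs are sorted by GWAS p-value and grouped into consecutive bins of
#' `bin_size` (default 1000; the final partial bin is kept). The
#' statistic is the Spearman correlation between per-bin mean tSDS and
#' per-bin mean p-value. A positive rho says the strongly associated bins
#' (small p) carry *negative* tSDS — recent selection favouring the
#' protective alleles.
#'
#' @param tsds Numeric vector of trait-aligned SDS.
#' @param gwas_p GWAS p-values (same length).
#' @param bin_size SNPs per bin (default 1000).
#' @param chrom,pos Optional tie-breakers for the p-sort.
#' @param per_snp If `TRUE`, correlate per-SNP tSDS with bin rank instead
#'   of bin means (alternative reading of the procedure; default `FALSE`).
#' @return List with `rho` and `n_bins`.
#' @export
binned_spearman <- function(tsds, gwas_p, bin_size = 1000, chrom = NULL,
                            pos = NULL, per_snp = FALSE) {
  stopifnot(length(tsds) == length(gwas_p))
  bin <- p_bins(gwas_p, bin_size, chrom, pos)
  n_bins <- max(bin)
  if (n_bins < 2) stop("need at least 2 p-value bins")
  if (per_snp) {
    rho <- stats::cor(tsds, tapply(gwas_p, bin, mean)[bin],
                      method = "spearman")
  } else {
    mean_tsds <- tapply(tsds, bin, mean)
    mean_p <- tapply(gwas_p, bin, mean)
    rho <- stats::cor(mean_tsds, mean_p, method = "spearman")
  }
  list(rho = unname(rho), n_bins = n_bins)
}

#' Genomic block-flip null for the tSDS rank correlation
#'
#' Null of no coupling between trait association and recent frequency
#' change that respects local LD: the genome is cut into physical blocks
#' of `block_size` (default 1 Mb, per chromosome, blocks
#' `[k Mb, (k+1) Mb)`), and each draw flips the *sign* of every tSDS in a
#' block together with probability 0.5, then recomputes the binned
#' Spearman correlation (bins are fixed by the p-order, which sign flips
#' do not change). The null draws are summarised by a fitted normal and
#' the headline p-value is the upper tail `P(N(mu, sigma) > rho_obs)`;
#' the add-one empirical p is also reported.
#'
#' @param tsds,gwas_p,chrom,pos Per-SNP vectors.
#' @param block_size Block width in bp (default 1e6).
#' @param bin_size SNPs per p-bin (default 1000).
#' @param n Number of draws (default 1000).
#' @param seed RNG seed.
#' @return A [null_distribution()] with `method = "block_flip"` and extra
#'   fields `p_normal`, `mu`, `sigma`, `n_blocks`, `degenerate`.
#' @export
block_flip_null <- function(tsds, gwas_p, chrom, pos, block_size = 1e6,
                            bin_size = 1000, n = 1000, seed = 1) {
  m <- length(tsds)
  stopifnot(length(gwas_p) == m, length(chrom) == m, length(pos) == m)
  block <- paste(chrom, floor(pos / block_size), sep = ":")
  blocks <- unique(block)
  if (length(blocks) < 2) stop("need at least 2 genomic blocks")
  degenerate <- all(tsds == 0)
  if (degenerate) warning("all tSDS are zero: null distribution degenerate")
  bin <- p_bins(gwas_p, bin_size, chrom, pos)
  n_bins <- max(bin)
  if (n_bins < 2) stop("need at least 2 p-value bins")
  obs <- suppressWarnings(
    binned_spearman(tsds, gwas_p, bin_size, chrom, pos)$rho)
  # per-(bin, block) tSDS sums: bin means under any flip are M %*% s / count
  M <- matrix(0, n_bins, length(blocks),
              dimnames = list(NULL, blocks))
  sums <- tapply(tsds, list(bin, factor(block, levels = blocks)), sum)
  sums[is.na(sums)] <- 0
  M[, ] <- sums
  bin_n <- tabulate(bin, n_bins)
  rank_p <- rank(as.vector(tapply(gwas_p, bin, mean)))
  set.seed(seed)
  S <- matrix(sample(c(-1, 1), length(blocks) * n, replace = TRUE),
              length(blocks), n)
  bin_means <- (M %*% S) / bin_n
  ranks <- apply(bin_means, 2, rank)
  rho_null <- suppressWarnings(as.vector(stats::cor(rank_p, ranks)))
  rho_null[is.na(rho_null)] <- 0
  mu <- mean(rho_null); sigma <- stats::sd(rho_null)
  p_normal <- if (sigma > 0)
    stats::pnorm(obs, mu, sigma, lower.tail = FALSE) else NA_real_
  k <- sum(rho_null >= obs)
  null_distribution(obs, rho_null, empirical_p(k, n),
                    method = "block_flip", seed = seed,
                    extra = list(p_normal = p_normal, mu = mu, sigma = sigma,
                                 n_blocks = length(blocks),
                                 degenerate = degenerate))
}
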
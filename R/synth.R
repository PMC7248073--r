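#' Configuration for the synthetic-data generator
#'
#' Defaults describe the world the analyses assume: a GWAS-style SNP set
#' with a U-shaped MAF spectrum, small log-odds effects with a minority of
#' genome-wide-significant hits, pseudo-haploid ancient samples with heavy
#' missingness laid out on the dated eight-leaf tree and evolving under
#' the Brownian-plus-trend frequency model, an ancestral-allele map with
#' tunable risk enrichment among significant SNPs, SDS scores with
#' tunable trait coupling, and an introgression tag set with tunable risk
#' enrichment. Every generator is a pure function of (config, seed).
#'
#' @param n_snps Number of SNPs (default 2000).
#' @param maf_shape Beta shape parameters of the MAF spectrum (default
#'   `c(0.5, 0.5)`, folded to the minor allele, truncated to
#'   \[0.01, 0.5\]).
#' @param beta_sd SD of null log-odds effects (default 0.01).
#' @param frac_significant Fraction of SNPs given inflated effects with
#'   p <= 1e-8 (default 0.05).
#' @param frac_ambiguous Fraction of strand-ambiguous A/T / C/G SNPs
#'   (default 0.05).
#' @param gwas_n Effective GWAS sample size for the Wald construction
#'   (default 53293, the size of a large psychiatric meta-analysis).
#' @param gamma True per-generation selection trend (default -7.72e-5,
#'   the published point estimate for the trait that motivated this
#'   pipeline).
#' @param d True per-generation drift variance (default 1e-6).
#' @param tree A [sample_tree()] (default [default_sample_tree()]).
#' @param samples_per_leaf Ancient samples drawn per leaf (default 5).
#' @param missingness Overall missing-call rate in ancient samples
#'   (default 0.4), realised as capture-style structured missingness
#'   (U-shaped per-variant rate times per-sample quality).
#' @param pseudo_haploid Ancient samples pseudo-haploid? (default `TRUE`).
#' @param age_jitter_sd SD (years) of sample-age jitter around the leaf
#'   age (default 200).
#' @param f0_range Root risk-allele frequency range (default
#'   `c(0.05, 0.95)`).
#' @param anc_enrich_sig P(ancestral = risk) among significant SNPs
#'   (default 0.7).
#' @param anc_enrich_null P(ancestral = risk) among non-associated SNPs
#'   (default 0.5).
#' @param anc_missing Fraction of SNPs without an ancestral call
#'   (default 0.05).
#' @param sds_coupling Mean tSDS of the most significant p-bin is
#'   `-sds_coupling` (default 0.3).
#' @param sds_bin_size SNPs per p-bin used by the coupling (default 1000).
#' @param tag_fraction Fraction of SNPs that tag introgressed haplotypes
#'   (default 0.1).
#' @param tag_enrichment P(archaic allele = risk allele) (default 0.8).
#' @param altai_hom_prob P(tag flagged Altai-homozygous) (default 0.8).
#' @param spacing_bp Inter-SNP spacing on the single synthetic chromosome
#'   (default 1000 bp, giving multiple 1-Mb blocks).
#' @param seed Global seed; stage seeds are derived deterministically.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_snps = 2000, maf_shape = c(0.5, 0.5),
                         beta_sd = 0.01, frac_significant = 0.05,
                         frac_ambiguous = 0.05, gwas_n = 53293,
                         gamma = -7.72e-5, d = 1e-6,
                         tree = default_sample_tree(),
                         samples_per_leaf = 5, missingness = 0.4,
                         pseudo_haploid = TRUE, age_jitter_sd = 200,
                         f0_range = c(0.05, 0.95),
                         anc_enrich_sig = 0.7, anc_enrich_null = 0.5,
                         anc_missing = 0.05,
                         sds_coupling = 0.3, sds_bin_size = 1000,
                         tag_fraction = 0.1, tag_enrichment = 0.8,
                         altai_hom_prob = 0.8,
                         spacing_bp = 1000, seed = 1) {
  stopifnot(n_snps >= 1, missingness >= 0, missingness < 1,
            frac_significant >= 0, frac_significant <= 1,
            anc_enrich_sig >= 0, anc_enrich_sig <= 1,
            tag_enrichment >= 0, tag_enrichment <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "synth_config")
}

#' @noRd
sample_allele_pairs <- function(n, frac_ambiguous, rng_ready = TRUE) {
  ambig <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2,
                  byrow = TRUE)
  pairs <- expand.grid(a = DNA_BASES, b = DNA_BASES,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  is_amb <- is_strand_ambiguous(pairs$a, pairs$b)
  clean <- as.matrix(pairs[!is_amb, ])
  amb_pick <- stats::runif(n) < frac_ambiguous
  out <- clean[sample.int(nrow(clean), n, replace = TRUE), , drop = FALSE]
  if (any(amb_pick))
    out[amb_pick, ] <- ambig[sample.int(4, sum(amb_pick), replace = TRUE), ]
  out
}

#' Generate a synthetic GWAS summary table with a truth sidecar
#'
#' MAFs are folded Beta draws truncated to \[0.01, 0.5\]; null effects are
#' N(0, beta_sd); a `frac_significant` subset gets Wald z-scores pushed
#' past genome-wide significance. P-values follow the Wald construction
#' `p = 2 Phi(-|beta|/se)`, `se = 1/sqrt(2 N maf (1-maf))`, so p, beta
#' and MAF are mutually coherent. The truth sidecar records the true risk
#' allele and category and is never consumed by analysis code.
#'
#' @param config A [synth_config()].
#' @param seed Seed (default derived from `config$seed`).
#' @return List: `gwas` (a [gwas_table()]), `truth` (data.frame).
#' @export
make_gwas <- function(config, seed = derive_seed(config$seed, "gwas")) {
  set.seed(seed)
  n <- config$n_snps
  raw <- stats::rbeta(n, config$maf_shape[1], config$maf_shape[2])
  maf <- pmax(pmin(raw, 1 - raw), 0.01)
  se <- 1 / sqrt(2 * config$gwas_n * maf * (1 - maf))
  beta <- stats::rnorm(n, 0, config$beta_sd)
  sig <- stats::runif(n) < config$frac_significant
  z_sig <- (5.8 + stats::rexp(sum(sig), rate = 1)) *
    sample(c(-1, 1), sum(sig), replace = TRUE)
  beta[sig] <- z_sig * se[sig]
  z <- beta / se
  pvalue <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
  alleles <- sample_allele_pairs(n, config$frac_ambiguous)
  gwas <- gwas_table(data.frame(
    snp_id = sprintf("rs%06d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * config$spacing_bp,
    effect_allele = alleles[, 1], other_allele = alleles[, 2],
    beta = beta, pvalue = pvalue, maf = maf,
    stringsAsFactors = FALSE))
  truth <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(n)),
    true_risk_allele = ifelse(beta > 0, alleles[, 1], alleles[, 2]),
    category = ifelse(pvalue <= 1e-8, "significant",
                      ifelse(pvalue >= 0.9, "non_associated", "middle")),
    maf = maf, stringsAsFactors = FALSE)
  list(gwas = gwas, truth = truth)
}

#' Generate an ancestral-allele map consistent with the truth sidecar
#'
#' Among significant SNPs the ancestral base equals the true risk allele
#' with probability `anc_enrich_sig`; elsewhere with `anc_enrich_null`.
#' A fraction of SNPs gets no call.
#'
#' @param config A [synth_config()].
#' @param gwas A [gwas_table()] from [make_gwas()].
#' @param truth Matching truth sidecar.
#' @param seed Seed.
#' @return An `ancestral_map` data.frame.
#' @export
make_ancestral <- function(config, gwas, truth,
                           seed = derive_seed(config$seed, "ancestral")) {
  set.seed(seed)
  idx <- match(gwas$snp_id, truth$snp_id)
  tr <- truth[idx, , drop = FALSE]
  p_anc <- ifelse(tr$category == "significant",
                  config$anc_enrich_sig, config$anc_enrich_null)
  risk <- tr$true_risk_allele
  nonrisk <- ifelse(gwas$effect_allele == risk, gwas$other_allele,
                    gwas$effect_allele)
  anc <- ifelse(stats::runif(nrow(gwas)) < p_anc, risk, nonrisk)
  keep <- stats::runif(nrow(gwas)) >= config$anc_missing
  structure(data.frame(snp_id = gwas$snp_id[keep],
                       chrom = gwas$chrom[keep],
                       pos = gwas$pos[keep],
                       ancestral = anc[keep], stringsAsFactors = FALSE),
            class = c("ancestral_map", "data.frame"))
}

#' Generate a dated ancient genotype panel under the frequency model
#'
#' Root risk-allele frequencies are uniform on `f0_range`; per-locus
#' frequencies evolve down the tree with the configured (gamma, d);
#' each leaf contributes `samples_per_leaf` individuals whose
#' (pseudo-haploid by default) dosages are Bernoulli draws from the leaf
#' frequency, with structured missingness (see [synth_config()]).
#' Sample ages are the leaf age plus
#' Gaussian jitter; hunter-gatherer ancestry is a logistic function of
#' age plus noise, so age confounds ancestry by construction.
#'
#' @param config A [synth_config()].
#' @param gwas A [gwas_table()] from [make_gwas()].
#' @param seed Seed.
#' @return List: `panel` (a [genotype_panel()]), `leaf_freqs` (risk-allele
#'   frequency matrix loci x leaves), `leaf` (leaf of each sample).
#' @export
make_ancient_panel <- function(config, gwas,
                               seed = derive_seed(config$seed, "ancient")) {
  set.seed(seed)
  n <- nrow(gwas)
  tree <- config$tree
  f0 <- stats::runif(n, config$f0_range[1], config$f0_range[2])
  sim <- simulate_dataset(tree, config$gamma, config$d, f0, n)
  risk_is_effect <- gwas$beta > 0
  # panel dosages count the "alt" allele = the GWAS effect allele
  leaves <- tree$leaves
  k <- config$samples_per_leaf
  ploidy_val <- if (config$pseudo_haploid) 1L else 2L
  n_samp <- k * length(leaves)
  dosage <- matrix(NA_integer_, n_samp, n)
  leaf_of <- rep(leaves, each = k)
  for (s in seq_len(n_samp)) {
    f_risk <- sim$leaf_freqs[, leaf_of[s]]
    f_alt <- ifelse(risk_is_effect, f_risk, 1 - f_risk)
    dosage[s, ] <- stats::rbinom(n, ploidy_val, f_alt)
  }
  if (config$missingness > 0) {
    # capture-style structured missingness: a U-shaped per-variant
    # component (a SNP is either well covered in almost everyone or
    # missing in most) times a per-sample quality factor, overall rate
    # ~ `missingness`. Purely i.i.d. missingness is incompatible with the
    # canonical two-step QC filter (no variant would survive a 90%
    # call-rate cut at 40% i.i.d. missingness).
    m <- config$missingness
    v <- stats::rbeta(n, 0.5 * m, 0.5 * (1 - m))
    q <- stats::runif(n_samp, m, 1 + 2 * m)
    p_miss <- pmin(outer(q, v), 0.98)
    dosage[matrix(stats::runif(length(dosage)), n_samp, n) < p_miss] <-
      NA_integer_
  }
  leaf_age <- tree$nodes$age_bp[match(leaf_of, tree$nodes$name)]
  age <- pmax(stats::rnorm(n_samp, leaf_age, config$age_jitter_sd), 0)
  hg <- pmin(pmax(stats::plogis((age - 25000) / 5000) +
                    stats::rnorm(n_samp, 0, 0.05), 0), 1)
  meta <- data.frame(
    sample_id = paste0(leaf_of, "_", rep(seq_len(k), length(leaves))),
    age_bp = age, continent = "Europe", hg_ancestry = hg,
    stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = gwas$snp_id, chrom = gwas$chrom,
                     pos = gwas$pos, ref = gwas$other_allele,
                     alt = gwas$effect_allele, stringsAsFactors = FALSE)
  panel <- genotype_panel(dosage, rep(ploidy_val, n_samp), snps, meta)
  list(panel = panel, leaf_freqs = sim$leaf_freqs, leaf = leaf_of)
}

#' Generate modern diploid panels with per-group frequency offsets
#'
#' Each group's risk-allele frequency is a shared baseline plus the
#' group's offset; dosages are Binomial(2, freq) with no missingness.
#'
#' @param config A [synth_config()].
#' @param gwas A [gwas_table()].
#' @param offsets Named numeric vector of per-group risk-frequency
#'   offsets (default `c(AFR = 0.02, EUR = 0)`).
#' @param n_per_group Samples per group (default 100).
#' @param seed Seed.
#' @return A diploid [genotype_panel()] with `continent` = group name.
#' @export
make_modern_panels <- function(config, gwas,
                               offsets = c(AFR = 0.02, EUR = 0),
                               n_per_group = 100,
                               seed = derive_seed(config$seed, "modern")) {
  set.seed(seed)
  n <- nrow(gwas)
  base <- stats::runif(n, config$f0_range[1], config$f0_range[2])
  risk_is_effect <- gwas$beta > 0
  groups <- names(offsets)
  n_samp <- n_per_group * length(groups)
  dosage <- matrix(NA_integer_, n_samp, n)
  grp <- rep(groups, each = n_per_group)
  for (g in groups) {
    f_risk <- pmin(pmax(base + offsets[[g]], 0), 1)
    f_alt <- ifelse(risk_is_effect, f_risk, 1 - f_risk)
    rows <- which(grp == g)
    dosage[rows, ] <- t(matrix(stats::rbinom(n * length(rows), 2,
                                             rep(f_alt, length(rows))),
                               n, length(rows)))
  }
  meta <- data.frame(sample_id = paste0(grp, "_", seq_len(n_samp)),
                     age_bp = 0, continent = grp, hg_ancestry = NA_real_,
                     stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = gwas$snp_id, chrom = gwas$chrom,
                     pos = gwas$pos, ref = gwas$other_allele,
                     alt = gwas$effect_allele, stringsAsFactors = FALSE)
  genotype_panel(dosage, rep(2L, n_samp), snps, meta)
}

#' Generate an SDS table with tunable trait coupling
#'
#' SNPs in the most significant GWAS p-bin get trait-aligned scores with
#' mean `-sds_coupling` (recent rise of the protective allele); all other
#' SNPs have mean 0; unit variance throughout. The stored score is
#' reported on a randomly chosen reference allele with the sign flipped
#' accordingly, so alignment has to be undone by [align_tsds()].
#'
#' @param config A [synth_config()].
#' @param gwas A [gwas_table()].
#' @param seed Seed.
#' @return An `sds_table` data.frame.
#' @export
make_sds <- function(config, gwas, seed = derive_seed(config$seed, "sds")) {
  set.seed(seed)
  n <- nrow(gwas)
  risk <- orient_risk(gwas)
  idx <- match(gwas$snp_id, risk$snp_id)
  bin <- p_bins(gwas$pvalue, config$sds_bin_size, gwas$chrom, gwas$pos)
  mu <- ifelse(bin == 1, -config$sds_coupling, 0)
  tsds <- stats::rnorm(n, mu, 1)
  ref_is_risk <- stats::runif(n) < 0.5
  ref_allele <- ifelse(ref_is_risk, risk$risk_allele[idx],
                       risk$nonrisk_allele[idx])
  keep <- !is.na(idx)   # beta == 0 SNPs have no orientation
  structure(data.frame(snp_id = gwas$snp_id,
                       chrom = gwas$chrom, pos = gwas$pos,
                       sds_reference_allele = ref_allele,
                       sds = ifelse(ref_is_risk, tsds, -tsds),
                       stringsAsFactors = FALSE)[keep, , drop = FALSE],
            class = c("sds_table", "data.frame"))
}

#' Generate an introgression tag-SNP table with tunable risk enrichment
#'
#' A `tag_fraction` subset of SNPs tags archaic haplotypes; the archaic
#' allele is the risk allele with probability `tag_enrichment`, and each
#' tag is flagged Altai-homozygous with probability `altai_hom_prob`.
#'
#' @param config A [synth_config()].
#' @param gwas A [gwas_table()].
#' @param seed Seed.
#' @return A `tag_snp_table` data.frame.
#' @export
make_tags <- function(config, gwas, seed = derive_seed(config$seed, "tags")) {
  set.seed(seed)
  risk <- orient_risk(gwas)
  m <- max(1L, round(config$tag_fraction * nrow(risk)))
  pick <- sort(sample.int(nrow(risk), m))
  arch_is_risk <- stats::runif(m) < config$tag_enrichment
  structure(data.frame(
    snp_id = risk$snp_id[pick],
    archaic_allele = ifelse(arch_is_risk, risk$risk_allele[pick],
                            risk$nonrisk_allele[pick]),
    altai_homozygous = stats::runif(m) < config$altai_hom_prob,
    stringsAsFactors = FALSE), class = c("tag_snp_table", "data.frame"))
}
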
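# Small fixtures built in code. Heavy ABC artifacts are memoised per session.

tiny_gwas <- function(beta = c(0.04, -0.04, 0.02),
                      pvalue = c(1e-9, 0.005, 0.95),
                      maf = c(0.2, 0.3, 0.4)) {
  n <- length(beta)
  gwas_table(data.frame(
    snp_id = paste0("rs", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1000L,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    beta = beta, pvalue = pvalue, maf = maf))
}

# panel whose dosages count the effect allele (alt = effect, ref = other)
tiny_panel <- function(dosage, gwas, ploidy = NULL,
                       age_bp = NULL, continent = "Europe", hg = NA_real_) {
  dosage <- as.matrix(dosage)
  n_s <- nrow(dosage)
  ploidy <- ploidy %||% rep(max(dosage, na.rm = TRUE), n_s)
  snps <- data.frame(snp_id = gwas$snp_id, chrom = gwas$chrom,
                     pos = gwas$pos, ref = gwas$other_allele,
                     alt = gwas$effect_allele)
  meta <- data.frame(sample_id = paste0("s", seq_len(n_s)),
                     age_bp = age_bp %||% seq(1000, by = 1000,
                                              length.out = n_s),
                     continent = rep(continent, length.out = n_s),
                     hg_ancestry = rep(hg, length.out = n_s))
  genotype_panel(dosage, ploidy, snps, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoised heavy ABC-DL artifacts shared by acceptance + abcdl tests;
# scales follow the desk-scale acceptance setup (reference table 10,000
# sims, pool 50,000 sims, 3,000 loci, default priors and tree)
.abc_cache <- new.env(parent = emptyenv())
abc_artifacts <- function() {
  if (is.null(.abc_cache$ref)) {
    pr <- abc_priors()
    tree <- default_sample_tree()
    .abc_cache$ref <- generate_reference_table(pr, tree, n_sims = 10000,
                                               n_loci = 3000, seed = 101)
    .abc_cache$ens <- train_summary_ensemble(.abc_cache$ref, seed = 202)
    .abc_cache$pool <- abc_pool(.abc_cache$ens, .abc_cache$ref,
                                n_sims = 50000, seed = 303)
  }
  as.list(.abc_cache)
}
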
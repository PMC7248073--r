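#' Default pipeline configuration
#'
#' A single global seed drives every stage (stage seeds are derived
#' deterministically from the stage name), so a rerun with the same
#' config is byte-identical. ABC settings default to desk scale; raise
#' `abc_n_sims` towards 1e6 for production runs.
#'
#' @param seed Global seed.
#' @param synth A [synth_config()] (its own seed is overridden by
#'   `seed`).
#' @param n_nulls Randomization draws for the resampling nulls
#'   (default 10000).
#' @param run_abcdl Run the (expensive) ABC stage? Default `TRUE`.
#' @param abc_ref_sims,abc_n_sims,abc_n_retain ABC scale parameters.
#' @param normalise Passed to [f_burden()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, synth = synth_config(seed = seed),
                            n_nulls = 10000, run_abcdl = TRUE,
                            abc_ref_sims = 5000, abc_n_sims = 20000,
                            abc_n_retain = 500, normalise = FALSE) {
  synth$seed <- seed
  structure(list(seed = seed, synth = synth, n_nulls = n_nulls,
                 run_abcdl = run_abcdl, abc_ref_sims = abc_ref_sims,
                 abc_n_sims = abc_n_sims, abc_n_retain = abc_n_retain,
                 normalise = normalise),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path Path to a JSON file of [pipeline_config()] fields (the
#'   `synth` entry holds [synth_config()] overrides).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth_args <- j$synth %||% list()
  j$synth <- do.call(synth_config, synth_args)
  do.call(pipeline_config, j)
}

#' @noRd
stage_file <- function(out_dir, name) file.path(out_dir, name)

#' @noRd
write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' Stages: `synth` (write all inputs), `qc`, `burden`, `trend`,
#' `ancestral`, `sds`, `introgression`, `abcdl`. Each stage writes
#' versioned outputs under `out_dir` and the run ends with a manifest
#' (input hashes, seeds, parameters). Stages can be run individually via
#' `only`; a stage whose upstream outputs are missing fails with a
#' dependency error.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param only Optional character vector of stage names to run.
#' @return Invisibly, a list of stage results.
#' @export
run_pipeline <- function(config, out_dir, only = NULL) {
  stages <- c("synth", "qc", "burden", "trend", "ancestral", "sds",
              "introgression", "abcdl")
  if (is.null(only)) {
    only <- if (config$run_abcdl) stages else setdiff(stages, "abcdl")
  }
  stopifnot(all(only %in% stages))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  need <- function(file, stage, dep) {
    if (!file.exists(file))
      stop("stage '", stage, "' needs output of stage '", dep,
           "': missing ", file, call. = FALSE)
    file
  }
  cfg <- config$synth

  if ("synth" %in% only) {
    gw <- make_gwas(cfg)
    write_gwas_summary(gw$gwas, stage_file(out_dir, "gwas.tsv"))
    data.table::fwrite(gw$truth, stage_file(out_dir, "truth.tsv"),
                       sep = "\t")
    anc <- make_ancient_panel(cfg, gw$gwas)
    write_genotypes_vcf(anc$panel, stage_file(out_dir, "ancient.vcf"))
    write_ancestral_bed(make_ancestral(cfg, gw$gwas, gw$truth),
                        stage_file(out_dir, "ancestral.bed"))
    write_sds_table(make_sds(cfg, gw$gwas),
                    stage_file(out_dir, "sds.tsv"))
    write_tag_snps(make_tags(cfg, gw$gwas),
                   stage_file(out_dir, "tags.tsv"))
    res$synth <- list(n_snps = nrow(gw$gwas))
  }

  gwas_path <- stage_file(out_dir, "gwas.tsv")
  if ("qc" %in% only) {
    need(gwas_path, "qc", "synth")
    need(stage_file(out_dir, "ancient.vcf"), "qc", "synth")
    gwas <- read_gwas_summary(gwas_path)
    panel <- read_genotypes_vcf(stage_file(out_dir, "ancient.vcf"),
                                stage_file(out_dir, "ancient.meta.tsv"))
    qc <- qc_pipeline(panel, gwas)
    write_genotypes_vcf(qc$panel, stage_file(out_dir, "qc.vcf"))
    data.table::fwrite(qc$report, stage_file(out_dir, "qc_report.tsv"),
                       sep = "\t")
    res$qc <- qc$report
  }

  if ("burden" %in% only) {
    need(stage_file(out_dir, "qc.vcf"), "burden", "qc")
    gwas <- read_gwas_summary(gwas_path)
    panel <- read_genotypes_vcf(stage_file(out_dir, "qc.vcf"),
                                stage_file(out_dir, "qc.meta.tsv"))
    burden <- f_burden(panel, orient_risk(gwas),
                       normalise = config$normalise)
    data.table::fwrite(burden, stage_file(out_dir, "burden.tsv"),
                       sep = "\t")
    res$burden <- burden
  }

  if ("trend" %in% only) {
    need(stage_file(out_dir, "burden.tsv"), "trend", "burden")
    burden <- data.table::fread(stage_file(out_dir, "burden.tsv"),
                                data.table = FALSE)
    gwas <- read_gwas_summary(gwas_path)
    panel <- read_genotypes_vcf(stage_file(out_dir, "qc.vcf"),
                                stage_file(out_dir, "qc.meta.tsv"))
    kt <- kendall_trend(burden$f, burden$age_bp)
    nd <- flip_null_trend(panel, orient_risk(gwas), n = config$n_nulls,
                          seed = derive_seed(config$seed, "trend"),
                          alternative = "less",
                          normalise = config$normalise)
    pk <- partial_kendall(burden$f, burden$hg_ancestry, -burden$age_bp)
    out <- list(tau = kt$tau, p_asymptotic = kt$p,
                flip_null = list(tau_obs = nd$observed,
                                 p_empirical = nd$p_empirical,
                                 n_draws = nd$n_draws, seed = nd$seed),
                partial_kendall_hg = pk)
    write_stage_json(out, stage_file(out_dir, "trend.json"))
    res$trend <- out
  }

  if ("ancestral" %in% only) {
    need(stage_file(out_dir, "ancestral.bed"), "ancestral", "synth")
    gwas <- read_gwas_summary(gwas_path)
    amap <- read_ancestral_bed(stage_file(out_dir, "ancestral.bed"))
    cls <- classify_snps(gwas, amap)
    nd <- maf_binned_null(cls$snps, n = config$n_nulls,
                          seed = derive_seed(config$seed, "ancestral"))
    out <- list(table = as.vector(cls$table),
                odds_ratio = nd$observed, p_empirical = nd$p_empirical,
                n_draws = nd$n_draws)
    write_stage_json(out, stage_file(out_dir, "ancestral.json"))
    res$ancestral <- out
  }

  if ("sds" %in% only) {
    need(stage_file(out_dir, "sds.tsv"), "sds", "synth")
    gwas <- read_gwas_summary(gwas_path)
    sds <- read_sds_table(stage_file(out_dir, "sds.tsv"))
    al <- align_tsds(sds, orient_risk(gwas))
    # aim for ~10 p-bins when the SNP set is smaller than the default bin
    bin_size <- max(2, min(cfg$sds_bin_size, ceiling(nrow(al) / 10)))
    bs <- binned_spearman(al$tsds, al$gwas_p, bin_size, al$chrom, al$pos)
    nd <- block_flip_null(al$tsds, al$gwas_p, al$chrom, al$pos,
                          bin_size = bin_size, n = min(config$n_nulls, 1000),
                          seed = derive_seed(config$seed, "sds"))
    out <- list(rho = bs$rho, n_bins = bs$n_bins,
                p_normal = nd$p_normal, p_empirical = nd$p_empirical)
    write_stage_json(out, stage_file(out_dir, "sds.json"))
    res$sds <- out
  }

  if ("introgression" %in% only) {
    need(stage_file(out_dir, "tags.tsv"), "introgression", "synth")
    gwas <- read_gwas_summary(gwas_path)
    tags <- read_tag_snps(stage_file(out_dir, "tags.tsv"))
    joined <- filter_tags(tags, gwas)
    nd <- permute_beta_null(joined, n = config$n_nulls,
                            seed = derive_seed(config$seed, "introgression"))
    out <- list(n_tags = nrow(joined), mean_beta = nd$observed,
                p_empirical = nd$p_empirical)
    write_stage_json(out, stage_file(out_dir, "introgression.json"))
    res$introgression <- out
  }

  if ("abcdl" %in% only) {
    need(stage_file(out_dir, "qc.vcf"), "abcdl", "qc")
    gwas <- read_gwas_summary(gwas_path)
    panel <- read_genotypes_vcf(stage_file(out_dir, "qc.vcf"),
                                stage_file(out_dir, "qc.meta.tsv"))
    burden <- f_burden(panel, orient_risk(gwas),
                       normalise = config$normalise)
    # observed raw summary: mean burden of the samples at each leaf,
    # leaves identified by the sample-id prefix written by the generator
    leaf_of <- sub("_[0-9]+$", "", burden$sample_id)
    tree <- cfg$tree
    if (!all(tree$leaves %in% leaf_of))
      stop("abcdl: panel lacks samples for some tree leaves")
    obs <- vapply(tree$leaves,
                  function(l) mean(burden$f[leaf_of == l]), numeric(1))
    priors <- abc_priors(f0 = cfg$f0_range)
    # simulate at the QC'd panel's locus count so observed and simulated
    # leaf means carry comparable noise
    ref <- generate_reference_table(
      priors, tree, n_sims = config$abc_ref_sims,
      n_loci = ncol(panel$dosage),
      seed = derive_seed(config$seed, "abc_ref"))
    ens <- train_summary_ensemble(
      ref, seed = derive_seed(config$seed, "abc_net"))
    pool <- abc_pool(ens, ref, n_sims = config$abc_n_sims,
                     seed = derive_seed(config$seed, "abc_pool"))
    est <- abc_estimate(obs, ens, ref, pool,
                        n_retain = config$abc_n_retain)
    out <- list(posterior_mean = est$posterior_mean,
                ci = est$ci, n_retained = est$n_retained,
                adjustment = est$adjustment)
    write_stage_json(out, stage_file(out_dir, "abcdl.json"))
    data.table::fwrite(data.frame(gamma = est$posterior_draws),
                       stage_file(out_dir, "abcdl_draws.tsv"), sep = "\t")
    res$abcdl <- out
  }

  # manifest: every number traceable to (input hash, seed)
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(stages, function(s) derive_seed(config$seed, s)), stages),
    parameters = list(n_nulls = config$n_nulls,
                      abc_ref_sims = config$abc_ref_sims,
                      abc_n_sims = config$abc_n_sims,
                      abc_n_retain = config$abc_n_retain,
                      normalise = config$normalise,
                      synth = config$synth[!vapply(config$synth, is.object,
                                                   logical(1))]),
    stages_run = only,
    files = stats::setNames(
      as.list(unname(tools::md5sum(outputs))), basename(outputs)))
  write_stage_json(manifest, stage_file(out_dir, "manifest.json"))
  invisible(res)
}
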
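#' Remove samples with excessive missingness
#'
#' First step of the two-step missingness filter applied to ancient
#' genotype panels: samples whose fraction of missing calls is strictly
#' above `max_missing` are removed (a sample at exactly the threshold is
#' retained). Sample order is preserved.
#'
#' @param panel A [genotype_panel()].
#' @param max_missing Maximum tolerated missing-call fraction (default 0.5).
#' @return Filtered `genotype_panel`.
#' @export
filter_individuals <- function(panel, max_missing = 0.5) {
  stopifnot(nrow(panel$dosage) > 0)
  miss <- rowMeans(is.na(panel$dosage))
  keep <- miss <= max_missing
  if (!any(keep)) stop("all samples removed by missingness filter")
  subset_panel(panel, samples = keep)
}

#' Remove variants with low call rate
#'
#' Second step of the missingness filter, run after
#' [filter_individuals()]: variants called in strictly less than
#' `min_callrate` of the retained samples are discarded.
#'
#' @param panel A [genotype_panel()].
#' @param min_callrate Minimum call-rate fraction (default 0.9).
#' @return Filtered `genotype_panel`.
#' @export
filter_variants <- function(panel, min_callrate = 0.9) {
  stopifnot(ncol(panel$dosage) > 0)
  callrate <- colMeans(!is.na(panel$dosage))
  subset_panel(panel, variants = callrate >= min_callrate)
}

#' Keep variants associated with the trait below a GWAS p-value threshold
#'
#' Retains panel variants that are present in the GWAS table with
#' `pvalue` strictly below `p_threshold` (default 0.01, the conventional
#' sub-significant inclusion threshold for burden sets). Variants absent
#' from the GWAS table are dropped.
#'
#' @param panel A [genotype_panel()].
#' @param gwas A [gwas_table()].
#' @param p_threshold Strict upper bound on the association p-value.
#' @return Filtered `genotype_panel`.
#' @export
subset_by_gwas_p <- function(panel, gwas, p_threshold = 0.01) {
  idx <- match(panel$snps$snp_id, gwas$snp_id)
  keep <- !is.na(idx) & gwas$pvalue[idx] < p_threshold
  subset_panel(panel, variants = keep)
}

# VIF of each variant in a dosage window: 1 / (1 - R^2) from regressing the
# (mean-imputed) dosage on the other variants. Constant columns carry no LD
# and get VIF 1; collinearity gives Inf.
#' @noRd
window_vif <- function(d) {
  w <- ncol(d)
  # mean-impute missing calls; heavy pseudo-haploid missingness makes
  # pairwise-complete regression ill-posed
  for (j in seq_len(w)) {
    mj <- is.na(d[, j])
    if (any(mj)) d[mj, j] <- mean(d[, j], na.rm = TRUE)
  }
  vif <- rep(1, w)
  sds <- apply(d, 2, stats::sd)
  for (j in seq_len(w)) {
    if (!is.finite(sds[j]) || sds[j] == 0) next
    pred <- d[, -j, drop = FALSE]
    pred <- pred[, apply(pred, 2, stats::sd) > 0, drop = FALSE]
    if (ncol(pred) == 0) next
    fit <- stats::lm.fit(cbind(1, pred), d[, j])
    r2 <- 1 - sum(fit$residuals^2) / (sum((d[, j] - mean(d[, j]))^2))
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  vif
}

#' Greedy windowed variance-inflation-factor LD pruning
#'
#' Mirrors the classic `indep <window> <step> <vif>` pruning: slide a
#' window of `window` variants in steps of `step`; within each window,
#' while any retained variant has VIF above `vif_threshold`, remove the one
#' with the largest VIF (ties broken by lowest index). Deterministic for a
#' fixed input.
#'
#' @param panel A [genotype_panel()].
#' @param window Window size in variant count (default 50).
#' @param step Step size in variant count (default 5).
#' @param vif_threshold VIF above which a variant is pruned (default 2).
#' @return Character vector of retained `snp_id`s, in panel order.
#' @export
ld_prune <- function(panel, window = 50, step = 5, vif_threshold = 2) {
  stopifnot(window >= 2, step >= 1, window > step, vif_threshold > 1)
  m <- ncol(panel$dosage)
  keep <- rep(TRUE, m)
  start <- 1L
  repeat {
    idx <- which(keep & seq_len(m) >= start & seq_len(m) < start + window)
    while (length(idx) >= 2) {
      vif <- window_vif(panel$dosage[, idx, drop = FALSE])
      worst <- which(vif > vif_threshold)
      if (!length(worst)) break
      drop_local <- worst[which.max(vif[worst])]  # which.max: lowest index tie-break
      keep[idx[drop_local]] <- FALSE
      idx <- idx[-drop_local]
    }
    if (start + window > m) break
    start <- start + step
  }
  panel$snps$snp_id[keep]
}

#' Run the full QC pipeline in the canonical order
#'
#' Order matters and is fixed: sample missingness, variant call rate, GWAS
#' p-value subset, LD pruning.
#'
#' @inheritParams filter_individuals
#' @inheritParams filter_variants
#' @inheritParams subset_by_gwas_p
#' @inheritParams ld_prune
#' @return List with the filtered `panel` and a `report` data.frame of
#'   sample/variant counts after each stage.
#' @export
qc_pipeline <- function(panel, gwas, max_missing = 0.5, min_callrate = 0.9,
                        p_threshold = 0.01, window = 50, step = 5,
                        vif_threshold = 2) {
  report <- data.frame(stage = character(), samples = integer(),
                       variants = integer())
  log_stage <- function(stage, p) rbind(report, data.frame(
    stage = stage, samples = nrow(p$dosage), variants = ncol(p$dosage)))
  report <- log_stage("input", panel)
  panel <- filter_individuals(panel, max_missing)
  report <- log_stage("sample_missingness", panel)
  panel <- filter_variants(panel, min_callrate)
  report <- log_stage("variant_callrate", panel)
  panel <- subset_by_gwas_p(panel, gwas, p_threshold)
  report <- log_stage("gwas_p_subset", panel)
  kept <- ld_prune(panel, window, step, vif_threshold)
  panel <- subset_panel(panel, variants = panel$snps$snp_id %in% kept)
  report <- log_stage("ld_prune", panel)
  list(panel = panel, report = report)
}
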
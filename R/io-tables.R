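#' Construct and validate a GWAS summary-statistics table
#'
#' The canonical per-SNP association table: identifier, position, the two
#' alleles, the log-odds effect size `beta` of the effect allele, the
#' association p-value and the minor allele frequency. Rows violating the
#' invariants (identical alleles, non-ACGT alleles, p outside (0, 1], MAF
#' outside (0, 0.5]) are dropped and counted in the `rejected` attribute.
#'
#' @param df data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `pvalue`, `maf`.
#' @return A validated `gwas_table` (data.frame subclass) with attribute
#'   `rejected` (number of dropped rows).
#' @export
gwas_table <- function(df) {
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "beta", "pvalue", "maf")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("GWAS table is missing required column(s): ",
         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$beta <- as.numeric(df$beta)
  df$pvalue <- as.numeric(df$pvalue)
  df$maf <- as.numeric(df$maf)
  ok <- is_valid_base(df$effect_allele) & is_valid_base(df$other_allele) &
    df$effect_allele != df$other_allele &
    is.finite(df$beta) &
    is.finite(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1 &
    is.finite(df$maf) & df$maf > 0 & df$maf <= 0.5 &
    !is.na(df$pos) & df$pos >= 1
  ok[is.na(ok)] <- FALSE
  rejected <- sum(!ok)
  if (rejected > 0)
    message(rejected, " GWAS row(s) rejected (invariant violations)")
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, rejected = rejected,
            class = c("gwas_table", "data.frame"))
}

#' Read a GWAS summary-statistics file
#'
#' Tab-delimited with a header naming the seven required columns (plus
#' `chrom`); gzip is handled transparently.
#'
#' @param path Path to the file.
#' @return A [gwas_table()].
#' @export
read_gwas_summary <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = list(
                            character = c("snp_id", "chrom")))
  gwas_table(df)
}

#' Write a GWAS table as tab-delimited text
#' @param gwas A [gwas_table()].
#' @param path Output path (`.gz` suffix gzips).
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(gwas, path) {
  data.table::fwrite(as.data.frame(gwas), path, sep = "\t")
  invisible(path)
}

#' Read ancestral-allele annotations from a BED-like file
#'
#' BED uses 0-based half-open intervals: a line `chr start end snp_id base`
#' annotates the 1-based position `end` (for a 1-bp feature,
#' `start = pos - 1`, `end = pos`). Rows with a non-ACGT base are dropped
#' (treated as "ancestral state unresolved").
#'
#' @param path Path to a 5-column BED file (no header).
#' @return data.frame `snp_id`, `chrom`, `pos` (1-based), `ancestral`,
#'   class `ancestral_map`.
#' @export
read_ancestral_bed <- function(path) {
  # rtracklayer's BED reader requires a numeric score in column 5; this
  # dialect carries the ancestral base there, so parse directly.
  df <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(df) < 5) stop("ancestral BED needs 5 columns: chrom start end id base")
  names(df)[1:5] <- c("chrom", "start", "end", "snp_id", "ancestral")
  if (any(df$end - df$start != 1L))
    stop("ancestral BED entries must be single positions (end - start == 1)")
  out <- data.frame(snp_id = as.character(df$snp_id),
                    chrom = as.character(df$chrom),
                    pos = as.integer(df$end),   # 0-based half-open -> 1-based
                    ancestral = toupper(as.character(df$ancestral)),
                    stringsAsFactors = FALSE)
  keep <- is_valid_base(out$ancestral)
  if (any(!keep))
    message(sum(!keep), " ancestral record(s) dropped (unresolved base)")
  structure(out[keep, , drop = FALSE], class = c("ancestral_map", "data.frame"))
}

#' Write an ancestral-allele map as BED5
#' @param amap data.frame with `snp_id`, `chrom`, `pos`, `ancestral`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ancestral_bed <- function(amap, path) {
  bed <- data.frame(amap$chrom, amap$pos - 1L, amap$pos, amap$snp_id,
                    amap$ancestral)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a singleton-density-score table
#'
#' Tab-delimited with header `snp_id chrom pos sds_reference_allele sds`.
#' The score is reported for `sds_reference_allele`; rows with a
#' non-finite score or invalid allele are rejected with a message.
#'
#' @param path Path to the table.
#' @return data.frame of valid records, class `sds_table`.
#' @export
read_sds_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("snp_id", "chrom")))
  req <- c("snp_id", "chrom", "pos", "sds_reference_allele", "sds")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("SDS table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$sds <- suppressWarnings(as.numeric(df$sds))
  df$sds_reference_allele <- toupper(as.character(df$sds_reference_allele))
  ok <- is.finite(df$sds) & is_valid_base(df$sds_reference_allele)
  if (any(!ok)) message(sum(!ok), " SDS row(s) rejected")
  structure(df[ok, req, drop = FALSE],
            class = c("sds_table", "data.frame"))
}

#' Write an SDS table
#' @param sds data.frame as returned by [read_sds_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sds_table <- function(sds, path) {
  data.table::fwrite(as.data.frame(sds), path, sep = "\t")
  invisible(path)
}

#' Read a table of introgression tag SNPs
#'
#' Tab-delimited with header `snp_id archaic_allele altai_homozygous`;
#' `altai_homozygous` marks tag SNPs whose archaic allele is homozygous in
#' the high-coverage Altai Neanderthal genome.
#'
#' @param path Path to the table.
#' @return data.frame, class `tag_snp_table`.
#' @export
read_tag_snps <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = "snp_id"))
  req <- c("snp_id", "archaic_allele", "altai_homozygous")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("tag-SNP table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$archaic_allele <- toupper(as.character(df$archaic_allele))
  df$altai_homozygous <- as.logical(df$altai_homozygous)
  ok <- is_valid_base(df$archaic_allele) & !is.na(df$altai_homozygous)
  if (any(!ok)) message(sum(!ok), " tag-SNP row(s) rejected")
  structure(df[ok, req, drop = FALSE],
            class = c("tag_snp_table", "data.frame"))
}

#' Write a tag-SNP table
#' @param tags data.frame as returned by [read_tag_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_snps <- function(tags, path) {
  data.table::fwrite(as.data.frame(tags), path, sep = "\t")
  invisible(path)
}

# Cross-check (chrom, pos) agreement between two tables joined on snp_id.
# The join key is the SNP identifier; coordinates are a consistency check.
#' @noRd
check_coordinates <- function(a, b, what) {
  shared <- intersect(a$snp_id, b$snp_id)
  ia <- match(shared, a$snp_id); ib <- match(shared, b$snp_id)
  bad <- a$chrom[ia] != b$chrom[ib] | a$pos[ia] != b$pos[ib]
  if (any(bad))
    stop("coordinate mismatch between tables (", what, ") for snp_id: ",
         paste(utils::head(shared[bad], 5), collapse = ", "))
  invisible(shared)
}
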
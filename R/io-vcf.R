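#' Genotype panel: dosage matrix plus sample metadata
#'
#' Container for a samples-by-SNPs dosage matrix in the style of an
#' ancient-DNA genotype panel. Dosages count copies of the ALT allele;
#' `NA` is a missing call. Ploidy is per sample: pseudo-haploid ancient
#' samples (one randomly drawn allele per covered site, "hemizygous-like")
#' have ploidy 1 and dosages in \{0, 1\}; diploid samples have ploidy 2
#' and dosages in \{0, 1, 2\}.
#'
#' @param dosage Integer matrix (samples x SNPs), `NA` = missing.
#' @param ploidy Integer vector (1 or 2), one per sample.
#' @param snps data.frame with `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param meta data.frame with `sample_id`, `age_bp` (years before present),
#'   `continent`, and optionally `hg_ancestry` in \[0, 1\].
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, ploidy, snps, meta) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  ploidy <- as.integer(ploidy)
  stopifnot(nrow(dosage) == length(ploidy),
            nrow(dosage) == nrow(meta),
            ncol(dosage) == nrow(snps),
            all(ploidy %in% c(1L, 2L)),
            all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(snps)),
            all(c("sample_id", "age_bp", "continent") %in% names(meta)))
  if (!"hg_ancestry" %in% names(meta)) meta$hg_ancestry <- NA_real_
  stopifnot(all(is.finite(meta$age_bp)), all(meta$age_bp >= 0))
  over <- sweep(dosage, 1, ploidy, ">")
  if (any(over, na.rm = TRUE) || any(dosage < 0, na.rm = TRUE))
    stop("dosage outside {0..ploidy} for some called genotype")
  rownames(dosage) <- meta$sample_id
  colnames(dosage) <- snps$snp_id
  structure(list(dosage = dosage, ploidy = ploidy,
                 snps = as.data.frame(snps), meta = as.data.frame(meta)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d samples x %d SNPs (%.1f%% missing; ploidy %s)\n",
    nrow(x$dosage), ncol(x$dosage),
    100 * mean(is.na(x$dosage)),
    paste(sort(unique(x$ploidy)), collapse = "/")))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel by samples and/or variants
#' @param panel A [genotype_panel()].
#' @param samples Logical/integer index over samples (default all).
#' @param variants Logical/integer index over variants (default all).
#' @return The subsetted `genotype_panel`; order preserved.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  s <- samples %||% seq_len(nrow(panel$dosage))
  v <- variants %||% seq_len(ncol(panel$dosage))
  genotype_panel(panel$dosage[s, v, drop = FALSE], panel$ploidy[s],
                 panel$snps[v, , drop = FALSE], panel$meta[s, , drop = FALSE])
}

# GT string -> c(dosage, n_alleles); missing -> NA dosage.
#' @noRd
parse_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]", fixed = FALSE)
  n <- lengths(alleles)
  flat <- unlist(alleles, use.names = FALSE)
  miss <- flat == "." | flat == ""
  val <- suppressWarnings(as.integer(flat))
  val[miss] <- NA_integer_
  dos <- vapply(split(val, rep(seq_along(n), n)),
                function(v) if (anyNA(v)) NA_integer_ else sum(v),
                integer(1))
  list(dosage = unname(dos), n_alleles = n)
}

#' Read a genotype panel from VCF plus a sample-metadata table
#'
#' Only the GT field is used. Haploid calls (`0`, `1`) yield ploidy-1
#' samples; diploid calls (`0/1`, `0|1`, ...) ploidy 2; `./.` and `.` are
#' missing. Multi-allelic records are skipped with a warning. Every VCF
#' sample must appear in the metadata table (`sample_id`, `age_bp`,
#' `continent`, optional `hg_ancestry`).
#'
#' @param path Path to a VCF (optionally gzipped).
#' @param meta_path Path to the tab-delimited metadata table.
#' @return A [genotype_panel()].
#' @export
read_genotypes_vcf <- function(path, meta_path) {
  vcf <- VariantAnnotation::readVcf(path)
  meta <- data.table::fread(meta_path, sep = "\t", header = TRUE,
                            data.table = FALSE,
                            colClasses = list(character = "sample_id"))
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) > 1L
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    vcf <- vcf[!multi]
    alt <- alt[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT   # variants x samples
  samp <- colnames(gt)
  missing_meta <- setdiff(samp, meta$sample_id)
  if (length(missing_meta))
    stop("VCF sample(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  meta <- meta[match(samp, meta$sample_id), , drop = FALSE]

  parsed <- parse_gt(as.vector(gt))
  dosage <- matrix(parsed$dosage, nrow = nrow(gt), ncol = ncol(gt))
  nall <- matrix(parsed$n_alleles, nrow = nrow(gt), ncol = ncol(gt))
  # called diploid entries must be consistent within a sample
  ploidy <- apply(nall, 2, max)
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- data.frame(
    snp_id = names(rr) %||% paste0("snp", seq_along(rr)),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt)),
    stringsAsFactors = FALSE)
  genotype_panel(t(dosage), ploidy, snps, meta)
}

#' Write a genotype panel to a (plain-text) VCF and a metadata table
#'
#' @param panel A [genotype_panel()].
#' @param path Output VCF path.
#' @param meta_path Output metadata TSV path; default replaces the VCF
#'   extension with `.meta.tsv`.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(panel, path,
                                meta_path = sub("\\.vcf(\\.gz)?$", ".meta.tsv",
                                                path)) {
  d <- t(panel$dosage)                      # variants x samples
  n_var <- nrow(d); n_samp <- ncol(d)
  gt <- matrix("", n_var, n_samp)
  for (j in seq_len(n_samp)) {
    if (panel$ploidy[j] == 1L) {
      gt[, j] <- ifelse(is.na(d[, j]), ".", as.character(d[, j]))
    } else {
      gt[, j] <- c("0/0", "0/1", "1/1")[d[, j] + 1L]
      gt[is.na(d[, j]), j] <- "./."
    }
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=paleoburden",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$meta$sample_id),
                    collapse = "\t"))
  body <- if (n_var == 0) character(0) else
    paste(panel$snps$chrom, panel$snps$pos, panel$snps$snp_id,
          panel$snps$ref, panel$snps$alt, ".", ".", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(c(header, body), con)
  close(con)
  data.table::fwrite(panel$meta, meta_path, sep = "\t")
  invisible(path)
}
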
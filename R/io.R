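## Readers and writers for the plain-text formats the pipeline exchanges:
## GT-only VCF, tab-delimited dosage matrices, labeled relationship-matrix
## TSV, and pedigree/phenotype CSV.

#' Read a genotype dosage matrix from a VCF
#'
#' Parses the GT field of a diploid biallelic VCF into an individuals x SNPs
#' dosage matrix (count of ALT alleles, `NA` for missing `./.` calls).
#'
#' @param path VCF file (plain or gzipped).
#' @return numeric dosage matrix with sample rownames and `ID` colnames.
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  conv <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x == "0/0"] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x == "1/1"] <- 2
    out
  }
  d <- apply(gt, 2, conv)
  rownames(d) <- rownames(gt)
  t(d)
}

#' Write a dosage matrix as a GT-only VCF
#'
#' Emits one contig with positions 1..n_snps and GT-only genotype records;
#' fractional (imputed) dosages are not representable and are rejected.
#'
#' @param dosage integer dosage matrix (individuals x SNPs).
#' @param path output path.
#' @export
write_vcf_dosage <- function(dosage, path) {
  if (any(!is.na(dosage) & dosage != round(dosage)))
    stop("VCF output requires integer dosages")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dosage)), collapse = "\t")),
             con)
  for (m in seq_len(ncol(dosage))) {
    g <- gt_code[as.character(dosage[, m])]
    g[is.na(g)] <- "./."
    writeLines(paste(c("chr1", m, colnames(dosage)[m], "A", "G", ".", "PASS",
                       ".", "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read/write tab-delimited dosage matrices
#'
#' @param path file path.
#' @return `read_dosage`: numeric matrix with dimnames.
#' @export
read_dosage <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' @rdname read_dosage
#' @param dosage matrix to write.
#' @export
write_dosage <- function(dosage, path) {
  utils::write.table(dosage, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read/write a labeled relationship matrix as TSV
#'
#' @param path file path.
#' @param kind,source provenance labels restored on read.
#' @return `read_relmat`: a `px_relmat`.
#' @export
read_relmat <- function(path, kind = "additive", source = "marker") {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  new_relmat(m, kind, source)
}

#' @rdname read_relmat
#' @param rel matrix to write.
#' @export
write_relmat <- function(rel, path) {
  utils::write.table(unclass(rel), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
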
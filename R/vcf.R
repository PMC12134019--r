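#' Optional VCF genotype I/O
#'
#' Minimal bridge between the pipeline's dosage tables and VCF: the reader
#' (requires the suggested vcfR package) extracts unphased GT fields as
#' minor-allele dosages with "./." as missing; the writer emits a minimal
#' sites-by-samples VCF with GT only.
#'
#' @param path VCF file path.
#' @return Genotype table (`subject_id` + one 0/1/2/NA column per variant).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c("./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0L)
  })
  geno_table(t(dosage), subject_id = colnames(gt))
}

#' @param genotypes Genotype table to export.
#' @rdname read_genotypes_vcf
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  rsids <- setdiff(names(genotypes), "subject_id")
  g <- geno_matrix(genotypes)
  gt_str <- matrix("./.", nrow = length(rsids), ncol = nrow(g))
  for (j in seq_along(rsids)) {
    v <- g[, rsids[j]]
    gt_str[j, ] <- c("0/0", "0/1", "1/1", "./.")[ifelse(is.na(v), 4L, v + 1L)]
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", genotypes$subject_id), collapse = "\t"))
  body <- vapply(seq_along(rsids), function(j) {
    paste(c("1", j, rsids[j], "A", "G", ".", "PASS", ".", "GT", gt_str[j, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
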
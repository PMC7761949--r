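# quick cohort builder: geno is a variants x samples dosage matrix
make_cohort <- function(geno, pos = NULL, chrom = NULL, ref = NULL,
                        alt = NULL, samples = NULL, meta = NULL) {
  geno <- as.matrix(geno)
  m <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(m) * 10000L
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  genotype_cohort(data.frame(chrom = chrom, pos = as.integer(pos),
                             ref = ref, alt = alt,
                             stringsAsFactors = FALSE),
                  geno, samples, meta)
}

write_toy_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
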
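#' Read a genotype cohort from VCF
#'
#' Parses diploid (or haploid, for sex chromosomes) GT calls into a
#' [genotype_cohort()]. Multi-allelic records and indels are dropped and
#' reported through the `dropped` attribute; phased separators are treated as
#' unphased. Haploid calls are mapped to the homozygote of the present allele,
#' matching array-genotyping convention for male X/Y.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_subset optional character vector of sample IDs to keep.
#' @param meta optional per-sample metadata data.frame (see
#'   [genotype_cohort()]).
#' @return a `genotype_cohort`; attribute `dropped` is a data.frame logging
#'   excluded records with a reason.
#' @export
read_vcf <- function(path, sample_subset = NULL, meta = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(vcf@gt) == 0 || !"FORMAT" %in% colnames(vcf@gt))
    stop("VCF has no genotype columns")
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("GT field missing from FORMAT")

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  bases <- c("A", "C", "G", "T")
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1 | nchar(alt) != 1)
  nonacgt <- !multi & !indel & (!toupper(ref) %in% bases | !toupper(alt) %in% bases)
  keep <- !(multi | indel | nonacgt)
  reason <- rep(NA_character_, length(keep))
  reason[multi] <- "multi-allelic"
  reason[indel] <- "indel"
  reason[nonacgt] <- "non-ACGT allele"
  dropped <- data.frame(chrom = chrom[!keep], pos = pos[!keep],
                        ref = ref[!keep], alt = alt[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  if (sum(keep) == 0) stop("no biallelic SNPs left after filtering")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, colnames(gt))
    if (length(missing_s))
      stop("samples not in VCF: ", paste(missing_s, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
  }

  geno <- gt_string_to_dosage(gt)
  variants <- data.frame(chrom = chrom[keep], pos = pos[keep],
                         ref = toupper(ref[keep]), alt = toupper(alt[keep]),
                         stringsAsFactors = FALSE)
  key <- variant_keys(variants)
  if (anyDuplicated(key)) stop("duplicate variant keys in VCF")
  bad_order <- tapply(variants$pos,
                      factor(variants$chrom, levels = unique(variants$chrom)),
                      function(p) any(diff(p) < 0))
  if (any(unlist(bad_order)))
    stop("VCF records not sorted by position within chromosome")

  out <- genotype_cohort(variants, geno, colnames(gt), meta = meta)
  attr(out, "dropped") <- dropped
  out
}

# "0/1", "1|1", "1" (haploid), "./.", "0/." -> dosage 0/1/2/NA.
# Haploid calls become the homozygote of the present allele.
gt_string_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  code <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) == 1) al <- c(al, al)   # haploid -> homozygous
    if (length(al) != 2 || any(al == ".") || any(al == ""))
      return(NA_integer_)
    ai <- suppressWarnings(as.integer(al))
    if (any(is.na(ai))) return(NA_integer_)
    if (any(ai > 1))
      stop("allele index > 1 in GT after biallelic filtering: ", s)
    sum(ai)
  }, integer(1))
  m <- matrix(code[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

#' Write a genotype cohort as plain-text VCF
#'
#' Minimal VCFv4.2 with a GT-only FORMAT. Dosage 0/1/2 maps to `0/0`, `0/1`,
#' `1/1`; missing to `./.`.
#'
#' @param cohort a `genotype_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  gt_map <- c("0/0", "0/1", "1/1")
  g <- cohort$geno
  body <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  body[ok] <- gt_map[g[ok] + 1L]
  v <- cohort$variants
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", cohort$samples), collapse = "\t"),
             paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".", ".", "GT",
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write sample metadata as tab-delimited text
#' @param meta data.frame with a `sample_id` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata written by [write_metadata()]
#' @param path tab-delimited file with header including `sample_id`.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
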
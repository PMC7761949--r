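#' Construct a genotype cohort
#'
#' A `genotype_cohort` holds biallelic SNP genotype calls for a set of samples,
#' coded as alternate-allele dosage: 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous non-reference, `NA` = missing. Variants are identified by
#' chromosome, 1-based position, reference and alternate allele, and must be
#' sorted by position within each chromosome with no duplicate keys.
#'
#' @param variants data.frame with columns `chrom` (character), `pos`
#'   (integer, 1-based), `ref`, `alt` (single bases, `ref != alt`).
#' @param geno integer matrix, variants x samples, values in `{0, 1, 2, NA}`.
#' @param samples character vector of sample identifiers (column order of
#'   `geno`).
#' @param meta optional data.frame of per-sample metadata with a `sample_id`
#'   column (e.g. `sex`, `stratum`, `status`, `time`, `event`).
#' @return An object of class `genotype_cohort`: a list with elements
#'   `variants`, `geno`, `samples`, `meta` and `alt_freq` (per-variant
#'   alternate-allele frequency among non-missing calls).
#' @export
genotype_cohort <- function(variants, geno, samples, meta = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants))
    stop("geno must have one row per variant")
  if (ncol(geno) != length(samples))
    stop("geno must have one column per sample")
  if (any(!geno %in% c(0L, 1L, 2L, NA)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(variants$ref == variants$alt))
    stop("ref and alt allele must differ")
  if (any(variants$pos < 1))
    stop("positions are 1-based and must be >= 1")
  key <- variant_keys(variants)
  if (anyDuplicated(key))
    stop("duplicate variant keys")
  unsorted <- unlist(tapply(variants$pos, factor(variants$chrom,
                                                 levels = unique(variants$chrom)),
                            function(p) any(diff(p) < 0)), use.names = FALSE)
  if (any(unsorted))
    stop("variants must be sorted by position within chromosome")
  if (anyDuplicated(samples))
    stop("duplicate sample ids")
  dimnames(geno) <- list(key, samples)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(meta)) stop("meta must have a sample_id column")
    meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  obj <- list(variants = variants, geno = geno,
              samples = as.character(samples), meta = meta,
              alt_freq = compute_alt_freq(geno))
  class(obj) <- "genotype_cohort"
  obj
}

variant_keys <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Alternate-allele frequencies from a dosage matrix
#'
#' @param geno variants x samples dosage matrix (0/1/2/NA).
#' @return numeric vector in `[0, 1]`; `NaN` where every call is missing.
#' @export
compute_alt_freq <- function(geno) {
  n_called <- rowSums(!is.na(geno))
  unname(rowSums(geno, na.rm = TRUE) / (2 * n_called))
}

#' @export
print.genotype_cohort <- function(x, ...) {
  cat("genotype_cohort:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' Number of variants / samples
#' @param cohort a `genotype_cohort`.
#' @return integer count.
#' @export
n_variants <- function(cohort) nrow(cohort$variants)

#' @rdname n_variants
#' @export
n_samples <- function(cohort) length(cohort$samples)

#' Classify a diploid genotype call
#'
#' Maps a pair of allele indices to a zygosity state. Half-missing calls are
#' treated as fully missing since het/hom status cannot be assigned.
#'
#' @param a1,a2 allele indices (0 = ref, 1 = alt) or `NA`.
#' @return one of `"HomRef"`, `"Het"`, `"HomNonRef"`, `"Missing"`.
#' @examples
#' classify_genotype(0, 1)  # "Het"
#' classify_genotype(1, 1)  # "HomNonRef"
#' classify_genotype(0, NA) # "Missing"
#' @export
classify_genotype <- function(a1, a2) {
  if (is.na(a1) || is.na(a2)) return("Missing")
  if (!a1 %in% c(0, 1) || !a2 %in% c(0, 1))
    stop("allele index > 1: multi-allelic call should have been dropped upstream")
  s <- a1 + a2
  c("HomRef", "Het", "HomNonRef")[s + 1]
}

#' Major allele of a variant in the cohort
#'
#' The major allele is the alternate allele when its cohort frequency exceeds
#' 0.5 and the reference allele otherwise; an exact tie at 0.5 resolves to the
#' reference allele so that balanced sites leave the minor-allele homozygote
#' count equal to the non-reference one.
#'
#' @param cohort a `genotype_cohort`.
#' @param index variant row index or variant key string.
#' @return `"ref"` or `"alt"`.
#' @export
major_allele <- function(cohort, index) {
  if (is.character(index))
    index <- match(index, variant_keys(cohort$variants))
  af <- cohort$alt_freq[index]
  if (is.na(af) || is.nan(af))
    stop("allele frequency undefined: all calls missing at this variant")
  if (af > 0.5) "alt" else "ref"
}

#' Restrict two cohorts to their shared variants
#'
#' Variants match only when chromosome, position, reference and alternate
#' allele are all identical; a site with swapped ref/alt is not shared. Sample
#' sets are untouched and variant order is preserved. Allele frequencies are
#' recomputed on the restricted matrices (they are per-cohort quantities and
#' unchanged by row subsetting, but recomputation keeps the invariant explicit).
#'
#' @param a,b `genotype_cohort` objects.
#' @return list with elements `a` and `b`, both restricted to the common keys.
#' @export
intersect_cohorts <- function(a, b) {
  ka <- variant_keys(a$variants)
  kb <- variant_keys(b$variants)
  common <- intersect(ka, kb)
  if (length(common) == 0)
    stop(sprintf("no shared variants (%d vs %d variants, 0 common keys)",
                 length(ka), length(kb)))
  sel_a <- ka %in% common
  sel_b <- kb %in% common
  list(a = genotype_cohort(a$variants[sel_a, , drop = FALSE],
                           a$geno[sel_a, , drop = FALSE], a$samples, a$meta),
       b = genotype_cohort(b$variants[sel_b, , drop = FALSE],
                           b$geno[sel_b, , drop = FALSE], b$samples, b$meta))
}
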
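SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "23", "24")

drop_sex_variants <- function(cohort) {
  keep <- !(cohort$variants$chrom %in% SEX_CHROMS)
  list(variants = cohort$variants[keep, , drop = FALSE],
       geno = cohort$geno[keep, , drop = FALSE],
       alt_freq = cohort$alt_freq[keep])
}

#' Per-sample zygosity counts
#'
#' Counts heterozygous, homozygous-reference, homozygous-non-reference and
#' homozygous-minor-allele sites for one sample. A site is homozygous-minor
#' when the sample is homozygous for the cohort-minor allele: homozygous
#' reference where the alternate allele is the cohort-major allele
#' (`alt_freq > 0.5`), homozygous non-reference elsewhere. Missing calls are
#' excluded from all het/hom counts.
#'
#' @param cohort a `genotype_cohort`.
#' @param sample sample identifier.
#' @param include_sex_chroms keep X/Y variants (default `TRUE`; sex-chromosome
#'   inclusion is what drives sex differences in the heterozygosity ratio, so
#'   it is switchable).
#' @return list with `n_het`, `n_hom_ref`, `n_hom_nonref`, `n_hom_minor`,
#'   `n_missing`.
#' @export
count_zygosity <- function(cohort, sample, include_sex_chroms = TRUE) {
  j <- match(sample, cohort$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  dat <- if (include_sex_chroms) cohort else drop_sex_variants(cohort)
  g <- dat$geno[, j]
  af <- dat$alt_freq
  alt_major <- !is.na(af) & af > 0.5
  list(n_het = sum(g == 1, na.rm = TRUE),
       n_hom_ref = sum(g == 0, na.rm = TRUE),
       n_hom_nonref = sum(g == 2, na.rm = TRUE),
       n_hom_minor = sum(g == 0 & alt_major, na.rm = TRUE) +
                     sum(g == 2 & !alt_major, na.rm = TRUE),
       n_missing = sum(is.na(g)))
}

#' Heterozygosity ratios
#'
#' `hr_nonref` is the number of heterozygous SNPs divided by the number of
#' homozygous non-reference SNPs; `hr_minor` divides by the count of sites
#' homozygous for the cohort-minor allele instead. A zero denominator yields
#' `NA` (the sample is flagged for exclusion from downstream regressions, not
#' an error).
#'
#' @param counts zygosity counts from [count_zygosity()].
#' @return ratio, or `NA` when undefined.
#' @examples
#' hr_nonref(list(n_het = 10, n_hom_nonref = 5))  # 2
#' @export
hr_nonref <- function(counts) {
  if (counts$n_hom_nonref == 0) return(NA_real_)
  counts$n_het / counts$n_hom_nonref
}

#' @rdname hr_nonref
#' @export
hr_minor <- function(counts) {
  if (counts$n_hom_minor == 0) return(NA_real_)
  counts$n_het / counts$n_hom_minor
}

#' Sliding-window run-of-homozygosity parameters
#'
#' Defaults mirror the documented defaults of the standard array-data ROH
#' scanner: 50-SNP windows tolerating 1 heterozygous and 5 missing calls, a
#' SNP is eligible when at least 5% of windows covering it are hits, and runs
#' are reported at >= 100 SNPs, >= 1000 kb, gaps <= 1000 kb and density at
#' least one SNP per 50 kb.
#'
#' @param window_snps window size in SNPs.
#' @param window_max_het maximum heterozygous calls for a window hit.
#' @param window_max_missing maximum missing calls for a window hit.
#' @param hit_proportion_threshold minimum hit proportion for SNP eligibility.
#' @param min_snps minimum SNPs in a reported segment.
#' @param min_length_kb minimum segment length (kb).
#' @param max_gap_kb split runs at inter-SNP gaps larger than this (kb).
#' @param min_density_kb_per_snp maximum kb per SNP within a segment.
#' @return an object of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, window_max_het = 1,
                       window_max_missing = 5,
                       hit_proportion_threshold = 0.05,
                       min_snps = 100, min_length_kb = 1000,
                       max_gap_kb = 1000, min_density_kb_per_snp = 50) {
  p <- list(window_snps = window_snps, window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            hit_proportion_threshold = hit_proportion_threshold,
            min_snps = min_snps, min_length_kb = min_length_kb,
            max_gap_kb = max_gap_kb,
            min_density_kb_per_snp = min_density_kb_per_snp)
  if (p$window_snps < 1 || p$min_snps < 1 || p$min_length_kb <= 0 ||
      p$max_gap_kb <= 0 || p$min_density_kb_per_snp <= 0 ||
      p$window_max_het < 0 || p$window_max_missing < 0)
    stop("roh_params must be positive")
  if (p$hit_proportion_threshold <= 0 || p$hit_proportion_threshold > 1)
    stop("hit_proportion_threshold must be in (0, 1]")
  class(p) <- "roh_params"
  p
}

#' Detect runs of homozygosity for one sample
#'
#' PLINK-style scan: per chromosome, a window of `window_snps` SNPs slides one
#' SNP at a time and is a "hit" when it contains at most `window_max_het`
#' heterozygous and `window_max_missing` missing calls. Each SNP's hit
#' proportion is the fraction of windows covering it that are hits; SNPs at or
#' above `hit_proportion_threshold` are eligible. Maximal runs of eligible
#' SNPs are split at gaps over `max_gap_kb`, trimmed so they start and end on
#' non-heterozygous calls, and reported when they satisfy the SNP-count,
#' length and density filters. Chromosomes with fewer SNPs than one window
#' yield no segments.
#'
#' @param cohort a `genotype_cohort`.
#' @param sample sample identifier.
#' @param params an [roh_params()] object.
#' @param include_sex_chroms keep X/Y variants.
#' @return data.frame of segments: `chrom`, `start_pos`, `end_pos` (1-based
#'   inclusive), `n_snps`, `length_kb`.
#' @export
detect_roh <- function(cohort, sample, params = roh_params(),
                       include_sex_chroms = TRUE) {
  j <- match(sample, cohort$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  dat <- if (include_sex_chroms) cohort else drop_sex_variants(cohort)
  out <- list()
  for (chrom in unique(dat$variants$chrom)) {
    sel <- dat$variants$chrom == chrom
    segs <- roh_scan_chrom(dat$geno[sel, j], dat$variants$pos[sel], params)
    if (nrow(segs)) {
      segs$chrom <- chrom
      out[[length(out) + 1]] <- segs
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), n_snps = integer(),
                      length_kb = numeric()))
  res <- do.call(rbind, out)
  res[, c("chrom", "start_pos", "end_pos", "n_snps", "length_kb")]
}

roh_scan_chrom <- function(g, pos, params) {
  empty <- data.frame(start_pos = integer(), end_pos = integer(),
                      n_snps = integer(), length_kb = numeric())
  m <- length(g)
  w <- params$window_snps
  if (m < w) return(empty)
  het <- as.integer(!is.na(g) & g == 1)
  mis <- as.integer(is.na(g))
  # window sums via cumulative sums; window s covers SNPs s..s+w-1
  ch <- c(0, cumsum(het))
  cm <- c(0, cumsum(mis))
  starts <- 1:(m - w + 1)
  hit <- (ch[starts + w] - ch[starts]) <= params$window_max_het &
         (cm[starts + w] - cm[starts]) <= params$window_max_missing
  # SNP i is covered by window starts max(1, i-w+1) .. min(i, m-w+1)
  chit <- c(0, cumsum(as.integer(hit)))
  i <- 1:m
  s1 <- pmax(1L, i - w + 1L)
  s2 <- pmin(i, m - w + 1L)
  prop <- (chit[s2 + 1] - chit[s1]) / (s2 - s1 + 1)
  eligible <- prop >= params$hit_proportion_threshold

  segs <- list()
  r <- rle(eligible)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  for (k in which(r$values)) {
    idx <- run_start[k]:run_end[k]
    # split at large gaps
    gap_split <- which(diff(pos[idx]) > params$max_gap_kb * 1000)
    piece_start <- c(1, gap_split + 1)
    piece_end <- c(gap_split, length(idx))
    for (p in seq_along(piece_start)) {
      piece <- idx[piece_start[p]:piece_end[p]]
      # trim to start/end on non-het calls
      while (length(piece) && het[piece[1]] == 1) piece <- piece[-1]
      while (length(piece) && het[piece[length(piece)]] == 1)
        piece <- piece[-length(piece)]
      if (!length(piece)) next
      n_snps <- length(piece)
      len_kb <- (pos[piece[n_snps]] - pos[piece[1]] + 1) / 1000
      if (n_snps >= params$min_snps && len_kb >= params$min_length_kb &&
          len_kb / n_snps <= params$min_density_kb_per_snp)
        segs[[length(segs) + 1]] <- data.frame(
          start_pos = pos[piece[1]], end_pos = pos[piece[n_snps]],
          n_snps = n_snps, length_kb = len_kb)
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

#' Median run-of-homozygosity length
#'
#' The per-sample summary used downstream is the median segment length in kb;
#' a sample with no detected segment scores 0 (minimally autozygous) so it
#' stays in the regressions rather than being dropped.
#'
#' @param segments segment data.frame from [detect_roh()].
#' @return median length in kb; 0 for an empty set.
#' @export
median_roh_length <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0) return(0)
  stats::median(segments$length_kb)
}

#' Standardize a vector to per-SD units
#'
#' Centers and scales by the sample standard deviation of the defined values;
#' `NA` entries propagate. Association effect sizes downstream are therefore
#' per standard deviation of the analysis stratum.
#'
#' @param x numeric vector.
#' @return standardized vector (mean 0, SD 1 over defined entries).
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 defined values to standardize")
  s <- stats::sd(x[ok])
  if (s == 0) stop("zero standard deviation: cannot standardize")
  (x - mean(x[ok])) / s
}

#' Autozygosity profile for every sample in a cohort
#'
#' Computes zygosity counts, both heterozygosity ratios, and (optionally) the
#' ROH scan with the median segment length per sample.
#'
#' @param cohort a `genotype_cohort`.
#' @param params an [roh_params()] object.
#' @param include_sex_chroms keep X/Y variants.
#' @param roh run the ROH scan (set `FALSE` to skip the slowest step).
#' @return an object of class `autozygosity_profile`: a data.frame with one
#'   row per sample (`sample_id`, counts, `hr_nonref`, `hr_minor`, `n_roh`,
#'   `roh_total_kb`, `roh_median_kb`) and the per-sample segment list in the
#'   `segments` attribute.
#' @export
autozygosity_profile <- function(cohort, params = roh_params(),
                                 include_sex_chroms = TRUE, roh = TRUE) {
  dat <- if (include_sex_chroms) cohort else drop_sex_variants(cohort)
  g <- dat$geno
  af <- dat$alt_freq
  alt_major <- !is.na(af) & af > 0.5
  n_het <- colSums(g == 1, na.rm = TRUE)
  n_hom_ref <- colSums(g == 0, na.rm = TRUE)
  n_hom_nonref <- colSums(g == 2, na.rm = TRUE)
  n_hom_minor <- colSums(g == 0 & alt_major, na.rm = TRUE) +
                 colSums(g == 2 & !alt_major, na.rm = TRUE)
  n_missing <- colSums(is.na(g))
  prof <- data.frame(
    sample_id = cohort$samples,
    n_het = n_het, n_hom_ref = n_hom_ref, n_hom_nonref = n_hom_nonref,
    n_hom_minor = n_hom_minor, n_missing = n_missing,
    hr_nonref = ifelse(n_hom_nonref > 0, n_het / n_hom_nonref, NA_real_),
    hr_minor = ifelse(n_hom_minor > 0, n_het / n_hom_minor, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
  segments <- NULL
  if (roh) {
    segments <- lapply(cohort$samples, function(s)
      detect_roh(cohort, s, params, include_sex_chroms))
    names(segments) <- cohort$samples
    prof$n_roh <- vapply(segments, nrow, integer(1))
    prof$roh_total_kb <- vapply(segments, function(s) sum(s$length_kb),
                                numeric(1))
    prof$roh_median_kb <- vapply(segments, median_roh_length, numeric(1))
  }
  attr(prof, "segments") <- segments
  class(prof) <- c("autozygosity_profile", "data.frame")
  prof
}

#' @export
print.autozygosity_profile <- function(x, ...) {
  cat("autozygosity_profile:", nrow(x), "samples\n")
  cat(sprintf("  mean hr_nonref: %.4f  mean hr_minor: %.4f\n",
              mean(x$hr_nonref, na.rm = TRUE),
              mean(x$hr_minor, na.rm = TRUE)))
  if ("roh_median_kb" %in% names(x))
    cat(sprintf("  mean n_roh: %.2f  mean median ROH length: %.1f kb\n",
                mean(x$n_roh), mean(x$roh_median_kb)))
  n_flag <- sum(is.na(x$hr_nonref))
  if (n_flag) cat(" ", n_flag, "sample(s) with undefined hr_nonref\n")
  invisible(x)
}

#' Write ROH segments as BED
#'
#' BED is 0-based half-open, so `start_pos` is shifted down by one while the
#' inclusive `end_pos` is written as-is.
#'
#' @param segments_by_sample named list of segment data.frames (the
#'   `segments` attribute of an [autozygosity_profile()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roh_bed <- function(segments_by_sample, path) {
  rows <- lapply(names(segments_by_sample), function(s) {
    seg <- segments_by_sample[[s]]
    if (!nrow(seg)) return(NULL)
    data.frame(chrom = seg$chrom, start = seg$start_pos - 1L,
               end = seg$end_pos, name = s, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(chrom = character(), start = integer(),
                       end = integer(), name = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
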
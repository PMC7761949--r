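test_that("zygosity counts separate non-reference from minor homozygotes", {
  # SNP1: alt is cohort-major (freq 5/6); SNP2: ref major (freq 1/6)
  g <- rbind(c(2L, 2L, 1L),
             c(1L, 0L, 0L))
  co <- make_cohort(g)
  cz <- count_zygosity(co, "S1")
  expect_equal(cz$n_het, 1)
  expect_equal(cz$n_hom_nonref, 1)
  expect_equal(cz$n_hom_minor, 0)   # S1 is homozygous only for major alleles

  # all hom-ref sample
  cz3 <- count_zygosity(make_cohort(matrix(0L, 5, 1)), "S1")
  expect_equal(cz3$n_het, 0)
  expect_equal(cz3$n_hom_nonref, 0)
  expect_equal(cz3$n_hom_ref, 5)

  expect_error(count_zygosity(co, "nope"), "unknown sample")
})

test_that("heterozygosity ratios follow their definitions and flag 0/0", {
  expect_equal(hr_nonref(list(n_het = 10, n_hom_nonref = 5)), 2)
  expect_equal(hr_nonref(list(n_het = 0, n_hom_nonref = 7)), 0)
  expect_true(is.na(hr_nonref(list(n_het = 4, n_hom_nonref = 0))))
  expect_equal(hr_minor(list(n_het = 12, n_hom_minor = 4)), 3)
})

test_that("hr_minor coincides with hr_nonref when no alt allele is major", {
  set.seed(3)
  freqs <- sample_frequencies(400, "uniform", c(0.05, 0.45), seed = 3)
  co <- simulate_genotypes(freqs, 0, 20, seed = 4)
  # alt_freq can still exceed 0.5 by sampling; keep only ref-major sites
  keep <- co$alt_freq <= 0.5
  co2 <- make_cohort(co$geno[keep, ], pos = co$variants$pos[keep])
  prof <- autozygosity_profile(co2, roh = FALSE)
  expect_equal(prof$hr_minor, prof$hr_nonref)
})

test_that("reference flips raise hr_minor above hr_nonref on average", {
  freqs <- sample_frequencies(4000, seed = 11)
  co <- simulate_genotypes(freqs, 0, 40, seed = 12)
  co_f <- flip_reference(co, 0.08, seed = 13)
  prof <- autozygosity_profile(co_f, roh = FALSE)
  expect_gt(mean(prof$hr_minor), mean(prof$hr_nonref))
  # and the flips shrink the nonref denominator's complement: hr_nonref drops
  prof0 <- autozygosity_profile(co, roh = FALSE)
  expect_lt(mean(prof$hr_nonref), mean(prof0$hr_nonref))
})

test_that("ROH scan finds a clean homozygous run and honors run filters", {
  # all-heterozygous sample yields nothing
  co_het <- make_cohort(matrix(1L, 200, 1))
  expect_equal(nrow(detect_roh(co_het, "S1")), 0)

  # 120 consecutive homozygous SNPs spaced 10 kb -> one segment of 120 SNPs
  co_hom <- make_cohort(matrix(0L, 120, 1))
  segs <- detect_roh(co_hom, "S1")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 120)
  expect_equal(segs$length_kb, (120 * 10000 - 10000 + 1) / 1000)
  expect_identical(segs, oracle_roh(co_hom$geno[, 1], co_hom$variants$pos,
                                    co_hom$variants$chrom, roh_params()))

  # het inserted at the midpoint with zero-het windows splits the run;
  # halves fail the 100-SNP filter at defaults but pass relaxed filters
  g <- matrix(0L, 121, 1); g[61] <- 1L
  co_mid <- make_cohort(g)
  p0 <- roh_params(window_max_het = 0)
  expect_equal(nrow(detect_roh(co_mid, "S1", p0)), 0)
  p1 <- roh_params(window_max_het = 0, min_snps = 30, min_length_kb = 200)
  segs2 <- detect_roh(co_mid, "S1", p1)
  expect_equal(nrow(segs2), 2)
  expect_identical(segs2, oracle_roh(g[, 1], co_mid$variants$pos,
                                     co_mid$variants$chrom, p1))

  # chromosome shorter than the window produces no windows, no error
  expect_equal(nrow(detect_roh(make_cohort(matrix(0L, 10, 1)), "S1")), 0)
})

test_that("median ROH length follows the empty-set convention", {
  seg <- function(kb) data.frame(chrom = "chr1", start_pos = 1L,
                                 end_pos = 1L, n_snps = 1L, length_kb = kb)
  expect_equal(median_roh_length(do.call(rbind, lapply(c(1000, 2000, 6000), seg))),
               2000)
  expect_equal(median_roh_length(do.call(rbind, lapply(c(1000, 2000), seg))),
               1500)
  expect_equal(median_roh_length(detect_roh(make_cohort(matrix(1L, 5, 1)), "S1")),
               0)
})

test_that("standardization gives per-SD units and rejects degenerate input", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize(c(2, 2, 2)), "zero standard deviation")
  expect_error(standardize(c(1, NA)), "at least 2")
  set.seed(5)
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  # NA propagates without affecting the others
  x[3] <- NA
  z2 <- standardize(x)
  expect_true(is.na(z2[3]))
  expect_equal(sd(z2, na.rm = TRUE), 1)
})

test_that("excluding sex chromosomes shrinks the sex gap in mean HR", {
  freqs <- sample_frequencies(3000, seed = 21)
  sex <- rep(c("female", "male"), each = 30)
  co <- simulate_genotypes(freqs, 0, 60, seed = 22, n_x_snps = 1500,
                           sex = sex)
  with_x <- autozygosity_profile(co, roh = FALSE, include_sex_chroms = TRUE)
  no_x <- autozygosity_profile(co, roh = FALSE, include_sex_chroms = FALSE)
  gap <- function(p) abs(mean(p$hr_nonref[sex == "female"]) -
                         mean(p$hr_nonref[sex == "male"]))
  expect_gt(gap(with_x), gap(no_x))
  # and with X in, females (diploid X, het possible) have the higher HR
  expect_gt(mean(with_x$hr_nonref[sex == "female"]),
            mean(with_x$hr_nonref[sex == "male"]))
})

test_that("profile matrix path agrees with per-sample counting", {
  freqs <- sample_frequencies(500, seed = 31)
  co <- simulate_genotypes(freqs, 0.1, 8, seed = 32)
  co$geno[sample(length(co$geno), 100)] <- NA  # sprinkle missingness
  co$alt_freq <- compute_alt_freq(co$geno)
  prof <- autozygosity_profile(co, roh = FALSE)
  for (s in c("S2", "S7")) {
    cz <- count_zygosity(co, s)
    row <- prof[prof$sample_id == s, ]
    expect_equal(row$n_het, cz$n_het)
    expect_equal(row$n_hom_nonref, cz$n_hom_nonref)
    expect_equal(row$n_hom_minor, cz$n_hom_minor)
    expect_equal(row$n_missing, cz$n_missing)
  }
  expect_equal(prof$n_het + prof$n_hom_ref + prof$n_hom_nonref +
                 prof$n_missing,
               rep(n_variants(co), n_samples(co)))
})

test_that("ROH segments export as 0-based half-open BED", {
  co <- make_cohort(matrix(0L, 120, 1))
  prof <- autozygosity_profile(co)
  path <- withr::local_tempfile(fileext = ".bed")
  write_roh_bed(attr(prof, "segments"), path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 10000 - 1)
  expect_equal(bed$V3, 1200000)
  expect_equal(bed$V3 - bed$V2, 120 * 10000 - 10000 + 1)
})
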
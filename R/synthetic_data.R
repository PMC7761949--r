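#' Synthetic cohort configuration
#'
#' Bundles every simulator knob with defaults chosen to match the statistical
#' structure the analysis assumes: a neutral derived-allele frequency spectrum
#' (density proportional to 1/p) truncated to [0.001, 0.999] with the
#' reference allele set to the ancestral allele, around 8% of sites with the
#' reference/major-allele labels swapped, panmictic Hardy-Weinberg genotypes
#' (F = 0), a per-SD log odds ratio of 1 for case-control labels, and
#' exponential survival with hazard coefficient 0.7 per SD under 20%
#' censoring.
#'
#' @param n_samples samples to simulate.
#' @param n_snps autosomal SNPs.
#' @param spectrum `"neutral"` (density proportional to 1/p), `"uniform"`, or
#'   `"fixed"` (supply `fixed_freqs`).
#' @param freq_bounds `(p_min, p_max)` truncation of the spectrum.
#' @param fixed_freqs frequency list recycled across SNPs when
#'   `spectrum = "fixed"`.
#' @param inbreeding_f inbreeding coefficient F in `[0, 1]`, scalar or
#'   per-sample.
#' @param flip_fraction fraction of sites whose ref/alt labels are swapped.
#' @param roh_tracts,roh_tract_len_snps injected homozygous tracts per sample
#'   and their length in SNPs (0 tracts disables injection).
#' @param n_x_snps SNPs on the simulated X block (diploid in females, haploid
#'   in males); 0 disables sex chromosomes.
#' @param female_fraction fraction of female samples.
#' @param risk_beta true per-SD log odds ratio for case-control labels.
#' @param baseline_prevalence case probability at the predictor mean.
#' @param hazard_beta true per-SD log hazard.
#' @param censoring_rate target fraction of censored subjects.
#' @param n_signatures signatures mixed into mutation catalogs.
#' @param mutations_per_sample somatic mutations drawn per sample.
#' @param seed integer seed; mandatory, every stochastic operation derives
#'   its stream from it.
#' @return a `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_samples = 200, n_snps = 5000,
                                    spectrum = "neutral",
                                    freq_bounds = c(0.001, 0.999),
                                    fixed_freqs = NULL,
                                    inbreeding_f = 0, flip_fraction = 0.08,
                                    roh_tracts = 0, roh_tract_len_snps = 150,
                                    n_x_snps = 0, female_fraction = 0.5,
                                    risk_beta = 1.0,
                                    baseline_prevalence = 0.5,
                                    hazard_beta = 0.7, censoring_rate = 0.2,
                                    n_signatures = 4,
                                    mutations_per_sample = 1000,
                                    seed = 1L) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1,
            all(inbreeding_f >= 0), all(inbreeding_f <= 1),
            baseline_prevalence > 0, baseline_prevalence < 1,
            censoring_rate >= 0, censoring_rate < 1,
            !is.null(seed))
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_cohort_config"
  cfg
}

# deterministic sub-stream seeds, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483629)
}

#' Draw derived-allele frequencies from a site frequency spectrum
#'
#' The neutral spectrum has density proportional to 1/p on
#' `[p_min, p_max]`, drawn by inverse CDF: `p = p_min * (p_max/p_min)^u`
#' with `u ~ Uniform(0, 1)` (so `log p` is uniform).
#'
#' @param n_snps number of frequencies.
#' @param spectrum `"neutral"`, `"uniform"` or `"fixed"`.
#' @param freq_bounds `(p_min, p_max)`, with `0 < p_min < p_max < 1`.
#' @param fixed_freqs values recycled when `spectrum = "fixed"`.
#' @param seed integer seed.
#' @return numeric vector of length `n_snps`.
#' @export
sample_frequencies <- function(n_snps, spectrum = "neutral",
                               freq_bounds = c(0.001, 0.999),
                               fixed_freqs = NULL, seed = 1L) {
  p_min <- freq_bounds[1]; p_max <- freq_bounds[2]
  if (!(p_min > 0 && p_max < 1 && p_min < p_max))
    stop("freq_bounds must satisfy 0 < p_min < p_max < 1")
  set.seed(seed)
  switch(spectrum,
    neutral = {
      u <- stats::runif(n_snps)
      p_min * (p_max / p_min)^u
    },
    uniform = stats::runif(n_snps, p_min, p_max),
    fixed = {
      if (is.null(fixed_freqs)) stop("fixed spectrum needs fixed_freqs")
      rep_len(fixed_freqs, n_snps)
    },
    stop("unknown spectrum: ", spectrum))
}

#' Simulate Hardy-Weinberg genotypes with inbreeding
#'
#' Per sample and site, the genotype is drawn with
#' `P(HomRef) = (1-p)^2 + F p (1-p)`, `P(Het) = 2 p (1-p) (1-F)`,
#' `P(HomAlt) = p^2 + F p (1-p)`. SNPs are laid out at a fixed 10 kb spacing
#' on 25 Mb synthetic autosomes so that kb-scale ROH thresholds are
#' deterministic functions of SNP counts. An optional X block is diploid in
#' females and haploid in males (haploid calls coded as the homozygote of the
#' present allele).
#'
#' @param freqs autosomal derived-allele frequencies (ref = ancestral).
#' @param f inbreeding coefficient, scalar or one per sample.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param n_x_snps SNPs on the X block (drawn from the same spectrum bounds
#'   as `freqs` by resampling from it).
#' @param sex optional character vector (`"female"`/`"male"`) of length
#'   `n_samples`; required when `n_x_snps > 0`.
#' @param spacing_bp inter-SNP spacing.
#' @param chrom_length_bp synthetic chromosome length.
#' @return a [genotype_cohort()] with samples `S1..Sn`; metadata holds `sex`
#'   and the true per-sample `f` in the `truth` attribute.
#' @export
simulate_genotypes <- function(freqs, f = 0, n_samples, seed = 1L,
                               n_x_snps = 0, sex = NULL,
                               spacing_bp = 10000, chrom_length_bp = 25e6) {
  m <- length(freqs)
  f <- rep_len(f, n_samples)
  set.seed(seed)
  if (n_x_snps > 0) {
    if (is.null(sex)) stop("sex required when simulating an X block")
    x_freqs <- sample(freqs, n_x_snps, replace = TRUE)
  }
  per_chrom <- chrom_length_bp %/% spacing_bp
  chrom_idx <- (seq_len(m) - 1) %/% per_chrom
  variants <- data.frame(
    chrom = paste0("chr", chrom_idx + 1),
    pos = as.integer(((seq_len(m) - 1) %% per_chrom + 1) * spacing_bp),
    ref = "A", alt = "G", stringsAsFactors = FALSE)

  geno <- matrix(NA_integer_, nrow = m, ncol = n_samples)
  for (j in seq_len(n_samples)) {
    p0 <- (1 - freqs)^2 + f[j] * freqs * (1 - freqs)
    p1 <- 2 * freqs * (1 - freqs) * (1 - f[j])
    r <- stats::runif(m)
    geno[, j] <- (r > p0) + (r > p0 + p1)
  }

  if (n_x_snps > 0) {
    xv <- data.frame(chrom = "chrX",
                     pos = as.integer(seq_len(n_x_snps) * spacing_bp),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
    gx <- matrix(NA_integer_, nrow = n_x_snps, ncol = n_samples)
    for (j in seq_len(n_samples)) {
      if (sex[j] == "male") {
        gx[, j] <- 2L * (stats::runif(n_x_snps) < x_freqs)
      } else {
        p0 <- (1 - x_freqs)^2 + f[j] * x_freqs * (1 - x_freqs)
        p1 <- 2 * x_freqs * (1 - x_freqs) * (1 - f[j])
        r <- stats::runif(n_x_snps)
        gx[, j] <- (r > p0) + (r > p0 + p1)
      }
    }
    variants <- rbind(variants, xv)
    geno <- rbind(geno, gx)
  }

  ids <- paste0("S", seq_len(n_samples))
  meta <- data.frame(sample_id = ids,
                     sex = if (is.null(sex)) NA_character_ else sex,
                     stringsAsFactors = FALSE)
  cohort <- genotype_cohort(variants, geno, ids, meta)
  attr(cohort, "truth") <- list(f = stats::setNames(f, ids),
                                freqs = c(freqs,
                                          if (n_x_snps > 0) x_freqs))
  cohort
}

#' Inject contiguous homozygous tracts
#'
#' Overwrites randomly placed contiguous SNP runs with homozygous calls (the
#' allele drawn by its site frequency), creating ground-truth ROH for the
#' detector. Overlapping tracts within a sample are merged and the merge is
#' recorded in the truth table.
#'
#' @param cohort a simulated `genotype_cohort`.
#' @param tracts tracts per sample.
#' @param tract_len_snps tract length in SNPs (must fit on one chromosome).
#' @param samples samples to receive tracts (default: all).
#' @param seed integer seed.
#' @return the cohort with tracts injected; truth tracts appended to the
#'   `truth` attribute as `roh_tracts`.
#' @export
inject_roh <- function(cohort, tracts, tract_len_snps, samples = NULL,
                       seed = 1L) {
  if (tracts == 0) return(cohort)
  if (is.null(samples)) samples <- cohort$samples
  set.seed(seed)
  truth <- attr(cohort, "truth")
  freqs <- truth$freqs
  if (is.null(freqs)) freqs <- cohort$alt_freq
  chroms <- unique(cohort$variants$chrom)
  rows_by_chrom <- lapply(chroms, function(cc) which(cohort$variants$chrom == cc))
  names(rows_by_chrom) <- chroms
  ok_chroms <- chroms[vapply(rows_by_chrom, length, integer(1)) >= tract_len_snps]
  if (!length(ok_chroms)) stop("tract does not fit on any chromosome")
  rec <- list()
  for (s in samples) {
    j <- match(s, cohort$samples)
    iv <- matrix(integer(), ncol = 2)
    for (t in seq_len(tracts)) {
      cc <- if (length(ok_chroms) == 1) ok_chroms else sample(ok_chroms, 1)
      rows <- rows_by_chrom[[cc]]
      start <- sample(length(rows) - tract_len_snps + 1, 1)
      iv <- rbind(iv, c(rows[start], rows[start + tract_len_snps - 1]))
    }
    iv <- merge_intervals(iv)
    for (r in seq_len(nrow(iv))) {
      idx <- iv[r, 1]:iv[r, 2]
      cohort$geno[idx, j] <- 2L * (stats::runif(length(idx)) < freqs[idx])
      rec[[length(rec) + 1]] <- data.frame(
        sample = s, chrom = cohort$variants$chrom[iv[r, 1]],
        start_pos = cohort$variants$pos[iv[r, 1]],
        end_pos = cohort$variants$pos[iv[r, 2]],
        n_snps = length(idx), stringsAsFactors = FALSE)
    }
  }
  cohort$alt_freq <- compute_alt_freq(cohort$geno)
  truth$roh_tracts <- do.call(rbind, rec)
  attr(cohort, "truth") <- truth
  cohort
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (r in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv[r, 1] <= out[last, 2] + 1) out[last, 2] <- max(out[last, 2], iv[r, 2])
    else out <- rbind(out, iv[r, ])
  }
  out
}

#' Swap reference/alternate labels at a random fraction of sites
#'
#' Emulates reference-genome sites where the reference allele is not the
#' population major allele (about 8% of array variants): at the selected
#' sites ref and alt labels are exchanged, genotype states re-expressed
#' (HomRef and HomNonRef swap, Het is invariant) and allele frequencies
#' recomputed.
#'
#' @param cohort a `genotype_cohort`.
#' @param flip_fraction fraction of sites to flip.
#' @param seed integer seed.
#' @return the flipped cohort; flipped site indices recorded in the `truth`
#'   attribute as `flipped_sites`.
#' @export
flip_reference <- function(cohort, flip_fraction, seed = 1L) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1)
  if (flip_fraction == 0) return(cohort)
  set.seed(seed)
  m <- n_variants(cohort)
  idx <- sort(sample(m, round(flip_fraction * m)))
  v <- cohort$variants
  tmp <- v$ref[idx]; v$ref[idx] <- v$alt[idx]; v$alt[idx] <- tmp
  g <- cohort$geno
  g[idx, ] <- 2L - g[idx, ]
  truth <- attr(cohort, "truth")
  out <- genotype_cohort(v, g, cohort$samples, cohort$meta)
  truth$flipped_sites <- idx
  attr(out, "truth") <- truth
  out
}

#' Simulate case-control labels from a logistic model
#'
#' `P(case) = plogis(alpha + beta * z)` with the intercept set from the
#' baseline prevalence.
#'
#' @param z standardized predictor (e.g. per-SD heterozygosity ratio).
#' @param risk_beta true per-SD log odds ratio.
#' @param baseline_prevalence case probability at `z = 0`.
#' @param seed integer seed.
#' @return integer 0/1 labels.
#' @export
simulate_case_control <- function(z, risk_beta, baseline_prevalence,
                                  seed = 1L) {
  set.seed(seed)
  alpha <- stats::qlogis(baseline_prevalence)
  stats::rbinom(length(z), 1, stats::plogis(alpha + risk_beta * z))
}

#' Simulate mutation catalogs from known signature exposures
#'
#' Per sample, `mutations_per_sample` motifs are drawn from the multinomial
#' mixture `refmat %*% exposure` after normalizing the exposure row to 1.
#'
#' @param true_exposures samples x signatures matrix of mixing weights (rows
#'   are renormalized to sum to 1).
#' @param refmat 96 x signatures reference matrix.
#' @param mutations_per_sample draws per sample.
#' @param seed integer seed.
#' @return 96 x samples catalog matrix.
#' @export
simulate_catalogs <- function(true_exposures, refmat, mutations_per_sample,
                              seed = 1L) {
  validate_signature_matrix(refmat)
  true_exposures <- as.matrix(true_exposures)
  if (ncol(true_exposures) != ncol(refmat))
    stop("exposure columns must match signatures")
  rs <- rowSums(true_exposures)
  if (any(rs <= 0)) stop("each exposure row must have positive total")
  set.seed(seed)
  probs <- refmat %*% t(true_exposures / rs)   # 96 x samples
  n <- ncol(probs)
  out <- matrix(0L, nrow = 96, ncol = n,
                dimnames = list(sbs96_motifs(),
                                rownames(true_exposures) %||%
                                  paste0("S", seq_len(n))))
  for (j in seq_len(n))
    if (mutations_per_sample > 0)
      out[, j] <- stats::rmultinom(1, mutations_per_sample, probs[, j])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a random reference signature matrix
#'
#' Draws sparse, peaky probability columns (Dirichlet-like via normalized
#' gamma draws with a handful of dominant motifs), a stand-in for a published
#' reference matrix in tests and demonstrations. Labelled `SYN1..SYNk` to
#' make the synthetic origin explicit.
#'
#' @param k number of signatures.
#' @param seed integer seed.
#' @param concentration gamma shape for the background mass.
#' @return 96 x k matrix passing [validate_signature_matrix()].
#' @export
simulate_signature_matrix <- function(k, seed = 1L, concentration = 0.1) {
  set.seed(seed)
  m <- matrix(stats::rgamma(96 * k, shape = concentration), nrow = 96)
  # a few dominant motifs per signature keep columns well separated
  for (j in seq_len(k))
    m[sample(96, 5), j] <- m[sample(96, 5), j] + stats::rgamma(5, shape = 3)
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(sbs96_motifs(), paste0("SYN", seq_len(k)))
  m
}

#' Simulate exponential survival with censoring
#'
#' Event times are exponential with rate `baseline_rate * exp(beta * z)`;
#' independent exponential censoring times are calibrated so the expected
#' censored fraction matches `censoring_rate`.
#'
#' @param z standardized covariate.
#' @param hazard_beta true per-SD log hazard.
#' @param censoring_rate target censored fraction in `[0, 1)`.
#' @param baseline_rate baseline hazard.
#' @param seed integer seed.
#' @return data.frame with `time` and `event` (1 = event observed).
#' @export
simulate_survival <- function(z, hazard_beta, censoring_rate,
                              baseline_rate = 0.1, seed = 1L) {
  set.seed(seed)
  n <- length(z)
  rate <- baseline_rate * exp(hazard_beta * z)
  t_event <- stats::rexp(n, rate)
  if (censoring_rate <= 0) {
    return(data.frame(time = t_event, event = 1L))
  }
  # P(censored | rate_i) = lc / (lc + rate_i); calibrate lc to the target mean
  f <- function(lc) mean(lc / (lc + rate)) - censoring_rate
  lc <- stats::uniroot(f, lower = 1e-12, upper = 1e12, tol = 1e-10)$root
  t_cens <- stats::rexp(n, lc)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}
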
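# Brute-force ROH scanner: explicit loops over every window, every SNP's
# covering windows, and every run; kept independent of the package's
# cumulative-sum implementation.
oracle_roh <- function(g, pos, chrom, params) {
  res <- list()
  for (cc in unique(chrom)) {
    sel <- which(chrom == cc)
    segs <- oracle_roh_chrom(g[sel], pos[sel], params)
    if (nrow(segs)) {
      segs$chrom <- cc
      res[[length(res) + 1]] <- segs
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), n_snps = integer(),
                      length_kb = numeric()))
  out <- do.call(rbind, res)
  out[, c("chrom", "start_pos", "end_pos", "n_snps", "length_kb")]
}

oracle_roh_chrom <- function(g, pos, p) {
  empty <- data.frame(start_pos = integer(), end_pos = integer(),
                      n_snps = integer(), length_kb = numeric())
  m <- length(g)
  w <- p$window_snps
  if (m < w) return(empty)
  nwin <- m - w + 1
  hit <- logical(nwin)
  for (s in seq_len(nwin)) {
    win <- g[s:(s + w - 1)]
    hit[s] <- sum(win == 1, na.rm = TRUE) <= p$window_max_het &&
      sum(is.na(win)) <= p$window_max_missing
  }
  eligible <- logical(m)
  for (i in seq_len(m)) {
    cov <- intersect(seq_len(nwin), (i - w + 1):i)
    eligible[i] <- mean(hit[cov]) >= p$hit_proportion_threshold
  }
  segs <- empty
  i <- 1
  while (i <= m) {
    if (!eligible[i]) { i <- i + 1; next }
    j <- i
    while (j < m && eligible[j + 1] &&
           (pos[j + 1] - pos[j]) <= p$max_gap_kb * 1000) j <- j + 1
    run <- i:j
    while (length(run) && !is.na(g[run[1]]) && g[run[1]] == 1)
      run <- run[-1]
    while (length(run) && !is.na(g[run[length(run)]]) &&
           g[run[length(run)]] == 1)
      run <- run[-length(run)]
    if (length(run)) {
      n <- length(run)
      len <- (pos[run[n]] - pos[run[1]] + 1) / 1000
      if (n >= p$min_snps && len >= p$min_length_kb &&
          len / n <= p$min_density_kb_per_snp)
        segs <- rbind(segs, data.frame(start_pos = pos[run[1]],
                                       end_pos = pos[run[n]],
                                       n_snps = n, length_kb = len))
    }
    i <- j + 1
  }
  segs
}

# standardized two-sample log-rank statistic computed from first principles
oracle_logrank <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E) / sqrt(V)
}

# grid search over the Cox partial likelihood (distinct event times)
oracle_cox_coef <- function(time, event, x, grid = seq(-4, 4, by = 0.001)) {
  nll <- vapply(grid, function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      rs <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[rs])))
    }
    -ll
  }, numeric(1))
  grid[which.min(nll)]
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
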
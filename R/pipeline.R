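#' Pipeline run configuration
#'
#' @param sim a [synthetic_cohort_config()] describing the cohort to
#'   generate (or `NULL` when `cohort` is supplied to the runner directly).
#' @param n_strata number of analysis strata; every association stage runs
#'   separately per stratum and the meta-analysis pools across them.
#' @param min_cases case-count gate for the logistic stage (tests require
#'   strictly more cases than this).
#' @param roh params for the ROH scan, an [roh_params()] object.
#' @param include_sex_chroms keep X/Y variants in HR and ROH.
#' @param fdr_alpha significance threshold on adjusted p for the signature
#'   table.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = synthetic_cohort_config(),
                            n_strata = 3, min_cases = 50,
                            roh = roh_params(),
                            include_sex_chroms = TRUE,
                            fdr_alpha = 0.05) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full autozygosity analysis end to end
#'
#' Generates a synthetic cohort (genotypes with optional inbreeding, injected
#' homozygous tracts and reference-allele flips), computes per-sample
#' heterozygosity ratios and ROH, then runs the downstream stages per
#' stratum: logistic cancer-risk association per SD for both HR and median
#' ROH length, signature refitting plus linear association with BH-FDR, Cox
#' survival with maximally selected dichotomization among cases, and a
#' DerSimonian-Laird random-effects meta-analysis pooling the per-stratum HR
#' risk effects. All tables are written tab-delimited to `out_dir` together
#' with a JSON run manifest; rerunning with the same configuration and seed
#' reproduces them byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param seed overrides the seed in `config$sim`.
#' @return invisibly, a list with `profile`, `risk`, `signature_assoc`,
#'   `survival`, `meta`, `manifest` (and the generated `cohort`).
#' @export
run_autozygosity_pipeline <- function(config = pipeline_config(),
                                      out_dir = NULL, seed = NULL) {
  sim <- config$sim
  if (!is.null(seed)) sim$seed <- seed
  seed0 <- sim$seed

  freqs <- sample_frequencies(sim$n_snps, sim$spectrum, sim$freq_bounds,
                              sim$fixed_freqs, seed = derive_seed(seed0, 1))
  sex <- NULL
  if (sim$n_x_snps > 0) {
    set.seed(derive_seed(seed0, 2))
    sex <- ifelse(stats::runif(sim$n_samples) < sim$female_fraction,
                  "female", "male")
  }
  cohort <- simulate_genotypes(freqs, sim$inbreeding_f, sim$n_samples,
                               seed = derive_seed(seed0, 3),
                               n_x_snps = sim$n_x_snps, sex = sex)
  if (sim$roh_tracts > 0)
    cohort <- inject_roh(cohort, sim$roh_tracts, sim$roh_tract_len_snps,
                         seed = derive_seed(seed0, 4))
  cohort <- flip_reference(cohort, sim$flip_fraction,
                           seed = derive_seed(seed0, 5))

  profile <- autozygosity_profile(cohort, config$roh,
                                  config$include_sex_chroms)
  n <- nrow(profile)
  stratum <- paste0("G", rep_len(seq_len(config$n_strata), n))
  cohort$meta$stratum <- stratum

  # risk stage: per-stratum logistic fits for each predictor
  risk_rows <- list()
  labels_by_stratum <- list()
  for (g in unique(stratum)) {
    in_g <- stratum == g
    z_hr <- tryCatch(standardize(profile$hr_nonref[in_g]),
                     error = function(e) NULL)
    if (is.null(z_hr)) next
    y <- simulate_case_control(z_hr, sim$risk_beta, sim$baseline_prevalence,
                               seed = derive_seed(seed0, 10 + match(g, unique(stratum))))
    labels_by_stratum[[g]] <- list(y = y, idx = which(in_g))
    for (pred in c("hr_nonref", "roh_median_kb")) {
      z <- tryCatch(standardize(profile[[pred]][in_g]),
                    error = function(e) NULL)
      res <- if (is.null(z))
        assoc_result(status = "constant-predictor")
      else
        logistic_assoc(z, y, min_cases = config$min_cases)
      auc <- if (!is.null(z) && res$status == "ok") roc_auc(z, y) else NA_real_
      risk_rows[[length(risk_rows) + 1]] <- data.frame(
        stratum = g, predictor = pred, logor = res$effect,
        stderr = res$stderr, ci_low = res$ci_low, ci_high = res$ci_high,
        p = res$p, auc = auc, cases = res$n_cases, controls = res$n_controls,
        status = res$status, stringsAsFactors = FALSE)
    }
  }
  risk <- do.call(rbind, risk_rows)

  # signature stage: catalogs from known mixtures, refit, linear association
  refmat <- simulate_signature_matrix(sim$n_signatures,
                                      seed = derive_seed(seed0, 20))
  set.seed(derive_seed(seed0, 21))
  true_expo <- matrix(stats::rgamma(n * sim$n_signatures, shape = 1),
                      nrow = n,
                      dimnames = list(profile$sample_id, colnames(refmat)))
  catalogs <- simulate_catalogs(true_expo, refmat, sim$mutations_per_sample,
                                seed = derive_seed(seed0, 22))
  expo <- fit_all_exposures(catalogs, refmat)$exposures
  sig_rows <- list()
  for (g in unique(stratum)) {
    in_g <- stratum == g
    z <- tryCatch(standardize(profile$hr_nonref[in_g]),
                  error = function(e) NULL)
    if (is.null(z)) next
    for (k in rownames(expo)) {
      res <- linear_assoc(expo[k, in_g], z)
      sig_rows[[length(sig_rows) + 1]] <- data.frame(
        stratum = g, signature = k, predictor = "hr_nonref",
        effect = res$effect, stderr = res$stderr, p = res$p,
        n = res$n_cases, stringsAsFactors = FALSE)
    }
  }
  signature_assoc <- do.call(rbind, sig_rows)
  signature_assoc$adjusted_p <- bh_fdr(signature_assoc$p)
  signature_assoc$significant <- signature_assoc$adjusted_p < config$fdr_alpha

  # survival stage among cases, per stratum
  surv_rows <- list()
  for (g in names(labels_by_stratum)) {
    lb <- labels_by_stratum[[g]]
    case_idx <- lb$idx[lb$y == 1]
    if (length(case_idx) < 30) next
    z <- tryCatch(standardize(profile$hr_nonref[case_idx]),
                  error = function(e) NULL)
    if (is.null(z)) next
    surv <- simulate_survival(z, sim$hazard_beta, sim$censoring_rate,
                              seed = derive_seed(seed0, 30 + match(g, names(labels_by_stratum))))
    fit <- tryCatch(survival_fit(surv$time, surv$event, z),
                    error = function(e) NULL)
    if (is.null(fit)) next
    surv_rows[[length(surv_rows) + 1]] <- data.frame(
      stratum = g, hazard_coef = fit$hazard_coef, se = fit$se,
      p_continuous = fit$p_continuous, cutpoint = fit$cutpoint,
      p_dichotomized = fit$p_dichotomized, n = fit$n,
      n_events = fit$n_events, stringsAsFactors = FALSE)
  }
  survival_tab <- if (length(surv_rows)) do.call(rbind, surv_rows) else
    data.frame()

  # meta-analysis across strata on the HR risk effects
  hr_ok <- risk$predictor == "hr_nonref" & risk$status == "ok"
  meta_tab <- data.frame()
  if (sum(hr_ok) >= 2) {
    mr <- meta_random_effects(risk$logor[hr_ok], risk$stderr[hr_ok])
    meta_tab <- data.frame(predictor = "hr_nonref",
                           pooled_effect = mr$pooled_effect,
                           pooled_se = mr$pooled_se, p = mr$p,
                           tau2 = mr$tau2, Q = mr$Q, q_p = mr$q_p, k = mr$k,
                           stringsAsFactors = FALSE)
  }

  manifest <- list(
    package = "autozyg",
    version = as.character(utils::packageVersion("autozyg")),
    seed = seed0,
    n_samples = sim$n_samples, n_snps = sim$n_snps,
    n_strata = config$n_strata,
    flip_fraction = sim$flip_fraction,
    n_samples_undefined_hr = sum(is.na(profile$hr_nonref)))

  res <- list(cohort = cohort, profile = profile, risk = risk,
              signature_assoc = signature_assoc, survival = survival_tab,
              meta = meta_tab, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  prof <- res$profile
  attr(prof, "segments") <- NULL
  tsv(as.data.frame(prof), "profile.tsv")
  tsv(res$risk, "risk.tsv")
  tsv(res$signature_assoc, "signature_assoc.tsv")
  tsv(res$survival, "survival.tsv")
  tsv(res$meta, "meta.tsv")
  segs <- attr(res$profile, "segments")
  if (!is.null(segs)) write_roh_bed(segs, file.path(out_dir, "roh.bed"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
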
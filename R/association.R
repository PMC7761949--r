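assoc_result <- function(effect = NA_real_, stderr = NA_real_, p = NA_real_,
                         n_cases = NA_integer_, n_controls = NA_integer_,
                         status = "ok", labels = list()) {
  z <- stats::qnorm(0.975)
  out <- list(effect = effect, stderr = stderr,
              ci_low = effect - z * stderr, ci_high = effect + z * stderr,
              p = p, n_cases = n_cases, n_controls = n_controls,
              status = status, labels = labels)
  class(out) <- "assoc_result"
  out
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result [%s]", x$status))
  if (length(x$labels))
    cat(" ", paste(unlist(x$labels), collapse = " / "))
  cat("\n")
  if (x$status == "ok")
    cat(sprintf("  effect %.4f (95%% CI %.4f to %.4f), p = %.3g\n",
                x$effect, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Case-control logistic association per standard deviation
#'
#' Maximum-likelihood logistic fit of binary status on a standardized
#' predictor, with intercept; reports the per-SD log odds ratio with Wald
#' 95% CI and two-sided p. Strata whose case count does not exceed
#' `min_cases` are reported as skipped, not errors; (quasi-)complete
#' separation is reported as flagged with no coefficient.
#'
#' @param x standardized predictor (per-SD units); entries with `NA` in `x`
#'   or `y` are dropped listwise.
#' @param y 0/1 (or logical) case indicator.
#' @param min_cases minimum case count gate (strictly greater than; default
#'   100).
#' @param labels optional named list of stratum labels carried into the
#'   result.
#' @return an `assoc_result` with `status` one of `"ok"`, `"skipped"`,
#'   `"separation"`.
#' @export
logistic_assoc <- function(x, y, min_cases = 100, labels = list()) {
  y <- as.integer(y)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("no variation in outcome")
  if (n1 <= min_cases)
    return(assoc_result(n_cases = n1, n_controls = n0,
                        status = "skipped", labels = labels))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (sep_warn || !fit$converged || abs(co["x", "Estimate"]) > 15)
    return(assoc_result(n_cases = n1, n_controls = n0,
                        status = "separation", labels = labels))
  assoc_result(effect = co["x", "Estimate"], stderr = co["x", "Std. Error"],
               p = co["x", "Pr(>|z|)"], n_cases = n1, n_controls = n0,
               labels = labels)
}

#' Ordinary least-squares association
#'
#' Linear regression of a response (e.g. a signature exposure) on an
#' autozygosity measure; slope, standard error and two-sided p.
#'
#' @param response numeric response vector.
#' @param x numeric predictor.
#' @param labels optional named list of labels carried into the result.
#' @return an `assoc_result`.
#' @export
linear_assoc <- function(response, x, labels = list()) {
  ok <- is.finite(response) & is.finite(x)
  response <- response[ok]; x <- x[ok]
  if (length(x) <= 2) stop("need more than 2 complete observations")
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  fit <- stats::lm(response ~ x)
  co <- summary(fit)$coefficients
  assoc_result(effect = co["x", "Estimate"], stderr = co["x", "Std. Error"],
               p = co["x", "Pr(>|t|)"],
               n_cases = length(x), n_controls = NA_integer_, labels = labels)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1, order preserved.
#'
#' @param pvals vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment estimator: with fixed-effect weights `w = 1/se^2` and fixed-effect
#' pooled mean, `Q = sum(w * (theta - theta_FE)^2)` and
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`; random-effects
#' weights `w* = 1/(se^2 + tau2)` give the pooled effect and its SE. The
#' heterogeneity p comes from the chi-square distribution of Q with k-1
#' degrees of freedom.
#'
#' @param effects per-stratum effect estimates.
#' @param ses their standard errors (positive).
#' @return object of class `meta_result`: `pooled_effect`, `pooled_se`, `p`
#'   (Wald), `tau2`, `Q`, `q_p`, `k`.
#' @export
meta_random_effects <- function(effects, ses) {
  k <- length(effects)
  if (k < 2) stop("meta-analysis needs at least 2 strata")
  if (length(ses) != k || any(ses <= 0)) stop("ses must be positive, length k")
  w <- 1 / ses^2
  theta_fe <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - theta_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  pooled <- sum(ws * effects) / sum(ws)
  pooled_se <- sqrt(1 / sum(ws))
  out <- list(pooled_effect = pooled, pooled_se = pooled_se,
              p = 2 * stats::pnorm(-abs(pooled / pooled_se)),
              tau2 = tau2, Q = Q,
              q_p = stats::pchisq(Q, df = k - 1, lower.tail = FALSE), k = k)
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result (DerSimonian-Laird, k = %d)\n", x$k))
  cat(sprintf("  pooled effect %.4f (SE %.4f), p = %.3g\n",
              x$pooled_effect, x$pooled_se, x$p))
  cat(sprintf("  heterogeneity: Q = %.3f, tau2 = %.4f, p = %.3g\n",
              x$Q, x$tau2, x$q_p))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney U probability that a random case outranks a random control,
#' ties counted one half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cox proportional-hazards fit on a continuous covariate
#'
#' Partial-likelihood fit with Breslow tie handling; hazard coefficient is
#' per SD when `x` is standardized.
#'
#' @param time follow-up times.
#' @param event 0/1 event indicator (at least 2 events).
#' @param x covariate (must vary).
#' @return list with `hazard_coef`, `se`, `p_continuous`, `n`, `n_events`.
#' @export
cox_fit <- function(time, event, x) {
  ok <- is.finite(time) & !is.na(event) & is.finite(x)
  time <- time[ok]; event <- as.integer(event[ok]); x <- x[ok]
  if (sum(event) < 2) stop("need at least 2 events")
  if (stats::sd(x) == 0) stop("constant covariate")
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
  co <- summary(fit)$coefficients
  list(hazard_coef = co[1, "coef"], se = co[1, "se(coef)"],
       p_continuous = co[1, "Pr(>|z|)"],
       n = length(time), n_events = sum(event))
}

#' Optimal dichotomization by maximally selected log-rank statistic
#'
#' Evaluates the two-sample log-rank statistic at every candidate cutpoint
#' between the 10th and 90th percentile of the covariate (groups `x <= cut`
#' vs `x > cut`) and returns the cut maximizing the absolute standardized
#' statistic, with the unadjusted log-rank p at that cut. Because the
#' cutpoint is selected to maximize the statistic, this p-value is
#' anti-conservative and should be read as descriptive alongside the
#' continuous-model p.
#'
#' @param time follow-up times.
#' @param event 0/1 event indicator.
#' @param x covariate to dichotomize.
#' @return list with `cutpoint`, `statistic` (|standardized log-rank|),
#'   `p_dichotomized`, and the candidate grid in `candidates`.
#' @export
maxstat_cutpoint <- function(time, event, x) {
  ok <- is.finite(time) & !is.na(event) & is.finite(x)
  time <- time[ok]; event <- as.integer(event[ok]); x <- x[ok]
  q <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  cuts <- sort(unique(x[x >= q[1] & x <= q[2]]))
  cuts <- cuts[cuts < max(x)]   # both sides non-empty
  if (length(cuts) < 2) stop("fewer than 2 candidate cutpoints")
  stat <- vapply(cuts, function(cc)
    logrank_stat(time, event, x <= cc), numeric(1))
  best <- which.max(abs(stat))
  list(cutpoint = cuts[best], statistic = abs(stat[best]),
       p_dichotomized = 2 * stats::pnorm(-abs(stat[best])),
       candidates = cuts)
}

# standardized two-sample log-rank statistic (observed - expected over
# sqrt(hypergeometric variance)), sign taken for group TRUE
logrank_stat <- function(time, event, group) {
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  obs <- sd_fit$obs[2]; expct <- sd_fit$exp[2]
  v <- if (is.matrix(sd_fit$var)) sd_fit$var[2, 2] else sd_fit$var[2]
  (obs - expct) / sqrt(v)
}

#' Survival analysis combining continuous and dichotomized models
#'
#' Runs [cox_fit()] on the continuous covariate and [maxstat_cutpoint()] for
#' the optimal split, mirroring the dual display of a continuous Cox p next
#' to a dichotomized log-rank p.
#'
#' @inheritParams cox_fit
#' @return object of class `survival_fit` with `hazard_coef`, `se`,
#'   `p_continuous`, `cutpoint`, `p_dichotomized`, `n`, `n_events`.
#' @export
survival_fit <- function(time, event, x) {
  cont <- cox_fit(time, event, x)
  cut <- maxstat_cutpoint(time, event, x)
  out <- c(cont, cut[c("cutpoint", "p_dichotomized")])
  class(out) <- "survival_fit"
  out
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("survival_fit: %d subjects, %d events\n", x$n, x$n_events))
  cat(sprintf("  continuous: hazard coef %.4f (SE %.4f), p = %.3g\n",
              x$hazard_coef, x$se, x$p_continuous))
  cat(sprintf("  dichotomized at %.4f: log-rank p = %.3g (descriptive)\n",
              x$cutpoint, x$p_dichotomized))
  invisible(x)
}
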
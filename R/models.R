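#' @importFrom MASS polr
#' @importFrom survival clogit strata coxph
NULL

# ---- FitResult ---------------------------------------------------------

fit_result <- function(analysis_id, n_used, estimates, scale,
                       exclusion_log = NULL, covariate_log = NULL,
                       flags = character(0), model = NULL) {
  structure(list(analysis_id = analysis_id, n_used = n_used,
                 estimates = estimates, scale = scale,
                 exclusion_log = exclusion_log, covariate_log = covariate_log,
                 flags = flags, model = model),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(x$analysis_id, " (n = ", x$n_used, "; scale: ", x$scale, ")\n", sep = "")
  est <- x$estimates
  est$p <- ifelse(est$p < 1e-5, "<1e-5", signif(est$p, 3))
  print(est, row.names = FALSE, digits = 4)
  if (!is.null(x$covariate_log) && nrow(x$covariate_log)) {
    cat("covariate screening:\n")
    print(x$covariate_log, row.names = FALSE, digits = 3)
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Wald-scale estimates table from a fitted glm/lm, optionally with a
# supplied covariance (e.g. cluster-robust) and exponentiation for ORs.
wald_estimates <- function(fit, vcov. = NULL, exponentiate = FALSE,
                           z_dist = TRUE, terms = NULL) {
  co <- stats::coef(fit)
  V <- vcov. %||% stats::vcov(fit)
  se <- sqrt(diag(V))[names(co)]
  stat <- co / se
  if (z_dist) {
    p <- 2 * stats::pnorm(-abs(stat))
  } else {
    p <- 2 * stats::pt(-abs(stat), df = stats::df.residual(fit))
  }
  q <- if (z_dist) stats::qnorm(0.975) else stats::qt(0.975, stats::df.residual(fit))
  lo <- co - q * se
  hi <- co + q * se
  out <- data.frame(term = names(co), estimate = unname(co),
                    conf_low = unname(lo), conf_high = unname(hi),
                    statistic = unname(stat), p = unname(p))
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf_low <- exp(out$conf_low)
    out$conf_high <- exp(out$conf_high)
  }
  if (!is.null(terms)) out <- out[out$term %in% terms | !grepl("Intercept", out$term), ]
  out
}

# ---- Covariate screening ----------------------------------------------

# Association p-value between two variables, choosing the test by type:
# numeric vs numeric -> Pearson correlation; numeric vs categorical ->
# one-way ANOVA; categorical vs categorical -> chi-square (no continuity
# correction, matching the large-sample setting).
assoc_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  num_x <- is.numeric(x); num_y <- is.numeric(y)
  if (num_x && num_y) return(stats::cor.test(x, y)$p.value)
  if (!num_x && !num_y) {
    return(stats::chisq.test(table(x, y), correct = FALSE)$p.value)
  }
  num <- if (num_x) x else y
  grp <- factor(if (num_x) y else x)
  if (nlevels(droplevels(grp)) < 2) return(1)
  stats::anova(stats::lm(num ~ grp))[["Pr(>F)"]][1]
}

#' Covariate-screening rule
#'
#' Makes the registered "include as a covariate if indicated" rule explicit
#' and symmetric: a candidate covariate is included if and only if it is
#' associated with both the exposure and the outcome at p < .05 on the
#' analysis sample. The decision and both p-values are always logged in the
#' fit result, whatever the outcome.
#'
#' @param data Analysis sample.
#' @param candidate,exposure,outcome Column names.
#' @param alpha Screening level (default 0.05).
#' @return List: `include` (logical), `p_exposure`, `p_outcome`.
#' @export
covariate_rule <- function(data, candidate, exposure, outcome, alpha = 0.05) {
  cand <- data[[candidate]]
  if (is.character(cand) || is.logical(cand)) cand <- factor(cand)
  pe <- assoc_p(cand, data[[exposure]])
  po <- assoc_p(cand, data[[outcome]])
  list(include = is.finite(pe) && is.finite(po) && pe < alpha && po < alpha,
       p_exposure = pe, p_outcome = po)
}

covariate_log_df <- function(candidate, rule) {
  data.frame(candidate = candidate, p_exposure = rule$p_exposure,
             p_outcome = rule$p_outcome, included = rule$include)
}

# ---- Descriptive analyses ---------------------------------------------

#' Distribution of weekly-averaged exposure levels (RQ1)
#'
#' Summarises the weekly-averaged noise-exposure level among ear-piece
#' users, for comparison with the 85 dBA Upper Exposure Action Value,
#' together with the weekly exposure duration and the within-exposure
#' average level.
#'
#' @param data Derived analysis table (see [derive_variables()]); nonusers
#'   are dropped automatically.
#' @return List: `n`, `median_weekly_level`, `p90_weekly_level`,
#'   `percentiles` (named vector, 10/25/50/75/90), `frac_above_85`
#'   (strictly exceeding), `median_weekly_hours` (exposure h per week of
#'   use) and `median_exposure_level` (dBA during exposure).
#' @export
rq1_describe <- function(data) {
  users <- data[data$device_use != "nonuser" & !is.na(data$weekly_level), ,
                drop = FALSE]
  if (!nrow(users)) {
    warning("no exposed participants: empty exposure summary", call. = FALSE)
    return(list(n = 0L, median_weekly_level = NA_real_, p90_weekly_level = NA_real_,
                percentiles = NULL, frac_above_85 = NA_real_,
                median_weekly_hours = NA_real_, median_exposure_level = NA_real_))
  }
  wl <- users$weekly_level
  qs <- stats::quantile(wl, c(0.1, 0.25, 0.5, 0.75, 0.9), names = TRUE)
  list(
    n = nrow(users),
    median_weekly_level = stats::median(wl),
    p90_weekly_level = unname(qs["90%"]),
    percentiles = qs,
    frac_above_85 = mean(wl > noise_constants()$ref_level),
    median_weekly_hours = stats::median(users$exposure_hours_total /
                                          users$weeks_of_use),
    median_exposure_level = stats::median(users$avg_level_during_exposure)
  )
}

#' Reported rates of signs of TTS (RQ2)
#'
#' Tabulates the five TTS-frequency response options among ear-piece users
#' with Sison-Glaz simultaneous 95% confidence intervals, plus the summary
#' percentages (any TTS; after at least half of shifts; after every shift).
#'
#' @param data Derived analysis table.
#' @param alpha Familywise error rate for the simultaneous intervals.
#' @return List: `table` (level, n, proportion, CI), `n`, `pct_any`,
#'   `pct_half_or_more`, `pct_every`.
#' @export
rq2_ttsprop <- function(data, alpha = 0.05) {
  users <- data[data$device_use != "nonuser" & !is.na(data$tts_prop), ,
                drop = FALSE]
  counts <- table(factor(users$tts_prop, levels = tts_levels()))
  ci <- sison_glaz_ci(as.numeric(counts), alpha = alpha)
  tab <- data.frame(level = tts_levels(), n = as.numeric(counts),
                    proportion = ci$estimate, lower = ci$lower, upper = ci$upper)
  prop <- ci$estimate
  list(table = tab, n = nrow(users),
       pct_any = 100 * sum(prop[-1]),
       pct_half_or_more = 100 * sum(prop[3:5]),
       pct_every = 100 * prop[5])
}

# ---- Regression analyses ----------------------------------------------

check_sparse_levels <- function(f, min_n = 5) {
  tab <- table(f)
  if (any(tab < min_n))
    warning("sparse outcome levels (< ", min_n, " observations): ",
            paste(names(tab)[tab < min_n], collapse = ", "), call. = FALSE)
}

#' Signs of TTS versus volume-control setting (RQ3)
#'
#' Proportional-odds (ordinal logistic) regression of the TTS-frequency
#' response on the energy-weighted average volume-control setting, among
#' ear-piece users, with age screened as a covariate by [covariate_rule()].
#' The slope is reported on the log-odds-per-percent scale with a Wald
#' statistic; empty response levels are dropped before fitting and sparse
#' levels raise a warning. Suspected separation is flagged and profile
#' likelihood confidence intervals are substituted for the Wald intervals.
#'
#' @param data Derived analysis table.
#' @return A `fit_result`.
#' @export
rq3_ordinal <- function(data) {
  sample <- analysis_sample(data, "RQ3")
  sample <- sample[!is.na(sample$tts_prop) & !is.na(sample$volume_average), ,
                   drop = FALSE]
  if (nrow(sample) < 10) stop_domain("too few observations for the ordinal model")
  if (stats::sd(sample$volume_average) == 0)
    stop_domain("volume average is constant: slope inestimable")
  y <- droplevels(factor(sample$tts_prop, levels = tts_levels(), ordered = TRUE))
  check_sparse_levels(y)
  rule <- covariate_rule(sample, "age", "volume_average", "tts_prop")
  form <- if (rule$include) y ~ volume_average + age else y ~ volume_average
  env <- sample
  env$y <- y
  fit <- MASS::polr(form, data = env, Hess = TRUE,
                    control = list(reltol = 1e-12))
  co <- stats::coef(fit)  # regression terms only, not the cutpoints
  se <- sqrt(diag(stats::vcov(fit)))[names(co)]
  flags <- character(0)
  est <- data.frame(term = names(co), estimate = unname(co),
                    conf_low = unname(co - 1.96 * se),
                    conf_high = unname(co + 1.96 * se),
                    statistic = unname(co / se),
                    p = unname(2 * stats::pnorm(-abs(co / se))))
  if (any(abs(co) > 10) || any(se > 10)) {
    flags <- "possible separation; profile CIs reported"
    pci <- suppressMessages(suppressWarnings(
      stats::confint(fit)))
    if (is.null(dim(pci))) pci <- matrix(pci, nrow = 1,
                                         dimnames = list(names(co), NULL))
    est$conf_low <- pci[est$term, 1]
    est$conf_high <- pci[est$term, 2]
  }
  fit_result("RQ3", n_used = nrow(sample), estimates = est,
             scale = "log-odds per unit predictor (proportional odds)",
             exclusion_log = attr(sample, "exclusion_log"),
             covariate_log = covariate_log_df("age", rule),
             flags = flags, model = fit)
}

# Shared logistic machinery for RQ4/RQ5.
logistic_fit <- function(analysis_id, sample, rhs_terms, exposure_col,
                         covariate_candidates = "age") {
  cov_log <- NULL
  included <- character(0)
  for (cand in covariate_candidates) {
    if (!cand %in% names(sample)) next
    rule <- covariate_rule(sample, cand, exposure_col, "tin_long")
    cov_log <- rbind(cov_log, covariate_log_df(cand, rule))
    if (rule$include) included <- c(included, cand)
  }
  form_unadj <- stats::reformulate(rhs_terms, response = "tin_long")
  form_adj <- stats::reformulate(c(rhs_terms, included), response = "tin_long")
  fit_unadj <- stats::glm(form_unadj, data = sample, family = stats::binomial())
  fit <- if (length(included))
    stats::glm(form_adj, data = sample, family = stats::binomial()) else fit_unadj
  flags <- character(0)
  mu <- stats::fitted(fit)
  if (any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(stats::coef(fit)) > 15))
    flags <- "possible separation (empty exposure x outcome cell)"
  est <- wald_estimates(fit, exponentiate = TRUE)
  est_unadj <- wald_estimates(fit_unadj, exponentiate = TRUE)
  res <- fit_result(analysis_id, n_used = nrow(sample), estimates = est,
                    scale = "odds ratio (Wald 95% CI)",
                    exclusion_log = attr(sample, "exclusion_log"),
                    covariate_log = cov_log, flags = flags, model = fit)
  res$estimates_unadjusted <- est_unadj
  res
}

#' Prolonged spontaneous tinnitus versus ear-piece use (RQ4)
#'
#' Logistic regression of tinnitus presence on ear-piece use (user vs
#' nonuser), on the registered sample (nonunilateral users and
#' contralateral-pathology side choices excluded), with age screened as a
#' covariate. Both adjusted and unadjusted estimates are retained
#' (`$estimates` and `$estimates_unadjusted`).
#'
#' @param data Derived analysis table.
#' @return A `fit_result` on the odds-ratio scale.
#' @export
rq4_logistic <- function(data) {
  sample <- analysis_sample(data, "RQ4")
  sample <- sample[!is.na(sample$tin_long) & !is.na(sample$age), , drop = FALSE]
  sample$device_user <- factor(ifelse(sample$device_use == "nonuser",
                                      "nonuser", "user"),
                               levels = c("nonuser", "user"))
  logistic_fit("RQ4", sample, rhs_terms = "device_user",
               exposure_col = "device_user")
}

#' Prolonged spontaneous tinnitus versus signs of TTS (RQ5)
#'
#' Logistic regression of tinnitus presence on the three-level TTS-instance
#' group (none / 1-100 / >100, entered as two dummies against "none"),
#' among ear-piece users, with age screened as a covariate.
#'
#' @param data Derived analysis table.
#' @return A `fit_result` on the odds-ratio scale.
#' @export
rq5_logistic <- function(data) {
  sample <- analysis_sample(data, "RQ5")
  sample <- sample[!is.na(sample$tin_long) & !is.na(sample$tts_group) &
                     !is.na(sample$age), , drop = FALSE]
  logistic_fit("RQ5", sample, rhs_terms = "tts_group",
               exposure_col = "tts_group")
}

#' Tinnitus location versus ear-piece location (RQ6)
#'
#' Ear-wise paired analysis among unilateral users with asymmetric
#' tinnitus: each participant contributes an exposed and a control ear, and
#' tinnitus presence is regressed on exposure status controlling for ear
#' (right/left). The primary fit is a fixed-effects logistic regression on
#' the ear-wise rows with participant-clustered robust (sandwich) standard
#' errors — within a pair exactly one ear carries the tinnitus, so
#' model-based standard errors would ignore the pairing. A
#' conditional-logistic variant (`method = "clogit"`) stratifies on
#' participant instead.
#'
#' @param data Derived analysis table.
#' @param method `"glm"` (default) or `"clogit"`.
#' @return A `fit_result` on the odds-ratio scale.
#' @export
rq6_earwise <- function(data, method = c("glm", "clogit")) {
  method <- match.arg(method)
  sample <- analysis_sample(data, "RQ6")
  ears <- earwise_reshape(sample)
  if (!nrow(ears)) stop_domain("no eligible participants for the ear-wise analysis")
  ears$ear <- factor(ears$ear, levels = c("left", "right"))
  flags <- character(0)
  tin_by_ear <- table(ears$ear[ears$tin_present])
  if (any(tin_by_ear == sum(tin_by_ear)))
    flags <- "all tinnitus on one fixed ear: separation"
  if (method == "glm") {
    fit <- stats::glm(tin_present ~ exposed + ear, data = ears,
                      family = stats::binomial())
    # participant-clustered robust covariance with the HC1 small-sample
    # correction; reference distribution t with (clusters - 1) df, the
    # standard finite-cluster treatment for robust Wald inference
    G <- length(unique(ears$participant_id))
    V <- sandwich::vcovCL(fit, cluster = ears$participant_id, type = "HC1")
    co <- stats::coef(fit)
    se <- sqrt(diag(V))[names(co)]
    stat <- co / se
    q <- stats::qt(0.975, df = G - 1)
    est <- data.frame(term = names(co), estimate = exp(co),
                      conf_low = exp(co - q * se),
                      conf_high = exp(co + q * se),
                      statistic = unname(stat),
                      p = 2 * stats::pt(-abs(stat), df = G - 1))
    scale <- "odds ratio (cluster-robust Wald 95% CI, t on clusters - 1 df)"
  } else {
    fit <- clogit(tin_present ~ exposed + ear + strata(participant_id),
                  data = ears)
    est <- wald_estimates(fit, exponentiate = TRUE)
    scale <- "odds ratio (conditional logistic, Wald 95% CI)"
  }
  fit_result("RQ6", n_used = length(unique(ears$participant_id)),
             estimates = est, scale = scale,
             exclusion_log = attr(sample, "exclusion_log"),
             flags = flags, model = fit)
}

#' Exposed-ear speech-perception deficit versus ear-piece use (RQ7)
#'
#' Linear regression of the between-ear digits-in-noise difference
#' (exposed-ear threshold minus control-ear threshold, imputed sides for
#' nonusers) on ear-piece use and exposed side. Participants failing the
#' 3-SD threshold quality-control rule are removed first (bounds computed
#' over the full table). When an `ear_tested_first` column is present, a
#' test-order covariate is screened by [covariate_rule()]. The mean
#' difference among users, with its 95% CI, is attached as
#' `$users_mean_diff`.
#'
#' @param data Derived analysis table.
#' @return A `fit_result` on the dB SNR scale.
#' @export
rq7_linear <- function(data) {
  qc <- din_outlier_filter(data)
  sample <- analysis_sample(qc$kept, "RQ7")
  sample <- sample[!is.na(sample$digits_diff), , drop = FALSE]
  if (anyNA(sample$device_side_full))
    stop_domain("device_side_full missing: side imputation for nonusers required")
  sample$device_user <- factor(ifelse(sample$device_use == "nonuser",
                                      "nonuser", "user"),
                               levels = c("nonuser", "user"))
  sample$device_side_full <- factor(sample$device_side_full,
                                    levels = c("left", "right"))
  cov_log <- NULL
  rhs <- c("device_user", "device_side_full")
  if ("ear_tested_first" %in% names(sample) && !anyNA(sample$ear_tested_first)) {
    rule <- covariate_rule(sample, "ear_tested_first", "device_user", "digits_diff")
    cov_log <- covariate_log_df("ear_tested_first", rule)
    if (rule$include) rhs <- c(rhs, "ear_tested_first")
  }
  fit <- stats::lm(stats::reformulate(rhs, response = "digits_diff"),
                   data = sample)
  est <- wald_estimates(fit, z_dist = FALSE)
  users <- sample$digits_diff[sample$device_user == "user"]
  tt <- stats::t.test(users)
  res <- fit_result("RQ7", n_used = nrow(sample), estimates = est,
                    scale = "dB SNR (t-based 95% CI)",
                    exclusion_log = attr(sample, "exclusion_log"),
                    covariate_log = cov_log, model = fit)
  res$users_mean_diff <- c(mean = unname(tt$estimate),
                           conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
  res$n_qc_excluded <- nrow(qc$excluded)
  res
}

#' Run the registered analyses on raw survey tables
#'
#' Derives the analysis variables and runs the requested analyses.
#'
#' @param participants Participants table.
#' @param segments Career-segments table.
#' @param curve A [calibration_curve()].
#' @param analyses Character vector from `RQ1`..`RQ7`, or `"all"`.
#' @param seed Integer seed (controls the nonuser side imputation).
#' @return Named list of analysis results.
#' @export
run_analyses <- function(participants, segments, curve = default_calibration(),
                         analyses = "all", seed = 1L) {
  all_ids <- paste0("RQ", 1:7)
  if (identical(analyses, "all")) analyses <- all_ids
  bad <- setdiff(analyses, all_ids)
  if (length(bad)) stop_domain("unknown analysis label: ", paste(bad, collapse = ", "))
  dat <- derive_variables(participants, segments, curve, seed = seed)
  runners <- list(
    RQ1 = function(d) rq1_describe(d),
    RQ2 = function(d) rq2_ttsprop(d),
    RQ3 = function(d) rq3_ordinal(d),
    RQ4 = function(d) rq4_logistic(d),
    RQ5 = function(d) rq5_logistic(d),
    RQ6 = function(d) rq6_earwise(d),
    RQ7 = function(d) rq7_linear(d)
  )
  out <- lapply(analyses, function(a) runners[[a]](dat))
  names(out) <- analyses
  attr(out, "derived") <- dat
  out
}
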
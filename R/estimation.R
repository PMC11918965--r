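## ITT-analog estimation on the person-trial table: descriptive prevalences
## and crude odds ratios, era-stratified pooled logistic regression with
## cluster-robust (sandwich) variance over participants, subgroup analyses,
## a Wald test of effect heterogeneity across eras, and random-intercept
## linear mixed models for the continuous scores.

#' Model specification for the pooled logistic / mixed-model fits
#'
#' @param outcome One of `"anxiety_mod_severe"`, `"depression_mod_severe"`
#'   (binary, logistic) or `"gad7_total"`, `"phq8_total"` (continuous, mixed
#'   model).
#' @param adjustment_set Character vector of covariate columns. The default
#'   mirrors the minimally sufficient adjustment set used in the motivating
#'   analysis: baseline healthcare access, baseline age, outcome-matched
#'   severity at time 0, baseline education, employment at time 0, gender,
#'   housing and food insecurity at time 0, and baseline susceptibility. The
#'   severity-at-time-0 covariate is chosen to match the outcome
#'   (`anx_t0` for anxiety/GAD-7, `dep_t0` for depression/PHQ-8).
#' @param era `"preuniversal"`, `"universal"` or `"both"` (no
#'   stratification).
#' @param cluster Cluster identifier column for the robust variance (default
#'   `participant_id`).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(outcome = c("anxiety_mod_severe",
                                   "depression_mod_severe",
                                   "gad7_total", "phq8_total"),
                       adjustment_set = NULL,
                       era = c("both", "preuniversal", "universal"),
                       cluster = "participant_id") {
  outcome <- match.arg(outcome)
  era <- match.arg(era)
  anx <- outcome %in% c("anxiety_mod_severe", "gad7_total")
  if (is.null(adjustment_set)) {
    adjustment_set <- c("healthcare_access", "age_band",
                        if (anx) "anx_t0" else "dep_t0",
                        "education", "employment_t0", "gender",
                        "housing_instability_t0", "food_insecurity_t0",
                        "susceptibility")
  }
  structure(list(outcome = outcome,
                 outcome_col = switch(outcome,
                   anxiety_mod_severe = "outcome_anx_severe",
                   depression_mod_severe = "outcome_dep_severe",
                   gad7_total = "outcome_gad7",
                   phq8_total = "outcome_phq8"),
                 binary = outcome %in% c("anxiety_mod_severe",
                                         "depression_mod_severe"),
                 severity_t0_col = if (anx) "anx_t0" else "dep_t0",
                 adjustment_set = adjustment_set, era = era,
                 cluster = cluster),
            class = "model_spec")
}

#' Prevalence with a Wald binomial confidence interval
#'
#' @param count Number with the outcome (0 <= count <= denom).
#' @param denom Person-trial denominator (> 0).
#' @param conf Confidence level (default 0.95).
#' @return A list: `pct` (percentage), `ci` (percentage-scale Wald interval),
#'   `count`, `denom`.
#' @export
#' @examples
#' prevalence(1171, 4846)  # 24.2 (23.0, 25.4)
prevalence <- function(count, denom, conf = 0.95) {
  if (denom <= 0) {
    stop_ttevax("E_PREVALENCE", "denominator must be positive")
  }
  if (count < 0 || count > denom) {
    stop_ttevax("E_PREVALENCE", "count must lie in 0..denom")
  }
  p <- count / denom
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p * (1 - p) / denom)
  list(pct = 100 * p, ci = 100 * c(max(0, p - half), min(1, p + half)),
       count = count, denom = denom)
}

#' Crude odds ratio from a 2x2 table
#'
#' Closed-form `OR = (a d) / (b c)` with a Woolf (log-scale) confidence
#' interval. All four cells must be positive; no continuity correction is
#' applied.
#'
#' @param a Treated with outcome; `b` treated without; `c` untreated with;
#'   `d` untreated without.
#' @param b,c,d See `a`.
#' @param conf Confidence level.
#' @return A list: `or`, `log_or`, `se_log_or`, `ci` (OR scale).
#' @export
#' @examples
#' crude_or(20, 10, 10, 20)  # OR 4
crude_or <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) {
    stop_ttevax("E_TABLE", "2x2 cells must be nonnegative")
  }
  if (any(cells == 0)) {
    stop_ttevax("E_ZERO_CELL",
                "zero cell (%s) in the 2x2 table; odds ratio undefined without a continuity correction",
                paste(names(cells)[cells == 0], collapse = ", "))
  }
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf) / 2)
  list(or = exp(log_or), log_or = log_or, se_log_or = se,
       ci = exp(log_or + c(-1, 1) * z * se))
}

#' Cluster-robust (sandwich) covariance of a fitted model
#'
#' CR0 sandwich `A^-1 B A^-1` with the meat `B` summed over per-cluster
#' score totals; with every cluster of size one this reduces to the HC0
#' heteroskedasticity-robust estimator. `"CR1"` applies the G/(G-1)
#' cluster-count correction.
#'
#' @param fit A fitted `glm`/`lm`.
#' @param cluster_ids Cluster membership vector, one entry per observation
#'   used in the fit.
#' @param type `"CR0"` (default) or `"CR1"`.
#' @return Covariance matrix of the coefficients.
#' @export
robust_cluster_variance <- function(fit, cluster_ids, type = c("CR0", "CR1")) {
  type <- match.arg(type)
  g <- length(unique(cluster_ids))
  k <- length(coef(fit))
  if (g < k) {
    warning(sprintf("only %d clusters for %d parameters; robust variance may be unstable",
                    g, k), call. = FALSE)
  }
  sandwich::vcovCL(fit, cluster = cluster_ids, type = "HC0",
                   cadjust = (type == "CR1"))
}

## flag (quasi-)separation: fitted probabilities numerically at 0/1 with a
## diverging coefficient. Divergence of the treatment coefficient is fatal
## (the estimand itself is unidentified); a diverging nuisance level (e.g. a
## rare factor cell with no events) degrades only that coefficient and is
## reported as a warning.
check_separation <- function(fit) {
  p <- fitted(fit)
  if (!any(p < 1e-10 | p > 1 - 1e-10)) {
    return(invisible(TRUE))
  }
  cf <- coef(fit)
  diverged <- names(cf)[!is.na(cf) & abs(cf) > 15]
  if ("treatment" %in% diverged) {
    stop_ttevax("E_SEPARATION",
                "quasi-separation detected in logistic fit (fitted probabilities at 0/1); check covariate pattern in: %s",
                paste(diverged, collapse = ", "))
  }
  if (length(diverged)) {
    warning(sprintf("quasi-separation in nuisance coefficient(s) %s; their estimates are unreliable",
                    paste(diverged, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Era-stratified pooled logistic regression
#'
#' Fits, by maximum likelihood (IRLS), the logistic regression of a binary
#' moderate-to-severe outcome on treatment plus the adjustment set over the
#' stack of person-trials of one era (or all), and reports the treatment
#' log-OR with both model-based and cluster-robust (participant-level)
#' standard errors. The confidence interval uses the robust SE.
#'
#' @param data One completed person-trial table (no missing outcome).
#' @param spec A [model_spec()] with a binary outcome.
#' @param cr_type Robust-variance flavour passed to
#'   [robust_cluster_variance()].
#' @return A list of class `effect_estimate`: `scale`, `point` (log-OR),
#'   `se_model`, `se_robust`, `ci95` (log-OR scale, robust), `or`, `or_ci95`,
#'   `n_person_trials`, `n_participants`, `era`, and the fitted `glm` as
#'   `fit`.
#' @export
fit_pooled_logistic <- function(data, spec, cr_type = "CR0") {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$binary) {
    stop_ttevax("E_MODEL", "fit_pooled_logistic requires a binary outcome")
  }
  dt <- as.data.table(data)
  if (spec$era != "both") {
    dt <- dt[era == spec$era]
  }
  if (!nrow(dt)) {
    stop_ttevax("E_EMPTY", "no person-trials in stratum '%s'", spec$era)
  }
  y <- dt[[spec$outcome_col]]
  if (anyNA(y)) {
    stop_ttevax("E_MISSING_OUTCOME",
                "outcome '%s' has missing values; impute first or drop incomplete person-trials",
                spec$outcome_col)
  }
  rhs <- paste(c("treatment", spec$adjustment_set), collapse = " + ")
  fml <- as.formula(paste(spec$outcome_col, "~", rhs))
  ## deviance tolerance well below 1e-8 so the coefficients themselves are
  ## accurate to ~1e-10 (the 2x2 closed-form equivalence relies on this)
  fit <- glm(fml, family = binomial(), data = dt,
             control = list(epsilon = 1e-12, maxit = 100L))
  if (!fit$converged) {
    stop_ttevax("E_NONCONVERGENCE", "logistic fit did not converge in 100 IRLS iterations")
  }
  check_separation(fit)
  vc_r <- robust_cluster_variance(fit, dt[[spec$cluster]], type = cr_type)
  point <- coef(fit)[["treatment"]]
  se_m <- sqrt(vcov(fit)["treatment", "treatment"])
  se_r <- sqrt(vc_r["treatment", "treatment"])
  ci <- point + c(-1, 1) * qnorm(0.975) * se_r
  structure(list(scale = "log_odds", point = point, se_model = se_m,
                 se_robust = se_r, ci95 = ci, or = exp(point),
                 or_ci95 = exp(ci), n_person_trials = nrow(dt),
                 n_participants = length(unique(dt[[spec$cluster]])),
                 era = spec$era, outcome = spec$outcome, fit = fit),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (x$scale == "log_odds") {
    cat(sprintf("%s [%s]: OR %.3f (95%% CI %.3f-%.3f), log-OR %.4f (robust SE %.4f), %d person-trials / %d participants\n",
                x$outcome, x$era, x$or, x$or_ci95[1], x$or_ci95[2], x$point,
                x$se_robust, x$n_person_trials, x$n_participants))
  } else {
    cat(sprintf("%s [%s]: coefficient %.3f points (95%% CI %.3f to %.3f, SE %.4f), %d person-trials / %d participants\n",
                x$outcome, x$era, x$point, x$ci95[1], x$ci95[2], x$se_robust,
                x$n_person_trials, x$n_participants))
  }
  invisible(x)
}

#' Subgroup analysis among those symptomatic at time zero
#'
#' Restricts the person-trials to those with moderate-to-severe symptoms
#' (of the outcome-matched instrument) as of the most recent measure at time
#' zero, drops the severity-at-time-0 covariate from the adjustment set
#' (it is constant in the subgroup), and refits.
#'
#' @param data Completed person-trial table.
#' @param spec A [model_spec()].
#' @param cr_type Robust-variance flavour.
#' @return An `effect_estimate` (logistic for binary outcomes, mixed model
#'   via [fit_random_intercept_lmm()] for continuous outcomes).
#' @export
subgroup_analysis <- function(data, spec, cr_type = "CR0") {
  stopifnot(inherits(spec, "model_spec"))
  dt <- as.data.table(data)
  cond <- spec$severity_t0_col
  if (!cond %in% names(dt)) {
    stop_ttevax("E_COLUMNS", "subgroup condition column '%s' absent", cond)
  }
  sub <- dt[dt[[cond]] %in% 1L]
  if (!nrow(sub)) {
    stop_ttevax("E_EMPTY", "subgroup '%s == 1' is empty", cond)
  }
  sub_spec <- spec
  sub_spec$adjustment_set <- setdiff(spec$adjustment_set, cond)
  if (spec$binary) {
    fit_pooled_logistic(sub, sub_spec, cr_type = cr_type)
  } else {
    fit_random_intercept_lmm(sub, sub_spec)
  }
}

#' Wald test of effect heterogeneity across vaccine eras
#'
#' `W = (b_pre - b_uni)^2 / (var_pre + var_uni)` compared to chi-square with
#' one degree of freedom, using the robust variances of two independent
#' stratum estimates on the log-odds (or coefficient) scale.
#'
#' @param est_pre,est_uni `effect_estimate` or `pooled_estimate` objects (or
#'   lists with `point` and a variance/SE).
#' @return A list: `statistic`, `p_value`, `difference`.
#' @export
#' @examples
#' wald_heterogeneity(list(point = 0, se_robust = 0.5),
#'                    list(point = 1, se_robust = 0.5))
wald_heterogeneity <- function(est_pre, est_uni) {
  get_pv <- function(e) {
    v <- if (!is.null(e$se_robust)) e$se_robust^2
         else if (!is.null(e$total_var)) e$total_var
         else if (!is.null(e$se)) e$se^2
         else stop_ttevax("E_WALD", "estimate carries no variance")
    c(e$point, v)
  }
  a <- get_pv(est_pre)
  b <- get_pv(est_uni)
  if (a[2] <= 0 || b[2] <= 0) {
    stop_ttevax("E_WALD", "variances must be positive")
  }
  W <- (a[1] - b[1])^2 / (a[2] + b[2])
  list(statistic = W, p_value = pchisq(W, df = 1, lower.tail = FALSE),
       difference = a[1] - b[1])
}

#' Random-intercept linear mixed model for continuous scores
#'
#' REML fit of the continuous GAD-7/PHQ-8 outcome on treatment plus the
#' adjustment set with a participant random intercept (repeated person-trial
#' measures); the treatment coefficient is the adjusted mean score
#' difference in points.
#'
#' @param data Completed person-trial table (typically a subgroup).
#' @param spec A [model_spec()] with a continuous outcome.
#' @param REML Use REML (default) or ML.
#' @return An `effect_estimate` with `scale = "score_points"`; `se_model`
#'   and `se_robust` both carry the model-based SE of the mixed model.
#' @export
fit_random_intercept_lmm <- function(data, spec, REML = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$binary) {
    stop_ttevax("E_MODEL", "fit_random_intercept_lmm requires a continuous outcome")
  }
  dt <- as.data.table(data)
  if (spec$era != "both") {
    dt <- dt[era == spec$era]
  }
  if (!nrow(dt)) {
    stop_ttevax("E_EMPTY", "no person-trials in stratum '%s'", spec$era)
  }
  if (anyNA(dt[[spec$outcome_col]])) {
    stop_ttevax("E_MISSING_OUTCOME", "outcome '%s' has missing values",
                spec$outcome_col)
  }
  rhs <- paste(c("treatment", spec$adjustment_set), collapse = " + ")
  fml <- as.formula(paste(spec$outcome_col, "~", rhs,
                          "+ (1 |", spec$cluster, ")"))
  fit <- tryCatch(
    lme4::lmer(fml, data = dt, REML = REML,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.nRE = "ignore")),
    error = function(e) {
      vc <- tryCatch(paste(utils::capture.output(lme4::VarCorr(e)),
                           collapse = " "), error = function(...) "")
      stop_ttevax("E_NONCONVERGENCE", "mixed model failed: %s %s",
                  conditionMessage(e), vc)
    })
  point <- lme4::fixef(fit)[["treatment"]]
  se <- sqrt(as.matrix(vcov(fit))["treatment", "treatment"])
  ci <- point + c(-1, 1) * qnorm(0.975) * se
  structure(list(scale = "score_points", point = point, se_model = se,
                 se_robust = se, ci95 = ci, or = NA_real_,
                 or_ci95 = c(NA_real_, NA_real_), n_person_trials = nrow(dt),
                 n_participants = length(unique(dt[[spec$cluster]])),
                 era = spec$era, outcome = spec$outcome, fit = fit),
            class = "effect_estimate")
}
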
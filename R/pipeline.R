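## End-to-end orchestration: build person-trials -> multiply impute missing
## outcomes -> era-stratified fits (overall + symptomatic-at-time-zero
## subgroups, binary + continuous) -> Rubin pooling -> Wald heterogeneity.

pool_fits <- function(fit_fun, completed, spec, ...) {
  ests <- lapply(completed, fit_fun, spec = spec, ...)
  pooled <- rubin_pool(vapply(ests, `[[`, numeric(1), "point"),
                       vapply(ests, `[[`, numeric(1), "se_robust")^2)
  first <- ests[[1]]
  list(pooled = pooled, template = first)
}

estimate_row <- function(outcome_label, era, analysis, scale, pooled, tmpl) {
  data.table(
    outcome = outcome_label, era = era, analysis = analysis, scale = scale,
    point = pooled$point, se = pooled$se,
    ci_lo = pooled$ci95[1], ci_hi = pooled$ci95[2],
    or = if (scale == "log_odds") exp(pooled$point) else NA_real_,
    or_lo = if (scale == "log_odds") exp(pooled$ci95[1]) else NA_real_,
    or_hi = if (scale == "log_odds") exp(pooled$ci95[2]) else NA_real_,
    n_person_trials = tmpl$n_person_trials,
    n_participants = tmpl$n_participants
  )
}

#' Run the complete target-trial-emulation analysis
#'
#' Orchestrates the pipeline on a long-format assessment table: person-trial
#' construction, multiple imputation of missing outcome scores (bypassed
#' when nothing is missing, so the complete-data analysis is returned
#' unchanged), era-stratified adjusted pooled logistic fits with
#' cluster-robust variance, subgroup fits among those symptomatic at time
#' zero (binary and random-intercept linear mixed model), Rubin pooling, and
#' Wald heterogeneity tests across eras. Deterministic given the imputation
#' seed.
#'
#' @param assessments Long-format assessment records.
#' @param trial_cfg A [trial_config()].
#' @param imp_spec An [imputation_spec()] (its `seed` drives all
#'   randomness).
#' @param outcomes Which outcomes to analyse: `"anxiety"`, `"depression"`.
#' @param eras Era strata to fit (default both).
#' @param adjustment_set Optional covariate vector overriding the default of
#'   [model_spec()] (the outcome-matched severity-at-time-0 column is
#'   substituted automatically).
#' @param subgroups Also run the symptomatic-at-time-zero subgroup analyses
#'   (default `TRUE`).
#' @param cr_type Robust-variance flavour (`"CR0"`/`"CR1"`).
#' @return A list of class `ttevax_report`: `flow` (flow summary), `m_used`
#'   (imputations analysed), `descriptives` (per outcome x era x arm counts,
#'   prevalences, crude ORs), `estimates` (pooled adjusted estimates), and
#'   `heterogeneity` (per outcome x analysis Wald tests).
#' @export
run_full_analysis <- function(assessments,
                              trial_cfg = trial_config(),
                              imp_spec = imputation_spec(),
                              outcomes = c("anxiety", "depression"),
                              eras = c("preuniversal", "universal"),
                              adjustment_set = NULL,
                              subgroups = TRUE,
                              cr_type = "CR0") {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  pt <- build_person_trials(assessments, trial_cfg)
  flow <- flow_accounting(assessments, pt)

  need_imp <- c(if ("anxiety" %in% outcomes) "outcome_gad7",
                if ("depression" %in% outcomes) "outcome_phq8")
  any_missing <- any(vapply(need_imp, function(cl) anyNA(pt[[cl]]), logical(1)))
  completed <- if (any_missing) {
    impute(pt, imp_spec,
           outcomes = c(if ("anxiety" %in% outcomes) "gad7",
                        if ("depression" %in% outcomes) "phq8"))
  } else {
    ## MI identity: no missing cells, analyse the single complete dataset
    structure(list(copy(pt)), class = "completed_datasets")
  }

  spec_for <- function(outcome_label, era, binary) {
    base <- model_spec(
      outcome = switch(paste(outcome_label, binary),
                       "anxiety TRUE" = "anxiety_mod_severe",
                       "anxiety FALSE" = "gad7_total",
                       "depression TRUE" = "depression_mod_severe",
                       "depression FALSE" = "phq8_total"),
      era = era)
    if (!is.null(adjustment_set)) {
      adj <- adjustment_set
      adj[adj %in% c("anx_t0", "dep_t0")] <- base$severity_t0_col
      base$adjustment_set <- unique(adj)
    }
    base
  }

  est_rows <- list()
  het_rows <- list()
  desc_rows <- list()
  d1 <- completed[[1]]
  for (oc in outcomes) {
    sev_col <- if (oc == "anxiety") "outcome_anx_severe" else "outcome_dep_severe"
    t0_col <- if (oc == "anxiety") "anx_t0" else "dep_t0"
    per_era <- list()
    per_era_sub <- list()
    for (er in eras) {
      ## descriptives from the first completed dataset
      for (arm in c(1L, 0L)) {
        sub <- d1[era == er & treatment == arm]
        nn <- sum(sub[[sev_col]], na.rm = TRUE)
        pv <- prevalence(nn, nrow(sub))
        desc_rows[[length(desc_rows) + 1L]] <- data.table(
          outcome = oc, era = er,
          arm = if (arm == 1L) "vaccinated" else "not_vaccinated",
          denom = nrow(sub), n_severe = nn, prev = pv$pct,
          prev_lo = pv$ci[1], prev_hi = pv$ci[2])
      }
      cells <- d1[era == er, .(
        a = sum(treatment == 1L & get(sev_col) == 1L),
        b = sum(treatment == 1L & get(sev_col) == 0L),
        c = sum(treatment == 0L & get(sev_col) == 1L),
        d = sum(treatment == 0L & get(sev_col) == 0L))]
      cor_ <- tryCatch(crude_or(cells$a, cells$b, cells$c, cells$d),
                       error = function(e) NULL)
      ## adjusted overall fit, pooled over imputations
      sp <- spec_for(oc, er, binary = TRUE)
      ov <- pool_fits(fit_pooled_logistic, completed, sp, cr_type = cr_type)
      per_era[[er]] <- ov$pooled
      est_rows[[length(est_rows) + 1L]] <-
        cbind(estimate_row(oc, er, "overall", "log_odds", ov$pooled,
                           ov$template),
              data.table(crude_or = if (is.null(cor_)) NA_real_ else cor_$or,
                         crude_or_lo = if (is.null(cor_)) NA_real_ else cor_$ci[1],
                         crude_or_hi = if (is.null(cor_)) NA_real_ else cor_$ci[2]))
      if (subgroups) {
        sg <- pool_fits(subgroup_analysis, completed, sp, cr_type = cr_type)
        per_era_sub[[er]] <- sg$pooled
        est_rows[[length(est_rows) + 1L]] <-
          cbind(estimate_row(oc, er, "subgroup", "log_odds", sg$pooled,
                             sg$template),
                data.table(crude_or = NA_real_, crude_or_lo = NA_real_,
                           crude_or_hi = NA_real_))
        sp_cont <- spec_for(oc, er, binary = FALSE)
        lm_ <- pool_fits(subgroup_analysis, completed, sp_cont)
        est_rows[[length(est_rows) + 1L]] <-
          cbind(estimate_row(oc, er, "subgroup_lmm", "score_points",
                             lm_$pooled, lm_$template),
                data.table(crude_or = NA_real_, crude_or_lo = NA_real_,
                           crude_or_hi = NA_real_))
      }
    }
    if (length(eras) == 2) {
      wt <- wald_heterogeneity(per_era[[eras[1]]], per_era[[eras[2]]])
      het_rows[[length(het_rows) + 1L]] <- data.table(
        outcome = oc, analysis = "overall", statistic = wt$statistic,
        p_value = wt$p_value)
      if (subgroups) {
        wt_s <- wald_heterogeneity(per_era_sub[[eras[1]]],
                                   per_era_sub[[eras[2]]])
        het_rows[[length(het_rows) + 1L]] <- data.table(
          outcome = oc, analysis = "subgroup", statistic = wt_s$statistic,
          p_value = wt_s$p_value)
      }
    }
  }

  structure(list(
    flow = flow,
    m_used = length(completed),
    person_trials = pt,
    descriptives = rbindlist(desc_rows, fill = TRUE),
    estimates = rbindlist(est_rows),
    heterogeneity = if (length(het_rows)) rbindlist(het_rows) else NULL
  ), class = "ttevax_report")
}

#' @export
print.ttevax_report <- function(x, ...) {
  print(x$flow)
  cat(sprintf("m = %d imputation(s) analysed\n", x$m_used))
  est <- x$estimates[x$estimates$analysis == "overall"]
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %s [%s]: aOR %.3f (95%% CI %.3f-%.3f)\n",
                est$outcome[i], est$era[i], est$or[i], est$or_lo[i],
                est$or_hi[i]))
  }
  if (!is.null(x$heterogeneity)) {
    h <- x$heterogeneity[x$heterogeneity$analysis == "overall"]
    for (i in seq_len(nrow(h))) {
      cat(sprintf("  era heterogeneity (%s): W = %.2f, p = %.4f\n",
                  h$outcome[i], h$statistic[i], h$p_value[i]))
    }
  }
  invisible(x)
}
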
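## Multiple imputation of missing outcome scores and Rubin's-rules pooling.
##
## Missing GAD-7/PHQ-8 totals in the person-trial table are imputed at the
## continuous-score level from a regression-based posterior-predictive model
## (or predictive-mean matching), rounded and clipped to the instrument
## range, with the severity indicator re-derived afterwards. Per-imputation
## estimates are combined on the log-OR/coefficient scale with Rubin's rules
## and Barnard-Rubin degrees of freedom.

default_imputation_predictors <- function() {
  c("age_band", "race_ethnicity", "gender", "income", "education",
    "employment_t0", "food_insecurity_t0", "housing_instability_t0",
    "children_household", "healthcare_access")
}

#' Specification of the imputation model
#'
#' @param m Number of imputations (default 20, comfortable for ~7%
#'   missingness).
#' @param predictors Covariate columns entering the imputation model. The
#'   default is the sociodemographic/auxiliary set (age, race/ethnicity,
#'   gender, income, education, employment, food insecurity, housing
#'   instability, children in household, healthcare access); the matching
#'   enrollment severity (`enroll_anx` for GAD-7, `enroll_dep` for PHQ-8) is
#'   added automatically per outcome.
#' @param include_treatment Also include treatment, era and their interaction
#'   in the imputation model (default `TRUE`). Keeping the exposure in the
#'   imputation model makes it congenial with the era-stratified analysis
#'   model; set to `FALSE` for a purely auxiliary-variable model.
#' @param method `"pmm"` (type-1 predictive-mean matching, default) or
#'   `"norm"` (Bayesian linear regression posterior-predictive draws).
#'   PMM is the default because GAD-7/PHQ-8 totals are bounded and strongly
#'   bimodal around the severity threshold: fully parametric normal draws
#'   overstate threshold crossings, while matching reuses observed scores
#'   and preserves the empirical score distribution.
#' @param seed Integer base seed; imputation i uses `seed + i`.
#' @return A list of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 20L,
                            predictors = default_imputation_predictors(),
                            include_treatment = TRUE,
                            method = c("pmm", "norm"),
                            seed = 1L) {
  method <- match.arg(method)
  if (m < 1) {
    stop_ttevax("E_CONFIG", "number of imputations m must be >= 1")
  }
  structure(list(m = as.integer(m), predictors = predictors,
                 include_treatment = isTRUE(include_treatment),
                 method = method, seed = as.integer(seed)),
            class = "imputation_spec")
}

outcome_meta <- function(outcome = c("gad7", "phq8")) {
  outcome <- match.arg(outcome)
  switch(outcome,
    gad7 = list(total = "outcome_gad7", severe = "outcome_anx_severe",
                enroll = "enroll_anx", max_total = 21L),
    phq8 = list(total = "outcome_phq8", severe = "outcome_dep_severe",
                enroll = "enroll_dep", max_total = 24L)
  )
}

## one posterior-predictive draw of the missing cells of `y`
## (Bayesian linear regression with the standard noninformative prior)
draw_imputation <- function(y, X, miss, method) {
  obs <- which(!miss)
  Xo <- X[obs, , drop = FALSE]
  ## drop aliased columns to keep the cross-product invertible
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[miss, keep, drop = FALSE]
  k <- ncol(Xo)
  n <- nrow(Xo)
  if (n <= k + 1) {
    stop_ttevax("E_IMPUTE", "too few observed outcomes (%d) to fit %d parameters",
                n, k)
  }
  fit <- .lm.fit(Xo, y[obs])
  beta_hat <- fit$coefficients
  resid <- fit$residuals
  df <- n - k
  s2 <- sum(resid^2) / df
  sigma2_star <- s2 * df / rchisq(1, df)
  XtX_inv <- chol2inv(chol(crossprod(Xo)))
  beta_star <- beta_hat +
    drop(t(chol(XtX_inv)) %*% rnorm(k)) * sqrt(sigma2_star)
  mu_mis <- drop(Xm %*% beta_star)
  if (method == "norm") {
    mu_mis + rnorm(length(mu_mis)) * sqrt(sigma2_star)
  } else {
    ## type-1 PMM: match draws against observed predictions and sample a
    ## donor among all observations within the 5th-smallest distance —
    ## with discrete predictors distances tie massively, and restricting to
    ## an arbitrary 5 of the tied donors would collapse the donor pool
    pred_obs <- drop(Xo %*% beta_hat)
    y_obs <- y[obs]
    kd <- min(5L, length(pred_obs))
    vapply(mu_mis, function(p) {
      d <- abs(pred_obs - p)
      thr <- sort(d, partial = kd)[kd]
      pool <- which(d <= thr)
      y_obs[pool[sample.int(length(pool), 1L)]]
    }, numeric(1))
  }
}

#' Multiply impute missing outcome scores
#'
#' Produces `m` completed copies of the person-trial table. Each originally
#' missing outcome total is drawn from the posterior-predictive distribution
#' of a linear regression on the specified predictors (plus the matching
#' enrollment severity and, by default, treatment x era), rounded and clipped
#' to the instrument range; severity indicators are re-derived from the
#' completed totals. Observed cells are identical across imputations.
#'
#' @param person_trials Person-trial table (from [build_person_trials()]).
#' @param spec An [imputation_spec()].
#' @param outcomes Which outcomes to impute: any of `"gad7"`, `"phq8"`.
#' @return A list of class `completed_datasets`; element i is the i-th
#'   completed `data.table` with attribute `imputation_index`.
#' @export
impute <- function(person_trials, spec = imputation_spec(),
                   outcomes = c("gad7", "phq8")) {
  stopifnot(inherits(spec, "imputation_spec"))
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  pt <- as.data.table(person_trials)

  metas <- lapply(outcomes, outcome_meta)
  need <- unique(c(spec$predictors, unlist(lapply(metas, `[[`, "enroll")),
                   if (spec$include_treatment) c("treatment", "era")))
  miss_cols <- setdiff(need, names(pt))
  if (length(miss_cols)) {
    stop_ttevax("E_COLUMNS", "person-trial table lacks predictor column(s): %s",
                paste(miss_cols, collapse = ", "))
  }
  for (cl in need) {
    if (anyNA(pt[[cl]])) {
      stop_ttevax("E_PREDICTOR_MISSING",
                  "imputation predictor '%s' has missing values; restrict to confounder-complete records first",
                  cl)
    }
  }

  completed <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    set.seed(spec$seed + i)
    di <- copy(pt)
    for (j in seq_along(outcomes)) {
      meta <- metas[[j]]
      y <- as.numeric(di[[meta$total]])
      miss <- is.na(y)
      if (!any(miss)) next
      rhs <- c(spec$predictors, meta$enroll,
               if (spec$include_treatment) "treatment * era")
      X <- model.matrix(as.formula(paste("~", paste(rhs, collapse = " + "))),
                        data = di)
      vals <- draw_imputation(y, X, miss, spec$method)
      vals <- pmin(pmax(round(vals), 0L), meta$max_total)
      set(di, which(miss), meta$total, as.integer(vals))
      set(di, NULL, meta$severe, as.integer(di[[meta$total]] >= 10L))
    }
    setattr(di, "imputation_index", i)
    completed[[i]] <- di
  }
  structure(completed, class = "completed_datasets")
}

#' @export
print.completed_datasets <- function(x, ...) {
  cat(sprintf("completed_datasets: m = %d imputations of %d person-trials\n",
              length(x), nrow(x[[1]])))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and variances on a common scale
#' (log-OR or model coefficient): pooled point = mean; total variance =
#' within + (1 + 1/m) between; 95% CI from a t distribution with
#' Barnard-Rubin degrees of freedom (classic Rubin df when `df_com` is
#' infinite). With m = 1 the single estimate passes through unchanged
#' (between-variance 0, normal CI).
#'
#' @param points Numeric vector of per-imputation estimates.
#' @param variances Numeric vector of per-imputation (squared-SE) variances.
#' @param df_com Complete-data residual degrees of freedom (default `Inf`).
#' @param conf Confidence level (default 0.95).
#' @return A list of class `pooled_estimate`: `point`, `within_var`,
#'   `between_var`, `total_var`, `se`, `df`, `ci95`, `m`.
#' @export
#' @examples
#' rubin_pool(c(0.5, 0.7), c(0.04, 0.06))  # point 0.6, total_var 0.08
rubin_pool <- function(points, variances, df_com = Inf, conf = 0.95) {
  if (length(points) != length(variances)) {
    stop_ttevax("E_POOL", "points and variances differ in length (%d vs %d)",
                length(points), length(variances))
  }
  if (!length(points)) {
    stop_ttevax("E_POOL", "nothing to pool")
  }
  m <- length(points)
  qbar <- mean(points)
  W <- mean(variances)
  B <- if (m == 1) 0 else var(points)
  Tv <- W + (1 + 1 / m) * B
  if (m == 1 || B == 0) {
    df <- Inf
  } else {
    lambda <- (1 + 1 / m) * B / Tv
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else {
      df_old
    }
  }
  crit <- if (is.finite(df)) qt(1 - (1 - conf) / 2, df) else
    qnorm(1 - (1 - conf) / 2)
  structure(list(point = qbar, within_var = W, between_var = B,
                 total_var = Tv, se = sqrt(Tv), df = df,
                 ci95 = c(qbar - crit * sqrt(Tv), qbar + crit * sqrt(Tv)),
                 m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4f (SE %.4f, 95%% CI %.4f to %.4f, m = %d)\n",
              x$point, x$se, x$ci95[1], x$ci95[2], x$m))
  invisible(x)
}

#' Bayesian information criterion
#'
#' `BIC = k * ln(n) - 2 * loglik`, used to compare candidate imputation
#' models.
#'
#' @param loglik Maximized log-likelihood.
#' @param k_params Number of free parameters (>= 0).
#' @param n_obs Number of observations (>= 1).
#' @return The BIC value.
#' @export
#' @examples
#' model_bic(-60, 2, 100)  # 2*log(100) + 120
model_bic <- function(loglik, k_params, n_obs) {
  if (n_obs < 1) {
    stop_ttevax("E_BIC", "n_obs must be positive")
  }
  if (k_params < 0) {
    stop_ttevax("E_BIC", "k_params must be nonnegative")
  }
  k_params * log(n_obs) - 2 * loglik
}
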
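## Synthetic longitudinal cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## ~quarterly online assessments Dec 2020 - Mar 2022, covariate-dependent
## first-dose uptake concentrated before the universal-availability cutoff
## (2021-04-19), GAD-7/PHQ-8 totals whose probability of crossing the
## moderate-to-severe threshold follows a logistic model with era-specific
## treatment effects, and ~7% missing outcome scores under MCAR or MAR.

default_assessment_months <- function() {
  as.Date(c("2020-12-01", "2021-03-01", "2021-06-01",
            "2021-09-01", "2021-12-01", "2022-03-01"))
}

#' Configuration for the synthetic cohort generator
#'
#' Holds every generative parameter: sample size, assessment calendar,
#' vaccine-uptake model, true era-specific treatment effects on the log-odds
#' scale, confounder structure, and the outcome-missingness process.
#'
#' Named coefficient vectors (`uptake_coefs`, `outcome_coefs`, `mar_coefs`)
#' refer to covariate columns; a name of the form `"column=level"` denotes an
#' indicator for a factor level (e.g. `"education=hs_or_less"`).
#'
#' @param n_participants Number of participants (>= 1).
#' @param assessment_months Strictly increasing Date vector of assessment
#'   waves (first of month). The last wave is outcome-only; all earlier waves
#'   are vaccination ("trial") waves. Default: Dec 2020, Mar/Jun/Sep/Dec
#'   2021, Mar 2022.
#' @param era_cutoff Date dividing the preuniversal and universal
#'   vaccine-availability eras (default 2021-04-19; a first dose on the
#'   cutoff itself is universal-era).
#' @param uptake_intercepts Per-trial-wave log-odds of a first dose for a
#'   covariate-reference participant still unvaccinated at that wave; length
#'   must equal the number of trial waves.
#' @param uptake_coefs Named log-odds coefficients of covariates on uptake.
#' @param true_effect_pre,true_effect_uni True conditional log-OR of
#'   vaccination on a moderate-to-severe outcome for doses in the
#'   preuniversal / universal era. Defaults are the magnitudes reported for
#'   anxiety in the motivating cohort (log 0.79 and log 1.23).
#' @param baseline_prevalence Length-2 numeric (anxiety, depression):
#'   marginal probability of a moderate-to-severe score among the untreated;
#'   each must lie strictly in (0, 1).
#' @param outcome_coefs Named log-odds coefficients of covariates on the
#'   outcome (the confounding pathway, shared by both instruments).
#' @param missing_rate Marginal probability that an outcome score is missing
#'   (default 0.07), applied to waves after the first.
#' @param missing_mechanism `"MAR"` (logistic in `mar_coefs` covariates) or
#'   `"MCAR"`.
#' @param mar_coefs Named log-odds coefficients steering MAR missingness.
#' @param retention Per-wave probability of remaining in follow-up
#'   (default 1: no dropout).
#' @param seed Integer RNG seed; the same config yields a byte-identical
#'   cohort.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants,
                             assessment_months = default_assessment_months(),
                             era_cutoff = as.Date("2021-04-19"),
                             uptake_intercepts = qlogis(c(0.10, 0.45, 0.18,
                                                          0.08, 0.05)),
                             uptake_coefs = c("susceptibility" = 0.4,
                                              "education=some_college" = -0.3,
                                              "education=hs_or_less" = -0.6),
                             true_effect_pre = log(0.79),
                             true_effect_uni = log(1.23),
                             baseline_prevalence = c(anxiety = 0.25,
                                                     depression = 0.27),
                             outcome_coefs = c("susceptibility" = 0.5,
                                               "education=some_college" = 0.15,
                                               "education=hs_or_less" = 0.30),
                             missing_rate = 0.07,
                             missing_mechanism = c("MAR", "MCAR"),
                             mar_coefs = c("susceptibility" = 0.5,
                                           "education=hs_or_less" = 0.4),
                             retention = 1.0,
                             seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  assessment_months <- floor_month(assessment_months)
  if (n_participants < 1) {
    stop_ttevax("E_CONFIG", "n_participants must be >= 1")
  }
  if (length(assessment_months) < 2 ||
      any(diff(month_id(assessment_months)) <= 0)) {
    stop_ttevax("E_CONFIG", "assessment_months must be strictly increasing")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_ttevax("E_CONFIG", "missing_rate must be in [0, 1)")
  }
  if (any(baseline_prevalence <= 0) || any(baseline_prevalence >= 1)) {
    stop_ttevax("E_CONFIG",
                "baseline_prevalence implies probabilities outside (0,1)")
  }
  n_trial_waves <- length(assessment_months) - 1L
  if (length(uptake_intercepts) != n_trial_waves) {
    stop_ttevax("E_CONFIG",
                "uptake_intercepts must have one entry per trial wave (%d)",
                n_trial_waves)
  }
  if (retention <= 0 || retention > 1) {
    stop_ttevax("E_CONFIG", "retention must be in (0, 1]")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    assessment_months = assessment_months,
    era_cutoff = as.Date(era_cutoff),
    uptake_intercepts = uptake_intercepts,
    uptake_coefs = uptake_coefs,
    true_effect_pre = true_effect_pre,
    true_effect_uni = true_effect_uni,
    baseline_prevalence = baseline_prevalence,
    outcome_coefs = outcome_coefs,
    missing_rate = missing_rate,
    missing_mechanism = missing_mechanism,
    mar_coefs = mar_coefs,
    retention = retention,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

## linear predictor from a named coefficient vector; "col=level" names are
## factor-level indicators, plain names are taken numerically (0/1 columns)
lin_pred <- function(df, coefs) {
  eta <- numeric(nrow(df))
  for (nm in names(coefs)) {
    if (grepl("=", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      if (!parts[1] %in% names(df)) {
        stop_ttevax("E_CONFIG", "coefficient refers to unknown column '%s'",
                    parts[1])
      }
      eta <- eta + coefs[[nm]] * as.numeric(df[[parts[1]]] == parts[2])
    } else {
      if (!nm %in% names(df)) {
        stop_ttevax("E_CONFIG", "coefficient refers to unknown column '%s'", nm)
      }
      eta <- eta + coefs[[nm]] * as.numeric(df[[nm]])
    }
  }
  eta
}

## solve the intercept so that mean(plogis(a + eta)) == target
solve_intercept <- function(eta, target) {
  f <- function(a) mean(plogis(a + eta)) - target
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

## draw an integer total consistent with the severe / not-severe class
draw_total <- function(severe, max_total, threshold = 10L) {
  n <- length(severe)
  low <- sample.int(threshold, n, replace = TRUE) - 1L           # 0..9
  high <- threshold - 1L + sample.int(max_total - threshold + 1L, n,
                                      replace = TRUE)            # 10..max
  ifelse(severe, high, low)
}

draw_baseline_covariates <- function(n) {
  samp <- function(levels, probs) {
    factor(levels[sample.int(length(levels), n, replace = TRUE, prob = probs)],
           levels = levels)
  }
  data.table(
    age_band = samp(c("18-49", "50-59", "60+"), c(0.71, 0.13, 0.16)),
    gender = samp(c("cis_male", "cis_female", "nonbinary_transgender"),
                  c(0.43, 0.55, 0.02)),
    race_ethnicity = samp(c("white_nh", "hispanic", "black_nh", "asian_pi",
                            "other"), c(0.60, 0.18, 0.12, 0.07, 0.03)),
    income = samp(c("lt_50k", "50k_100k", "gte_100k"), c(0.42, 0.31, 0.27)),
    education = samp(c("college", "some_college", "hs_or_less"),
                     c(0.58, 0.28, 0.14)),
    children_household = rbinom(n, 1, 0.32),
    exposure_risk = rbinom(n, 1, 0.38),
    susceptibility = rbinom(n, 1, 0.21),
    healthcare_access = rbinom(n, 1, 0.43),
    employment = samp(c("employed", "out_of_work", "other"),
                      c(0.65, 0.12, 0.23)),
    food_insecurity = rbinom(n, 1, 0.27),
    housing_instability = samp(c("never", "rarely_sometimes",
                                 "usually_always"), c(0.52, 0.32, 0.16))
  )
}

#' Simulate a longitudinal assessment cohort
#'
#' Draws covariates, a per-wave first-dose uptake process (vaccination is
#' absorbing), GAD-7/PHQ-8 totals whose threshold-crossing probability
#' follows the configured logistic outcome model, and outcome missingness.
#' First-dose dates fall inside the wave month in which uptake occurs, so a
#' wave's scores are treated outcomes exactly when the dose wave precedes the
#' score wave.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with `assessments` (long-format
#'   `data.table`, one row per participant-wave) and `truth` (generating
#'   parameters, including the solved outcome intercepts).
#' @export
#' @examples
#' cohort <- simulate_cohort(synthetic_config(200, seed = 42))
#' nrow(cohort$assessments)
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_participants
  months <- cfg$assessment_months
  n_waves <- length(months)
  n_trials <- n_waves - 1L

  covars <- draw_baseline_covariates(n)
  eta_uptake <- lin_pred(covars, cfg$uptake_coefs)
  eta_outcome <- lin_pred(covars, cfg$outcome_coefs)

  ## monotone dropout: participant observed at waves 1..last_wave
  last_wave <- if (cfg$retention >= 1) {
    rep.int(n_waves, n)
  } else {
    pmin(1L + stats::rgeom(n, 1 - cfg$retention), n_waves)
  }

  ## absorbing uptake process over trial waves
  dose_wave <- rep(NA_integer_, n)
  for (w in seq_len(n_trials)) {
    p <- plogis(cfg$uptake_intercepts[w] + eta_uptake)
    newly <- is.na(dose_wave) & last_wave >= w & runif(n) < p
    dose_wave[newly] <- w
  }
  dose_day <- sample.int(28L, n, replace = TRUE)
  first_dose_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  has_dose <- !is.na(dose_wave)
  first_dose_date[has_dose] <- as.Date(sprintf(
    "%s-%02d", format(months[dose_wave[has_dose]], "%Y-%m"),
    dose_day[has_dose]))
  effect <- numeric(n)
  effect[has_dose] <- ifelse(first_dose_date[has_dose] < cfg$era_cutoff,
                             cfg$true_effect_pre, cfg$true_effect_uni)

  alpha <- c(
    anxiety = solve_intercept(eta_outcome, cfg$baseline_prevalence[[1]]),
    depression = solve_intercept(eta_outcome, cfg$baseline_prevalence[[2]])
  )

  rows <- vector("list", n_waves)
  for (w in seq_len(n_waves)) {
    present <- which(last_wave >= w)
    treated <- has_dose[present] & dose_wave[present] < w
    eta_w <- eta_outcome[present] + treated * effect[present]
    sev_anx <- runif(length(present)) < plogis(alpha[["anxiety"]] + eta_w)
    sev_dep <- runif(length(present)) < plogis(alpha[["depression"]] + eta_w)
    gad7 <- draw_total(sev_anx, 21L)
    phq8 <- draw_total(sev_dep, 24L)
    vaccinated <- has_dose[present] & dose_wave[present] <= w
    rows[[w]] <- data.table(
      participant_id = present,
      assessment_month = months[w],
      vaccinated_ever = vaccinated,
      first_dose_date = fifelse(vaccinated, first_dose_date[present],
                                as.Date(NA)),
      gad7_total = as.integer(gad7),
      phq8_total = as.integer(phq8),
      covars[present]
    )
  }
  assessments <- rbindlist(rows)
  setkey(assessments, participant_id, assessment_month)
  assessments[, gad7_mod_severe := as.integer(gad7_total >= 10L)]
  assessments[, phq8_mod_severe := as.integer(phq8_total >= 10L)]

  cohort <- structure(list(
    assessments = assessments,
    truth = list(config = cfg, alpha = alpha, n_vaccinated = sum(has_dose))
  ), class = "synthetic_cohort")

  if (cfg$missing_rate > 0) {
    cohort <- inject_missingness(cohort, cfg$missing_rate,
                                 cfg$missing_mechanism,
                                 seed = cfg$seed + 1L,
                                 mar_coefs = cfg$mar_coefs)
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  a <- x$assessments
  cat(sprintf(
    "synthetic_cohort: %d participants, %d assessment rows, %d waves\n",
    length(unique(a$participant_id)), nrow(a),
    length(unique(a$assessment_month))))
  invisible(x)
}

#' Blank outcome scores under a chosen missingness mechanism
#'
#' Sets GAD-7/PHQ-8 totals (and the derived severity indicators) to missing,
#' independently per instrument-cell. Under MCAR every eligible cell is
#' blanked with the same probability; under MAR the per-cell probability is a
#' logistic function of observed covariates (`mar_coefs`), with the intercept
#' solved so the marginal rate equals `rate`. Covariates are never blanked.
#' First-wave (enrollment) scores are spared by default because the analytic
#' design requires complete enrollment severity.
#'
#' @param cohort A `synthetic_cohort`.
#' @param rate Marginal missingness probability in \[0, 1).
#' @param mechanism `"MAR"` or `"MCAR"`.
#' @param seed Integer seed.
#' @param mar_coefs Named covariate coefficients for the MAR mechanism (all
#'   zero makes MAR empirically identical to MCAR).
#' @param spare_first_wave Keep the first wave's scores complete
#'   (default `TRUE`).
#' @return The cohort with blanked outcome cells.
#' @export
inject_missingness <- function(cohort, rate,
                               mechanism = c("MAR", "MCAR"),
                               seed = 1L,
                               mar_coefs = c("susceptibility" = 0.5,
                                             "education=hs_or_less" = 0.4),
                               spare_first_wave = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (rate < 0 || rate >= 1) {
    stop_ttevax("E_CONFIG", "missingness rate must be in [0, 1)")
  }
  mechanism <- match.arg(mechanism)
  if (rate == 0) {
    return(cohort)
  }
  set.seed(seed)
  a <- copy(cohort$assessments)
  eligible <- rep(TRUE, nrow(a))
  if (spare_first_wave) {
    eligible <- a$assessment_month != min(a$assessment_month)
  }
  p <- if (mechanism == "MCAR") {
    rep(rate, nrow(a))
  } else {
    eta <- lin_pred(a, mar_coefs)
    plogis(solve_intercept(eta[eligible], rate) + eta)
  }
  drop_gad <- eligible & runif(nrow(a)) < p
  drop_phq <- eligible & runif(nrow(a)) < p
  a[drop_gad, `:=`(gad7_total = NA_integer_, gad7_mod_severe = NA_integer_)]
  a[drop_phq, `:=`(phq8_total = NA_integer_, phq8_mod_severe = NA_integer_)]
  cohort$assessments <- a
  cohort$truth$missing <- list(rate = rate, mechanism = mechanism,
                               seed = seed)
  cohort
}
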
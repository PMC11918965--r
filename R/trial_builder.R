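## Sequential trial emulation.
##
## Each assessment wave through Dec 2021 opens a nonrandomized "trial".
## Participants who completed that wave's assessment and reported vaccination
## status enter: still-unvaccinated participants contribute one unvaccinated
## person-trial per wave until vaccinated; a participant first reporting
## vaccination contributes exactly one vaccinated person-trial at that wave
## and then exits the sequence. Time zero is the month of the first dose
## (vaccinated) or of assessment completion (unvaccinated); the outcome is
## the first score observed 2-5 months after time zero (generally ~3).

#' Configuration for person-trial construction
#'
#' @param trial_months Date vector of trial (assessment) months, increasing;
#'   default the Dec 2020 wave plus the four subsequent waves through Dec
#'   2021.
#' @param era_cutoff Date starting the universal vaccine era (a first dose on
#'   or after this date is universal-era). Default 2021-04-19.
#' @param outcome_lag_window Integer length-2: allowed whole months between
#'   time zero and the outcome assessment (inclusive). Default `c(2, 5)`; the
#'   earliest assessment in the window is used.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(trial_months = default_assessment_months()[1:5],
                         era_cutoff = as.Date("2021-04-19"),
                         outcome_lag_window = c(2L, 5L)) {
  trial_months <- floor_month(trial_months)
  if (any(diff(month_id(trial_months)) <= 0)) {
    stop_ttevax("E_CONFIG", "trial_months must be strictly increasing")
  }
  if (length(outcome_lag_window) != 2 ||
      outcome_lag_window[1] > outcome_lag_window[2] ||
      outcome_lag_window[1] < 1) {
    stop_ttevax("E_CONFIG", "outcome_lag_window must be a nonempty 1+ range")
  }
  structure(list(trial_months = trial_months,
                 era_cutoff = as.Date(era_cutoff),
                 outcome_lag_window = as.integer(outcome_lag_window)),
            class = "trial_config")
}

#' Assign the vaccine-availability era of a date
#'
#' The universal era begins on the cutoff date itself: a first dose on or
#' after 2021-04-19 is universal-era, strictly before is preuniversal.
#'
#' @param date Date vector (first-dose date, or a time-zero month's midpoint
#'   for unvaccinated person-trials). Must be non-missing.
#' @param cutoff Era cutoff date.
#' @return Factor with levels `preuniversal`, `universal`.
#' @export
#' @examples
#' assign_era(as.Date(c("2021-04-18", "2021-04-19")))
assign_era <- function(date, cutoff = as.Date("2021-04-19")) {
  date <- as.Date(date)
  if (anyNA(date)) {
    stop_ttevax("E_ERA_DATE", "cannot assign an era to a missing date")
  }
  factor(ifelse(date >= as.Date(cutoff), "universal", "preuniversal"),
         levels = c("preuniversal", "universal"))
}

time_updated_cols <- c("employment", "food_insecurity", "housing_instability")
baseline_cols <- c("age_band", "gender", "race_ethnicity", "income",
                   "education", "children_household", "exposure_risk",
                   "susceptibility", "healthcare_access")

#' Validate a long-format assessment table
#'
#' Checks the structural invariants person-trial construction relies on:
#' at most one record per participant-month, vaccination an absorbing state,
#' first-dose dates only on vaccinated records and never after the assessment
#' that reports them.
#'
#' @param assessments data.frame/data.table of assessment records.
#' @return Invisibly, the table as a keyed `data.table` with an internal
#'   month index column.
#' @export
validate_assessments <- function(assessments) {
  dt <- as.data.table(assessments)
  required <- c("participant_id", "assessment_month", "vaccinated_ever",
                "first_dose_date", "gad7_total", "phq8_total")
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop_ttevax("E_COLUMNS", "assessment table lacks column(s): %s",
                paste(miss, collapse = ", "))
  }
  dt[, assessment_month := floor_month(assessment_month)]
  dt[, month_id := month_id(assessment_month)]
  setkey(dt, participant_id, month_id)
  if (anyDuplicated(dt, by = c("participant_id", "month_id"))) {
    dup <- dt[duplicated(dt, by = c("participant_id", "month_id"))]
    stop_ttevax("E_DUPLICATE_RECORD",
                "participant %s has multiple records in %s",
                dup$participant_id[1],
                format(dup$assessment_month[1], "%Y-%m"))
  }
  ## vaccination must be absorbing among reported statuses
  status <- dt[!is.na(vaccinated_ever)]
  bad <- status[, .(nonmono = any(as.integer(vaccinated_ever) <
                                    cummax(as.integer(vaccinated_ever)))),
                by = participant_id][nonmono == TRUE]
  if (nrow(bad)) {
    stop_ttevax("E_NONMONOTONE_VACCINATION",
                "vaccination history is not absorbing for participant(s): %s",
                paste(head(bad$participant_id, 5), collapse = ", "))
  }
  ghost <- dt[vaccinated_ever %in% FALSE & !is.na(first_dose_date)]
  if (nrow(ghost)) {
    stop_ttevax("E_DOSE_WITHOUT_STATUS",
                "participant %s has a first-dose date on an unvaccinated record",
                ghost$participant_id[1])
  }
  late <- dt[vaccinated_ever %in% TRUE & !is.na(first_dose_date) &
               month_id(first_dose_date) > month_id]
  if (nrow(late)) {
    stop_ttevax("E_DOSE_AFTER_ASSESSMENT",
                "participant %s reports a first dose (%s) after the %s assessment",
                late$participant_id[1], format(late$first_dose_date[1]),
                format(late$assessment_month[1], "%Y-%m"))
  }
  invisible(dt)
}

#' Build the person-trial table
#'
#' Expands a validated long-format assessment table into one row per
#' person-trial (see module description above), snapshots covariates as of
#' time zero and links the follow-up outcome.
#'
#' @param assessments Long-format assessment records (one row per
#'   participant-month) with vaccination status, instrument totals and
#'   covariates.
#' @param cfg A [trial_config()].
#' @return A `data.table` of person-trials: identifiers
#'   (`participant_id`, `trial_index`), assignment (`treatment`, `time_zero`,
#'   `era`, `first_dose_date`), the covariate snapshot (baseline covariates,
#'   `employment_t0`, `food_insecurity_t0`, `housing_instability_t0`,
#'   `anx_t0`, `dep_t0`, `gad7_t0`, `phq8_t0`, `enroll_anx`, `enroll_dep`),
#'   and outcomes (`outcome_month`, `outcome_gad7`, `outcome_phq8`,
#'   `outcome_anx_severe`, `outcome_dep_severe`).
#' @export
build_person_trials <- function(assessments, cfg = trial_config()) {
  stopifnot(inherits(cfg, "trial_config"))
  dt <- validate_assessments(assessments)
  tm_ids <- month_id(cfg$trial_months)

  status <- dt[month_id %in% tm_ids & !is.na(vaccinated_ever)]
  if (!nrow(status)) {
    stop_ttevax("E_EMPTY", "no eligible assessments at any trial month")
  }

  unvacc <- status[vaccinated_ever == FALSE,
                   .(participant_id, report_id = month_id)]
  vacc <- status[vaccinated_ever == TRUE,
                 .(report_id = month_id[1], first_dose_date = first_dose_date[1]),
                 by = participant_id]
  no_date <- vacc[is.na(first_dose_date)]
  if (nrow(no_date)) {
    warning(sprintf(
      "dropping %d vaccinated entr%s with missing first-dose date (participant%s %s): cannot assign time zero or era",
      nrow(no_date), if (nrow(no_date) == 1) "y" else "ies",
      if (nrow(no_date) == 1) "" else "s",
      paste(head(no_date$participant_id, 5), collapse = ", ")),
      call. = FALSE)
    vacc <- vacc[!is.na(first_dose_date)]
  }

  if (nrow(unvacc)) {
    unvacc[, `:=`(treatment = 0L, tz_id = report_id,
                  first_dose_date = as.Date(NA))]
  }
  if (nrow(vacc)) {
    vacc[, `:=`(treatment = 1L, tz_id = month_id(first_dose_date))]
  }
  pt <- rbindlist(list(unvacc, vacc), use.names = TRUE, fill = TRUE)
  if (!nrow(pt)) {
    stop_ttevax("E_EMPTY", "no person-trials could be constructed")
  }
  pt[, trial_index := match(report_id, tm_ids)]
  pt[, time_zero := month_from_id(tz_id)]
  pt[, era := {
    d <- fifelse(treatment == 1L, first_dose_date, month_midpoint(time_zero))
    assign_era(d, cfg$era_cutoff)
  }]

  ## outcome linkage: earliest assessment with lag in the window
  cand <- dt[, .(participant_id, month_id, gad7_total, phq8_total,
                 out_month = assessment_month)]
  setkey(cand, participant_id, month_id)
  pt[, `:=`(lo_id = tz_id + cfg$outcome_lag_window[1],
            hi_id = tz_id + cfg$outcome_lag_window[2])]
  linked <- cand[pt, on = .(participant_id, month_id >= lo_id,
                            month_id <= hi_id), mult = "first",
                 .(outcome_gad7 = x.gad7_total, outcome_phq8 = x.phq8_total,
                   outcome_month = x.out_month)]
  pt[, `:=`(outcome_gad7 = linked$outcome_gad7,
            outcome_phq8 = linked$outcome_phq8,
            outcome_month = linked$outcome_month)]
  pt[, `:=`(outcome_anx_severe = as.integer(outcome_gad7 >= 10L),
            outcome_dep_severe = as.integer(outcome_phq8 >= 10L))]

  pt <- snapshot_covariates(pt, dt)
  setkey(pt, participant_id, trial_index)
  pt[, c("report_id", "lo_id", "hi_id") := NULL]
  setcolorder(pt, c("participant_id", "trial_index", "treatment",
                    "time_zero", "era", "first_dose_date"))
  attr(pt, "trial_config") <- cfg
  pt[]
}

#' Snapshot covariates as of time zero
#'
#' Baseline covariates are copied from the enrollment (first) record;
#' time-updated covariates (employment, food insecurity, housing
#' instability) come from the most recent assessment at or before time zero;
#' anxiety/depression severity at time zero is the most recent non-missing
#' measure at or before time zero. Enrollment severity is also carried for
#' use as an imputation-model predictor.
#'
#' @param person_trials Person-trial table (internal columns `tz_id`
#'   present).
#' @param dt Validated assessment `data.table` (from
#'   [validate_assessments()]).
#' @return The person-trial table with snapshot columns added.
#' @keywords internal
snapshot_covariates <- function(person_trials, dt) {
  pt <- person_trials
  have_base <- intersect(baseline_cols, names(dt))
  have_tu <- intersect(time_updated_cols, names(dt))

  enrol <- dt[, c(.SD[1], .(enroll_anx = gad7_mod_severe[1],
                            enroll_dep = phq8_mod_severe[1])),
              by = participant_id,
              .SDcols = have_base]
  pt <- merge(pt, enrol, by = "participant_id", sort = FALSE)

  if (length(have_tu)) {
    tu <- dt[, c(list(participant_id = participant_id, month_id = month_id),
                 .SD), .SDcols = have_tu]
    setnames(tu, have_tu, paste0(have_tu, "_t0"))
    setkey(tu, participant_id, month_id)
    snap <- tu[pt[, .(participant_id, month_id = tz_id)],
               on = .(participant_id, month_id), roll = Inf]
    if (anyNA(snap[[paste0(have_tu[1], "_t0")]])) {
      bad <- pt$participant_id[which(is.na(snap[[paste0(have_tu[1], "_t0")]]))]
      stop_ttevax("E_NO_BASELINE",
                  "no assessment at or before time zero for participant(s): %s",
                  paste(head(unique(bad), 5), collapse = ", "))
    }
    pt <- cbind(pt, snap[, paste0(have_tu, "_t0"), with = FALSE])
  }

  ## most recent non-missing severity at or before time zero
  sa <- dt[!is.na(gad7_mod_severe),
           .(participant_id, month_id, anx_t0 = gad7_mod_severe,
             gad7_t0 = gad7_total)]
  setkey(sa, participant_id, month_id)
  snap_a <- sa[pt[, .(participant_id, month_id = tz_id)],
               on = .(participant_id, month_id), roll = Inf]
  sd <- dt[!is.na(phq8_mod_severe),
           .(participant_id, month_id, dep_t0 = phq8_mod_severe,
             phq8_t0 = phq8_total)]
  setkey(sd, participant_id, month_id)
  snap_d <- sd[pt[, .(participant_id, month_id = tz_id)],
               on = .(participant_id, month_id), roll = Inf]
  pt[, `:=`(anx_t0 = snap_a$anx_t0, gad7_t0 = snap_a$gad7_t0,
            dep_t0 = snap_d$dep_t0, phq8_t0 = snap_d$phq8_t0)]
  pt
}

#' Flow accounting for the trial sequence
#'
#' Summarizes the construction the way a study-flow diagram would: enrolled
#' participants, participants contributing at least one person-trial, total
#' and vaccinated person-trials, and the split of vaccinated person-trials by
#' era (shares sum to 100).
#'
#' @param assessments The assessment table the person-trials were built from.
#' @param person_trials Output of [build_person_trials()].
#' @return A list of class `flow_summary`.
#' @export
flow_accounting <- function(assessments, person_trials) {
  pt <- as.data.table(person_trials)
  n_vacc <- pt[treatment == 1L, .N]
  n_pre <- pt[treatment == 1L & era == "preuniversal", .N]
  n_uni <- n_vacc - n_pre
  structure(list(
    n_enrolled = length(unique(as.data.table(assessments)$participant_id)),
    n_eligible = length(unique(pt$participant_id)),
    n_person_trials = nrow(pt),
    n_vaccinated_person_trials = n_vacc,
    n_vaccinated_preuniversal = n_pre,
    n_vaccinated_universal = n_uni,
    vaccinated_share_preuniversal = if (n_vacc) 100 * n_pre / n_vacc else NA_real_,
    vaccinated_share_universal = if (n_vacc) 100 * n_uni / n_vacc else NA_real_
  ), class = "flow_summary")
}

#' @export
print.flow_summary <- function(x, ...) {
  cat(sprintf(
    paste0("flow: %d enrolled -> %d eligible -> %d person-trials ",
           "(%d vaccinated: %.1f%% preuniversal, %.1f%% universal)\n"),
    x$n_enrolled, x$n_eligible, x$n_person_trials,
    x$n_vaccinated_person_trials, x$vaccinated_share_preuniversal,
    x$vaccinated_share_universal))
  invisible(x)
}
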
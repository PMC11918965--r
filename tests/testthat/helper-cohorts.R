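# Shared fixtures and independent oracles.
#
# The brute-force person-trial enumerator below deliberately shares no code
# with the package: it walks each participant's timeline record by record
# with its own month arithmetic, so it can serve as an oracle for
# build_person_trials().

wave_months <- as.Date(c("2020-12-01", "2021-03-01", "2021-06-01",
                         "2021-09-01", "2021-12-01", "2022-03-01"))
trial_waves <- wave_months[1:5]

.mid <- function(d) {
  as.integer(format(as.Date(d), "%Y")) * 12L +
    as.integer(format(as.Date(d), "%m"))
}

# Hand-rolled timeline walker (oracle for build_person_trials)
brute_force_person_trials <- function(assessments,
                                      trial_months = trial_waves,
                                      cutoff = as.Date("2021-04-19"),
                                      window = c(2L, 5L)) {
  a <- as.data.frame(assessments)
  res <- list()
  for (pid in sort(unique(a$participant_id))) {
    recs <- a[a$participant_id == pid, ]
    recs <- recs[order(recs$assessment_month), ]
    exited <- FALSE
    for (k in seq_along(trial_months)) {
      if (exited) break
      tm <- trial_months[k]
      row <- recs[recs$assessment_month == tm, ]
      if (nrow(row) == 0 || is.na(row$vaccinated_ever)) next
      if (row$vaccinated_ever) {
        exited <- TRUE
        if (is.na(row$first_dose_date)) next  # cannot place time zero
        tz <- as.Date(format(row$first_dose_date, "%Y-%m-01"))
        era <- if (row$first_dose_date >= cutoff) "universal" else "preuniversal"
        trt <- 1L
      } else {
        tz <- tm
        era <- if (as.Date(format(tm, "%Y-%m-15")) >= cutoff)
          "universal" else "preuniversal"
        trt <- 0L
      }
      lags <- .mid(recs$assessment_month) - .mid(tz)
      cand <- recs[lags >= window[1] & lags <= window[2], ]
      out_g <- out_p <- NA_integer_
      out_m <- as.Date(NA)
      if (nrow(cand)) {
        out_g <- cand$gad7_total[1]
        out_p <- cand$phq8_total[1]
        out_m <- cand$assessment_month[1]
      }
      res[[length(res) + 1L]] <- data.frame(
        participant_id = pid, trial_index = k, treatment = trt,
        time_zero = tz, era = era, outcome_month = out_m,
        outcome_gad7 = out_g, outcome_phq8 = out_p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out[order(out$participant_id, out$trial_index), ]
}

# Random small assessment table exercising skipped waves, staggered uptake
# and missing scores; respects the structural invariants the builder
# validates (absorbing vaccination, dose month <= reporting month).
random_toy_cohort <- function(n = 10, p_present = 0.85, p_missing_score = 0.1,
                              p_missing_status = 0.05) {
  rows <- list()
  for (pid in seq_len(n)) {
    present <- runif(length(wave_months)) < p_present
    present[sample.int(length(wave_months), 1)] <- TRUE
    first_present <- which(present)[1]
    # dose reported at a random present trial wave (or never)
    dose_wave <- NA_integer_
    report_wave <- NA_integer_
    cand <- which(present[1:5])
    cand <- cand[cand >= first_present]
    if (length(cand) && runif(1) < 0.6) {
      report_wave <- cand[sample.int(length(cand), 1)]
      # dose in any month from the participant's first present wave up to
      # the reporting wave month
      lo <- .mid(wave_months[first_present])
      hi <- .mid(wave_months[report_wave])
      rng <- seq(lo, hi)
      dose_mid <- rng[sample.int(length(rng), 1)]
      yr <- dose_mid %/% 12L
      mo <- dose_mid %% 12L
      if (mo == 0L) { yr <- yr - 1L; mo <- 12L }
      dose_date <- as.Date(sprintf("%d-%02d-%02d", yr, mo,
                                   sample.int(28, 1)))
    } else {
      dose_date <- as.Date(NA)
    }
    for (w in which(present)) {
      vac <- if (!is.na(report_wave) && w >= report_wave) TRUE else FALSE
      status_missing <- runif(1) < p_missing_status && !vac
      g <- if (runif(1) < p_missing_score) NA_integer_ else
        sample(0:21, 1)
      p8 <- if (runif(1) < p_missing_score) NA_integer_ else
        sample(0:24, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid,
        assessment_month = wave_months[w],
        vaccinated_ever = if (status_missing) NA else vac,
        first_dose_date = if (vac) dose_date else as.Date(NA),
        gad7_total = g, phq8_total = p8,
        gad7_mod_severe = ifelse(is.na(g), NA_integer_,
                                 as.integer(g >= 10)),
        phq8_mod_severe = ifelse(is.na(p8), NA_integer_,
                                 as.integer(p8 >= 10)),
        susceptibility = rbinom(1, 1, 0.3),
        employment = "employed",
        food_insecurity = 0L,
        housing_instability = "never",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Three-participant fixture used across builder tests:
#   P1 never vaccinated, completes all waves      -> 5 unvaccinated trials
#   P2 unvaccinated at waves 1-2, dose before w3  -> 2 unvaccinated + 1 vacc
#   P3 already vaccinated at wave 1               -> 1 vaccinated trial
toy_three_participants <- function() {
  mk <- function(pid, w, vac, dose, g = 5L) {
    data.frame(participant_id = pid, assessment_month = wave_months[w],
               vaccinated_ever = vac, first_dose_date = dose,
               gad7_total = g, phq8_total = g,
               gad7_mod_severe = as.integer(g >= 10),
               phq8_mod_severe = as.integer(g >= 10),
               susceptibility = 0L, employment = "employed",
               food_insecurity = 0L, housing_instability = "never",
               stringsAsFactors = FALSE)
  }
  rbind(
    do.call(rbind, lapply(1:6, function(w) mk(1L, w, FALSE, as.Date(NA)))),
    mk(2L, 1, FALSE, as.Date(NA)), mk(2L, 2, FALSE, as.Date(NA)),
    mk(2L, 3, TRUE, as.Date("2021-05-20"), g = 12L),
    mk(2L, 4, TRUE, as.Date("2021-05-20")),
    mk(3L, 1, TRUE, as.Date("2020-12-10")),
    mk(3L, 2, TRUE, as.Date("2020-12-10"))
  )
}

# Expand a 2x2 contingency table (a,b = treated with/without outcome;
# c,d = untreated) into unit rows with unique cluster ids
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    outcome_anx_severe = c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d)),
    treatment = c(rep(1L, a + b), rep(0L, c + d)),
    era = "both",
    participant_id = seq_len(a + b + c + d)
  )
}
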
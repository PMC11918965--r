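test_that("assign_era splits dates at the universal-availability cutoff", {
  expect_identical(as.character(assign_era(as.Date("2021-04-18"))),
                   "preuniversal")
  expect_identical(as.character(assign_era(as.Date("2021-04-19"))),
                   "universal")
  expect_identical(as.character(assign_era(as.Date("2020-12-15"))),
                   "preuniversal")
  expect_error(assign_era(as.Date(NA)), "missing date")
})

test_that("re-entry and single-entry rules produce the expected trials", {
  a <- toy_three_participants()
  pt <- build_person_trials(a)

  # P1: never vaccinated, completes all 5 trial waves -> 5 unvaccinated
  p1 <- pt[pt$participant_id == 1L]
  expect_identical(nrow(p1), 5L)
  expect_true(all(p1$treatment == 0L))
  expect_identical(p1$trial_index, 1:5)
  # unvaccinated time zero = assessment month; era from its month
  expect_identical(p1$time_zero, trial_waves)
  expect_identical(as.character(p1$era),
                   c("preuniversal", "preuniversal", "universal",
                     "universal", "universal"))

  # P2: unvaccinated at waves 1-2, dose 2021-05-20 reported at wave 3
  p2 <- pt[pt$participant_id == 2L]
  expect_identical(nrow(p2), 3L)
  expect_identical(p2$treatment, c(0L, 0L, 1L))
  expect_identical(p2$trial_index, 1:3)
  # vaccinated time zero = month of first dose, era from the exact date
  expect_identical(p2$time_zero[3], as.Date("2021-05-01"))
  expect_identical(as.character(p2$era[3]), "universal")

  # P3: already vaccinated at wave 1 -> exactly one vaccinated trial
  p3 <- pt[pt$participant_id == 3L]
  expect_identical(nrow(p3), 1L)
  expect_identical(p3$treatment, 1L)
  expect_identical(p3$trial_index, 1L)
  expect_identical(as.character(p3$era), "preuniversal")
})

test_that("outcomes link to the earliest assessment in the lag window", {
  a <- toy_three_participants()
  pt <- build_person_trials(a)
  # P1 trial 1 (tz Dec 2020): window Feb-May 2021 -> Mar 2021 (lag 3)
  p1 <- pt[pt$participant_id == 1L]
  expect_identical(p1$outcome_month[1], as.Date("2021-03-01"))
  # P2 vaccinated trial (tz May 2021): window Jul-Oct -> Sep 2021 (lag 4)
  p2 <- pt[pt$participant_id == 2L]
  expect_identical(p2$outcome_month[3], as.Date("2021-09-01"))
  expect_identical(p2$outcome_gad7[3], 5L)

  # two assessments in the window: the earlier one wins
  wide <- trial_config(outcome_lag_window = c(2L, 7L))
  ptw <- build_person_trials(a, wide)
  expect_identical(ptw[ptw$participant_id == 1L]$outcome_month[1],
                   as.Date("2021-03-01"))

  # no assessment inside the window -> missing outcome
  narrow <- trial_config(outcome_lag_window = c(1L, 1L))
  ptn <- build_person_trials(a, narrow)
  expect_true(is.na(ptn[ptn$participant_id == 1L]$outcome_month[1]))
  expect_true(is.na(ptn[ptn$participant_id == 1L]$outcome_gad7[1]))
})

test_that("covariate snapshots use the most recent measure at time zero", {
  a <- toy_three_participants()
  # make P2's employment and severity vary over time
  a$employment[a$participant_id == 2L] <-
    c("employed", "out_of_work", "employed", "employed")
  a$gad7_total[a$participant_id == 2L &
                 a$assessment_month == wave_months[2]] <- NA_integer_
  a$gad7_mod_severe[a$participant_id == 2L &
                      a$assessment_month == wave_months[2]] <- NA_integer_
  pt <- build_person_trials(a)
  p2 <- pt[pt$participant_id == 2L]
  # vaccinated trial tz = May 2021: last assessment at/before is Mar (wave 2)
  expect_identical(p2$employment_t0[3], "out_of_work")
  # severity at Mar is missing -> falls back to the Dec 2020 measure
  expect_identical(p2$anx_t0[3], 0L)
  # baseline covariates always come from enrollment
  expect_true(all(p2$susceptibility == 0L))
  # severity measured at the time-zero assessment itself is used as-is
  p1 <- pt[pt$participant_id == 1L]
  expect_identical(p1$anx_t0, rep(0L, 5))
})

test_that("structural data errors are caught by name", {
  a <- toy_three_participants()

  bad <- a
  bad$vaccinated_ever[bad$participant_id == 2L] <- c(FALSE, TRUE, FALSE, TRUE)
  bad$first_dose_date[bad$participant_id == 2L] <-
    as.Date(c(NA, "2021-02-01", NA, "2021-02-01"))
  expect_error(build_person_trials(bad), "not absorbing.*2")

  late <- a
  late$first_dose_date[late$participant_id == 3L] <-
    as.Date("2021-01-10")  # reported at Dec 2020 assessment
  expect_error(build_person_trials(late), "after the 2020-12 assessment")

  dup <- rbind(a, a[a$participant_id == 1L &
                      a$assessment_month == wave_months[1], ])
  expect_error(build_person_trials(dup), "multiple records")

  ghost <- a
  ghost$first_dose_date[which(ghost$participant_id == 1L)[1]] <-
    as.Date("2020-12-01")
  expect_error(build_person_trials(ghost), "unvaccinated record")

  nodose <- a
  nodose$first_dose_date[nodose$participant_id == 3L] <- as.Date(NA)
  expect_warning(pt <- build_person_trials(nodose),
                 "missing first-dose date")
  expect_false(3L %in% pt$participant_id)
  # other participants are unaffected
  expect_identical(nrow(pt[pt$participant_id == 1L]), 5L)
})

test_that("each participant enters once per trial and once vaccinated", {
  set.seed(404)
  for (i in 1:10) {
    a <- random_toy_cohort(n = 12)
    pt <- suppressWarnings(build_person_trials(a))
    counts <- table(pt$participant_id)
    expect_true(all(counts <= 5))
    vacc_counts <- table(pt$participant_id[pt$treatment == 1L])
    expect_true(all(vacc_counts == 1))
    # no trial after the first vaccinated trial
    dtp <- as.data.frame(pt)
    for (pid in unique(dtp$participant_id)) {
      rows <- dtp[dtp$participant_id == pid, ]
      if (any(rows$treatment == 1L)) {
        expect_identical(max(rows$trial_index),
                         rows$trial_index[rows$treatment == 1L])
      }
    }
    # every person-trial belongs to exactly one era
    expect_false(anyNA(pt$era))
  }
})

test_that("builder matches the brute-force timeline enumerator", {
  set.seed(505)
  for (i in 1:12) {
    a <- random_toy_cohort(n = 10)
    got <- as.data.frame(suppressWarnings(build_person_trials(a)))
    got <- got[order(got$participant_id, got$trial_index),
               c("participant_id", "trial_index", "treatment", "time_zero",
                 "era", "outcome_month", "outcome_gad7", "outcome_phq8")]
    got$era <- as.character(got$era)
    rownames(got) <- NULL
    want <- suppressWarnings(brute_force_person_trials(a))
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("flow accounting partitions vaccinated trials across eras", {
  a <- toy_three_participants()
  pt <- build_person_trials(a)
  fl <- flow_accounting(a, pt)
  expect_identical(fl$n_enrolled, 3L)
  expect_identical(fl$n_eligible, 3L)
  expect_identical(fl$n_person_trials, 9L)
  expect_identical(fl$n_vaccinated_person_trials, 2L)
  expect_identical(fl$n_vaccinated_preuniversal, 1L)
  expect_equal(fl$vaccinated_share_preuniversal +
                 fl$vaccinated_share_universal, 100)
})
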
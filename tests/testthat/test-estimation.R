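test_that("prevalence recomputes percentages with Wald intervals", {
  p <- prevalence(25, 100)
  expect_equal(p$pct, 25)
  expect_equal(p$ci,
               100 * (0.25 + c(-1, 1) * qnorm(0.975) *
                        sqrt(0.25 * 0.75 / 100)))
  z <- prevalence(0, 50)
  expect_equal(z$pct, 0)
  expect_equal(z$ci, c(0, 0))
  expect_error(prevalence(1, 0), "positive")
  expect_error(prevalence(5, 4), "0..denom")
})

test_that("crude_or is ad/bc with a Woolf interval and guards zero cells", {
  expect_equal(crude_or(10, 10, 10, 10)$or, 1)
  expect_equal(crude_or(20, 10, 10, 20)$or, 4)
  # printed-counts example: cells (532, 2662, 1171, 3675) -> ~0.627
  tab <- crude_or(532, 3194 - 532, 1171, 4846 - 1171)
  expect_equal(tab$or, (532 * 3675) / (2662 * 1171))
  expect_equal(round(tab$or, 3), 0.627)
  expect_equal(tab$se_log_or,
               sqrt(1 / 532 + 1 / 2662 + 1 / 1171 + 1 / 3675))
  expect_error(crude_or(0, 5, 5, 5), "zero cell \\(a\\)")
  expect_error(crude_or(3, 5, -1, 5), "nonnegative")
})

test_that("treatment-only logistic reproduces the closed-form 2x2 log-OR", {
  spec <- model_spec("anxiety_mod_severe", adjustment_set = character(0),
                     era = "both")
  set.seed(7)
  for (i in 1:10) {
    cells <- 2L + stats::rpois(4, 30)
    d <- expand_2x2(cells[1], cells[2], cells[3], cells[4])
    est <- fit_pooled_logistic(d, spec)
    expect_equal(est$point,
                 log(cells[1] * cells[4] / (cells[2] * cells[3])),
                 tolerance = 1e-8)
    # clusters all of size one: robust variance equals HC0, and the Woolf
    # SE matches the model-based one on a saturated 2x2
    expect_equal(est$se_robust^2,
                 sandwich::vcovHC(est$fit, type = "HC0")["treatment",
                                                         "treatment"])
  }
})

test_that("cluster-robust variance matches a hand-rolled sandwich", {
  cfg <- synthetic_config(400, missing_rate = 0, seed = 12)
  pt <- build_person_trials(simulate_cohort(cfg)$assessments)
  spec <- model_spec("anxiety_mod_severe",
                     adjustment_set = c("susceptibility", "education"),
                     era = "both")
  est <- fit_pooled_logistic(pt, spec)
  fit <- est$fit
  # independent computation: bread = (X'WX)^-1, meat from per-cluster
  # score sums of the logistic log-likelihood
  X <- model.matrix(fit)
  y <- fit$y
  mu <- fitted(fit)
  U <- X * (y - mu)
  cl <- pt$participant_id
  Usum <- rowsum(U, cl)
  A_inv <- vcov(fit) / 1  # glm dispersion is 1 for binomial
  V_hand <- A_inv %*% crossprod(Usum) %*% A_inv
  V_pkg <- robust_cluster_variance(fit, cl, type = "CR0")
  expect_equal(unname(V_pkg), unname(V_hand), tolerance = 1e-5)
  # CR1 applies the G/(G-1) factor
  g <- length(unique(cl))
  V1 <- robust_cluster_variance(fit, cl, type = "CR1")
  expect_equal(unname(V1), unname(V_hand) * g / (g - 1), tolerance = 1e-5)
})

test_that("duplicating whole clusters leaves point and robust SE in place", {
  set.seed(31)
  d <- expand_2x2(25, 35, 30, 28)
  d$participant_id <- rep(seq_len(59), length.out = nrow(d))
  spec <- model_spec("anxiety_mod_severe", adjustment_set = character(0),
                     era = "both")
  est <- fit_pooled_logistic(d, spec)
  d2 <- rbind(d, d)  # same cluster ids: each cluster doubled
  est2 <- fit_pooled_logistic(d2, spec)
  expect_equal(est2$point, est$point, tolerance = 1e-8)
  # robust variance reflects the duplication (unchanged), model-based halves
  expect_equal(est2$se_robust, est$se_robust, tolerance = 1e-6)
  expect_equal(est2$se_model^2, est$se_model^2 / 2, tolerance = 1e-6)
})

test_that("missing outcomes and empty strata are refused", {
  cfg <- synthetic_config(150, missing_rate = 0.1, seed = 3)
  pt <- build_person_trials(simulate_cohort(cfg)$assessments)
  spec <- model_spec("anxiety_mod_severe",
                     adjustment_set = "susceptibility", era = "both")
  expect_error(fit_pooled_logistic(pt, spec), "impute first")
  expect_error(
    fit_pooled_logistic(data.frame(), model_spec("gad7_total")),
    "binary outcome")
})

test_that("quasi-separation is reported instead of silently returned", {
  d <- data.frame(outcome_anx_severe = c(rep(1L, 20), rep(0L, 20)),
                  treatment = c(rep(1L, 20), rep(0L, 20)),
                  era = "both", participant_id = 1:40)
  spec <- model_spec("anxiety_mod_severe", adjustment_set = character(0),
                     era = "both")
  expect_error(suppressWarnings(fit_pooled_logistic(d, spec)),
               "quasi-separation")
})

test_that("subgroup analysis filters rows and drops the defining covariate", {
  cfg <- synthetic_config(600, missing_rate = 0, seed = 8)
  pt <- build_person_trials(simulate_cohort(cfg)$assessments)
  spec <- model_spec("anxiety_mod_severe",
                     adjustment_set = c("susceptibility", "anx_t0"),
                     era = "both")
  sg <- subgroup_analysis(pt, spec)
  expect_identical(sg$n_person_trials, as.integer(sum(pt$anx_t0 == 1L,
                                                      na.rm = TRUE)))
  expect_false("anx_t0" %in% attr(terms(sg$fit), "term.labels"))
  empty <- pt[pt$anx_t0 == 0L | is.na(pt$anx_t0)]
  empty$anx_t0 <- 0L
  expect_error(subgroup_analysis(empty, spec), "empty")
})

test_that("wald_heterogeneity matches the closed form and chi-square tail", {
  same <- list(point = 0.5, se_robust = 0.2)
  w0 <- wald_heterogeneity(same, same)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)

  w <- wald_heterogeneity(list(point = 0, se_robust = 0.5),
                          list(point = 1, se_robust = 0.5))
  expect_equal(w$statistic, 2)
  expect_equal(w$p_value, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(round(w$p_value, 3), 0.157)

  expect_error(wald_heterogeneity(list(point = 1, se_robust = 0), same),
               "positive")
  # pooled estimates (total_var) are accepted too
  pe <- rubin_pool(c(0.4, 0.6), c(0.05, 0.05))
  expect_silent(wald_heterogeneity(pe, same))
})

test_that("random-intercept LMM recovers a known subgroup shift", {
  # one observation per participant: fixed effect equals OLS
  set.seed(20)
  n <- 300
  d <- data.frame(
    outcome_gad7 = rnorm(n, 12, 3), treatment = rbinom(n, 1, 0.5),
    susceptibility = rbinom(n, 1, 0.3), era = "both",
    participant_id = seq_len(n))
  d$outcome_gad7 <- d$outcome_gad7 - 1.2 * d$treatment
  spec <- model_spec("gad7_total", adjustment_set = "susceptibility",
                     era = "both")
  lmm <- fit_random_intercept_lmm(d, spec)
  ols <- lm(outcome_gad7 ~ treatment + susceptibility, data = d)
  expect_equal(lmm$point, unname(coef(ols)["treatment"]), tolerance = 1e-4)
  expect_equal(lmm$scale, "score_points")

  # repeated measures with a true participant intercept: shift recovered
  m <- 250
  b <- rnorm(m, 0, 2)
  reps <- data.frame(
    participant_id = rep(seq_len(m), each = 3),
    treatment = rep(rbinom(m, 1, 0.5), each = 3),
    susceptibility = rep(rbinom(m, 1, 0.3), each = 3), era = "both")
  reps$outcome_gad7 <- 12 + rep(b, each = 3) - 1.2 * reps$treatment +
    0.5 * reps$susceptibility + rnorm(nrow(reps), 0, 2)
  lmm2 <- fit_random_intercept_lmm(reps, spec)
  expect_lt(abs(lmm2$point + 1.2), 3 * lmm2$se_model)
})
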
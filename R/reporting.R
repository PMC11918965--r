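## Publication-style outputs: a sociodemographic characteristics table by
## era x vaccination status, effect tables shaped like the motivating
## study's result tables, and JSON writers for the flow summary and report.

#' Sociodemographic characteristics by era and vaccination status
#'
#' Tabulates person-trials into era x treatment columns with counts and
#' column percentages for each categorical covariate, plus mean (SD) and
#' median (IQR) of the GAD-7/PHQ-8 scores as of the most recent measure at
#' time zero.
#'
#' @param person_trials Output of [build_person_trials()].
#' @param covariates Covariate columns to tabulate (default: all baseline
#'   covariates plus the time-updated snapshot columns present).
#' @return A `data.table` in long layout: `variable`, `level`, `column`
#'   (era_arm), `n`, `pct` for categoricals, and `statistic`/`value` rows for
#'   the score summaries.
#' @export
make_table1 <- function(person_trials, covariates = NULL) {
  pt <- as.data.table(person_trials)
  if (is.null(covariates)) {
    covariates <- intersect(
      c(baseline_cols, paste0(time_updated_cols, "_t0"), "anx_t0", "dep_t0"),
      names(pt))
  }
  pt[, column := paste(era, fifelse(treatment == 1L, "vaccinated",
                                    "not_vaccinated"), sep = "_")]
  cat_rows <- rbindlist(lapply(covariates, function(v) {
    tab <- pt[, .(n = .N), by = .(column, level = as.character(get(v)))]
    tab[, pct := 100 * n / sum(n), by = column]
    tab[, variable := v]
    tab
  }), use.names = TRUE)
  score_rows <- rbindlist(lapply(c("gad7_t0", "phq8_t0"), function(v) {
    if (!v %in% names(pt)) return(NULL)
    pt[, .(variable = v,
           mean = mean(get(v), na.rm = TRUE),
           sd = stats::sd(get(v), na.rm = TRUE),
           median = as.numeric(stats::median(get(v), na.rm = TRUE)),
           q1 = as.numeric(stats::quantile(get(v), 0.25, na.rm = TRUE)),
           q3 = as.numeric(stats::quantile(get(v), 0.75, na.rm = TRUE))),
       by = column]
  }), use.names = TRUE)
  pt[, column := NULL]
  list(categorical = cat_rows[, .(variable, level, column, n, pct)],
       scores = score_rows)
}

#' Effect table in the published layout
#'
#' Reshapes a [run_full_analysis()] report into rows of person-trial
#' denominator, outcome count, prevalence (95% CI), crude OR (95% CI) and
#' adjusted OR (95% CI) per outcome, era and arm — the layout of the
#' motivating study's main results tables.
#'
#' @param report A `ttevax_report`.
#' @param analysis `"overall"` or `"subgroup"`.
#' @return A `data.table`.
#' @export
make_table2 <- function(report, analysis = c("overall", "subgroup")) {
  analysis <- match.arg(analysis)
  est <- as.data.table(report$estimates)
  sel <- which(est[["analysis"]] == analysis)  # plain vector: avoids NSE
  est <- est[sel]
  desc <- as.data.table(report$descriptives)
  out <- merge(desc,
               est[, .(outcome, era, aor = or, aor_lo = or_lo, aor_hi = or_hi,
                       crude_or, crude_or_lo, crude_or_hi)],
               by = c("outcome", "era"), all.x = TRUE)
  ## crude / adjusted ORs only apply to the vaccinated row (reference 1.00)
  out[arm == "not_vaccinated",
      c("aor", "aor_lo", "aor_hi", "crude_or", "crude_or_lo",
        "crude_or_hi") := .(1, NA_real_, NA_real_, 1, NA_real_, NA_real_)]
  setcolorder(out, c("outcome", "era", "arm", "denom", "n_severe", "prev",
                     "prev_lo", "prev_hi"))
  out[]
}

#' Write a flow summary as JSON
#'
#' @param flow A `flow_summary` (from [flow_accounting()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_flow_json <- function(flow, path) {
  jsonlite::write_json(unclass(flow), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a full analysis report as JSON
#'
#' Serializes the flow summary, descriptives, pooled estimates and
#' heterogeneity tests; rerunning the pipeline with the same seed reproduces
#' the file byte for byte.
#'
#' @param report A `ttevax_report`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    flow = unclass(report$flow),
    m_used = report$m_used,
    descriptives = report$descriptives,
    estimates = report$estimates,
    heterogeneity = report$heterogeneity
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Published marginal counts from the motivating study
#'
#' Loads the small CSV of published person-trial denominators, outcome
#' counts and flow totals shipped with the package, used to recompute the
#' printed descriptive statistics.
#'
#' @return A `data.table` with columns `table`, `outcome`, `era`, `arm`,
#'   `n_severe`, `denom`.
#' @export
published_counts <- function() {
  path <- system.file("extdata", "published_counts.csv", package = "ttevax",
                      mustWork = TRUE)
  fread(path)
}

#' Published study-flow totals from the motivating study
#'
#' @return A named numeric vector: enrolled participants, eligible
#'   participants, person-trials, vaccinated person-trials, and vaccinated
#'   person-trials in the preuniversal era.
#' @export
published_flow <- function() {
  path <- system.file("extdata", "published_flow.csv", package = "ttevax",
                      mustWork = TRUE)
  x <- fread(path)
  setNames(x$value, x$quantity)
}
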
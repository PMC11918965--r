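## GAD-7 / PHQ-8 scoring and moderate-to-severe classification.
##
## Both screeners use 0-3 item responses; totals range 0-21 (GAD-7, 7 items)
## and 0-24 (PHQ-8, 8 items). A total >= 10 denotes moderate-to-severe
## symptoms, the single cut used throughout this package.

#' Instrument metadata
#'
#' Number of items and maximum total for the supported mental-health
#' screeners.
#'
#' @param instrument `"GAD7"` or `"PHQ8"`.
#' @return A list with `n_items` and `max_total`.
#' @export
#' @examples
#' instrument_info("GAD7")
instrument_info <- function(instrument = c("GAD7", "PHQ8")) {
  instrument <- match.arg(instrument)
  switch(instrument,
    GAD7 = list(n_items = 7L, max_total = 21L),
    PHQ8 = list(n_items = 8L, max_total = 24L)
  )
}

#' Classify a screener total as moderate-to-severe
#'
#' Dichotomizes a GAD-7 or PHQ-8 total at the conventional cut-point:
#' totals at or above `threshold` (default 10) indicate moderate-to-severe
#' symptoms.
#'
#' @param total Integer vector of totals (may contain `NA`).
#' @param instrument `"GAD7"` or `"PHQ8"` (sets the valid range).
#' @param threshold Cut-point; classification is `total >= threshold`.
#' @return Logical vector (`NA` where `total` is `NA`).
#' @export
#' @examples
#' classify_severity(10, "GAD7")   # TRUE: boundary is inclusive
#' classify_severity(9,  "PHQ8")   # FALSE
classify_severity <- function(total, instrument = c("GAD7", "PHQ8"),
                              threshold = 10L) {
  instrument <- match.arg(instrument)
  info <- instrument_info(instrument)
  ok <- is.na(total) | (total >= 0 & total <= info$max_total &
                          total == round(total))
  if (!all(ok)) {
    stop_ttevax("E_SCORE_RANGE",
                "%s total out of range 0..%d at position %d (value %s)",
                instrument, info$max_total, which(!ok)[1],
                format(total[which(!ok)[1]]))
  }
  total >= threshold
}

#' Score a GAD-7 or PHQ-8 item vector
#'
#' Sums the item responses and classifies the total at the
#' moderate-to-severe cut. Item vectors must be complete; any missing item
#' makes the total missing and such records are handled upstream (score-level
#' imputation), never prorated here.
#'
#' @param items Integer vector of item responses, each in 0..3; length 7 for
#'   GAD-7, 8 for PHQ-8.
#' @param instrument `"GAD7"` or `"PHQ8"`.
#' @param threshold Severity cut-point passed to [classify_severity()].
#' @return A list of class `instrument_score` with elements `instrument`,
#'   `total` and `severe`.
#' @export
#' @examples
#' score_instrument(c(2, 1, 1, 2, 0, 1, 2, 1), "PHQ8")  # total 10, severe
score_instrument <- function(items, instrument = c("GAD7", "PHQ8"),
                             threshold = 10L) {
  instrument <- match.arg(instrument)
  info <- instrument_info(instrument)
  if (length(items) != info$n_items) {
    stop_ttevax("E_ITEM_COUNT", "%s expects %d items, got %d",
                instrument, info$n_items, length(items))
  }
  bad <- which(is.na(items) | !(items %in% 0:3))
  if (length(bad)) {
    stop_ttevax("E_ITEM_RANGE",
                "%s item %d is invalid (value %s); items must be in 0..3",
                instrument, bad[1], format(items[bad[1]]))
  }
  total <- as.integer(sum(items))
  structure(
    list(instrument = instrument, total = total,
         severe = classify_severity(total, instrument, threshold)),
    class = "instrument_score"
  )
}

#' @export
print.instrument_score <- function(x, ...) {
  cat(sprintf("%s total %d (%s)\n", x$instrument, x$total,
              if (x$severe) "moderate/severe" else "none/mild"))
  invisible(x)
}

#' Check pre-computed totals against item sums
#'
#' When an assessment table carries both item columns and a total column the
#' two must agree; a silent mismatch would corrupt the outcome definition.
#'
#' @param items Matrix or data.frame of item columns (rows = records).
#' @param totals Integer vector of stated totals (NA allowed where items are
#'   incomplete).
#' @param instrument `"GAD7"` or `"PHQ8"`.
#' @return Invisibly `TRUE`; errors on the first mismatching row.
#' @export
check_totals <- function(items, totals, instrument = c("GAD7", "PHQ8")) {
  instrument <- match.arg(instrument)
  items <- as.matrix(items)
  if (ncol(items) != instrument_info(instrument)$n_items) {
    stop_ttevax("E_ITEM_COUNT", "%s expects %d item columns, got %d",
                instrument, instrument_info(instrument)$n_items, ncol(items))
  }
  sums <- rowSums(items)
  comparable <- !is.na(sums) & !is.na(totals)
  bad <- which(comparable & sums != totals)
  if (length(bad)) {
    stop_ttevax("E_TOTAL_MISMATCH",
                "%s stated total (%d) != item sum (%d) at row %d",
                instrument, totals[bad[1]], sums[bad[1]], bad[1])
  }
  invisible(TRUE)
}
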
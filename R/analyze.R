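# Analysis entry point for user-supplied trial data (wide or long CSV).

#' Analyse a trial with the six-test battery
#'
#' Runs the full battery on trial data in either layout.  With the
#' *wide* layout this is [run_battery()].  With the *long* layout
#' (below-level muscle rows only) the summed-score tests operate on
#' per-participant sums over the rows present -- i.e. totals over the
#' below-level muscles, since at- and above-level scores are not part of
#' the long format; this is recorded in each result's
#' `detail$totals_scope`.  Rows with a missing `y_out`, `y_base` or
#' `y_auto` are dropped row-wise for the transitional test; participants
#' with incomplete data are dropped from the summed-score tests.
#'
#' @param data Trial `data.frame` or CSV path.
#' @param format `"wide"` or `"long"`.
#' @param config Battery configuration, see [run_battery()].
#' @return A `battery_result` of six `ordtrial_test`s.
#' @export
analyze_trial <- function(data, format = c("wide", "long"), config = list()) {
  format <- match.arg(format)
  if (is.character(data)) {
    data <- if (format == "wide") read_cohort_csv(data) else read_rows_long_csv(data)
  }
  if (format == "wide") return(run_battery(data, config))

  rows <- data
  rows_fit <- rows[stats::complete.cases(rows[, c("y_out", "y_base", "y_auto")]), ,
                   drop = FALSE]

  agg <- function(v) tapply(v, rows$participant_id, sum)
  pid <- names(agg(rows$y_out))
  complete <- !is.na(agg(rows$y_out)) & !is.na(agg(rows$y_base))
  y2 <- as.numeric(agg(rows$y_out))[complete]
  y1 <- as.numeric(agg(rows$y_base))[complete]
  arm <- as.numeric(tapply(rows$arm, rows$participant_id, `[`, 1L))[complete]
  delta <- y2 - y1
  scope <- "below-level muscles only"

  mode <- config$i_test_mode %||% "asymptotic"
  iB <- config$i_test_B %||% 9999L
  B <- config$permutations %||% 1000L
  strata_rule <- config$strata %||% "constellation"
  # participant stratum from the long rows: the side-wise motor levels
  ml_of <- tapply(rows$motor_level, rows$participant_id, function(m) {
    u <- unique(m)
    if (strata_rule == "higher_level") segments_uems()[min(seg_index(u))]
    else paste(sort(u), collapse = "/")
  })
  lab <- as.character(ml_of)[complete]

  welch <- function(y, method) {
    yt <- y[arm == 1]; yc <- y[arm == 0]
    if (length(yt) < 2 || length(yc) < 2 ||
        (stats::var(yt) == 0 && stats::var(yc) == 0)) {
      return(new_test_result(method, 0, 1, detail = list(flagged = TRUE,
                                                         totals_scope = scope)))
    }
    tt <- stats::t.test(yt, yc)
    new_test_result(method, unname(tt$statistic), tt$p.value,
                    estimate = mean(yt) - mean(yc),
                    detail = list(df = unname(tt$parameter),
                                  totals_scope = scope))
  }
  anc <- if (stats::var(y1) == 0) {
    r <- welch(y2, "ancova"); r$detail$fallback <- "t_test"; r
  } else {
    fit <- stats::lm(y2 ~ arm + y1)
    cf <- summary(fit)$coefficients
    new_test_result("ancova", cf["arm", "t value"], cf["arm", "Pr(>|t|)"],
                    estimate = cf["arm", "Estimate"],
                    detail = list(totals_scope = scope))
  }

  structure(list(
    t_test = welch(y2, "t_test"),
    t_test_delta = welch(delta, "t_test_delta"),
    i_test = itest_core(y2, arm, lab, mode, iB, "i_test",
                        detail = list(strata_rule = strata_rule,
                                      totals_scope = scope)),
    i_test_delta = itest_core(delta, arm, lab, mode, iB, "i_test_delta",
                              detail = list(strata_rule = strata_rule,
                                            totals_scope = scope)),
    ancova = anc,
    transitional = transitional_permutation_test(rows_fit, B = B,
                                                 options = config$fit_options %||% list())),
    class = "battery_result")
}
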
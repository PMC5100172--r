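# The six treatment-effect analyses applied to one (simulated or real)
# trial: two t-tests and an ANCOVA on summed scores, two stratified
# independence tests, and the transitional-model permutation test.

new_test_result <- function(method, statistic, p_value, estimate = NA_real_,
                            detail = list()) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 estimate = estimate, detail = detail),
            class = "ordtrial_test")
}

#' @export
print.ordtrial_test <- function(x, ...) {
  cat(sprintf("%-12s statistic=%8.4f  p=%.4g%s\n", x$method,
              x$statistic, x$p_value,
              if (isTRUE(x$detail$flagged)) "  [flagged]" else ""))
  invisible(x)
}

#' Summed motor scores per participant
#'
#' Computes the conventional summed endpoints: total follow-up score
#' \eqn{Y^*_2 = \sum_m Y_{m,2}}, total baseline score \eqn{Y^*_1}, and
#' their difference \eqn{Y^{**} = Y^*_2 - Y^*_1}.  Participants with any
#' missing muscle score are excluded (count kept in the
#' `"n_excluded"` attribute).
#'
#' @param records Wide cohort `data.frame`.
#' @return `data.frame` with `id, arm, y_star_1, y_star_2, y_double_star`.
#' @export
total_scores <- function(records) {
  validate_cohort(records)
  b <- as.matrix(records[, muscle_cols("base")])
  f <- as.matrix(records[, muscle_cols("fu")])
  ok <- stats::complete.cases(b) & stats::complete.cases(f)
  out <- data.frame(id = records$id[ok], arm = records$arm[ok],
                    y_star_1 = as.integer(rowSums(b[ok, , drop = FALSE])),
                    y_star_2 = as.integer(rowSums(f[ok, , drop = FALSE])))
  out$y_double_star <- out$y_star_2 - out$y_star_1
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Welch t-test on summed scores
#'
#' Two-sided two-sample Welch t-test comparing the arms on the total
#' follow-up score, or on its change from baseline when
#' `use_delta = TRUE`.  The estimate is mean(treatment) - mean(control).
#'
#' @param records Wide cohort `data.frame`.
#' @param use_delta Test the baseline-to-follow-up change instead of the
#'   follow-up total.
#' @return An `ordtrial_test`.
#' @export
t_test_total <- function(records, use_delta = FALSE) {
  ts <- total_scores(records)
  y <- if (use_delta) ts$y_double_star else ts$y_star_2
  method <- if (use_delta) "t_test_delta" else "t_test"
  yt <- y[ts$arm == 1]; yc <- y[ts$arm == 0]
  detail <- list(n_trt = length(yt), n_ctrl = length(yc),
                 n_excluded = attr(ts, "n_excluded"))
  if (length(yt) < 2 || length(yc) < 2)
    return(new_test_result(method, NA_real_, NA_real_,
                           detail = c(detail, flagged = TRUE)))
  if (stats::var(yt) == 0 && stats::var(yc) == 0) {
    same <- mean(yt) == mean(yc)
    return(new_test_result(method, if (same) 0 else Inf,
                           if (same) 1 else 0,
                           estimate = mean(yt) - mean(yc),
                           detail = c(detail, flagged = !same)))
  }
  tt <- stats::t.test(yt, yc)
  new_test_result(method, unname(tt$statistic), tt$p.value,
                  estimate = mean(yt) - mean(yc),
                  detail = c(detail, df = unname(tt$parameter)))
}

#' Baseline-adjusted ANCOVA on summed scores
#'
#' Ordinary least squares of the total follow-up score on an intercept,
#' the treatment indicator and the total baseline score; the test is the
#' two-sided t-test on the treatment coefficient.  With a constant
#' baseline the model is rank-deficient and the test falls back to the
#' unadjusted [t_test_total()] (recorded in `detail$fallback`).
#'
#' @param records Wide cohort `data.frame`.
#' @return An `ordtrial_test` with method label `"ancova"`.
#' @export
ancova_total <- function(records) {
  ts <- total_scores(records)
  if (nrow(ts) < 3 || stats::var(ts$y_star_1) == 0) {
    res <- t_test_total(records)
    res$method <- "ancova"
    res$detail$fallback <- "t_test"
    return(res)
  }
  fit <- stats::lm(y_star_2 ~ arm + y_star_1, data = ts)
  cf <- summary(fit)$coefficients
  if (!"arm" %in% rownames(cf)) {
    res <- t_test_total(records)
    res$method <- "ancova"
    res$detail$fallback <- "t_test"
    return(res)
  }
  new_test_result("ancova", cf["arm", "t value"], cf["arm", "Pr(>|t|)"],
                  estimate = cf["arm", "Estimate"],
                  detail = list(n = nrow(ts), df = fit$df.residual,
                                n_excluded = attr(ts, "n_excluded")))
}

strata_labels <- function(records, rule = c("constellation", "higher_level")) {
  rule <- match.arg(rule)
  if (rule == "constellation") {
    paste0(records$left_ml, "/", records$right_ml)
  } else {
    segments_uems()[pmin(seg_index(records$left_ml), seg_index(records$right_ml))]
  }
}

#' Stratified conditional independence test on summed scores
#'
#' A conditional test of independence between the summed score and the
#' treatment arm, stratified by motor level.  Within each stratum the
#' linear statistic \eqn{T = \sum_{i: arm_i = 1} y_i} is compared to its
#' permutation expectation and variance given the stratum margins;
#' stratum contributions are added and the standardized statistic
#' \eqn{Z = (T - E) / \sqrt{V}} is referred to the standard normal
#' (`mode = "asymptotic"`) or to `B` random within-stratum relabelings
#' (`mode = "montecarlo"`).  Strata with fewer than two participants, or
#' with all participants in one arm, carry no information and contribute
#' zero variance.
#'
#' @param records Wide cohort `data.frame`.
#' @param use_delta Test the change score instead of the follow-up total.
#' @param strata `"constellation"` (left/right motor-level pair, default)
#'   or `"higher_level"` (the more rostral of the two levels).
#' @param mode Null reference: `"asymptotic"` (default) or
#'   `"montecarlo"`.
#' @param B Relabelings for the Monte-Carlo mode.
#' @return An `ordtrial_test` with method `"i_test"` or
#'   `"i_test_delta"`; `statistic` is Z.
#' @export
stratified_independence_test <- function(records, use_delta = FALSE,
                                         strata = c("constellation", "higher_level"),
                                         mode = c("asymptotic", "montecarlo"),
                                         B = 9999) {
  mode <- match.arg(mode)
  ts <- total_scores(records)
  keep <- match(ts$id, records$id)
  lab <- strata_labels(records[keep, , drop = FALSE], strata)
  y <- if (use_delta) ts$y_double_star else ts$y_star_2
  method <- if (use_delta) "i_test_delta" else "i_test"
  itest_core(y, ts$arm, lab, mode, B, method,
             detail = list(strata_rule = strata,
                           n_excluded = attr(ts, "n_excluded")))
}

# Standardized within-stratum linear statistic and its permutation null.
itest_core <- function(y, arm, lab, mode, B, method, detail = list()) {
  groups <- split(seq_along(y), lab)
  # single-arm or singleton strata contribute T = E exactly (no free
  # relabeling within them), so they drop out of T - E and of V alike.
  stat_parts <- function(arm) {
    Tn <- 0; E <- 0; V <- 0
    for (g in groups) {
      ns <- length(g); ms <- sum(arm[g])
      if (ns < 2 || ms == 0 || ms == ns) next
      ybar <- mean(y[g])
      Tn <- Tn + sum(y[g][arm[g] == 1])
      E <- E + ms * ybar
      V <- V + ms * (ns - ms) / (ns * (ns - 1)) * sum((y[g] - ybar)^2)
    }
    c(Tn, E, V)
  }

  obs <- stat_parts(arm)
  degenerate <- obs[3] <= 0
  Z <- if (degenerate) 0 else (obs[1] - obs[2]) / sqrt(obs[3])
  detail <- c(list(n = length(y), n_strata = length(groups), mode = mode),
              detail)
  if (degenerate) {
    detail$flagged <- TRUE
    return(new_test_result(method, 0, 1, detail = detail))
  }
  if (mode == "asymptotic") {
    p <- 2 * stats::pnorm(-abs(Z))
  } else {
    t_obs <- abs(obs[1] - obs[2])
    cnt <- 0L
    for (b in seq_len(B)) {
      perm <- arm
      for (g in groups) perm[g] <- perm[g][sample.int(length(g))]
      pb <- stat_parts(perm)
      if (abs(pb[1] - pb[2]) >= t_obs - 1e-12) cnt <- cnt + 1L
    }
    p <- (1 + cnt) / (B + 1)
    detail$permutations <- B
  }
  new_test_result(method, Z, min(p, 1), detail = detail)
}

#' Permutation test for the transitional treatment effect
#'
#' Fits the transitional proportional-odds model with a treatment term,
#' then rebuilds the null distribution of \eqn{\hat\beta_{trt}} by
#' permuting the arm allocation across *participants* (all rows of a
#' participant move together, which respects the clustering of muscles
#' within participant) and refitting `B` times.  The two-sided p-value
#' uses the add-one estimator \eqn{(1 + \#\{|\hat\beta^*| \ge
#' |\hat\beta|\}) / (B + 1)}.  Permutation refits are warm-started from
#' the observed optimum; non-converged refits are discarded and the
#' achieved `B` reported, with the result flagged when more than 5% are
#' lost, or when the observed fit itself is flagged.
#'
#' @param records Wide cohort `data.frame`, or long-format rows already
#'   containing a `y_out` column (as from [build_transitional_rows()]).
#' @param B Number of permutations (default 1000).
#' @param options Fitting options passed through, see
#'   [fit_proportional_odds()].
#' @return An `ordtrial_test` with method `"transitional"`; `estimate`
#'   and `statistic` are \eqn{\hat\beta_{trt}}.
#' @export
transitional_permutation_test <- function(records, B = 1000, options = list()) {
  rows <- if ("y_out" %in% names(records)) records
          else build_transitional_rows(records)
  detail <- list(n_rows = nrow(rows), permutations = B)
  if (length(unique(rows$arm)) < 2L)
    return(new_test_result("transitional", NA_real_, NA_real_,
                           detail = c(detail, flagged = TRUE)))

  des <- encode_design(rows, include_treatment = TRUE)
  X <- des$X
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    keep <- sort(dec$pivot[seq_len(dec$rank)])
    if (!"trt" %in% colnames(X)[keep])
      return(new_test_result("transitional", NA_real_, NA_real_,
                             detail = c(detail, flagged = TRUE,
                                        reason = "treatment aliased")))
    X <- X[, keep, drop = FALSE]
  }
  K <- length(des$outcome_levels)
  trt_col <- which(colnames(X) == "trt")
  maxit <- options$maxit %||% 500L
  gtol <- options$gtol %||% 1e-6

  obs <- fit_po_xy(X, des$y, K, maxit = maxit, gtol = gtol)
  beta_hat <- unname(obs$beta[["trt"]])
  if (!obs$converged || obs$separation)
    return(new_test_result("transitional", beta_hat, NA_real_,
                           estimate = beta_hat,
                           detail = c(detail, flagged = TRUE,
                                      reason = "observed fit not converged")))

  pid <- match(rows$participant_id, unique(rows$participant_id))
  arm_p <- rows$arm[match(unique(rows$participant_id), rows$participant_id)]
  beta_star <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    X[, trt_col] <- sample(arm_p)[pid]
    ref <- fit_po_xy(X, des$y, K, start = obs$theta, maxit = maxit, gtol = gtol)
    if (ref$converged && !ref$separation) beta_star[b] <- unname(ref$beta[["trt"]])
  }
  used <- sum(!is.na(beta_star))
  p <- (1 + sum(abs(beta_star) >= abs(beta_hat), na.rm = TRUE)) / (used + 1)
  detail$permutations_used <- used
  detail$flagged <- used < 0.95 * B
  new_test_result("transitional", beta_hat, p, estimate = beta_hat,
                  detail = detail)
}

#' Run the full six-test battery on one trial
#'
#' Applies, in this fixed order: `t_test`, `t_test_delta`, `i_test`,
#' `i_test_delta`, `ancova`, `transitional`.  Individual test failures
#' are flagged in their results, never aborting the battery.
#'
#' @param records Wide cohort `data.frame`.
#' @param config List of settings: `permutations` (B for the
#'   transitional test, default 1000), `strata`, `i_test_mode`,
#'   `i_test_B`, `fit_options`.
#' @return Object of class `battery_result`: a named list of six
#'   `ordtrial_test`s.
#' @export
#' @examples
#' pop <- make_synthetic_population(seed = 1)
#' trial <- simulate_trial(pop, n_total = 40, beta_trt = 0, seed = 11)
#' res <- run_battery(trial, config = list(permutations = 49))
#' vapply(res, function(r) r$p_value, numeric(1))
run_battery <- function(records, config = list()) {
  B <- config$permutations %||% 1000L
  strata <- config$strata %||% "constellation"
  mode <- config$i_test_mode %||% "asymptotic"
  iB <- config$i_test_B %||% 9999L
  fo <- config$fit_options %||% list()
  res <- list(
    t_test = t_test_total(records, use_delta = FALSE),
    t_test_delta = t_test_total(records, use_delta = TRUE),
    i_test = stratified_independence_test(records, FALSE, strata, mode, iB),
    i_test_delta = stratified_independence_test(records, TRUE, strata, mode, iB),
    ancova = ancova_total(records),
    transitional = transitional_permutation_test(records, B = B, options = fo))
  structure(res, class = "battery_result")
}

#' @export
print.battery_result <- function(x, ...) {
  cat("Treatment-effect test battery\n")
  for (r in x) print(r)
  invisible(x)
}

#' @export
as.data.frame.battery_result <- function(x, ...) {
  data.frame(method = vapply(x, `[[`, "", "method"),
             statistic = vapply(x, `[[`, 0, "statistic"),
             p_value = vapply(x, `[[`, 0, "p_value"),
             estimate = vapply(x, `[[`, 0, "estimate"),
             flagged = vapply(x, function(r) isTRUE(r$detail$flagged), NA),
             row.names = NULL)
}

#' Write a battery report as JSON
#'
#' @param battery A `battery_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_battery_json <- function(battery, path) {
  obj <- lapply(unclass(battery), function(r) {
    r["detail"] <- list(r$detail[!vapply(r$detail, is.null, NA)])
    unclass(r)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
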
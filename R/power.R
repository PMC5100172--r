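# Monte-Carlo power machinery: scenario grid, rejection fractions with
# Wilson score intervals, and figure exports.

#' Wilson score interval for a binomial proportion
#'
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}
#'            {1 + z^2/n}}
#' with `z` the two-sided normal quantile of the requested confidence.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level, default 0.95.
#' @return Numeric `c(low, high)`.
#' @export
#' @examples
#' round(wilson_interval(50, 1000), 3)    # 0.038 0.065
#' round(wilson_interval(967, 1000), 3)   # 0.954 0.976
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("successes must lie in 0..n")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c(low = max(0, (centre - half) / denom),
    high = min(1, (centre + half) / denom))
}

# Deterministic 32-bit child seed for replicate r of a scenario; keeps
# replicates individually reproducible and order-independent.
child_seed <- function(root, r) {
  as.integer((as.double(root %% 2147483647L) * 48271 + r * 16807) %% 2147483647)
}

#' Estimate power for one trial scenario
#'
#' Simulates `n_replications` trials under the scenario, runs the test
#' battery on each, and reports per-method rejection fractions at level
#' `alpha` with Wilson confidence intervals.  Each replicate runs on its
#' own child seed derived from `seed`, so results do not depend on
#' execution order.  A replicate whose test is flagged (e.g. the observed
#' transitional fit did not converge) counts as a non-rejection; if a
#' method accumulates more than 1% flagged replicates those are dropped
#' from its denominator instead (both counts are reported).
#'
#' @param pop A [population_model()].
#' @param n_total Total trial size.
#' @param beta_trt Treatment log odds ratio.
#' @param n_replications Number of simulated trials (reference design: 1000).
#' @param alpha Nominal level; rejection is `p <= alpha`.
#' @param seed Root seed of the scenario.
#' @param methods Subset of the six method labels to run.
#' @param config Battery configuration, see [run_battery()].
#' @param confidence Wilson interval confidence, default 0.95.
#' @param progress Print a dot every 50 replicates?
#' @return `data.frame`, one row per method: `n_total, beta_trt, or,
#'   method, rejections, replicates_used, flagged, power, wilson_low,
#'   wilson_high`.
#' @export
run_scenario <- function(pop, n_total, beta_trt, n_replications = 1000,
                         alpha = 0.05, seed = 1,
                         methods = c("t_test", "t_test_delta", "i_test",
                                     "i_test_delta", "ancova", "transitional"),
                         config = list(), confidence = 0.95,
                         progress = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  rej <- stats::setNames(integer(length(methods)), methods)
  flg <- stats::setNames(integer(length(methods)), methods)
  for (r in seq_len(n_replications)) {
    res <- with_seed(child_seed(seed, r), {
      trial <- simulate_trial(pop, n_total, beta_trt)
      run_battery_subset(trial, methods, config)
    })
    for (m in methods) {
      p <- res[[m]]$p_value
      if (isTRUE(res[[m]]$detail$flagged) || is.na(p)) {
        flg[m] <- flg[m] + 1L
      } else if (p <= alpha) {
        rej[m] <- rej[m] + 1L
      }
    }
    if (progress && r %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  used <- ifelse(flg > 0.01 * n_replications, n_replications - flg,
                 n_replications)
  ci <- t(vapply(methods, function(m) wilson_interval(rej[m], used[m], confidence),
                 numeric(2)))
  data.frame(n_total = n_total, beta_trt = beta_trt, or = exp(beta_trt),
             method = methods, rejections = as.integer(rej),
             replicates_used = as.integer(used), flagged = as.integer(flg),
             power = rej / used,
             wilson_low = ci[, 1], wilson_high = ci[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

run_battery_subset <- function(trial, methods, config) {
  B <- config$permutations %||% 1000L
  strata <- config$strata %||% "constellation"
  mode <- config$i_test_mode %||% "asymptotic"
  iB <- config$i_test_B %||% 9999L
  fo <- config$fit_options %||% list()
  res <- list()
  for (m in methods) {
    res[[m]] <- switch(m,
      t_test = t_test_total(trial, FALSE),
      t_test_delta = t_test_total(trial, TRUE),
      i_test = stratified_independence_test(trial, FALSE, strata, mode, iB),
      i_test_delta = stratified_independence_test(trial, TRUE, strata, mode, iB),
      ancova = ancova_total(trial),
      transitional = transitional_permutation_test(trial, B = B, options = fo),
      stop("unknown method: ", m))
  }
  res
}

#' The scenario grid of the reference simulation design
#'
#' Seven total trial sizes (50..200 by 25) crossed with six treatment
#' effects, log odds ratios 0 to log(1.5) in odds-ratio steps of 0.1 --
#' 42 scenarios.
#'
#' @return List with `sizes` and `effects`.
#' @export
default_scenario_grid <- function() {
  list(sizes = seq(50L, 200L, by = 25L),
       effects = log(seq(1.0, 1.5, by = 0.1)))
}

#' Run a grid of power scenarios
#'
#' Cartesian product of `sizes` and `effects`; each scenario gets its own
#' root seed derived from `seed` so the grid can be split or reordered
#' without changing results.
#'
#' @param pop A [population_model()].
#' @param sizes Integer vector of total trial sizes.
#' @param effects Numeric vector of treatment log odds ratios.
#' @param n_replications Replicates per scenario.
#' @param seed Root seed.
#' @inheritParams run_scenario
#' @return Row-bound `data.frame` of [run_scenario()] tables.
#' @export
run_grid <- function(pop, sizes = default_scenario_grid()$sizes,
                     effects = default_scenario_grid()$effects,
                     n_replications = 1000, alpha = 0.05, seed = 1,
                     methods = c("t_test", "t_test_delta", "i_test",
                                 "i_test_delta", "ancova", "transitional"),
                     config = list(), progress = FALSE) {
  if (!length(sizes) || !length(effects)) stop("empty scenario grid")
  out <- list()
  k <- 0L
  for (ef in effects) {
    for (nt in sizes) {
      k <- k + 1L
      if (progress)
        cat(sprintf("scenario %d/%d: n=%d OR=%.1f\n",
                    k, length(sizes) * length(effects), nt, exp(ef)))
      out[[k]] <- run_scenario(pop, nt, ef, n_replications, alpha,
                               seed = child_seed(seed, 100000L + k),
                               methods = methods, config = config)
    }
  }
  do.call(rbind, out)
}

#' Write a power table as CSV
#'
#' @param table Output of [run_grid()] or [run_scenario()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_power_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

open_device <- function(path, width = 9, height = 5) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 110, height = height * 110,
                              res = 110, type = "cairo"),
         stop("unsupported figure format: .", ext))
}

#' Plot the treatment-induced shift in score probabilities
#'
#' Two-panel bar chart of the six outcome-category probabilities under
#' control (left) and treatment (right) for one covariate constellation.
#' The default constellation is a C8 key muscle under a C5 motor level
#' (code `"C5.-3"`), baseline score 1, autoregressive score 3, and an
#' odds ratio of 1.3 -- with a positive effect, low scores lose and high
#' scores gain probability mass.
#'
#' @param coeffs A [coefficient_set()] (its own `beta_trt` is ignored).
#' @param out_path Figure file; `.pdf`, `.svg` or `.png`.
#' @param lev,y_base,y_auto Covariate constellation displayed.
#' @param beta_trt Treatment log odds ratio of the treatment panel.
#' @return Invisibly, the 2x6 matrix of plotted probabilities.
#' @export
plot_score_shift <- function(coeffs, out_path, lev = "C5.-3", y_base = 1,
                             y_auto = 3, beta_trt = log(1.3)) {
  co <- coeffs
  co$beta_trt <- beta_trt
  pr <- rbind(
    control = predict_category_probabilities(co, lev, y_base, y_auto, arm = 0)[1, ],
    treatment = predict_category_probabilities(co, lev, y_base, y_auto, arm = 1)[1, ])
  open_device(out_path)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  ymax <- max(pr) * 1.15
  for (i in 1:2) {
    graphics::barplot(pr[i, ], ylim = c(0, ymax), col = c("grey60", "steelblue")[i],
                      xlab = "motor score", ylab = "probability",
                      main = sprintf("%s arm", rownames(pr)[i]))
    graphics::mtext(sprintf("lev=%s, base=%d, auto=%d%s", lev, y_base, y_auto,
                            if (i == 2) sprintf(", OR=%.2f", exp(beta_trt)) else ""),
                    side = 3, line = 0, cex = 0.8)
  }
  invisible(pr)
}

#' Plot power against trial size
#'
#' One line per method at a fixed treatment effect (default: the median
#' effect present in the table).
#'
#' @param table Power table from [run_grid()].
#' @param out_path Figure file; `.pdf`, `.svg` or `.png`.
#' @param effect Treatment effect (log OR) to display; matched with a
#'   small tolerance.
#' @return Invisibly, the subset of `table` plotted.
#' @export
plot_power_curves <- function(table, out_path, effect = NULL) {
  if (is.null(effect)) {
    efs <- sort(unique(table$beta_trt))
    effect <- efs[ceiling((length(efs) + 1) / 2)]  # upper median, cf. log(1.3)
  }
  sub <- table[abs(table$beta_trt - effect) < 1e-8, , drop = FALSE]
  if (!nrow(sub)) stop("no rows at the requested effect")
  methods <- unique(sub$method)
  sizes <- sort(unique(sub$n_total))
  open_device(out_path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  cols <- grDevices::hcl.colors(max(3, length(methods)), "Dark 3")
  graphics::plot(range(sizes), c(0, 1), type = "n",
                 xlab = "total trial size", ylab = "power",
                 main = sprintf("Power at OR = %.2f", exp(effect)))
  for (j in seq_along(methods)) {
    mi <- sub[sub$method == methods[j], ]
    mi <- mi[order(mi$n_total), ]
    graphics::lines(mi$n_total, mi$power, col = cols[j], lwd = 2)
    graphics::points(mi$n_total, mi$power, col = cols[j], pch = 19)
  }
  graphics::abline(h = 0.05, lty = 3)
  graphics::legend("topleft", legend = methods, col = cols[seq_along(methods)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(sub)
}

#' Heatmap of power over the full size-by-effect grid
#'
#' Raw-grid analog of a contour display (no smoothing: the export is the
#' measured grid itself) for one method.
#'
#' @param table Power table from [run_grid()].
#' @param out_path Figure file.
#' @param method Method label to display.
#' @return Invisibly, the power matrix (sizes x effects).
#' @export
plot_power_grid <- function(table, out_path, method = "transitional") {
  sub <- table[table$method == method, , drop = FALSE]
  if (!nrow(sub)) stop("method not present in table: ", method)
  sizes <- sort(unique(sub$n_total))
  effects <- sort(unique(sub$beta_trt))
  z <- matrix(NA_real_, length(sizes), length(effects))
  for (i in seq_along(sizes)) {
    for (j in seq_along(effects)) {
      v <- sub$power[sub$n_total == sizes[i] & abs(sub$beta_trt - effects[j]) < 1e-8]
      if (length(v)) z[i, j] <- v[1]
    }
  }
  open_device(out_path, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  graphics::filled.contour(sizes, effects, z,
                           color.palette = function(n) grDevices::hcl.colors(n, "Blues 3", rev = TRUE),
                           xlab = "total trial size", ylab = "treatment effect (log OR)",
                           main = sprintf("Power: %s", method))
  invisible(z)
}
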
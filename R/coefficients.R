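# Parameter container for the cumulative-logit transitional model.

#' Construct a coefficient set for the transitional proportional-odds model
#'
#' The model for one analysed muscle is
#' \deqn{logit P(Y \le k) = \alpha_{k+1} - \eta,\qquad
#'       \eta = \beta_{lev}(x_{lev}) + \beta_{base}(y_{base}) +
#'              \beta_{auto}(y_{auto}) + \beta_{trt}\, x_{trt},}
#' so positive slopes push probability mass toward *higher* outcome scores
#' (a positive treatment effect means better recovery).  `exp(beta_trt)`
#' is the conditional odds ratio between arms.
#'
#' @param cutpoints Strictly increasing numeric vector, one fewer entries
#'   than outcome categories (5 cutpoints for the 0..5 score scale).
#' @param beta_lev Named numeric over the codes of [lev_levels()]; the
#'   reference `"C5.-1"` must be 0.  Missing names are filled with 0.
#' @param beta_base,beta_auto Named numeric over score levels `"0"`..`"5"`
#'   with `"0"` fixed at 0.  Missing names are filled with 0.
#' @param beta_trt Treatment log odds ratio (0 = no effect).
#' @param outcome_levels Integer vector of outcome categories the
#'   cutpoints refer to; defaults to `0:5`.
#' @return An object of class `coefficient_set`.
#' @export
#' @examples
#' cs <- coefficient_set(cutpoints = qlogis((1:5) / 6))
#' predict_category_probabilities(cs, "C5.-1", 0, 0, 0)  # uniform 1/6
coefficient_set <- function(cutpoints,
                            beta_lev = NULL,
                            beta_base = NULL,
                            beta_auto = NULL,
                            beta_trt = 0,
                            outcome_levels = 0:5) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) != length(outcome_levels) - 1L)
    stop("need length(outcome_levels) - 1 cutpoints")
  if (any(diff(cutpoints) <= 0))
    stop("cutpoints must be strictly increasing")
  beta_lev <- fill_named(beta_lev, lev_levels(), "beta_lev")
  score_lv <- as.character(0:5)
  beta_base <- fill_named(beta_base, score_lv, "beta_base")
  beta_auto <- fill_named(beta_auto, score_lv, "beta_auto")
  if (beta_lev[["C5.-1"]] != 0) stop("beta_lev reference C5.-1 must be 0")
  if (beta_base[["0"]] != 0 || beta_auto[["0"]] != 0)
    stop("beta_base/beta_auto reference level 0 must be 0")
  structure(
    list(cutpoints = cutpoints, beta_lev = beta_lev, beta_base = beta_base,
         beta_auto = beta_auto, beta_trt = as.numeric(beta_trt),
         outcome_levels = as.integer(outcome_levels)),
    class = "coefficient_set")
}

fill_named <- function(x, nm, what) {
  out <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(x)) {
    if (is.null(names(x))) stop(what, " must be a named vector")
    bad <- setdiff(names(x), nm)
    if (length(bad)) stop(what, ": unknown level(s) ", paste(bad, collapse = ", "))
    out[names(x)] <- as.numeric(x)
  }
  out
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("Transitional proportional-odds coefficients\n")
  cat("  cutpoints:", paste(sprintf("%.3f", x$cutpoints), collapse = " "), "\n")
  cat("  beta_trt :", sprintf("%.4f (OR %.3f)", x$beta_trt, exp(x$beta_trt)), "\n")
  cat("  non-zero lev/base/auto terms:",
      sum(x$beta_lev != 0), "/", sum(x$beta_base != 0), "/",
      sum(x$beta_auto != 0), "\n")
  invisible(x)
}

# Linear predictor eta for vectors of covariates.
linear_predictor <- function(coeffs, lev, y_base, y_auto, arm) {
  unname(coeffs$beta_lev[lev] +
           coeffs$beta_base[as.character(y_base)] +
           coeffs$beta_auto[as.character(y_auto)] +
           coeffs$beta_trt * arm)
}

#' Category probabilities under a coefficient set
#'
#' Evaluates the six outcome-category probabilities for one or more
#' covariate settings.  Cumulative probabilities are
#' `plogis(cutpoint - eta)` and the category probabilities their adjacent
#' differences, with the top category closing the telescope at 1.
#'
#' @param coeffs A [coefficient_set()].
#' @param lev Motor-level/distance code(s), see [lev_code()].
#' @param y_base Baseline score(s) 0..5 of the same muscle.
#' @param y_auto Follow-up score(s) 0..5 of the muscle just rostral.
#' @param arm 0 (control) or 1 (treatment).
#' @return A numeric matrix, one row per covariate setting, columns named
#'   by outcome category; rows sum to 1.
#' @export
predict_category_probabilities <- function(coeffs, lev, y_base, y_auto, arm = 0) {
  eta <- linear_predictor(coeffs, lev, y_base, y_auto, arm)
  K <- length(coeffs$outcome_levels)
  cum <- stats::plogis(outer(eta, coeffs$cutpoints, function(e, a) a - e))
  cum <- cbind(cum, 1)
  pr <- cum - cbind(0, cum[, -K, drop = FALSE])
  colnames(pr) <- as.character(coeffs$outcome_levels)
  pr
}

#' Draw outcome scores from the transitional model
#'
#' One draw per covariate setting, via a single uniform deviate and the
#' inverse CDF.  Consuming exactly one deviate per draw keeps parallel
#' simulation arms on identical random streams: changing `beta_trt` never
#' shifts the stream seen by control participants.
#'
#' @inheritParams predict_category_probabilities
#' @return Integer vector of scores.
#' @export
sample_score <- function(coeffs, lev, y_base, y_auto, arm = 0) {
  pr <- predict_category_probabilities(coeffs, lev, y_base, y_auto, arm)
  u <- stats::runif(nrow(pr))
  cum <- pr
  for (j in seq_len(ncol(pr))[-1]) cum[, j] <- cum[, j - 1] + pr[, j]
  idx <- rowSums(u > cum[, -ncol(cum), drop = FALSE]) + 1L
  coeffs$outcome_levels[idx]
}

#' Export / import a coefficient set as JSON
#'
#' Levels are written with explicit labels (`"lev:C6.-2"`, `"base:3"`,
#' `"auto:1"`) so files are self-describing and robust to level order.
#'
#' @param coeffs A [coefficient_set()].
#' @param path File path.
#' @return `write_coefficients_json` returns `path` invisibly;
#'   `read_coefficients_json` returns a [coefficient_set()].
#' @export
write_coefficients_json <- function(coeffs, path) {
  slopes <- c(
    stats::setNames(as.list(coeffs$beta_lev), paste0("lev:", names(coeffs$beta_lev))),
    stats::setNames(as.list(coeffs$beta_base), paste0("base:", names(coeffs$beta_base))),
    stats::setNames(as.list(coeffs$beta_auto), paste0("auto:", names(coeffs$beta_auto))))
  obj <- list(cutpoints = coeffs$cutpoints,
              outcome_levels = coeffs$outcome_levels,
              beta_trt = coeffs$beta_trt,
              slopes = slopes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_coefficients_json
#' @export
read_coefficients_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sl <- unlist(obj$slopes)
  pick <- function(prefix) {
    keep <- startsWith(names(sl), prefix)
    stats::setNames(sl[keep], substring(names(sl)[keep], nchar(prefix) + 1L))
  }
  coefficient_set(cutpoints = obj$cutpoints,
                  beta_lev = pick("lev:"),
                  beta_base = pick("base:"),
                  beta_auto = pick("auto:"),
                  beta_trt = obj$beta_trt,
                  outcome_levels = obj$outcome_levels)
}
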
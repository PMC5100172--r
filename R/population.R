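# Reference-population model: everything the trial simulator needs.
#
# A real trial simulator would be parameterized from an observational
# cohort (motor-level constellation frequencies, baseline score vectors,
# at-level follow-up frequencies, transitional-model coefficients).  Such
# cohorts are not redistributable, so the package ships a synthetic
# generator whose defaults emulate the qualitative structure of cervical
# SCI recovery data: lower scores with increasing distance below the
# motor level, near-normal strength above it, and spontaneous recovery
# between baseline and follow-up.

#' Default configuration of the synthetic population generator
#'
#' Returns the full default config as a named list; any subset of these
#' entries may be overridden via the `config` argument of
#' [make_synthetic_population()] or a JSON file.
#'
#' Entries:
#' \describe{
#'   \item{ml_marginals}{Per-segment marginal motor-level probabilities
#'     (C5..T1), one body side.}
#'   \item{concordance}{Log-weight boost for identical left/right motor
#'     levels; left/right levels are correlated in real cohorts.}
#'   \item{constellation_weights}{Optional explicit named weights
#'     (`"C5/C6"` = left/right); overrides the marginal construction.
#'     `"T1/T1"` must have weight 0: such participants contribute no
#'     below-level muscle and are excluded by design.}
#'   \item{at_ml_weights}{Follow-up score weights (scores 0..5) for the
#'     muscle at the motor level; a 6-vector shared by all segments or a
#'     5x6 matrix (rows C5..T1).}
#'   \item{at_ml_baseline_weights}{Baseline score weights for the at-level
#'     muscle (mass on 3..5: the exam definition implies moderate
#'     strength at the level).}
#'   \item{spared_prob}{Per distance 1..4 below the level, probability
#'     that a below-level muscle is partially spared at baseline.}
#'   \item{spared_weights, weak_weights}{Baseline score weights for
#'     spared (mass on 3..5) and non-spared (mass on 0..2) below-level
#'     muscles.}
#'   \item{baseline_pool_size}{Baseline vectors generated per
#'     constellation.}
#'   \item{coefficients}{Either explicit `cutpoints`/`beta_lev`/
#'     `beta_base`/`beta_auto`, or the compact form `cutpoints` plus
#'     `lev_dist_step`, `lev_ml_step`, `base_step`, `auto_step` from
#'     which the per-level effects are built linearly.}
#' }
#'
#' @return Named list.
#' @export
default_population_config <- function() {
  list(
    ml_marginals = c(C5 = 0.40, C6 = 0.25, C7 = 0.15, C8 = 0.10, T1 = 0.10),
    concordance = 2,
    constellation_weights = NULL,
    at_ml_weights = c(2, 3, 6, 22, 34, 33),
    at_ml_baseline_weights = c(0, 0, 0, 40, 35, 25),
    spared_prob = c(0.35, 0.25, 0.18, 0.12),
    spared_weights = c(0, 0, 0, 40, 40, 20),
    weak_weights = c(60, 30, 10, 0, 0, 0),
    baseline_pool_size = 50,
    coefficients = list(
      cutpoints = c(-0.2, 1.0, 2.0, 3.0, 4.2),
      lev_dist_step = -0.5,
      lev_ml_step = -0.15,
      base_step = 0.5,
      auto_step = 0.5))
}

#' Construct a population model
#'
#' Low-level validating constructor; most users will call
#' [make_synthetic_population()] or [estimate_population_from_cohort()].
#'
#' @param constellation_freq Named probabilities over left/right
#'   motor-level constellations (`"C5/C6"` style labels); must exclude
#'   `"T1/T1"` and sum to 1 (renormalized exactly on construction).
#' @param baseline_pool Named list, one entry per constellation with
#'   positive frequency: a matrix of baseline vectors (columns `L_C5` ..
#'   `R_T1`, scores 0..5), sampled from with replacement.
#' @param at_ml_freq 5x6 matrix (rows C5..T1) of follow-up score
#'   probabilities for the at-level muscle; rows sum to 1.
#' @param coefficients A [coefficient_set()] with `beta_trt = 0`
#'   (spontaneous recovery only; treatment is injected at simulation
#'   time).
#' @return Object of class `population_model`.
#' @export
population_model <- function(constellation_freq, baseline_pool,
                             at_ml_freq, coefficients) {
  labs <- constellation_labels(include_t1t1 = TRUE)
  if (is.null(names(constellation_freq)) ||
      !all(names(constellation_freq) %in% labs))
    stop("constellation_freq: names must be constellation labels like 'C5/C6'")
  if (any(constellation_freq < 0))
    stop("constellation_freq: negative probability")
  if (isTRUE(constellation_freq["T1/T1"] > 0))
    stop("constellation_freq: (T1,T1) must have probability 0")
  s <- sum(constellation_freq)
  if (s <= 0) stop("constellation_freq: weights sum to zero")
  constellation_freq <- constellation_freq[setdiff(names(constellation_freq), "T1/T1")]
  constellation_freq <- constellation_freq / sum(constellation_freq)

  active <- names(constellation_freq)[constellation_freq > 0]
  miss <- setdiff(active, names(baseline_pool))
  if (length(miss))
    stop("baseline_pool: missing pool for constellation(s) ",
         paste(miss, collapse = ", "))
  for (cl in active) {
    pool <- baseline_pool[[cl]]
    if (!is.matrix(pool) || ncol(pool) != 10L || nrow(pool) < 1L)
      stop("baseline_pool[['", cl, "']]: need a non-empty matrix with 10 columns")
    if (any(pool < 0 | pool > 5 | pool != round(pool)))
      stop("baseline_pool[['", cl, "']]: scores must be integers in 0..5")
  }

  at_ml_freq <- as.matrix(at_ml_freq)
  if (!all(dim(at_ml_freq) == c(5L, 6L)))
    stop("at_ml_freq: need a 5x6 matrix (segments x scores)")
  if (any(at_ml_freq < 0)) stop("at_ml_freq: negative probability")
  rs <- rowSums(at_ml_freq)
  if (any(rs <= 0)) stop("at_ml_freq: a row sums to zero")
  at_ml_freq <- sweep(at_ml_freq, 1, rs, "/")
  dimnames(at_ml_freq) <- list(segments_uems(), as.character(0:5))

  if (!inherits(coefficients, "coefficient_set"))
    stop("coefficients: need a coefficient_set")
  if (coefficients$beta_trt != 0)
    stop("coefficients: population model must have beta_trt = 0")

  structure(list(constellation_freq = constellation_freq,
                 baseline_pool = baseline_pool,
                 at_ml_freq = at_ml_freq,
                 coefficients = coefficients),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model for trial simulation\n")
  cat(sprintf("  constellations with mass: %d (of 24 valid)\n",
              sum(x$constellation_freq > 0)))
  sizes <- vapply(x$baseline_pool, nrow, 0L)
  cat(sprintf("  baseline pools: %d, sizes %d..%d\n",
              length(sizes), min(sizes), max(sizes)))
  cat(sprintf("  coefficients: %d cutpoints, beta_trt fixed at 0\n",
              length(x$coefficients$cutpoints)))
  invisible(x)
}

#' Generate a synthetic reference population
#'
#' Builds a fully specified [population_model()] from a configuration
#' (see [default_population_config()]) and a seed.  Constellation
#' frequencies and coefficients are deterministic functions of the
#' config; baseline pools are drawn stochastically, so different seeds
#' give different pools under identical frequencies.  The generator
#' leaves the caller's RNG state untouched.
#'
#' @param config Named list overriding entries of
#'   [default_population_config()], or a path handled by
#'   [read_population_config()] upstream.
#' @param seed Integer seed for pool generation.
#' @return A `population_model`.
#' @export
#' @examples
#' pop <- make_synthetic_population(seed = 1)
#' sum(pop$constellation_freq)   # 1
make_synthetic_population <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(default_population_config(), config)
  check_weights <- function(w, field, len = NULL) {
    if (!is.null(len) && length(w) != len)
      stop(field, ": expected length ", len)
    if (any(w < 0)) stop(field, ": negative weight")
    if (sum(w) <= 0) stop(field, ": weights sum to zero")
    w
  }

  # constellation frequencies: explicit weights, or marginals + concordance
  labs <- constellation_labels()
  if (!is.null(cfg$constellation_weights)) {
    w <- unlist(cfg$constellation_weights)
    if (isTRUE(w["T1/T1"] > 0))
      stop("constellation_weights: (T1,T1) must have weight 0")
    bad <- setdiff(names(w), constellation_labels(include_t1t1 = TRUE))
    if (length(bad))
      stop("constellation_weights: unknown label(s) ", paste(bad, collapse = ", "))
    freq <- stats::setNames(numeric(length(labs)), labs)
    freq[intersect(names(w), labs)] <- w[intersect(names(w), labs)]
    check_weights(freq, "constellation_weights")
  } else {
    m <- cfg$ml_marginals
    if (!is.null(names(m)) && all(segments_uems() %in% names(m)))
      m <- m[segments_uems()]                    # accept any name order
    m <- check_weights(m, "ml_marginals", 5L)
    m <- m / sum(m)
    cl <- split_constellation(labs)
    freq <- m[seg_index(cl$left)] * m[seg_index(cl$right)] *
      exp(cfg$concordance * (cl$left == cl$right))
    names(freq) <- labs
  }
  freq <- freq / sum(freq)

  at_w <- cfg$at_ml_weights
  at_ml <- if (is.matrix(at_w)) at_w else matrix(at_w, 5, 6, byrow = TRUE)
  for (i in 1:5) check_weights(at_ml[i, ], "at_ml_weights")
  check_weights(cfg$at_ml_baseline_weights, "at_ml_baseline_weights", 6L)
  check_weights(cfg$spared_weights, "spared_weights", 6L)
  check_weights(cfg$weak_weights, "weak_weights", 6L)
  if (length(cfg$spared_prob) != 4L || any(cfg$spared_prob < 0 | cfg$spared_prob > 1))
    stop("spared_prob: need 4 probabilities in [0,1]")

  coeffs <- build_config_coefficients(cfg$coefficients)

  pools <- with_seed(seed, {
    out <- list()
    for (cl in names(freq)[freq > 0]) {
      out[[cl]] <- synth_baseline_pool(cl, cfg)
    }
    out
  })

  population_model(freq, pools, at_ml, coeffs)
}

build_config_coefficients <- function(cc) {
  if (inherits(cc, "coefficient_set")) {
    if (cc$beta_trt != 0) stop("coefficients: beta_trt must be 0 in a population")
    return(cc)
  }
  if (!is.null(cc$beta_lev) || !is.null(cc$beta_base) || !is.null(cc$beta_auto)) {
    return(coefficient_set(cutpoints = cc$cutpoints,
                           beta_lev = unlist(cc$beta_lev),
                           beta_base = unlist(cc$beta_base),
                           beta_auto = unlist(cc$beta_auto)))
  }
  codes <- lev_levels()
  parts <- strsplit(codes, ".", fixed = TRUE)
  ml_idx <- seg_index(vapply(parts, `[`, "", 1L))
  dist <- -as.integer(vapply(parts, `[`, "", 2L))
  beta_lev <- stats::setNames(
    cc$lev_dist_step * (dist - 1L) + cc$lev_ml_step * (ml_idx - 1L), codes)
  beta_lev <- beta_lev - beta_lev[["C5.-1"]]
  sc <- 0:5
  coefficient_set(
    cutpoints = cc$cutpoints,
    beta_lev = beta_lev,
    beta_base = stats::setNames(cc$base_step * sc, sc),
    beta_auto = stats::setNames(cc$auto_step * sc, sc))
}

# One constellation's pool of baseline vectors.  Above-level muscles are
# intact (5); the at-level muscle gets moderate strength; below-level
# muscles are a spared/weak mixture with sparing decaying with distance.
synth_baseline_pool <- function(label, cfg) {
  cl <- split_constellation(label)
  n <- cfg$baseline_pool_size
  pool <- matrix(0L, n, 10L,
                 dimnames = list(NULL, sub("^base_", "", muscle_cols("base"))))
  draw <- function(n, w) sample(0:5, n, replace = TRUE, prob = w / sum(w))
  for (side in 1:2) {
    ml <- seg_index(c(cl$left, cl$right)[side])
    for (s in 1:5) {
      col <- (side - 1L) * 5L + s
      if (s < ml) {
        pool[, col] <- 5L
      } else if (s == ml) {
        pool[, col] <- draw(n, cfg$at_ml_baseline_weights)
      } else {
        d <- s - ml
        spared <- stats::runif(n) < cfg$spared_prob[d]
        v <- draw(n, cfg$weak_weights)
        if (any(spared)) v[spared] <- draw(sum(spared), cfg$spared_weights)
        pool[, col] <- v
      }
    }
  }
  pool
}

#' Estimate a population model from an observed cohort
#'
#' The empirical counterpart of [make_synthetic_population()]: takes a
#' wide cohort with both timepoints and extracts (i) the relative
#' frequencies of left/right motor-level constellations, after removing
#' (T1,T1) participants, who contribute no analysable muscle; (ii) the
#' observed baseline vectors grouped by constellation, used later as
#' resampling pools; (iii) the follow-up score frequencies of the
#' at-level muscle per segment; and (iv) the transitional-model
#' coefficients fitted without a treatment term.
#'
#' @param records Wide cohort `data.frame` (see [read_cohort_csv()]).
#' @return A `population_model`.
#' @export
estimate_population_from_cohort <- function(records) {
  validate_cohort(records)
  if (!nrow(records)) stop("empty cohort")
  t1t1 <- records$left_ml == "T1" & records$right_ml == "T1"
  records <- records[!t1t1, , drop = FALSE]
  if (!nrow(records))
    stop("all participants have motor level (T1,T1): nothing to analyse")

  lab <- paste0(records$left_ml, "/", records$right_ml)
  labs <- constellation_labels()
  freq <- stats::setNames(numeric(length(labs)), labs)
  tab <- table(lab)
  freq[names(tab)] <- as.numeric(tab) / nrow(records)

  base <- as.matrix(records[, muscle_cols("base")])
  colnames(base) <- sub("^base_", "", colnames(base))
  pools <- lapply(split(seq_len(nrow(records)), lab),
                  function(i) base[i, , drop = FALSE])

  segs <- segments_uems()
  at_ml <- matrix(1 / 6, 5, 6, dimnames = list(segs, as.character(0:5)))
  unseen <- character(0)
  for (s in 1:5) {
    sc <- c(records[[paste0("fu_L_", segs[s])]][records$left_ml == segs[s]],
            records[[paste0("fu_R_", segs[s])]][records$right_ml == segs[s]])
    if (length(sc)) {
      at_ml[s, ] <- tabulate(sc + 1L, 6L) / length(sc)
    } else {
      unseen <- c(unseen, segs[s])   # uniform placeholder, never sampled
    }
  }

  fit <- fit_proportional_odds(build_transitional_rows(records),
                               include_treatment = FALSE)
  pm <- population_model(freq, pools, at_ml, fit$coefficients)
  attr(pm, "fit") <- fit
  attr(pm, "at_ml_unobserved") <- unseen
  pm
}

#' Read a population generator config from JSON
#'
#' @param path JSON file with any subset of the entries of
#'   [default_population_config()].
#' @return Named list suitable for [make_synthetic_population()].
#' @export
read_population_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON objects arrive as named lists; flatten the numeric-leaf entries
  flat <- c("ml_marginals", "constellation_weights", "at_ml_weights",
            "at_ml_baseline_weights", "spared_prob", "spared_weights",
            "weak_weights")
  for (f in intersect(flat, names(cfg)))
    if (is.list(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  if (is.list(cfg$coefficients))
    cfg$coefficients <- lapply(cfg$coefficients,
                               function(x) if (is.list(x)) unlist(x) else x)
  cfg$comment <- NULL
  cfg
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
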
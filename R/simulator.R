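# Two-arm trial simulation from a population model.
#
# Per participant and side, follow-up scores are built rostral to caudal:
# muscles above the motor level stay intact (score 5), the at-level
# muscle is drawn from the population's at-level frequencies (same law in
# both arms), and every below-level muscle is drawn from the transitional
# model conditional on its own baseline score and the follow-up score
# just simulated for the muscle above it.  The treatment effect enters
# only through beta_trt on below-level muscles of treatment-arm
# participants.
#
# Every random draw consumes exactly one uniform deviate and the order
# of consumption depends only on motor levels, never on beta_trt or arm,
# so control-arm participants are byte-identical across treatment-effect
# settings under the same seed.

#' Draw motor-level constellations
#'
#' i.i.d. multinomial draws from the population's constellation
#' frequencies; (T1,T1) has probability zero by construction and is never
#' produced.
#'
#' @param pop A [population_model()].
#' @param n Number of participants.
#' @return `data.frame` with columns `left_ml`, `right_ml`.
#' @export
sample_motor_levels <- function(pop, n) {
  lab <- sample(names(pop$constellation_freq), n, replace = TRUE,
                prob = pop$constellation_freq)
  cl <- split_constellation(lab)
  data.frame(left_ml = cl$left, right_ml = cl$right, stringsAsFactors = FALSE)
}

#' Draw baseline score vectors
#'
#' Samples, uniformly with replacement, one stored baseline vector per
#' participant from the pool matching that participant's constellation.
#'
#' @param pop A [population_model()].
#' @param constellations `data.frame` as returned by
#'   [sample_motor_levels()].
#' @return Integer matrix, one row per participant, columns `L_C5..R_T1`.
#' @export
sample_baseline <- function(pop, constellations) {
  lab <- paste0(constellations$left_ml, "/", constellations$right_ml)
  n <- length(lab)
  out <- matrix(0L, n, 10L, dimnames = list(NULL, sub("^base_", "", muscle_cols("base"))))
  u <- stats::runif(n)
  for (cl in unique(lab)) {
    pool <- pop$baseline_pool[[cl]]
    if (is.null(pool) || !nrow(pool))
      stop("no baseline pool for constellation ", cl)
    i <- which(lab == cl)
    out[i, ] <- pool[1L + floor(u[i] * nrow(pool)), , drop = FALSE]
  }
  out
}

#' Allocate treatment arms 1:1
#'
#' Exact-balance allocation: a random permutation of
#' `floor(n/2)` treatment and `ceiling(n/2)` control labels (for even `n`
#' the arms are exactly equal).
#'
#' @param n Number of participants (>= 2).
#' @return Integer vector of 0 (control) / 1 (treatment).
#' @export
allocate_arms <- function(n) {
  if (n < 2) stop("need at least 2 participants")
  sample(rep(0:1, length.out = n))
}

#' Simulate follow-up scores for a baseline-complete cohort
#'
#' Completes records that already carry arm, motor levels and baseline
#' scores, per the scheme described above.  `beta_trt` is the postulated
#' treatment log odds ratio applied to below-level muscles of
#' treatment-arm participants; the control-arm generating law does not
#' depend on it.
#'
#' @param pop A [population_model()].
#' @param records `data.frame` with `id, arm, left_ml, right_ml` and the
#'   ten `base_*` columns.
#' @param beta_trt Treatment effect on the log-odds scale.
#' @return `records` with the ten `fu_*` columns filled in.
#' @export
simulate_followup <- function(pop, records, beta_trt = 0) {
  segs <- segments_uems()
  n <- nrow(records)
  co <- pop$coefficients
  co$beta_trt <- beta_trt
  for (side in c("L", "R")) {
    ml_idx <- seg_index(records[[if (side == "L") "left_ml" else "right_ml"]])
    fu <- matrix(5L, n, 5L)
    for (s in 1:5) {
      at <- which(ml_idx == s)
      if (length(at)) {
        cp <- cumsum(pop$at_ml_freq[s, ])[1:5]
        fu[at, s] <- findInterval(stats::runif(length(at)), cp)
      }
      below <- which(ml_idx < s & ml_idx <= 4L)
      if (length(below)) {
        fu[below, s] <- sample_score(
          co,
          lev = lev_code(segs[ml_idx[below]], segs[s]),
          y_base = records[[paste0("base_", side, "_", segs[s])]][below],
          y_auto = fu[below, s - 1L],
          arm = records$arm[below])
      }
    }
    for (s in 1:5) records[[paste0("fu_", side, "_", segs[s])]] <- fu[, s]
  }
  records
}

#' Simulate one two-arm randomized trial
#'
#' Composes the full pipeline: constellations, baseline resampling, 1:1
#' arm allocation, and follow-up simulation with the treatment effect
#' acting through the transitional model.
#'
#' @param pop A [population_model()].
#' @param n_total Total trial size (both arms).
#' @param beta_trt Treatment log odds ratio (0 = null trial).
#' @param seed Optional integer; if given, the trial is generated under
#'   this seed and the caller's RNG state is untouched.  If `NULL`, the
#'   current RNG stream is used (and advanced).
#' @return Wide cohort `data.frame` (see [read_cohort_csv()]).
#' @export
#' @examples
#' pop <- make_synthetic_population(seed = 1)
#' trial <- simulate_trial(pop, n_total = 50, beta_trt = log(1.3), seed = 7)
#' table(trial$arm)
simulate_trial <- function(pop, n_total, beta_trt = 0, seed = NULL) {
  go <- function() {
    cons <- sample_motor_levels(pop, n_total)
    base <- sample_baseline(pop, cons)
    arms <- allocate_arms(n_total)
    rec <- data.frame(id = seq_len(n_total), arm = arms,
                      left_ml = cons$left_ml, right_ml = cons$right_ml,
                      stringsAsFactors = FALSE)
    for (j in 1:10) rec[[muscle_cols("base")[j]]] <- base[, j]
    simulate_followup(pop, rec, beta_trt)
  }
  if (is.null(seed)) go() else with_seed(seed, go())
}
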
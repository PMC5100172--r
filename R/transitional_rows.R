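# Long-format construction: one row per analysed (below-level) muscle.

#' Build the long-format rows of the transitional model
#'
#' Expands a wide cohort (one row per participant, 10 baseline and 10
#' follow-up scores) into the muscle-level long format the transitional
#' model is fitted on.  Per side, one row is produced for every key muscle
#' strictly below that side's motor level.  The autoregressive covariate
#' `y_auto` of a row is the *follow-up* score of the muscle just rostral
#' to it: the at-level muscle for distance -1, otherwise the previous
#' below-level muscle.  A side with motor level T1 contributes no rows.
#'
#' @param records Wide cohort `data.frame`; see [read_cohort_csv()] for
#'   the column layout (`id, arm, left_ml, right_ml, base_L_C5..fu_R_T1`).
#' @return `data.frame` with columns `participant_id, side, segment,
#'   motor_level, lev, y_base, y_auto, y_out, arm`.
#' @export
#' @examples
#' pop <- make_synthetic_population(seed = 1)
#' trial <- simulate_trial(pop, n_total = 8, beta_trt = 0, seed = 2)
#' rows <- build_transitional_rows(trial)
#' table(rows$lev)
build_transitional_rows <- function(records) {
  validate_cohort(records)
  segs <- segments_uems()
  out <- vector("list", 8L)
  k <- 0L
  for (side in c("L", "R")) {
    ml <- records[[if (side == "L") "left_ml" else "right_ml"]]
    ml_idx <- seg_index(ml)
    for (s in 2:5) {
      sel <- which(ml_idx < s & ml_idx <= 4L)
      if (!length(sel)) next
      base_col <- paste0("base_", side, "_", segs[s])
      fu_col <- paste0("fu_", side, "_", segs[s])
      auto_col <- paste0("fu_", side, "_", segs[s - 1L])
      k <- k + 1L
      out[[k]] <- data.frame(
        participant_id = records$id[sel],
        side = side,
        segment = segs[s],
        motor_level = ml[sel],
        lev = lev_code(ml[sel], segs[s]),
        y_base = records[[base_col]][sel],
        y_auto = records[[auto_col]][sel],
        y_out = records[[fu_col]][sel],
        arm = records$arm[sel],
        stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, out[seq_len(k)])
  if (is.null(rows)) {
    stop("no below-level muscles: every side has motor level T1")
  }
  rows <- rows[order(match(rows$participant_id, records$id), rows$side,
                     seg_index(rows$segment)), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

validate_cohort <- function(records) {
  need <- c("id", "arm", "left_ml", "right_ml",
            muscle_cols("base"), muscle_cols("fu"))
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  seg_index(records$left_ml)
  seg_index(records$right_ml)
  sc <- as.matrix(records[, c(muscle_cols("base"), muscle_cols("fu"))])
  ok <- is.na(sc) | (sc >= 0 & sc <= 5 & sc == round(sc))
  if (!all(ok)) stop("motor scores must be integers in 0..5")
  if (!all(records$arm %in% c(0, 1))) stop("arm must be 0 or 1")
  invisible(records)
}

#' Read / write trial data
#'
#' Two plain-CSV layouts are supported.  The *wide* layout has one row per
#' participant: `id, arm, left_ml, right_ml`, ten baseline columns
#' `base_L_C5 .. base_R_T1` and ten follow-up columns `fu_L_C5 .. fu_R_T1`
#' (sides L/R, segments C5..T1).  The *long* layout is the transitional
#' row format of [build_transitional_rows()]; on input `y_auto` may be
#' omitted only if the wide columns needed to rebuild it are present
#' elsewhere, so normally it is required.
#'
#' @param path CSV file path.
#' @param records,rows Data frame to write.
#' @return The data frame read, or `path` invisibly for writers.
#' @export
read_cohort_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(rec)
  rec
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(records, path) {
  validate_cohort(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort_csv
#' @export
read_rows_long_csv <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "lev", "y_base", "y_auto", "y_out", "arm")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("long trial data missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(rows$lev), lev_levels())
  if (length(bad)) stop("unknown lev code(s): ", paste(bad, collapse = ", "))
  rows
}

#' @rdname read_cohort_csv
#' @export
write_rows_long_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
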
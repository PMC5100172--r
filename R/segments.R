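# Segment bookkeeping for the ten-muscle upper-extremity motor exam.
#
# Each body side contributes five key muscles, one per spinal segment
# C5 < C6 < C7 < C8 < T1 (rostral to caudal).  A side's motor level (ML)
# is the most caudal segment with normal function: muscles rostral to the
# ML are intact, the muscle at the ML is moderately impaired, and muscles
# caudal to it are the analysis target of the transitional model.

#' Spinal segments of the upper-extremity motor exam
#'
#' Returns the five segment labels in rostral-to-caudal order
#' (`C5 < C6 < C7 < C8 < T1`).  This order is total and is relied upon
#' throughout the package: a muscle is "below" a motor level when its
#' segment comes strictly later in this vector.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' segments_uems()
segments_uems <- function() c("C5", "C6", "C7", "C8", "T1")

#' Valid motor-level/distance codes
#'
#' The transitional model indexes every analysed muscle by the combination
#' of the side's motor level and the (negative) distance, in key muscles,
#' from that level.  Only muscles strictly below the level are analysed, so
#' a motor level of C5 contributes distances -1..-4, C6 contributes -1..-3,
#' C7 -1..-2, C8 -1, and T1 nothing.  That makes exactly ten codes; the
#' reference code is `"C5.-1"`.
#'
#' @return Character vector of the 10 codes, reference first.
#' @export
#' @examples
#' lev_levels()          # 10 codes
lev_levels <- function() {
  segs <- segments_uems()
  out <- character(0)
  for (i in 1:4) {
    for (d in 1:(5 - i)) out <- c(out, paste0(segs[i], ".-", d))
  }
  out
}

seg_index <- function(segment) {
  idx <- match(segment, segments_uems())
  if (anyNA(idx)) {
    stop("unknown segment label(s): ",
         paste(unique(segment[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Motor-level/distance code of a key muscle
#'
#' Maps a (motor level, segment) pair to its code, e.g. `lev_code("C5",
#' "C8")` is `"C5.-3"`: the C8 key muscle is the third muscle below a C5
#' motor level.  Vectorised over both arguments.
#'
#' @param motor_level Segment label(s) of the side's motor level; must be
#'   C5--C8 (a T1 motor level has no muscle below it).
#' @param segment Segment label(s) of the muscle, strictly caudal to
#'   `motor_level`.
#' @return Character vector of codes such as `"C6.-2"`.
#' @export
#' @examples
#' lev_code("C5", "C6")   # "C5.-1", the reference code
#' lev_code("C5", "T1")   # "C5.-4"
lev_code <- function(motor_level, segment) {
  ml <- seg_index(motor_level)
  sg <- seg_index(segment)
  n <- max(length(ml), length(sg))
  ml <- rep_len(ml, n); sg <- rep_len(sg, n)
  if (any(ml == 5L)) stop("motor level T1: no muscles below")
  if (any(sg <= ml)) stop("segment at or above motor level: not below level")
  paste0(segments_uems()[ml], ".", ml - sg)
}

# Constellation labels: "left/right", e.g. "C5/C6".  (T1,T1) is invalid:
# such a participant has no muscle below either motor level and does not
# contribute to the transitional analysis.
constellation_labels <- function(include_t1t1 = FALSE) {
  segs <- segments_uems()
  lab <- as.vector(outer(segs, segs, function(l, r) paste0(l, "/", r)))
  if (!include_t1t1) lab <- setdiff(lab, "T1/T1")
  lab
}

split_constellation <- function(label) {
  parts <- strsplit(label, "/", fixed = TRUE)
  left <- vapply(parts, `[`, "", 1L)
  right <- vapply(parts, `[`, "", 2L)
  seg_index(left); seg_index(right)  # validate
  list(left = left, right = right)
}

# Column names of the wide cohort layout: base_L_C5 .. fu_R_T1.
muscle_cols <- function(prefix) {
  paste0(prefix, "_", rep(c("L", "R"), each = 5), "_", segments_uems())
}
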
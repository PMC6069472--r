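#' NIPS indicator record
#'
#' The Neonatal Infant Pain Scale scores five behavioural/physiological
#' indicators as 0 or 1 (facial expression, breathing pattern, arm
#' movement, leg movement, state of arousal) and cry on three categories
#' 0, 1, 2. The total ranges from 0 to 7.
#'
#' @param facial_expression,breathing,arms,legs,arousal Integers in {0, 1}.
#' @param cry Integer in {0, 1, 2}.
#' @return An object of class `nips_indicators`.
#' @export
nips_indicators <- function(facial_expression = 0L, cry = 0L, breathing = 0L,
                            arms = 0L, legs = 0L, arousal = 0L) {
  check01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || !(x %in% c(0L, 1L))) {
      stop("NIPS indicator '", nm, "' must be 0 or 1")
    }
    as.integer(x)
  }
  if (!is.numeric(cry) || length(cry) != 1L || is.na(cry) || !(cry %in% 0:2)) {
    stop("NIPS indicator 'cry' must be 0, 1 or 2")
  }
  structure(list(
    facial_expression = check01(facial_expression, "facial_expression"),
    cry = as.integer(cry),
    breathing = check01(breathing, "breathing"),
    arms = check01(arms, "arms"),
    legs = check01(legs, "legs"),
    arousal = check01(arousal, "arousal")
  ), class = "nips_indicators")
}

#' Total NIPS score
#'
#' Sum of the six indicator scores; ranges from 0 (all indicators at rest)
#' to 7 (all five binary indicators at 1 and cry at 2).
#'
#' @param ind A [nips_indicators()] record.
#' @return Integer in 0-7.
#' @export
nips_total <- function(ind) {
  stopifnot(inherits(ind, "nips_indicators"))
  sum(ind$facial_expression, ind$cry, ind$breathing, ind$arms, ind$legs,
      ind$arousal)
}

validate_nips_score <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score != floor(score) || score < 0 || score > 7) {
    stop("NIPS total score must be an integer in 0-7, got ", score)
  }
  as.integer(score)
}

#' Binary pain label from a NIPS total
#'
#' Scores 3-7 are labelled `"pain"`, 0-2 `"no_pain"`.
#'
#' @param score Integer NIPS total in 0-7.
#' @return `"pain"` or `"no_pain"`.
#' @export
pain_label <- function(score) {
  score <- validate_nips_score(score)
  if (score >= 3L) "pain" else "no_pain"
}

#' Pain severity group from a NIPS total
#'
#' No pain for totals 0-2, moderate pain for 3-4, severe pain above 4.
#'
#' @param score Integer NIPS total in 0-7.
#' @return `"none"`, `"moderate"` or `"severe"`.
#' @export
severity <- function(score) {
  score <- validate_nips_score(score)
  if (score <= 2L) "none" else if (score <= 4L) "moderate" else "severe"
}

#' Segment a procedure video into the seven analysis epochs
#'
#' A recording is split into seven half-open intervals, in seconds:
#' a baseline of up to five minutes before the painful procedure (T0), the
#' procedure itself (T1), and five one-minute windows after its completion
#' (T2-T6). Post-procedure windows that run past the end of the video are
#' truncated and flagged; a T0 shorter than 300 s (procedure starting early
#' in the recording) is likewise flagged.
#'
#' @param procedure_start,procedure_end Procedure onset/offset in seconds,
#'   `0 <= start < end <= video_duration`.
#' @param video_duration Video length in seconds.
#' @return A data frame with columns `epoch_id`, `start`, `end`,
#'   `truncated`; always exactly 7 rows, intervals `[start, end)`.
#' @export
segment_epochs <- function(procedure_start, procedure_end, video_duration) {
  if (!is.finite(procedure_start) || !is.finite(procedure_end) ||
      !is.finite(video_duration)) {
    stop("epoch boundaries must be finite")
  }
  if (procedure_start >= procedure_end) {
    stop("procedure_start must be strictly before procedure_end")
  }
  if (procedure_start < 0 || procedure_end > video_duration) {
    stop("procedure interval must lie within the video")
  }
  t0_start <- max(0, procedure_start - 300)
  starts <- c(t0_start, procedure_start,
              procedure_end + 60 * (0:4))
  ends <- c(procedure_start, procedure_end,
            procedure_end + 60 * (1:5))
  truncated <- logical(7)
  truncated[1] <- procedure_start < 300
  for (k in 3:7) {
    if (starts[k] > video_duration) {
      starts[k] <- video_duration
      ends[k] <- video_duration
      truncated[k] <- TRUE
    } else if (ends[k] > video_duration) {
      ends[k] <- video_duration
      truncated[k] <- TRUE
    }
  }
  data.frame(epoch_id = paste0("T", 0:6), start = starts, end = ends,
             truncated = truncated, stringsAsFactors = FALSE)
}

#' Map an epoch interval to frame indices
#'
#' Half-open second intervals map to 0-based frame indices
#' `floor(start * fs) ... floor(end * fs) - 1`.
#'
#' @param start,end Interval in seconds, `start <= end`.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of 0-based frame indices (possibly empty).
#' @export
epoch_frames <- function(start, end, fs) {
  stopifnot(fs > 0, start <= end)
  lo <- floor(start * fs)
  hi <- floor(end * fs) - 1
  if (hi < lo) integer(0) else as.integer(lo:hi)
}
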
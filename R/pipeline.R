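#' Extract all feature streams of one video
#'
#' Runs the full per-video representation: the 19 geometry signals are
#' summarised by the 16 x 3 temporal descriptor scheme into the
#' DG_DisFace (528) and DG_DisPose (384) streams; when a frame stack is
#' supplied, the 31 patch gradient signals likewise give the DA_Gradient
#' (1488) stream and the LBP-TOP histograms the DA_LBP-TOP (5487) stream.
#'
#' @param seq A [landmark_sequence()].
#' @param stack Optional aligned [frame_stack()]; without it only the two
#'   geometric streams are produced.
#' @param mapping Landmark mapping ([default_mapping()]).
#' @param rap RAP configuration ([default_rap_config()]).
#' @return Named list of numeric vectors: `dface`, `dpose` and, with
#'   frames, `gradient`, `lbptop`.
#' @export
extract_streams <- function(seq, stack = NULL, mapping = default_mapping(),
                            rap = default_rap_config()) {
  geo <- geometry_signals(seq, mapping)
  fs <- attr(geo, "fs")
  streams <- list(
    dface = build_stream(geo[deformation_names()], fs = fs),
    dpose = build_stream(geo[pose_names()], fs = fs)
  )
  if (!is.null(stack)) {
    grad <- gradient_signals(stack, seq, rap)
    streams$gradient <- build_stream(grad, fs = attr(grad, "fs"))
    streams$lbptop <- video_appearance(stack, seq, rap)
  }
  streams
}

#' Turn a synthetic cohort into labelled pain instances
#'
#' Extracts the requested feature streams for every video of a
#' [simulate_cohort()] result. When appearance streams (`gradient`,
#' `lbptop`) are requested, each video's frames are rendered on the fly
#' with [render_frames()] and discarded after feature extraction, so the
#' full cohort never resides in memory as pixels.
#'
#' @param cohort A `synthetic_cohort`.
#' @param streams Stream names to extract (default all four).
#' @param mapping Landmark mapping.
#' @param rap RAP configuration.
#' @return List of [pain_instance()] objects, one per video.
#' @export
cohort_instances <- function(cohort,
                             streams = c("dface", "dpose", "gradient", "lbptop"),
                             mapping = default_mapping(),
                             rap = default_rap_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  need_frames <- any(c("gradient", "lbptop") %in% streams)
  lapply(cohort$videos, function(v) {
    stack <- if (need_frames) {
      render_frames(v$seq, v$pain, cohort$spec$pain_effect$wrinkle_contrast,
                    v$render_seed)
    }
    feats <- extract_streams(v$seq, stack, mapping, rap)
    pain_instance(v$subject, v$epoch_id, feats[streams], v$nips_score)
  })
}
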
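#' Frame-level facial deformation distances
#'
#' Computes the 11 pain-related deformation distances of the NFCS-inspired
#' scheme for a single landmark frame: eyebrow-eye, upper-lower eyelid,
#' eyebrow-mouth, eye-mouth and nose-mouth distances on each applicable
#' side, and the mouth width and height. Each distance is the Euclidean
#' distance, in pixels, between the centroids of the two landmark groups
#' named in the mapping; centroids make the measure robust to single-point
#' jitter, and the whole definition lives in the mapping so an alternative
#' landmark convention needs no code change.
#'
#' @param frame A [landmark_frame()].
#' @param mapping A mapping from [default_mapping()] or [read_mapping()].
#' @return Named numeric vector of 11 non-negative distances, in the order
#'   of [deformation_names()].
#' @export
compute_deformation <- function(frame, mapping = default_mapping()) {
  compute_distances(frame, mapping, deformation_names())
}

#' Frame-level head-pose distances
#'
#' Distance-based head pose parameters: the distances from the left and
#' right face-boundary landmarks to the brow, eye, nose and mouth centroids
#' on the corresponding side. Lateral head movement (head shaking, a common
#' pain behaviour in infants) shortens these distances on one side and
#' lengthens them on the other, so their temporal course carries the
#' head-shake signature without any 3-D pose estimation.
#'
#' @inheritParams compute_deformation
#' @return Named numeric vector of 8 non-negative distances, in the order
#'   of [pose_names()].
#' @export
compute_pose <- function(frame, mapping = default_mapping()) {
  compute_distances(frame, mapping, pose_names())
}

compute_distances <- function(frame, mapping, which) {
  stopifnot(inherits(frame, "landmark_frame"))
  check_mapping(mapping, unique(unlist(mapping$distances[which])))
  missing <- setdiff(which, names(mapping$distances))
  if (length(missing)) {
    stop("mapping is missing distance definition(s): ",
         paste(missing, collapse = ", "))
  }
  pts <- frame$points
  centroid <- function(group) {
    idx <- mapping$groups[[group]]
    colMeans(pts[idx, , drop = FALSE])
  }
  out <- vapply(which, function(nm) {
    pair <- mapping$distances[[nm]]
    sqrt(sum((centroid(pair[1]) - centroid(pair[2]))^2))
  }, numeric(1))
  names(out) <- which
  out
}

#' Geometry signals for a whole landmark sequence
#'
#' Evaluates the 11 deformation and 8 pose distances on every frame,
#' yielding 19 named temporal signals (one sample per frame, at the
#' sequence's sampling rate), ready for [temporal_signal()] /
#' [build_stream()].
#'
#' @param seq A [landmark_sequence()].
#' @param mapping A mapping from [default_mapping()].
#' @return Named list of 19 numeric vectors (11 deformation then 8 pose),
#'   each of length `length(seq)`, with attribute `fs`.
#' @export
geometry_signals <- function(seq, mapping = default_mapping()) {
  stopifnot(inherits(seq, "landmark_sequence"))
  nms <- c(deformation_names(), pose_names())
  per_frame <- lapply(seq$frames, function(f) {
    tryCatch(
      c(compute_deformation(f, mapping), compute_pose(f, mapping)),
      error = function(e) {
        stop("frame ", f$frame_index, ": ", conditionMessage(e))
      })
  })
  mat <- do.call(rbind, per_frame)
  out <- lapply(nms, function(nm) mat[, nm])
  names(out) <- nms
  attr(out, "fs") <- seq$fs
  out
}

#' Hemiface feature selection
#'
#' Restricts a feature stream to the subject's left or right hemiface, for
#' profile-view pain assessment. Lateral distances and patches stay with
#' their side; midline features (nose-mouth distance, mouth width/height,
#' and midline patches) belong to both hemifaces, so a hemiface model keeps
#' the mouth and nose evidence that remains visible in profile.
#'
#' @param stream One of `"dface"`, `"dpose"`, `"gradient"`, `"lbptop"`.
#' @param side `"left"`, `"right"` or `"whole"`.
#' @param mapping Landmark mapping (for the distance-based streams).
#' @param rap RAP configuration (for the patch-based streams).
#' @return Integer vector of positions to keep within the stream's feature
#'   vector, in the stream's native order.
#' @export
hemiface_select <- function(stream = c("dface", "dpose", "gradient", "lbptop"),
                            side = c("whole", "left", "right"),
                            mapping = default_mapping(),
                            rap = default_rap_config()) {
  stream <- match.arg(stream)
  side <- match.arg(side)
  n_block <- switch(stream, dface = 48L, dpose = 48L, gradient = 48L,
                    lbptop = 177L)
  units <- switch(stream,
    dface = deformation_names(),
    dpose = pose_names(),
    gradient = ,
    lbptop = paste0("patch", seq_along(rap$indices))
  )
  keep_unit <- if (stream %in% c("dface", "dpose")) {
    unit_side <- distance_side(units)
    switch(side,
      whole = rep(TRUE, length(units)),
      left = unit_side %in% c("left", "mid"),
      right = unit_side %in% c("right", "mid"))
  } else {
    switch(side,
      whole = rep(TRUE, length(units)),
      left = rap$side %in% c("left", "mid"),
      right = rap$side %in% c("right", "mid"))
  }
  blocks <- which(keep_unit)
  as.integer(unlist(lapply(blocks, function(b) ((b - 1L) * n_block + 1L):(b * n_block))))
}

distance_side <- function(names) {
  vapply(names, function(nm) {
    if (nm %in% c("d_nm", "d_mw", "d_mh")) "mid"
    else if (grepl("l$", nm)) "left"
    else "right"
  }, character(1), USE.NAMES = FALSE)
}
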
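#' Extract a square patch around a landmark
#'
#' Crops a `size` x `size` region-around-point (RAP) centred on the rounded
#' landmark position. Landmark coordinates are 0-based pixels (origin
#' top-left, x rightward along columns, y downward along rows); for the
#' even default size the crop spans offsets `-(size/2 - 1) ... size/2`
#' around the centre pixel. Out-of-bounds pixels are filled by edge
#' replication, so every crop is exactly `size` x `size`.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param center Numeric `(x, y)` landmark position, 0-based pixels.
#' @param size Patch side length (default 32).
#' @return `size` x `size` numeric matrix.
#' @export
extract_patch <- function(image, center, size = 32L) {
  if (!is.matrix(image) || !length(image)) stop("image must be a non-empty matrix")
  if (length(center) != 2L || !all(is.finite(center))) {
    stop("patch center must be a finite (x, y) pair")
  }
  size <- as.integer(size)
  cx <- round(center[1]); cy <- round(center[2])
  half <- size %/% 2L
  offs <- (-(half - 1L)):(size - half)  # e.g. -15..16 for size 32
  rows <- pmin(pmax(cy + offs + 1L, 1L), nrow(image))
  cols <- pmin(pmax(cx + offs + 1L, 1L), ncol(image))
  image[rows, cols, drop = FALSE]
}

# 3x3 Sobel gradient magnitude of a matrix, edge-replicated borders.
sobel_magnitude <- function(m) {
  r <- nrow(m); c <- ncol(m)
  p <- m[c(1, 1:r, r), c(1, 1:c, c)]  # replicate edges
  sh <- function(dr, dc) p[(2 + dr):(r + 1 + dr), (2 + dc):(c + 1 + dc)]
  # x increases with column index, y with row index
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Per-frame gradient texture parameters over the 31 RAPs
#'
#' For each region-around-point, the mean over its 32 x 32 crop of the
#' Sobel gradient magnitude `sqrt(gx^2 + gy^2)` (3 x 3 operators,
#' edge-replicated borders). One value per patch: 31 texture parameters
#' per frame, zero exactly where the patch is constant.
#'
#' @param image Numeric matrix (grayscale frame).
#' @param centers 31 x 2 matrix of `(x, y)` RAP centres (0-based pixels).
#' @param size Patch side length (default 32).
#' @return Numeric vector of 31 non-negative mean gradient magnitudes.
#' @export
gradient_frame <- function(image, centers, size = 32L) {
  centers <- as.matrix(centers)
  if (nrow(centers) != 31L || ncol(centers) != 2L) {
    stop("expected 31 (x, y) RAP centers, got ", nrow(centers))
  }
  vapply(seq_len(31L), function(i) {
    mean(sobel_magnitude(extract_patch(image, centers[i, ], size)))
  }, numeric(1))
}

#' Gradient texture signals for a whole video
#'
#' Follows each RAP landmark across frames and evaluates
#' [gradient_frame()] on every frame, yielding 31 temporal signals that
#' feed the DA_Gradient descriptor stream.
#'
#' @param stack A [frame_stack()].
#' @param seq The aligned [landmark_sequence()].
#' @param rap RAP configuration ([default_rap_config()]).
#' @return Named list of 31 numeric signals (`patch1` ...), attribute `fs`.
#' @export
gradient_signals <- function(stack, seq, rap = default_rap_config()) {
  check_alignment(stack, seq)
  mat <- vapply(seq_along(stack$images), function(t) {
    centers <- seq$frames[[t]]$points[rap$indices, , drop = FALSE]
    gradient_frame(stack$images[[t]], centers, rap$patch_size)
  }, numeric(31L))
  out <- lapply(seq_len(31L), function(i) mat[i, ])
  names(out) <- paste0("patch", seq_len(31L))
  attr(out, "fs") <- seq$fs
  out
}

check_alignment <- function(stack, seq) {
  stopifnot(inherits(stack, "frame_stack"), inherits(seq, "landmark_sequence"))
  if (length(stack$images) != length(seq$frames)) {
    stop("frame stack (", length(stack$images), ") and landmark sequence (",
         length(seq$frames), ") are misaligned")
  }
}

# 256-entry lookup: 8-bit LBP code -> uniform-2 bin in 1..59.
# Codes with at most two circular 0/1 transitions get their own bin
# (58 of them, numbered in ascending code order); all others share bin 59.
lbp_uniform_table <- local({
  table <- NULL
  function() {
    if (is.null(table)) {
      codes <- 0:255
      bits <- t(vapply(codes, function(k) as.integer(intToBits(k)[1:8]), integer(8)))
      trans <- rowSums(bits != bits[, c(2:8, 1)])
      tab <- integer(256)
      tab[trans <= 2] <- seq_len(sum(trans <= 2))
      tab[trans > 2] <- 59L
      stopifnot(sum(trans <= 2) == 58L)
      table <<- tab
    }
    table
  }
})

# LBP codes of the interior pixels of a 2-D slice; 8 neighbours at radius 1
# on the integer ring, bit k set when neighbour >= centre. Neighbour order:
# east, north-east, north, north-west, west, south-west, south, south-east
# (counter-clockwise from the positive first-axis direction).
lbp_codes <- function(m) {
  r <- nrow(m); c <- ncol(m)
  if (r < 3L || c < 3L) return(integer(0))
  ctr <- m[2:(r - 1), 2:(c - 1)]
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  code <- matrix(0L, r - 2L, c - 2L)
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]
    nb <- m[(2 + dr):(r - 1 + dr), (2 + dc):(c - 1 + dc)]
    code <- code + bitwShiftL(as.integer(nb >= ctr), k - 1L)
  }
  as.integer(code)
}

lbp_hist59 <- function(codes) {
  if (!length(codes)) return(numeric(59))
  as.numeric(tabulate(lbp_uniform_table()[codes + 1L], nbins = 59L))
}

#' LBP-TOP descriptor of one patch volume
#'
#' Local Binary Patterns on Three Orthogonal Planes: the patch volume
#' (a landmark-following stack of crops) is sliced along the XY
#' (appearance), XT and YT (horizontal and vertical motion) plane
#' families; every pixel with a full 8-neighbourhood in its plane is coded
#' with the radius-1, 8-neighbour LBP (neighbour >= centre sets the bit)
#' and accumulated into the 59-bin uniform-2 histogram of its plane family.
#' The three histograms are concatenated XY, XT, YT into a 177-vector.
#' Before normalisation each plane histogram sums to the number of coded
#' pixels of that plane family; with `normalize = TRUE` (default) each
#' plane is L1-normalised. The coding compares gray levels only, so the
#' descriptor is invariant under monotone gray-level shifts.
#'
#' @param volume 3-D numeric array `[y, x, t]` with at least 3 frames.
#' @param normalize L1-normalise each 59-bin plane histogram.
#' @return Numeric vector of length 177.
#' @export
lbp_top_patch <- function(volume, normalize = TRUE) {
  d <- dim(volume)
  if (length(d) != 3L) stop("volume must be a 3-D array [y, x, t]")
  if (d[3] < 3L) stop("LBP-TOP needs at least 3 frames (temporal planes undefined)")
  h_xy <- numeric(59); h_xt <- numeric(59); h_yt <- numeric(59)
  for (t in seq_len(d[3])) {
    h_xy <- h_xy + lbp_hist59(lbp_codes(volume[, , t]))
  }
  for (y in seq_len(d[1])) {
    h_xt <- h_xt + lbp_hist59(lbp_codes(volume[y, , ]))  # [x, t] slice
  }
  for (x in seq_len(d[2])) {
    h_yt <- h_yt + lbp_hist59(lbp_codes(volume[, x, ]))  # [y, t] slice
  }
  if (normalize) {
    l1 <- function(h) if (sum(h) > 0) h / sum(h) else h
    h_xy <- l1(h_xy); h_xt <- l1(h_xt); h_yt <- l1(h_yt)
  }
  c(h_xy, h_xt, h_yt)
}

#' Build the patch volume following one landmark across frames
#'
#' @param stack A [frame_stack()].
#' @param seq The aligned [landmark_sequence()].
#' @param landmark_id Landmark index (1-based).
#' @param size Patch side length.
#' @return 3-D array `[y, x, t]` of per-frame crops.
#' @export
patch_volume <- function(stack, seq, landmark_id, size = 32L) {
  check_alignment(stack, seq)
  T_ <- length(stack$images)
  vol <- array(0, dim = c(size, size, T_))
  for (t in seq_len(T_)) {
    vol[, , t] <- extract_patch(stack$images[[t]],
                                seq$frames[[t]]$points[landmark_id, ], size)
  }
  vol
}

#' LBP-TOP appearance descriptor of a whole video
#'
#' Computes [lbp_top_patch()] on the volume of each of the 31 RAPs
#' (patches follow their landmark frame by frame) and concatenates the
#' 177-vectors in configuration order: 5487 = 177 x 31 values per video,
#' the DA_LBP-TOP stream.
#'
#' @param stack A [frame_stack()].
#' @param seq The aligned [landmark_sequence()].
#' @param rap RAP configuration ([default_rap_config()]).
#' @return Numeric vector of length `177 * length(rap$indices)` (5487 for
#'   the default 31 patches).
#' @export
video_appearance <- function(stack, seq, rap = default_rap_config()) {
  check_alignment(stack, seq)
  out <- lapply(rap$indices, function(id) {
    lbp_top_patch(patch_volume(stack, seq, id, rap$patch_size),
                  normalize = rap$normalize)
  })
  unlist(out, use.names = FALSE)
}
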
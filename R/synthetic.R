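#' Neutral 68-point template face
#'
#' A fixed neutral landmark layout on a 256 x 256 pixel canvas, following
#' the package's 68-point convention (see [default_mapping()]). The layout
#' is exactly mirror-symmetric about the vertical axis x = 128, which the
#' hemiface tests rely on. Coordinates are 0-based pixels.
#'
#' @return 68 x 2 numeric matrix with columns `x`, `y`.
#' @export
template_face <- function() {
  pts <- matrix(NA_real_, 68, 2, dimnames = list(NULL, c("x", "y")))
  # face boundary: half-ellipse from left temple through chin to right temple
  phi <- pi * (0:16) / 16
  pts[1:17, ] <- cbind(128 - 85 * cos(phi), 115 + 95 * sin(phi))
  # eyebrows
  pts[18:22, ] <- cbind(c(68, 79, 90, 101, 112), c(98, 93, 91, 92, 95))
  pts[23:27, ] <- cbind(256 - c(112, 101, 90, 79, 68), c(95, 92, 91, 93, 98))
  # nose bridge and base
  pts[28:31, ] <- cbind(rep(128, 4), c(106, 119, 132, 145))
  pts[32:36, ] <- cbind(c(112, 120, 128, 136, 144), c(153, 156, 158, 156, 153))
  # eyes (outer corner, upper lid x2, inner corner, lower lid x2)
  pts[37:42, ] <- cbind(c(72, 82, 94, 104, 94, 82),
                        c(110, 105, 105, 110, 115, 115))
  pts[43:48, ] <- cbind(256 - c(104, 94, 82, 72, 82, 94),
                        c(110, 105, 105, 110, 115, 115))
  # outer lip contour
  pts[49:60, ] <- cbind(
    c(98, 108, 117, 128, 139, 148, 158, 148, 139, 128, 117, 108),
    c(180, 173, 169, 167, 169, 173, 180, 187, 191, 193, 191, 187))
  # inner lip contour
  pts[61:68, ] <- cbind(c(104, 116, 128, 140, 152, 140, 128, 116),
                        c(180, 176, 175, 176, 180, 184, 185, 184))
  pts
}

#' Cohort specification for the synthetic generator
#'
#' Defines the conditions a generated cohort emulates: a NICU-style study
#' in which each subject contributes several one-epoch videos, some during
#' a painful procedure and some at baseline. Pain epochs superimpose, on
#' the neutral template, the canonical infant pain actions: brow lowering
#' (decreased eyebrow-eye distance), eye squeeze (decreased eyelid
#' distance), vertical mouth stretch (increased mouth height), lateral
#' head shaking (sinusoidal boundary shift) and high-frequency wrinkle
#' texture in the brow/nasolabial regions. No-pain epochs carry landmark
#' jitter only. The default effect magnitudes are a few pixels on a
#' 256-pixel face - visible but not caricatured - over 2-second epochs at
#' 30 Hz.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param epochs_per_subject Videos per subject (default 4: two pain, two
#'   baseline).
#' @param fs Sampling rate in Hz (default 30).
#' @param frames_per_epoch Frames per video (default 60).
#' @param pain_effect Named list of effect magnitudes: `eyebrow_drop`,
#'   `eyelid_close`, `mouth_open`, `headshake_amp` (pixels) and
#'   `wrinkle_contrast` (gray levels).
#' @param noise_sd Landmark jitter standard deviation in pixels (default 1).
#' @param seed Integer seed fixing the full output bit-exactly.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12L, epochs_per_subject = 4L, fs = 30,
                        frames_per_epoch = 60L,
                        pain_effect = list(eyebrow_drop = 6, eyelid_close = 4,
                                           mouth_open = 10, headshake_amp = 6,
                                           wrinkle_contrast = 40),
                        noise_sd = 1, seed = 1L) {
  if (n_subjects < 1L) stop("a cohort needs at least one subject")
  pe <- utils::modifyList(list(eyebrow_drop = 6, eyelid_close = 4,
                               mouth_open = 10, headshake_amp = 6,
                               wrinkle_contrast = 40), pain_effect)
  if (any(unlist(pe) < 0) || noise_sd < 0) {
    stop("effect magnitudes and noise_sd must be >= 0")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 epochs_per_subject = as.integer(epochs_per_subject),
                 fs = fs, frames_per_epoch = as.integer(frames_per_epoch),
                 pain_effect = pe, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# raised-cosine activation envelope over the epoch: 0 at the ends, 1 mid-epoch
pain_envelope <- function(n) {
  if (n < 2L) return(rep(0, n))
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Generate one synthetic landmark sequence
#'
#' Landmark jitter is drawn first from `seed`, then the deterministic pain
#' deformation is superimposed, so a pain epoch and a neutral epoch
#' generated with the same seed share their noise realisation and differ
#' only by the pain actions (a matched pair).
#'
#' @param n_frames Number of frames (>= 2).
#' @param fs Sampling rate in Hz.
#' @param pain Logical; apply the pain deformation.
#' @param effect Effect-magnitude list (see [cohort_spec()]).
#' @param noise_sd Landmark jitter SD in pixels.
#' @param seed Integer seed.
#' @param video_id Identifier for the sequence.
#' @return A [landmark_sequence()].
#' @export
synthetic_sequence <- function(n_frames = 60L, fs = 30, pain = FALSE,
                               effect = cohort_spec()$pain_effect,
                               noise_sd = 1, seed = 1L,
                               video_id = "synthetic") {
  tmpl <- template_face()
  set.seed(seed)
  noise <- array(stats::rnorm(68 * 2 * n_frames, sd = noise_sd),
                 dim = c(68, 2, n_frames))
  env <- pain_envelope(n_frames)
  tt <- (0:(n_frames - 1)) / fs
  frames <- lapply(seq_len(n_frames), function(i) {
    pts <- tmpl + noise[, , i]
    if (pain) {
      e <- env[i]
      pts[18:27, 2] <- pts[18:27, 2] + effect$eyebrow_drop * e
      lid <- effect$eyelid_close / 2 * e
      pts[c(38, 39, 44, 45), 2] <- pts[c(38, 39, 44, 45), 2] + lid
      pts[c(41, 42, 47, 48), 2] <- pts[c(41, 42, 47, 48), 2] - lid
      open <- effect$mouth_open * e
      pts[c(56:60, 66:68), 2] <- pts[c(56:60, 66:68), 2] + open
      pts[c(49, 55, 61, 65), 2] <- pts[c(49, 55, 61, 65), 2] + 0.4 * open
      pts[7:11, 2] <- pts[7:11, 2] + 0.5 * open
      shake <- effect$headshake_amp * sin(2 * pi * 2 * tt[i])
      pts[1:17, 1] <- pts[1:17, 1] + shake
    }
    pts
  })
  landmark_sequence(frames, fs = fs, video_id = video_id)
}

# additive Gaussian blob on a local window (darkens for amp > 0)
add_blob <- function(img, x, y, amp, sigma) {
  r0 <- max(1L, round(y) + 1L - 3L * sigma); r1 <- min(nrow(img), round(y) + 1L + 3L * sigma)
  c0 <- max(1L, round(x) + 1L - 3L * sigma); c1 <- min(ncol(img), round(x) + 1L + 3L * sigma)
  if (r0 > r1 || c0 > c1) return(img)
  ys <- r0:r1; xs <- c0:c1
  g <- exp(-outer((ys - 1 - y)^2, (xs - 1 - x)^2, "+") / (2 * sigma^2))
  img[ys, xs] <- img[ys, xs] - amp * g
  img
}

# oriented sinusoidal grating inside a Gaussian window (wrinkle patch)
add_grating <- function(img, x, y, amp, sigma = 10, wavelength = 4, theta = 0) {
  r0 <- max(1L, round(y) + 1L - 3L * sigma); r1 <- min(nrow(img), round(y) + 1L + 3L * sigma)
  c0 <- max(1L, round(x) + 1L - 3L * sigma); c1 <- min(ncol(img), round(x) + 1L + 3L * sigma)
  if (r0 > r1 || c0 > c1) return(img)
  ys <- r0:r1; xs <- c0:c1
  win <- exp(-outer((ys - 1 - y)^2, (xs - 1 - x)^2, "+") / (2 * sigma^2))
  phase <- outer((ys - 1) * sin(theta), (xs - 1) * cos(theta), "+")
  img[ys, xs] <- img[ys, xs] + amp * win * sin(2 * pi * phase / wavelength)
  img
}

# smooth per-subject skin texture field (sum of low-frequency gratings)
subject_texture <- function(seed, height = 256L, width = 256L) {
  set.seed(seed)
  tex <- matrix(0, height, width)
  ys <- 0:(height - 1); xs <- 0:(width - 1)
  for (k in 1:4) {
    fx <- stats::runif(1, 0.005, 0.03); fy <- stats::runif(1, 0.005, 0.03)
    ph <- stats::runif(1, 0, 2 * pi); amp <- stats::runif(1, 2, 5)
    tex <- tex + amp * sin(2 * pi * outer(ys * fy, xs * fx, "+") + ph)
  }
  tex
}

#' Render the grayscale frames of a synthetic video
#'
#' Draws a schematic face from the per-frame landmarks: a shaded facial
#' ellipse over a smooth per-subject skin texture, dark Gaussian blobs at
#' the brow, eye, nostril and mouth landmarks (so the appearance moves
#' with the geometry), plus - in pain epochs - oriented sinusoidal
#' gratings in the glabellar, nasal-root and nasolabial regions whose
#' contrast follows the pain envelope. Not photorealistic; it exists to
#' exercise the gradient and LBP-TOP features in a controlled way.
#'
#' @param seq The video's [landmark_sequence()].
#' @param pain Logical; add wrinkle gratings with the pain envelope.
#' @param wrinkle_contrast Grating amplitude in gray levels.
#' @param texture_seed Seed for the per-subject skin texture and pixel
#'   noise.
#' @param height,width Canvas size in pixels.
#' @return A [frame_stack()] on the 0-255 gray scale.
#' @export
render_frames <- function(seq, pain = FALSE, wrinkle_contrast = 40,
                          texture_seed = 1L, height = 256L, width = 256L) {
  stopifnot(inherits(seq, "landmark_sequence"))
  n <- length(seq$frames)
  env <- pain_envelope(n)
  tex <- subject_texture(texture_seed, height, width)
  ys <- 0:(height - 1); xs <- 0:(width - 1)
  face <- 1 / outer(((ys - 140) / 105)^2, ((xs - 128) / 88)^2, "+")
  base <- 185 - 45 * (face >= 1) + tex
  base <- base + 15 * outer(rep(1, height), (xs - 128) / 128) * (face >= 1)
  set.seed(texture_seed + 1L)
  imgs <- vector("list", n)
  for (t in seq_len(n)) {
    pts <- seq$frames[[t]]$points
    img <- base
    for (i in 18:27) img <- add_blob(img, pts[i, 1], pts[i, 2], 55, 3)
    for (i in 37:48) img <- add_blob(img, pts[i, 1], pts[i, 2], 65, 3)
    for (i in c(32, 36)) img <- add_blob(img, pts[i, 1], pts[i, 2], 40, 3)
    for (i in 49:60) img <- add_blob(img, pts[i, 1], pts[i, 2], 45, 3)
    for (i in 61:68) img <- add_blob(img, pts[i, 1], pts[i, 2], 30, 2)
    if (pain && wrinkle_contrast > 0 && env[t] > 0) {
      amp <- wrinkle_contrast * env[t]
      glab <- colMeans(pts[c(22, 23), , drop = FALSE])  # between the brows
      nroot <- pts[28, ]
      img <- add_grating(img, glab[1], glab[2] - 4, amp, sigma = 8, theta = pi / 2)
      img <- add_grating(img, nroot[1], nroot[2], amp, sigma = 8, theta = pi / 2)
      img <- add_grating(img, pts[32, 1] - 10, pts[32, 2] + 6, amp, sigma = 8,
                         theta = pi / 4)
      img <- add_grating(img, pts[36, 1] + 10, pts[36, 2] + 6, amp, sigma = 8,
                         theta = -pi / 4)
      img <- add_grating(img, pts[20, 1], pts[20, 2] - 8, amp, sigma = 6,
                         theta = pi / 2)
      img <- add_grating(img, pts[25, 1], pts[25, 2] - 8, amp, sigma = 6,
                         theta = pi / 2)
    }
    img <- img + matrix(stats::rnorm(height * width, sd = 1), height, width)
    imgs[[t]] <- pmin(pmax(img, 0), 255)
  }
  frame_stack(imgs)
}

# epoch slots in assignment order: id + whether it is a pain epoch
epoch_slots <- function(n) {
  slots <- list(c("T0", FALSE), c("T1", TRUE), c("T2", TRUE), c("T6", FALSE),
                c("T3", TRUE), c("T5", FALSE), c("T4", TRUE))
  if (n > length(slots)) stop("at most 7 epochs per subject (T0-T6)")
  slots[seq_len(n)]
}

# indicator record with a given total, filled in a fixed order
nips_for_total <- function(total) {
  total <- as.integer(total)
  cry <- min(2L, total); rest <- total - cry
  fields <- c("facial_expression", "breathing", "arms", "legs", "arousal")
  vals <- as.integer(seq_along(fields) <= rest)
  do.call(nips_indicators, c(list(cry = cry), as.list(stats::setNames(vals, fields))))
}

#' Simulate a synthetic cohort (in memory)
#'
#' Draws subject metadata (gender balanced; gestational ages normal with
#' mean 36.4 and SD 2.7 weeks, truncated to 30.4-40.6; races white, black
#' and asian in proportions 0.5 / 0.37 / 0.13) and, for every subject and
#' epoch slot, a landmark sequence via [synthetic_sequence()]. Pain epochs
#' receive NIPS totals drawn from 3-7, baseline epochs from 0-2, so labels
#' are consistent with the generated dynamics. Frames are not rendered
#' here: each video entry carries the parameters from which
#' [render_frames()] reproduces them deterministically.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with `spec`, `subjects`
#'   (list of [subject_record()]) and `videos` (one entry per
#'   subject-epoch: `video_id`, `subject`, `epoch_id`, `pain`,
#'   `nips` ([nips_indicators()]), `nips_score`, `seq`, `render_seed`).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  genders <- sample(rep(c("male", "female"), length.out = n))
  ga <- pmin(pmax(stats::rnorm(n, 36.4, 2.7), 30.4), 40.6)
  races <- sample(c("white", "black", "asian"), n, replace = TRUE,
                  prob = c(0.5, 0.37, 0.13))
  subjects <- lapply(seq_len(n), function(i) {
    subject_record(sprintf("S%02d", i), genders[i], ga[i], races[i])
  })
  slots <- epoch_slots(spec$epochs_per_subject)
  videos <- list()
  idx <- 0L
  for (i in seq_len(n)) {
    for (sl in slots) {
      idx <- idx + 1L
      pain <- as.logical(sl[2])
      total <- if (pain) sample(3:7, 1) else sample(0:2, 1)
      vseed <- (spec$seed * 7919L + idx * 104729L) %% 2147483647L
      videos[[idx]] <- list(
        video_id = sprintf("S%02d_%s", i, sl[1]),
        subject = subjects[[i]],
        epoch_id = sl[1],
        pain = pain,
        nips = nips_for_total(total),
        nips_score = total,
        seq = synthetic_sequence(spec$frames_per_epoch, spec$fs, pain,
                                 spec$pain_effect, spec$noise_sd,
                                 seed = vseed,
                                 video_id = sprintf("S%02d_%s", i, sl[1])),
        render_seed = (spec$seed * 131L + i * 977L) %% 2147483647L)
    }
  }
  structure(list(spec = spec, subjects = subjects, videos = videos),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Materialises a cohort in the package's file formats: one landmark CSV
#' per video (`landmarks/<video_id>.csv`), optionally one PNG frame
#' directory per video (`frames/<video_id>/`), a subject metadata CSV and
#' an annotation CSV (`video_id`, `subject_id`, `epoch_id`, the six NIPS
#' indicator columns, `nips_total`, `label`).
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param render Also render and write the PNG frame stacks (default
#'   `FALSE`; they are large and reproducible from the cohort specification).
#' @return The cohort (invisibly), as from [simulate_cohort()].
#' @export
generate_cohort <- function(spec = cohort_spec(), dir, render = FALSE) {
  cohort <- simulate_cohort(spec)
  dir.create(file.path(dir, "landmarks"), recursive = TRUE, showWarnings = FALSE)
  for (v in cohort$videos) {
    write_landmarks(v$seq, file.path(dir, "landmarks", paste0(v$video_id, ".csv")))
    if (render) {
      stack <- render_frames(v$seq, v$pain, spec$pain_effect$wrinkle_contrast,
                             v$render_seed)
      write_frames(stack, file.path(dir, "frames", v$video_id))
    }
  }
  write_metadata(cohort$subjects, file.path(dir, "metadata.csv"))
  ann <- do.call(rbind, lapply(cohort$videos, function(v) {
    data.frame(video_id = v$video_id, subject_id = v$subject$subject_id,
               epoch_id = v$epoch_id,
               facial_expression = v$nips$facial_expression, cry = v$nips$cry,
               breathing = v$nips$breathing, arms = v$nips$arms,
               legs = v$nips$legs, arousal = v$nips$arousal,
               nips_total = v$nips_score, label = pain_label(v$nips_score),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(cohort)
}
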
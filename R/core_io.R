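#' Construct a landmark frame
#'
#' A single frame of 68 ordered (x, y) facial landmark coordinates, in
#' pixels, origin at the top-left corner, x rightward, y downward.
#'
#' @param points 68 x 2 numeric matrix of finite coordinates.
#' @param frame_index Integer frame index, >= 0.
#' @return An object of class `landmark_frame`.
#' @export
landmark_frame <- function(points, frame_index = 0L) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 68L || ncol(points) != 2L) {
    stop("frame ", frame_index, ": expected 68 (x, y) points, got ",
         nrow(points), " x ", ncol(points))
  }
  if (!all(is.finite(points))) {
    stop("frame ", frame_index, ": non-finite landmark coordinates")
  }
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L) stop("frame_index must be >= 0")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, frame_index = frame_index),
            class = "landmark_frame")
}

#' Construct a landmark sequence
#'
#' One video's worth of landmark frames with its sampling rate.
#'
#' @param frames List of [landmark_frame()] objects (or 68 x 2 matrices),
#'   frame indices 0, 1, 2, ...
#' @param fs Sampling rate in Hz, > 0.
#' @param video_id Identifier string.
#' @return An object of class `landmark_sequence`.
#' @export
landmark_sequence <- function(frames, fs = 30, video_id = "video") {
  if (length(frames) < 2L) stop("a landmark sequence needs at least 2 frames")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive sampling rate in Hz")
  }
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (inherits(f, "landmark_frame")) {
      if (f$frame_index != i - 1L) {
        stop("frame indices must increase by 1 from 0; frame ", i,
             " has index ", f$frame_index)
      }
      f
    } else {
      landmark_frame(f, frame_index = i - 1L)
    }
  })
  structure(list(frames = frames, fs = as.numeric(fs),
                 video_id = as.character(video_id)),
            class = "landmark_sequence")
}

#' @export
length.landmark_sequence <- function(x) length(x$frames)

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf("<landmark_sequence '%s': %d frames of 68 points at %g Hz>\n",
              x$video_id, length(x$frames), x$fs))
  invisible(x)
}

#' Write / read a landmark sequence as CSV
#'
#' Dialect: a comment line `# fs=<Hz>`, a header
#' `frame,x0,y0,...,x67,y67`, then one row per frame. Coordinates are
#' written with full double precision so that read/write round-trips
#' bit-exactly for finite values.
#'
#' @param seq A [landmark_sequence()].
#' @param path Output file path.
#' @return `write_landmarks` returns `path` invisibly; `read_landmarks`
#'   returns a [landmark_sequence()].
#' @export
write_landmarks <- function(seq, path) {
  stopifnot(inherits(seq, "landmark_sequence"))
  header <- paste0("frame,", paste0("x", 0:67, ",", "y", 0:67, collapse = ","))
  rows <- vapply(seq$frames, function(f) {
    coords <- as.vector(t(f$points))  # x0,y0,x1,y1,...
    paste(c(format_num(f$frame_index), vapply(coords, format_num, character(1))),
          collapse = ",")
  }, character(1))
  con <- file(path, "wb")  # binary mode: LF endings, byte-stable output
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%s", format_num(seq$fs)), header, rows),
             con, sep = "\n")
  invisible(path)
}

format_num <- function(x) {
  if (x == floor(x) && abs(x) < 2^31) sprintf("%d", as.integer(x))
  else sprintf("%.17g", x)
}

#' @rdname write_landmarks
#' @param video_id Identifier for the sequence; defaults to the file name
#'   without extension.
#' @export
read_landmarks <- function(path, video_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  fs_line <- grep("^#\\s*fs\\s*=", lines, value = TRUE)
  if (length(fs_line) != 1L) stop("landmark file must carry one '# fs=<Hz>' line")
  fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", fs_line))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 1L) stop("landmark file has no header")
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  expected <- c("frame", paste0(c("x", "y"), rep(0:67, each = 2)))
  if (!identical(header, expected)) {
    stop("landmark file header does not match the documented dialect")
  }
  rows <- body[-1]
  frames <- lapply(seq_along(rows), function(i) {
    vals <- as.numeric(strsplit(rows[i], ",", fixed = TRUE)[[1]])
    if (length(vals) != 137L) {
      stop("frame ", i - 1L, ": expected 137 fields (frame index + 68 points), got ",
           length(vals))
    }
    pts <- matrix(vals[-1], ncol = 2, byrow = TRUE)
    landmark_frame(pts, frame_index = vals[1])
  })
  landmark_sequence(frames, fs = fs,
                    video_id = video_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Construct a frame stack
#'
#' Ordered grayscale images aligned to a landmark sequence. Images are
#' numeric matrices (rows = y, columns = x) on a 0-255 gray scale.
#'
#' @param images List of equally sized numeric matrices.
#' @return An object of class `frame_stack` with `images`, `height`, `width`.
#' @export
frame_stack <- function(images) {
  if (!length(images)) stop("empty frame stack")
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have the same shape")
  }
  structure(list(images = images, height = dims[1, 1], width = dims[2, 1]),
            class = "frame_stack")
}

#' @export
length.frame_stack <- function(x) length(x$images)

#' Write / read a frame stack as a directory of PNG files
#'
#' Frames are written as zero-padded 8-bit grayscale PNGs
#' (`frame_000000.png`, ...).
#'
#' @param stack A [frame_stack()].
#' @param dir Directory (created if needed).
#' @return `write_frames` returns `dir` invisibly; `read_frames` returns a
#'   [frame_stack()].
#' @export
write_frames <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$images)) {
    img <- pmin(pmax(stack$images[[i]], 0), 255)
    png::writePNG(img / 255, file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (!length(files)) stop("no frame PNGs found in ", dir)
  imgs <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * 255
  })
  frame_stack(imgs)
}

#' Construct a subject record
#'
#' @param subject_id Identifier string.
#' @param gender One of `"male"`, `"female"`, `"unknown"`.
#' @param gestational_age_weeks Gestational age at birth in weeks (> 0).
#'   Infants born before 37 weeks are preterm; 37-42 weeks is full-term.
#' @param race One of `"white"`, `"black"`, `"asian"`, `"unknown"`.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, gender = "unknown",
                           gestational_age_weeks = 38, race = "unknown") {
  gender <- match.arg(gender, c("male", "female", "unknown"))
  race <- match.arg(race, c("white", "black", "asian", "unknown"))
  ga <- as.numeric(gestational_age_weeks)
  if (!is.finite(ga) || ga <= 0) stop("gestational_age_weeks must be > 0")
  structure(list(subject_id = as.character(subject_id), gender = gender,
                 gestational_age_weeks = ga, race = race),
            class = "subject_record")
}

#' Gestational age class of a subject
#'
#' @param subject A [subject_record()].
#' @return `"preterm"` (< 37 weeks), `"fullterm"` (37-42 weeks) or
#'   `"postterm"` (> 42 weeks).
#' @export
age_class <- function(subject) {
  ga <- subject$gestational_age_weeks
  if (ga < 37) "preterm" else if (ga <= 42) "fullterm" else "postterm"
}

#' Construct a pain instance
#'
#' One epoch of one subject's video: its feature streams, NIPS score and
#' the derived binary label. The label is always derived from the score
#' (pain iff NIPS >= 3), never supplied independently.
#'
#' @param subject A [subject_record()].
#' @param epoch_id One of `"T0"` ... `"T6"`.
#' @param streams Named list of numeric feature vectors (e.g. `dface`,
#'   `dpose`, `gradient`, `lbptop`).
#' @param nips_score Integer NIPS total in 0-7.
#' @return An object of class `pain_instance`.
#' @export
pain_instance <- function(subject, epoch_id, streams, nips_score) {
  stopifnot(inherits(subject, "subject_record"))
  epoch_id <- match.arg(epoch_id, paste0("T", 0:6))
  if (!is.list(streams) || is.null(names(streams)) || any(!nzchar(names(streams)))) {
    stop("streams must be a named list of feature vectors")
  }
  structure(list(subject = subject, epoch_id = epoch_id, streams = streams,
                 nips_score = validate_nips_score(nips_score),
                 label = pain_label(nips_score)),
            class = "pain_instance")
}

#' Write predictions alongside ground truth as CSV
#'
#' @param instances List of [pain_instance()] objects.
#' @param predictions Data frame with columns `predicted`, `confidence`, and
#'   one `vote_<stream>` column per fused stream (as produced by
#'   [loso_evaluate()]), one row per instance.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_results <- function(instances, predictions, path) {
  vote_cols <- grep("^vote_", names(predictions), value = TRUE)
  if (length(instances) != nrow(predictions)) {
    stop("instances and predictions must have equal length")
  }
  df <- data.frame(
    subject_id = vapply(instances, function(x) x$subject$subject_id, character(1)),
    epoch_id = vapply(instances, function(x) x$epoch_id, character(1)),
    label = vapply(instances, function(x) x$label, character(1)),
    predicted = as.character(predictions$predicted),
    confidence = as.numeric(predictions$confidence),
    stringsAsFactors = FALSE
  )
  for (vc in vote_cols) df[[vc]] <- as.character(predictions[[vc]])
  if (nrow(df) == 0L) {
    # keep the full header even for an empty run
    df <- df[0, , drop = FALSE]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the subject metadata table
#'
#' Columns: `subject_id`, `gender`, `gestational_age_weeks`, `race`.
#'
#' @param subjects List of [subject_record()] objects.
#' @param path CSV path.
#' @export
write_metadata <- function(subjects, path) {
  df <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    gender = vapply(subjects, `[[`, character(1), "gender"),
    gestational_age_weeks = vapply(subjects, `[[`, numeric(1),
                                   "gestational_age_weeks"),
    race = vapply(subjects, `[[`, character(1), "race"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    subject_record(df$subject_id[i], df$gender[i],
                   df$gestational_age_weeks[i], df$race[i])
  })
}
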
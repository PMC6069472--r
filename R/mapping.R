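#' Default 68-point landmark group mapping
#'
#' The package follows the common 68-point facial annotation convention:
#' points 1-17 trace the face boundary (jawline) from the subject's left
#' temple through the chin to the right temple; 18-22 and 23-27 are the left
#' and right eyebrows; 28-31 the nose bridge and 32-36 the nose base; 37-42
#' and 43-48 the left and right eyes (corner, two upper-lid, corner, two
#' lower-lid points); 49-60 the outer lip contour and 61-68 the inner lip
#' contour. "Left" and "right" refer to the subject's anatomical side.
#' Indices are 1-based.
#'
#' Every symbolic point group used by the geometry features is defined here,
#' so an alternative landmark ordering only requires a different mapping
#' (see [read_mapping()]); no distance definition hard-codes an index.
#'
#' The mapping has two parts:
#' \describe{
#'   \item{groups}{named list: group name -> integer landmark indices.}
#'   \item{distances}{named list: distance name -> character pair of group
#'     names. Each distance is the Euclidean distance between the centroids
#'     of its two groups.}
#' }
#'
#' Deformation distances (11): `d_ebl`/`d_ebr` eyebrow-eye, `d_el`/`d_er`
#' upper-lower eyelid, `d_mbl`/`d_mbr` eyebrow-mouth, `d_eml`/`d_emr`
#' eye-mouth, `d_nm` nose-mouth, `d_mw`/`d_mh` mouth width and height
#' (inner lip contour by default). Pose distances (8): face boundary to
#' brow/eye/nose/mouth on each side (`d_bbl`, `d_bel`, `d_bnl`, `d_bml`,
#' `d_bbr`, `d_ber`, `d_bnr`, `d_bmr`).
#'
#' @param lip Which lip contour defines mouth width/height: `"inner"`
#'   (default) or `"outer"`.
#' @return A list with elements `groups` and `distances`.
#' @export
default_mapping <- function(lip = c("inner", "outer")) {
  lip <- match.arg(lip)
  groups <- list(
    boundary_left  = 1:8,
    boundary_right = 10:17,
    chin           = 9L,
    brow_left      = 18:22,
    brow_right     = 23:27,
    nose           = 28:36,
    nose_base      = 32:36,
    eye_left       = 37:42,
    eye_right      = 43:48,
    eye_left_upper  = 38:39,
    eye_left_lower  = 41:42,
    eye_right_upper = 44:45,
    eye_right_lower = 47:48,
    mouth          = 49:68,
    mouth_corner_left_outer  = 49L,
    mouth_corner_right_outer = 55L,
    mouth_corner_left_inner  = 61L,
    mouth_corner_right_inner = 65L,
    lip_upper_outer = 50:54,
    lip_lower_outer = 56:60,
    lip_upper_inner = 62:64,
    lip_lower_inner = 66:68
  )
  mw <- if (lip == "inner") {
    c("mouth_corner_left_inner", "mouth_corner_right_inner")
  } else {
    c("mouth_corner_left_outer", "mouth_corner_right_outer")
  }
  mh <- if (lip == "inner") {
    c("lip_upper_inner", "lip_lower_inner")
  } else {
    c("lip_upper_outer", "lip_lower_outer")
  }
  distances <- list(
    # facial deformation (11)
    d_ebl = c("brow_left", "eye_left"),
    d_ebr = c("brow_right", "eye_right"),
    d_el  = c("eye_left_upper", "eye_left_lower"),
    d_er  = c("eye_right_upper", "eye_right_lower"),
    d_mbl = c("brow_left", "mouth"),
    d_mbr = c("brow_right", "mouth"),
    d_eml = c("eye_left", "mouth"),
    d_emr = c("eye_right", "mouth"),
    d_nm  = c("nose_base", "mouth"),
    d_mw  = mw,
    d_mh  = mh,
    # head pose (8)
    d_bbl = c("boundary_left", "brow_left"),
    d_bel = c("boundary_left", "eye_left"),
    d_bnl = c("boundary_left", "nose"),
    d_bml = c("boundary_left", "mouth"),
    d_bbr = c("boundary_right", "brow_right"),
    d_ber = c("boundary_right", "eye_right"),
    d_bnr = c("boundary_right", "nose"),
    d_bmr = c("boundary_right", "mouth")
  )
  structure(list(groups = groups, distances = distances),
            class = "painface_mapping")
}

#' Names of the deformation and pose distances
#'
#' @return Character vectors, in the fixed stream order.
#' @export
deformation_names <- function() {
  c("d_ebl", "d_ebr", "d_el", "d_er", "d_mbl", "d_mbr",
    "d_eml", "d_emr", "d_nm", "d_mw", "d_mh")
}

#' @rdname deformation_names
#' @export
pose_names <- function() {
  c("d_bbl", "d_bel", "d_bnl", "d_bml", "d_bbr", "d_ber", "d_bnr", "d_bmr")
}

#' Default region-around-point (RAP) configuration
#'
#' The appearance features use 31 square patches centred on landmarks in the
#' wrinkle-prone regions: the eyebrows (10 patches), eye corners and lids
#' (8), nasal root and base (4) and the mouth outline (9). The selection is
#' configuration, not algorithm: any list of 31 indices keeps the printed
#' feature dimensions (31 gradient parameters per frame, 5487 = 177 x 31
#' LBP-TOP values per video).
#'
#' Each patch is assigned a facial side (`"left"`, `"right"` or `"mid"`)
#' used by hemiface feature selection; midline patches belong to both
#' hemifaces. The `mirror` vector pairs each patch with its contralateral
#' counterpart (its own position for midline patches), so that hemiface
#' feature vectors can be compared elementwise across sides.
#'
#' @param patch_size Side length in pixels of the square patch (default 32).
#' @param normalize Logical; L1-normalise each LBP-TOP plane histogram
#'   (default `TRUE`).
#' @return A list with `indices` (31 landmark indices), `side` (character
#'   vector of the same length), `mirror` (integer positions), `patch_size`,
#'   `normalize`.
#' @export
default_rap_config <- function(patch_size = 32L, normalize = TRUE) {
  indices <- c(
    18:22, 23:27,               # left brow (5), right brow (5)
    37L, 38L, 40L, 41L,         # left eye: outer corner, upper lid, inner corner, lower lid
    43L, 45L, 46L, 48L,         # right eye, mirror counterparts of the above
    28L, 31L, 32L, 36L,         # nasal root, bridge base, left and right alae
    49L, 51L, 53L, 55L, 57L, 59L, 61L, 63L, 65L  # mouth outline (9)
  )
  side <- c(
    rep("left", 5), rep("right", 5),
    rep("left", 4), rep("right", 4),
    "mid", "mid", "left", "right",
    "left", "left", "right", "right", "right", "left", "left", "mid", "right"
  )
  mirror <- c(10:6, 5:1,
              17L, 16L, 15L, 18L, 13L, 12L, 11L, 14L,
              19L, 20L, 22L, 21L,
              26L, 25L, 24L, 23L, 28L, 27L, 31L, 30L, 29L)
  stopifnot(length(indices) == 31L, length(side) == 31L,
            identical(mirror[mirror], seq_len(31L)))
  list(indices = indices, side = side, mirror = mirror,
       patch_size = as.integer(patch_size), normalize = isTRUE(normalize))
}

#' Contralateral counterpart of each distance name
#'
#' Maps every deformation or pose distance name to its mirror-image name
#' (midline distances map to themselves).
#'
#' @param names Character vector of distance names.
#' @return Character vector of the same length.
#' @export
mirror_distance_names <- function(names) {
  swap <- function(nm) {
    if (grepl("l$", nm)) sub("l$", "r", nm)
    else if (grepl("r$", nm) && nm != "d_er") sub("r$", "l", nm)
    else if (nm == "d_er") "d_el"
    else nm
  }
  vapply(names, swap, character(1), USE.NAMES = FALSE)
}

#' Read a mapping or RAP configuration from YAML or JSON
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return The parsed configuration list. For a mapping file the result has
#'   class `painface_mapping`.
#' @export
read_mapping <- function(path) {
  cfg <- read_config_file(path)
  if (!all(c("groups", "distances") %in% names(cfg))) {
    stop("mapping file must define 'groups' and 'distances'")
  }
  cfg$groups <- lapply(cfg$groups, as.integer)
  cfg$distances <- lapply(cfg$distances, as.character)
  structure(cfg, class = "painface_mapping")
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported configuration format: .", ext)
  }
}

check_mapping <- function(mapping, needed = NULL) {
  if (!inherits(mapping, "painface_mapping")) {
    stop("'mapping' must be a painface_mapping (see default_mapping())")
  }
  needed <- needed %||% unique(unlist(mapping$distances))
  missing <- setdiff(needed, names(mapping$groups))
  if (length(missing)) {
    stop("mapping is missing point group(s): ", paste(missing, collapse = ", "))
  }
  invisible(mapping)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
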
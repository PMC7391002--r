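# Configural facial features computed from detector bounding boxes and eye /
# nose landmarks. Detection itself is out of scope: landmarks are inputs.

#' Configural facial features from landmarks
#'
#' Computes, per face, the three configural features commonly entered
#' alongside low-level visual features in preference models:
#' * `eye_distance` -- Euclidean distance between the two eye centres,
#'   normalised by face size;
#' * `fwhr` -- facial width-to-height ratio, the detector box's
#'   `width / height`;
#' * `nose_eyes_distance` -- distance between the bottom of the nose and the
#'   midpoint of the two eyes, normalised by face size.
#'
#' "Face size" is the bounding-box height by default (the usual detector-box
#' normaliser, keeping both distance features dimensionless); the box
#' diagonal is available as an alternative.
#'
#' @param landmarks A data frame with one row per face and columns `item_id`,
#'   `box_x`, `box_y`, `box_w`, `box_h` (detector bounding box, pixels),
#'   `lex`, `ley`, `rex`, `rey` (left/right eye centres) and `nx`, `ny`
#'   (bottom of the nose).
#' @param normalizer `"height"` (default) or `"diagonal"`.
#' @return A tibble with columns `item_id`, `eye_distance`, `fwhr`,
#'   `nose_eyes_distance`.
#' @examples
#' lm <- tibble::tibble(item_id = "f1", box_x = 0, box_y = 0,
#'                      box_w = 140, box_h = 140,
#'                      lex = 40, ley = 50, rex = 100, rey = 50,
#'                      nx = 70, ny = 110)
#' facial_features(lm) # eye_distance = 60/140, fwhr = 1
#' @export
facial_features <- function(landmarks, normalizer = c("height", "diagonal")) {
  normalizer <- match.arg(normalizer)
  need <- c("item_id", "box_x", "box_y", "box_w", "box_h",
            "lex", "ley", "rex", "rey", "nx", "ny")
  missing_cols <- setdiff(need, names(landmarks))
  if (length(missing_cols)) {
    abort(paste0("landmarks table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(landmarks$box_w <= 0) || any(landmarks$box_h <= 0)) {
    abort("face box width and height must be positive")
  }
  if (any(landmarks$lex == landmarks$rex & landmarks$ley == landmarks$rey)) {
    abort("eye centres must be distinct")
  }
  face_size <- switch(normalizer,
    height = landmarks$box_h,
    diagonal = sqrt(landmarks$box_w^2 + landmarks$box_h^2)
  )
  if (any(face_size == 0)) abort("face size must be nonzero")
  mid_x <- (landmarks$lex + landmarks$rex) / 2
  mid_y <- (landmarks$ley + landmarks$rey) / 2
  tibble(
    item_id = landmarks$item_id,
    eye_distance = sqrt((landmarks$lex - landmarks$rex)^2 +
                          (landmarks$ley - landmarks$rey)^2) / face_size,
    fwhr = landmarks$box_w / landmarks$box_h,
    nose_eyes_distance = sqrt((landmarks$nx - mid_x)^2 +
                                (landmarks$ny - mid_y)^2) / face_size
  )
}
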
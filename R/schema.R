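# 106-point facial landmark schema.
#
# Commercial landmark detectors (Face++-style "Detect" endpoints) return 106
# named points in pixel coordinates covering the facial contour, eyebrows,
# eyes, nose and mouth.  The vendor numbering is not part of any standard, so
# the schema here is configurable: the math only needs the *names* of the
# three anchor points (the two inner eye corners and a nose point) that
# define the face-anchored coordinate frame.

#' Canonical names of the 106 facial landmark points
#'
#' Returns the point names, in canonical order, of the 106-point landmark
#' schema used throughout the package: 33 facial-contour points, 9 points per
#' eyebrow, 10 per eye (including inner/outer corners), 15 nose points and 20
#' mouth points.
#'
#' @return Character vector of length 106.
#' @export
face_point_names <- function() {
  c(
    paste0("contour_left_", 1:16),
    "contour_chin",
    paste0("contour_right_", 16:1),
    paste0("left_eyebrow_", 1:9),
    paste0("right_eyebrow_", 1:9),
    "left_eye_inner_corner", "left_eye_outer_corner",
    paste0("left_eye_", 1:7), "left_eye_pupil",
    "right_eye_inner_corner", "right_eye_outer_corner",
    paste0("right_eye_", 1:7), "right_eye_pupil",
    "nose_bridge_1", "nose_bridge_2", "nose_bridge_3", "nose_tip",
    paste0("nose_left_contour_", 1:4), paste0("nose_right_contour_", 1:4),
    "nose_left_wing", "nose_right_wing", "nose_base",
    "mouth_left_corner", "mouth_right_corner",
    paste0("mouth_upper_lip_top_", 1:5),
    paste0("mouth_upper_lip_bottom_", 3:1),
    paste0("mouth_lower_lip_top_", 1:3),
    paste0("mouth_lower_lip_bottom_", 5:1),
    "mouth_upper_center", "mouth_lower_center"
  )
}

#' Landmark schema with anchor designations
#'
#' A schema map binds the ordered point names to the three anchors that
#' define the relative (face-anchored) coordinate system: the two inner eye
#' corners and a nose point.  The inter-ocular midpoint becomes the origin,
#' the inner eye corners map to (-1, 0) and (1, 0), and the nose anchor maps
#' to (0, -1).  Which of the nose points the frame should be pinned to is a
#' modelling choice; the default is the nose tip.
#'
#' @param names Character vector of point names (default the canonical 106).
#' @param left_eye,right_eye,nose Names of the anchor points.
#' @return Object of class `face_schema` with fields `names`, `anchors`
#'   (named character vector) and `anchor_idx` (named integer vector).
#' @export
face_schema <- function(names = face_point_names(),
                        left_eye = "left_eye_inner_corner",
                        right_eye = "right_eye_inner_corner",
                        nose = "nose_tip") {
  stopifnot(is.character(names), !anyDuplicated(names))
  anchors <- c(left_eye = left_eye, right_eye = right_eye, nose = nose)
  idx <- match(anchors, names)
  if (anyNA(idx)) {
    stop("anchor point(s) not in schema: ",
         paste(anchors[is.na(idx)], collapse = ", "))
  }
  if (anyDuplicated(idx)) stop("anchor points must be distinct")
  structure(
    list(names = names, anchors = anchors,
         anchor_idx = stats::setNames(as.integer(idx), names(anchors))),
    class = "face_schema"
  )
}

#' @export
print.face_schema <- function(x, ...) {
  cat("<face_schema> ", length(x$names), " points; anchors: ",
      paste(sprintf("%s=%s", names(x$anchors), x$anchors), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Stylized neutral-face template
#'
#' Pixel coordinates (image frame, y growing downward) of a frontal neutral
#' face laid out for the canonical schema.  Used by the synthetic cohort
#' generator; realism is not the goal -- the layout only has to give every
#' point a distinct, plausible location and put the anchors in a
#' non-degenerate configuration.
#'
#' @param schema A [face_schema()].
#' @param center Image-frame position of the inter-ocular midpoint.
#' @param eye_half_distance Half the inner-eye-corner distance, in pixels.
#'   This is the pixel length of one relative-coordinate unit.
#' @return Numeric matrix 106 x 2 (columns `m`, `n`), rownames = point names.
#' @export
face_template <- function(schema = face_schema(), center = c(320, 240),
                          eye_half_distance = 30) {
  u <- eye_half_distance  # one relative unit, in pixels
  nm <- schema$names
  P <- matrix(NA_real_, length(nm), 2, dimnames = list(nm, c("m", "n")))
  put <- function(name, x, y) P[name, ] <<- center + u * c(x, y)

  # facial contour: lower half-ellipse from left temple to right temple
  th <- seq(pi, 2 * pi, length.out = 33)
  for (i in 1:33) {
    put(c(paste0("contour_left_", 1:16), "contour_chin",
          paste0("contour_right_", 16:1))[i],
        2.4 * cos(th[i]), -1.2 - 3.4 * sin(th[i]))
  }
  # eyebrows: arcs above the eyes
  for (s in c(-1, 1)) {
    side <- if (s < 0) "left" else "right"
    tt <- seq(-0.5, 0.5, length.out = 9)
    for (i in 1:9) {
      put(paste0(side, "_eyebrow_", i),
          s * (1.5 + 0.9 * tt[i]), -1.1 - 0.35 * cos(pi * tt[i]))
    }
  }
  # eyes: inner corner at (+-1, 0), outer at (+-2, 0), rim of 7, pupil
  for (s in c(-1, 1)) {
    side <- if (s < 0) "left" else "right"
    put(paste0(side, "_eye_inner_corner"), s * 1, 0)
    put(paste0(side, "_eye_outer_corner"), s * 2, 0)
    tt <- seq(0.25, 1.75, length.out = 7)
    for (i in 1:7) {
      put(paste0(side, "_eye_", i),
          s * (1.5 + 0.5 * cos(pi * tt[i])), -0.22 * sin(pi * tt[i]))
    }
    put(paste0(side, "_eye_pupil"), s * 1.5, 0)
  }
  # nose: bridge down the midline, tip at (0, -1) relative... note image y
  # grows downward, so "below the eyes" is positive n; the nose anchor sits
  # at +1 unit in n, and the relative frame's basis absorbs the flip.
  put("nose_bridge_1", 0, 0.25); put("nose_bridge_2", 0, 0.55)
  put("nose_bridge_3", 0, 0.8); put("nose_tip", 0, 1)
  for (s in c(-1, 1)) {
    side <- if (s < 0) "left" else "right"
    for (i in 1:4) {
      put(paste0("nose_", side, "_contour_", i),
          s * (0.12 + 0.1 * i), 0.35 + 0.17 * i)
    }
    put(paste0("nose_", side, "_wing"), s * 0.55, 1.02)
  }
  put("nose_base", 0, 1.15)
  # mouth: two lip arcs between the corners
  put("mouth_left_corner", -0.9, 1.75)
  put("mouth_right_corner", 0.9, 1.75)
  xs5 <- seq(-0.6, 0.6, length.out = 5)
  for (i in 1:5) put(paste0("mouth_upper_lip_top_", i), xs5[i],
                     1.6 - 0.08 * cos(pi * xs5[i] / 1.2))
  xs3 <- seq(-0.35, 0.35, length.out = 3)
  for (i in 1:3) put(paste0("mouth_upper_lip_bottom_", i), xs3[i], 1.72)
  for (i in 1:3) put(paste0("mouth_lower_lip_top_", i), xs3[i], 1.8)
  for (i in 1:5) put(paste0("mouth_lower_lip_bottom_", i), xs5[i],
                     1.92 + 0.1 * cos(pi * xs5[i] / 1.2))
  put("mouth_upper_center", 0, 1.66)
  put("mouth_lower_center", 0, 1.86)

  stopifnot(!anyNA(P))
  P
}

#' Default expression-signal point set
#'
#' Key points that carry the smile signal in the synthetic generator: the
#' mouth region plus the outer eye corners (the regions a smile displaces).
#'
#' @param schema A [face_schema()].
#' @return Character vector of point names.
#' @export
default_signal_points <- function(schema = face_schema()) {
  nm <- schema$names
  c(grep("^mouth_", nm, value = TRUE),
    grep("eye_outer_corner$", nm, value = TRUE),
    grep("^nose_(left|right)_wing$", nm, value = TRUE))
}
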
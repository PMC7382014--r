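# Face-anchored relative coordinate system.
#
# Rigid head motion (the subject swaying in front of the camera) contaminates
# expression-amplitude measurements made in pixel coordinates.  The fix is a
# non-Cartesian frame anchored to the face itself: origin at the midpoint of
# the inner eye corners, the right inner eye corner pinned at (1, 0), the
# left at (-1, 0), and a nose point at (0, -1).  Any point p then has
# relative coordinates (x, y) solving
#
#     p - origin = x * a + y * b
#
# with basis vectors a = right_eye - origin and b = origin - nose.  The basis
# vectors are *not* Euclidean unit vectors -- their pixel length is the
# eye-half-distance -- which is exactly what makes the frame invariant under
# translation, rotation and uniform scaling of the image.

#' Face basis of one frame
#'
#' @param frame Numeric `P x 2` matrix of absolute coordinates with point
#'   names as rownames (one frame of a `landmark_sequence`).
#' @param schema A [face_schema()] naming the anchors.
#' @param tol Degeneracy tolerance: the basis is rejected when
#'   `|det| <= tol * |a| * |b|` (scale-free, default 1e-6).
#' @return Object of class `face_basis`: list with `origin`, `a`, `b`, `det`.
#' @export
face_basis <- function(frame, schema = face_schema(), tol = 1e-6) {
  le <- frame[schema$anchors[["left_eye"]], ]
  re <- frame[schema$anchors[["right_eye"]], ]
  no <- frame[schema$anchors[["nose"]], ]
  origin <- (le + re) / 2
  a <- re - origin
  b <- origin - no
  det <- a[1] * b[2] - a[2] * b[1]
  if (abs(det) <= tol * sqrt(sum(a^2)) * sqrt(sum(b^2))) {
    stop("degenerate face: eye corners and nose anchor are (nearly) collinear")
  }
  structure(list(origin = unname(origin), a = unname(a), b = unname(b),
                 det = unname(det)),
            class = "face_basis")
}

#' Absolute-to-relative coordinate conversion
#'
#' Solves the 2x2 linear system `p - origin = x a + y b` exactly (Cramer's
#' rule).  The anchors map to (1,0) / (-1,0) / (0,-1) and the origin to
#' (0,0).
#'
#' @param p Numeric length-2 point or `k x 2` matrix of absolute coordinates.
#' @param basis A [face_basis()].
#' @return Relative coordinates, same shape as `p`.
#' @export
to_relative <- function(p, basis) {
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, 1, 2)
  dm <- p[, 1] - basis$origin[1]
  dn <- p[, 2] - basis$origin[2]
  x <- (dm * basis$b[2] - dn * basis$b[1]) / basis$det
  y <- (basis$a[1] * dn - basis$a[2] * dm) / basis$det
  out <- cbind(x = x, y = y)
  rownames(out) <- rownames(p)
  if (vec) out[1, ] else out
}

#' Inverse conversion (relative to absolute)
#'
#' @param q Relative length-2 point or `k x 2` matrix.
#' @param basis A [face_basis()].
#' @return Absolute coordinates `origin + x a + y b`.
#' @export
from_relative <- function(q, basis) {
  vec <- is.null(dim(q))
  if (vec) q <- matrix(q, 1, 2)
  out <- cbind(
    basis$origin[1] + q[, 1] * basis$a[1] + q[, 2] * basis$b[1],
    basis$origin[2] + q[, 1] * basis$a[2] + q[, 2] * basis$b[2]
  )
  colnames(out) <- c("m", "n")
  rownames(out) <- rownames(q)
  if (vec) out[1, ] else out
}

#' Convert a whole record to relative coordinates
#'
#' By default the basis is recomputed every frame (`per_frame`), so head pose
#' changes within the record are cancelled frame by frame; `first_frame`
#' reuses frame 0's basis throughout (kept for ablation).
#'
#' @param seq A `landmark_sequence`.
#' @param schema A [face_schema()].
#' @param basis_policy `"per_frame"` (default) or `"first_frame"`.
#' @return Object of class `relative_sequence`: same metadata as `seq`,
#'   `coords` array `N x P x 2` of relative (x, y), and `bases` (list of
#'   per-frame `face_basis`).
#' @export
to_relative_sequence <- function(seq, schema = face_schema(),
                                 basis_policy = c("per_frame", "first_frame")) {
  stopifnot(inherits(seq, "landmark_sequence"))
  basis_policy <- match.arg(basis_policy)
  N <- n_frames(seq)
  rel <- seq$coords
  dimnames(rel)[[3]] <- c("x", "y")
  bases <- vector("list", N)
  b0 <- NULL
  for (i in seq_len(N)) {
    fr <- seq$coords[i, , ]
    if (basis_policy == "per_frame" || i == 1L) {
      b0 <- tryCatch(face_basis(fr, schema),
                     error = function(e) stop("frame ", i - 1, ": ",
                                              conditionMessage(e)))
    }
    bases[[i]] <- b0
    rel[i, , ] <- to_relative(fr, b0)
  }
  structure(
    list(coords = rel, bases = bases, basis_policy = basis_policy,
         subject_id = seq$subject_id, record_id = seq$record_id,
         label = seq$label, frame_interval_s = seq$frame_interval_s),
    class = "relative_sequence"
  )
}

#' @export
print.relative_sequence <- function(x, ...) {
  cat(sprintf(
    "<relative_sequence> record %s (subject %s, %s): %d frames, basis=%s\n",
    x$record_id, x$subject_id, x$label, n_frames(x), x$basis_policy))
  invisible(x)
}
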
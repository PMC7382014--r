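# Per-keypoint trajectory features.
#
# Two feature families per key point, 8 features in all:
#
#  * expression amplitude, on *relative* coordinates (hypomimia shrinks these):
#      R_x_max  = max(x) - min(x)            horizontal range
#      R_y_max  = max(y) - min(y)            vertical range
#      cov_rel  = Cov(X, Y)                  population covariance
#      cov_abs  = Cov(X_abs, Y_abs)          covariance of the *absolute*
#                                            track (reflects head shaking)
#  * positional jitter, on *absolute* pixel coordinates (tremor raises these):
#      jitter_abs   mean distance between adjacent frames
#      jitter_ppq5  mean distance from the centered 5-frame mean position
#      jitter_rap   mean distance from the centered 3-frame mean position
#      jitter_ddp   mean |difference of adjacent inter-frame distances|
#
# All windows are fully interior (no partial windows at the ends), giving
# divisors N-1, N-4, N-2 and N-2 respectively.  The jitter statistics are
# plain averages of pixel distances -- no normalization by mean position.

FEATURE_NAMES <- c("R_x_max", "R_y_max", "cov_rel", "cov_abs",
                   "jitter_abs", "jitter_ppq5", "jitter_rap", "jitter_ddp")
AMPLITUDE_FEATURES <- FEATURE_NAMES[1:4]
JITTER_FEATURES <- FEATURE_NAMES[5:8]

#' Coordinate ranges of one trajectory
#' @param xs,ys Per-frame coordinate values (length N >= 1).
#' @return Named numeric `c(R_x_max, R_y_max)`, each `max - min`.
#' @export
ranges <- function(xs, ys) {
  stopifnot(length(xs) >= 1, length(ys) == length(xs))
  c(R_x_max = max(xs) - min(xs), R_y_max = max(ys) - min(ys))
}

#' Population covariance E(XY) - E(X)E(Y)
#' @param xs,ys Equal-length numeric vectors (N >= 1); divisor is N.
#' @return Scalar covariance.
#' @export
covariance <- function(xs, ys) {
  stopifnot(length(xs) >= 1, length(ys) == length(xs))
  mean(xs * ys) - mean(xs) * mean(ys)
}

#' Euclidean distance between two positions
#' @param p,q Length-2 numeric vectors.
#' @return Scalar distance.
#' @export
euclid <- function(p, q) sqrt(sum((p - q)^2))

#' Mean position of a set of position vectors
#' @param P Numeric `N x 2` matrix (rows = positions).
#' @return Length-2 column means.
#' @export
mean_position <- function(P) {
  stopifnot(is.matrix(P), nrow(P) >= 1, ncol(P) == 2)
  colMeans(P)
}

.check_traj <- function(traj, min_n) {
  if (!is.matrix(traj) || ncol(traj) != 2) {
    stop("trajectory must be an N x 2 matrix")
  }
  if (nrow(traj) < min_n) {
    stop("trajectory needs at least ", min_n, " frames, got ", nrow(traj))
  }
}

.step_lengths <- function(traj) {
  d <- diff(traj)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

#' Absolute positional jitter
#'
#' Mean Euclidean distance between adjacent frames, `sum d(p_i, p_{i+1}) /
#' (N - 1)`.
#'
#' @param traj Numeric `N x 2` matrix of per-frame positions (N >= 2).
#' @return Scalar jitter (pixels when fed absolute coordinates).
#' @export
jitter_abs <- function(traj) {
  .check_traj(traj, 2)
  mean(.step_lengths(traj))
}

.jitter_window <- function(traj, half) {
  n <- nrow(traj)
  K <- 2 * half + 1
  i <- (half + 1):(n - half)
  # deviation from the centered window mean, computed as the mean of
  # pairwise differences sum_k (p_i - p_{i+k}) / K: algebraically identical
  # to p_i - mean(window) but exactly zero on a static trajectory
  devx <- devy <- numeric(length(i))
  for (k in setdiff(-half:half, 0)) {
    devx <- devx + (traj[i, 1] - traj[i + k, 1])
    devy <- devy + (traj[i, 2] - traj[i + k, 2])
  }
  mean(sqrt((devx / K)^2 + (devy / K)^2))
}

#' Five-point period-perturbation jitter (PPQ5)
#'
#' Mean distance between each interior frame and the mean position of the 5
#' adjacent frames centered on it; divisor `N - 4`.
#'
#' @inheritParams jitter_abs
#' @return Scalar jitter.
#' @export
jitter_ppq5 <- function(traj) {
  .check_traj(traj, 5)
  .jitter_window(traj, 2L)
}

#' Relative-average-perturbation jitter (RAP)
#'
#' Mean distance between each interior frame and the mean position of the 3
#' adjacent frames centered on it; divisor `N - 2`.
#'
#' @inheritParams jitter_abs
#' @return Scalar jitter.
#' @export
jitter_rap <- function(traj) {
  .check_traj(traj, 3)
  .jitter_window(traj, 1L)
}

#' Difference-of-differences jitter (DDP)
#'
#' Mean absolute difference between consecutive inter-frame distances,
#' `sum_i |d(p_i, p_{i+1}) - d(p_{i-1}, p_i)| / (N - 2)`.
#'
#' @inheritParams jitter_abs
#' @return Scalar jitter.
#' @export
jitter_ddp <- function(traj) {
  .check_traj(traj, 3)
  mean(abs(diff(.step_lengths(traj))))
}

#' Canonical 848 feature column names
#'
#' Point-major order: for each of the 106 points (schema order), the 8
#' features in the order R_x_max, R_y_max, cov_rel, cov_abs, jitter_abs,
#' jitter_ppq5, jitter_rap, jitter_ddp, named `"{point}__{feature}"`.
#'
#' @param schema A [face_schema()].
#' @return Character vector of length `106 * 8 = 848`.
#' @export
feature_column_names <- function(schema = face_schema()) {
  as.vector(t(outer(schema$names, FEATURE_NAMES, paste, sep = "__")))
}

#' Extract the 848-feature block of one record
#'
#' Amplitude features come from the relative coordinates; `cov_abs` and the
#' four jitter features from the absolute pixel coordinates.  Records
#' shorter than 5 frames (the PPQ5 window) are rejected.
#'
#' @param seq A `landmark_sequence` (absolute coordinates).
#' @param rel The matching `relative_sequence`; computed from `seq` when
#'   omitted.
#' @param schema A [face_schema()].
#' @return Named numeric vector of 848 features in canonical column order.
#' @export
extract_record <- function(seq, rel = NULL, schema = face_schema()) {
  stopifnot(inherits(seq, "landmark_sequence"))
  if (is.null(rel)) rel <- to_relative_sequence(seq, schema)
  stopifnot(inherits(rel, "relative_sequence"),
            identical(rel$record_id, seq$record_id),
            n_frames(rel) == n_frames(seq))
  N <- n_frames(seq)
  if (N < 5) {
    stop("record ", seq$record_id, " rejected: ", N,
         " frames < minimum 5 (PPQ5 window)")
  }
  pn <- dimnames(seq$coords)[[2]]
  out <- numeric(length(pn) * 8)
  names(out) <- feature_column_names(schema)
  for (j in seq_along(pn)) {
    abs_traj <- seq$coords[, j, ]
    rel_traj <- rel$coords[, j, ]
    vals <- c(
      ranges(rel_traj[, 1], rel_traj[, 2]),
      cov_rel = covariance(rel_traj[, 1], rel_traj[, 2]),
      cov_abs = covariance(abs_traj[, 1], abs_traj[, 2]),
      jitter_abs = jitter_abs(abs_traj),
      jitter_ppq5 = jitter_ppq5(abs_traj),
      jitter_rap = jitter_rap(abs_traj),
      jitter_ddp = jitter_ddp(abs_traj)
    )
    out[((j - 1) * 8 + 1):(j * 8)] <- vals
  }
  out
}

#' Build the per-record feature table of a cohort
#'
#' @param seqs List of `landmark_sequence`.
#' @param rels Optional list of matching `relative_sequence` (computed when
#'   omitted).
#' @param schema A [face_schema()].
#' @param basis_policy Passed to [to_relative_sequence()] when `rels` is
#'   omitted.
#' @return `data.frame` with columns `record_id`, `subject_id`, `label`
#'   (factor PD/control) followed by the 848 feature columns.
#' @export
feature_table <- function(seqs, rels = NULL, schema = face_schema(),
                          basis_policy = "per_frame") {
  if (is.null(rels)) {
    rels <- lapply(seqs, to_relative_sequence, schema = schema,
                   basis_policy = basis_policy)
  }
  stopifnot(length(rels) == length(seqs))
  feat <- t(vapply(seq_along(seqs),
                   function(i) extract_record(seqs[[i]], rels[[i]], schema),
                   numeric(848)))
  meta <- data.frame(
    record_id = vapply(seqs, `[[`, "", "record_id"),
    subject_id = vapply(seqs, `[[`, "", "subject_id"),
    label = factor(vapply(seqs, `[[`, "", "label"), levels = VALID_LABELS),
    stringsAsFactors = FALSE
  )
  cbind(meta, as.data.frame(feat))
}

#' Split a feature table into metadata and feature matrix
#' @param table A [feature_table()] data frame.
#' @return List with `meta` (data.frame), `x` (numeric matrix records x 848),
#'   `y` (0/1 numeric, PD = 1), `labels` (factor), `groups` (subject ids).
#' @keywords internal
split_feature_table <- function(table) {
  meta_cols <- c("record_id", "subject_id", "label")
  stopifnot(all(meta_cols %in% names(table)))
  x <- as.matrix(table[, setdiff(names(table), meta_cols), drop = FALSE])
  if (nrow(x) == 0) stop("feature table has zero rows")
  labels <- factor(table$label, levels = VALID_LABELS)
  list(meta = table[meta_cols], x = x,
       y = as.numeric(labels == "PD"), labels = labels,
       groups = as.character(table$subject_id))
}
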
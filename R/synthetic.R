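# Synthetic landmark cohort generator.
#
# Stands in for the (unreleased) clinical smile videos.  The generated world
# has the statistical structure the analysis assumes:
#
#  * two groups (PD / control), repeated records per subject;
#  * a smooth smile: half-sine displacement of the mouth/eye-corner region
#    over the record, with group-dependent amplitude (hypomimia = smaller
#    amplitude in the PD group);
#  * group-dependent per-frame isotropic Gaussian positional noise standing
#    in for tremor.  At 10 Hz sampling, physiological 4-6 Hz tremor sits at
#    or above the Nyquist frequency, so a sinusoidal tremor model would be
#    aliased anyway; white positional noise is what the jitter statistics
#    actually measure;
#  * optional rigid head motion (drift or rotation) as a nuisance that the
#    relative coordinate frame must cancel.

#' Synthetic cohort configuration
#'
#' Defaults mirror the clinical study design this package emulates: 33 PD
#' and 31 control subjects, 3 records per subject, 5-second records sampled
#' every 0.1 s (50 frames).  Amplitudes are in relative-coordinate units
#' (fractions of the eye-half-distance); tremor sigmas in pixels.
#'
#' @param n_pd,n_ctrl Subject counts per group.
#' @param records_per_subject Records (videos) per subject.
#' @param frames_per_record Frames per record.
#' @param frame_interval_s Seconds between frames.
#' @param smile_amplitude_pd,smile_amplitude_ctrl Peak smile displacement of
#'   the signal points, in relative units.  PD default 0.10 vs control 0.25:
#'   hypomimic smiles have well under half the excursion of controls.
#' @param tremor_sigma_pd,tremor_sigma_ctrl Per-frame isotropic positional
#'   noise SD in pixels (PD default 0.6, control 0.2 -- a 3x contrast).
#' @param head_motion `"drift"`, `"rotation"` or `"none"`.
#' @param head_motion_magnitude Total drift in pixels, or total rotation in
#'   degrees, over one record.
#' @param signal_points Point names carrying the smile signal.
#' @param eye_half_distance,center Template geometry, see [face_template()].
#' @param subject_sd Log-scale SD of per-subject amplitude and tremor
#'   multipliers (biological variability between subjects).
#' @param record_sd Log-scale SD of the per-record amplitude multiplier
#'   (take-to-take variability of one subject's smile).
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_pd = 33, n_ctrl = 31, records_per_subject = 3,
                             frames_per_record = 50, frame_interval_s = 0.1,
                             smile_amplitude_pd = 0.10,
                             smile_amplitude_ctrl = 0.25,
                             tremor_sigma_pd = 0.6, tremor_sigma_ctrl = 0.2,
                             head_motion = c("drift", "none", "rotation"),
                             head_motion_magnitude = 5,
                             signal_points = default_signal_points(),
                             eye_half_distance = 30, center = c(320, 240),
                             subject_sd = 0.2, record_sd = 0.05, seed = 1L) {
  head_motion <- match.arg(head_motion)
  stopifnot(n_pd >= 1, n_ctrl >= 1, records_per_subject >= 1,
            frames_per_record >= 1, frame_interval_s > 0,
            smile_amplitude_pd >= 0, smile_amplitude_ctrl >= 0,
            tremor_sigma_pd >= 0, tremor_sigma_ctrl >= 0,
            head_motion_magnitude >= 0, subject_sd >= 0, record_sd >= 0,
            eye_half_distance > 0)
  structure(list(
    n_pd = as.integer(n_pd), n_ctrl = as.integer(n_ctrl),
    records_per_subject = as.integer(records_per_subject),
    frames_per_record = as.integer(frames_per_record),
    frame_interval_s = frame_interval_s,
    smile_amplitude_pd = smile_amplitude_pd,
    smile_amplitude_ctrl = smile_amplitude_ctrl,
    tremor_sigma_pd = tremor_sigma_pd, tremor_sigma_ctrl = tremor_sigma_ctrl,
    head_motion = head_motion,
    head_motion_magnitude = head_motion_magnitude,
    signal_points = signal_points,
    eye_half_distance = eye_half_distance, center = center,
    subject_sd = subject_sd, record_sd = record_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# per-point smile displacement directions, in template pixel space:
# away from the mouth center and slightly upward (negative n = up).
.smile_directions <- function(template, signal_points) {
  mouth_center <- colMeans(template[c("mouth_left_corner",
                                      "mouth_right_corner",
                                      "mouth_upper_center",
                                      "mouth_lower_center"), , drop = FALSE])
  dirs <- matrix(0, length(signal_points), 2,
                 dimnames = list(signal_points, c("m", "n")))
  for (p in signal_points) {
    v <- template[p, ] - mouth_center
    len <- sqrt(sum(v^2))
    v <- if (len < 1e-9) c(0, 0) else v / len
    d <- v + c(0, -0.8)              # outward from mouth + upward pull
    dirs[p, ] <- d / sqrt(sum(d^2))
  }
  dirs
}

#' Generate a synthetic landmark cohort
#'
#' Fully reproducible from `cfg$seed`: same config, same cohort bit for bit.
#'
#' @param cfg A [synthetic_config()].
#' @param schema A [face_schema()].
#' @return List with `sequences` (list of `landmark_sequence`) and
#'   `manifest` (data.frame: subject_id, record_id, label, frame_interval).
#' @export
generate_cohort <- function(cfg = synthetic_config(), schema = face_schema()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  template <- face_template(schema, cfg$center, cfg$eye_half_distance)
  dirs <- .smile_directions(template, cfg$signal_points)
  sig_idx <- match(cfg$signal_points, schema$names)
  N <- cfg$frames_per_record
  P <- length(schema$names)
  tt <- seq(0, 1, length.out = N)
  smile_profile <- sin(pi * tt)  # half-sine: neutral -> peak -> neutral

  subjects <- data.frame(
    subject_id = c(sprintf("pd%02d", seq_len(cfg$n_pd)),
                   sprintf("ct%02d", seq_len(cfg$n_ctrl))),
    label = rep(c("PD", "control"), c(cfg$n_pd, cfg$n_ctrl)),
    stringsAsFactors = FALSE
  )
  seqs <- list()
  for (s in seq_len(nrow(subjects))) {
    pd <- subjects$label[s] == "PD"
    amp0 <- if (pd) cfg$smile_amplitude_pd else cfg$smile_amplitude_ctrl
    sig0 <- if (pd) cfg$tremor_sigma_pd else cfg$tremor_sigma_ctrl
    # between-subject biological variability (lognormal multipliers)
    amp_subj <- amp0 * exp(stats::rnorm(1, 0, cfg$subject_sd))
    sig_subj <- sig0 * exp(stats::rnorm(1, 0, cfg$subject_sd / 2))
    for (r in seq_len(cfg$records_per_subject)) {
      amp <- amp_subj * exp(stats::rnorm(1, 0, cfg$record_sd))  # take-to-take
      coords <- array(rep(template, each = N), c(N, P, 2),
                      dimnames = list(NULL, schema$names, c("m", "n")))
      # smile displacement of the signal points
      disp <- amp * cfg$eye_half_distance
      for (k in seq_along(sig_idx)) {
        coords[, sig_idx[k], 1] <-
          coords[, sig_idx[k], 1] + disp * smile_profile * dirs[k, 1]
        coords[, sig_idx[k], 2] <-
          coords[, sig_idx[k], 2] + disp * smile_profile * dirs[k, 2]
      }
      # rigid head-motion nuisance applied to all points
      if (cfg$head_motion == "drift" && cfg$head_motion_magnitude > 0) {
        ang <- stats::runif(1, 0, 2 * pi)
        sh <- cfg$head_motion_magnitude * tt
        coords[, , 1] <- coords[, , 1] + sh * cos(ang)
        coords[, , 2] <- coords[, , 2] + sh * sin(ang)
      } else if (cfg$head_motion == "rotation" &&
                 cfg$head_motion_magnitude > 0) {
        th <- cfg$head_motion_magnitude * pi / 180 * tt
        for (i in seq_len(N)) {
          R <- matrix(c(cos(th[i]), sin(th[i]), -sin(th[i]), cos(th[i])), 2)
          ctr <- matrix(cfg$center, P, 2, byrow = TRUE)
          coords[i, , ] <- (coords[i, , ] - ctr) %*% t(R) + ctr
        }
      }
      # tremor: white isotropic positional noise, every point, every frame
      if (sig_subj > 0) {
        coords <- coords + stats::rnorm(length(coords), 0, sig_subj)
      }
      seqs[[length(seqs) + 1L]] <- landmark_sequence(
        coords, subjects$subject_id[s],
        sprintf("%s_r%d", subjects$subject_id[s], r),
        subjects$label[s], cfg$frame_interval_s, schema)
    }
  }
  manifest <- data.frame(
    subject_id = vapply(seqs, `[[`, "", "subject_id"),
    record_id = vapply(seqs, `[[`, "", "record_id"),
    label = vapply(seqs, `[[`, "", "label"),
    frame_interval = cfg$frame_interval_s,
    stringsAsFactors = FALSE
  )
  list(sequences = seqs, manifest = manifest)
}

#' Audit the effects realized by a synthetic cohort
#'
#' Checks that the generator delivered its configured contrasts: per-group
#' mean absolute jitter and mean vertical amplitude (R_y_max) over the
#' signal points.
#'
#' @param cohort Output of [generate_cohort()], or a list of
#'   `landmark_sequence`.
#' @param signal_points Point names to average amplitude over.
#' @param schema A [face_schema()].
#' @return data.frame with one row per group: `label`, `n_records`,
#'   `mean_jitter_abs`, `mean_R_y_max`.
#' @export
effect_audit <- function(cohort, signal_points = default_signal_points(),
                         schema = face_schema()) {
  seqs <- if (!is.null(cohort$sequences)) cohort$sequences else cohort
  rows <- lapply(seqs, function(s) {
    rel <- to_relative_sequence(s, schema)
    j <- mean(vapply(seq_along(schema$names),
                     function(k) jitter_abs(s$coords[, k, ]), numeric(1)))
    idx <- match(signal_points, schema$names)
    ry <- mean(vapply(idx, function(k) {
      ranges(rel$coords[, k, 1], rel$coords[, k, 2])[["R_y_max"]]
    }, numeric(1)))
    data.frame(label = s$label, jitter_abs = j, R_y_max = ry)
  })
  df <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(df, df$label), function(g) {
    data.frame(label = g$label[1], n_records = nrow(g),
               mean_jitter_abs = mean(g$jitter_abs),
               mean_R_y_max = mean(g$R_y_max))
  }))
  rownames(out) <- NULL
  out
}
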
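# Shared fixtures, built in code at test time.

SCHEMA <- face_schema()

# random but non-degenerate landmark frame: template + mild point scatter
random_frame <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- face_template(SCHEMA)
  tpl + matrix(rnorm(length(tpl), 0, 2), nrow(tpl), ncol(tpl))
}

# random landmark sequence of n frames
random_sequence <- function(n = 6, seed = 1, subject = "s1", record = "r1",
                            label = "PD") {
  set.seed(seed)
  frames <- lapply(seq_len(n), function(i) random_frame())
  landmark_sequence(frames, subject, record, label, 0.1, SCHEMA)
}

# apply a similarity transform (rotation th, scale s, translation tr) to a
# P x 2 matrix of image coordinates
similarity <- function(P, th = 0, s = 1, tr = c(0, 0)) {
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  out <- s * P %*% t(R)
  out[, 1] <- out[, 1] + tr[1]
  out[, 2] <- out[, 2] + tr[2]
  dimnames(out) <- dimnames(P)
  out
}

# write one frame as a Face++-dialect JSON fixture; drop/add keys on demand
write_json_frame <- function(frame, path, drop = character(), extra = NULL) {
  lm <- lapply(seq_len(nrow(frame)), function(i) {
    list(x = frame[i, 1], y = frame[i, 2])
  })
  names(lm) <- rownames(frame)
  lm <- lm[setdiff(names(lm), drop)]
  if (!is.null(extra)) lm <- c(lm, extra)
  jsonlite::write_json(list(landmark = lm), path, auto_unbox = TRUE,
                       digits = NA)
  path
}

# small cohort + feature table, cached per test run
small_cohort <- function(n = 6, seed = 11, ...) {
  generate_cohort(synthetic_config(n_pd = n, n_ctrl = n, seed = seed, ...))
}

small_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- feature_table(small_cohort()$sequences)
    cache
  }
})

# independent brute-force jitter oracles (naive double loops, no shared code
# with the package implementations)
oracle_dist <- function(p, q) sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)

oracle_jitter_abs <- function(traj) {
  n <- nrow(traj); acc <- 0
  for (i in 1:(n - 1)) acc <- acc + oracle_dist(traj[i, ], traj[i + 1, ])
  acc / (n - 1)
}

oracle_jitter_window <- function(traj, half) {
  n <- nrow(traj); acc <- 0; cnt <- 0
  for (i in (half + 1):(n - half)) {
    w <- traj[(i - half):(i + half), , drop = FALSE]
    avg <- c(sum(w[, 1]), sum(w[, 2])) / nrow(w)
    acc <- acc + oracle_dist(traj[i, ], avg)
    cnt <- cnt + 1
  }
  acc / cnt
}

oracle_jitter_ddp <- function(traj) {
  n <- nrow(traj); acc <- 0
  for (i in 2:(n - 1)) {
    acc <- acc + abs(oracle_dist(traj[i, ], traj[i + 1, ]) -
                       oracle_dist(traj[i - 1, ], traj[i, ]))
  }
  acc / (n - 2)
}

random_traj <- function(n) matrix(rnorm(2 * n, 0, 5), n, 2)
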
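test_that("amplitude primitives match hand-computed values", {
  expect_equal(unname(ranges(c(0.1, 0.5, 0.3), c(0, 0, 0))[1]), 0.4)
  expect_equal(unname(ranges(c(1, 1), c(2, 2))), c(0, 0))
  expect_equal(unname(ranges(c(-1, 1), c(2, -2))), c(2, 4))

  expect_equal(covariance(c(1, 2, 3), c(2, 4, 6)), 4 / 3)   # 28/3 - 8
  expect_equal(covariance(c(1, 2, 3), c(5, 5, 5)), 0)
  expect_equal(covariance(c(0, 1), c(0, 1)), 0.25)           # 0.5 - 0.25

  expect_equal(euclid(c(0, 0), c(3, 4)), 5)
  expect_equal(euclid(c(2, 2), c(2, 2)), 0)
  expect_equal(euclid(c(1, 1), c(4, 5)), 5)

  expect_equal(mean_position(rbind(c(0, 0), c(2, 4))), c(1, 2))
  expect_equal(mean_position(rbind(c(7, -3))), c(7, -3))
  expect_equal(mean_position(rbind(c(1, 0), c(0, 1), c(-1, -1))), c(0, 0))
})

test_that("jitter statistics match their printed-window definitions", {
  expect_equal(jitter_abs(rbind(c(0, 0), c(3, 4), c(3, 4))), 2.5)
  expect_equal(jitter_abs(rbind(c(0, 0), c(1, 0), c(2, 0))), 1)
  expect_equal(jitter_abs(matrix(1, 4, 2)), 0)

  expect_equal(jitter_rap(rbind(c(0, 0), c(3, 0), c(0, 0))), 2)
  expect_equal(jitter_rap(matrix(2, 5, 2)), 0)

  expect_equal(jitter_ppq5(rbind(c(0, 0), c(0, 0), c(5, 0), c(0, 0),
                                 c(0, 0))), 4)
  expect_equal(jitter_ppq5(matrix(0, 5, 2)), 0)

  expect_equal(jitter_ddp(rbind(c(0, 0), c(1, 0), c(3, 0), c(6, 0))), 1)
  expect_equal(jitter_ddp(rbind(c(0, 0), c(0, 3), c(0, 3))), 3)
  expect_equal(jitter_ddp(rbind(c(0, 0), c(2, 0), c(4, 0), c(6, 0))), 0)

  expect_error(jitter_abs(matrix(0, 1, 2)), "at least 2")
  expect_error(jitter_rap(matrix(0, 2, 2)), "at least 3")
  expect_error(jitter_ppq5(matrix(0, 4, 2)), "at least 5")
})

test_that("jitters match independent brute-force oracles to 1e-12", {
  set.seed(99)
  for (k in 1:300) {
    n <- sample(5:50, 1)
    tr <- random_traj(n)
    expect_equal(jitter_abs(tr), oracle_jitter_abs(tr), tolerance = 1e-12)
    expect_equal(jitter_rap(tr), oracle_jitter_window(tr, 1),
                 tolerance = 1e-12)
    expect_equal(jitter_ppq5(tr), oracle_jitter_window(tr, 2),
                 tolerance = 1e-12)
    expect_equal(jitter_ddp(tr), oracle_jitter_ddp(tr), tolerance = 1e-12)
  }
})

test_that("rap and ppq5 vanish on affine-in-time trajectories (property)", {
  set.seed(7)
  for (k in 1:25) {
    n <- sample(5:40, 1)
    p0 <- rnorm(2); v <- rnorm(2)
    tr <- cbind(p0[1] + v[1] * (1:n), p0[2] + v[2] * (1:n))
    expect_lt(jitter_rap(tr), 1e-10)
    expect_lt(jitter_ppq5(tr), 1e-10)
    expect_lt(jitter_ddp(tr), 1e-10)  # constant speed
  }
})

test_that("jitters and cov_abs scale correctly under coordinate scaling", {
  set.seed(3)
  tr <- random_traj(30)
  for (s in c(0.5, 2, 17)) {
    expect_equal(jitter_abs(s * tr), s * jitter_abs(tr))
    expect_equal(jitter_rap(s * tr), s * jitter_rap(tr))
    expect_equal(jitter_ppq5(s * tr), s * jitter_ppq5(tr))
    expect_equal(jitter_ddp(s * tr), s * jitter_ddp(tr))
    expect_equal(covariance(s * tr[, 1], s * tr[, 2]),
                 s^2 * covariance(tr[, 1], tr[, 2]))
  }
})

test_that("expected jitter_abs grows with noise level (property)", {
  base <- cbind(seq(0, 10, length.out = 40), seq(0, 5, length.out = 40))
  sig <- c(0.1, 0.5, 2)
  means <- vapply(sig, function(s) {
    mean(vapply(1:30, function(seed) {
      set.seed(seed)
      jitter_abs(base + matrix(rnorm(80, 0, s), 40, 2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("extract_record assembles the 848-feature block correctly", {
  s <- small_cohort(n = 1, seed = 5)$sequences[[1]]
  v <- extract_record(s)
  expect_length(v, 848)
  expect_identical(names(v), feature_column_names(SCHEMA))
  expect_true(all(is.finite(v)))

  # static record: all ranges and jitters zero
  fr <- random_frame(seed = 2)
  st <- landmark_sequence(rep(list(fr), 6), "s", "r", "control", 0.1, SCHEMA)
  vs <- extract_record(st)
  # ranges and jitters exactly zero; covariances zero to rounding
  expect_true(all(vs[grep("max$|jitter", names(vs))] == 0))
  expect_lt(max(abs(vs)), 1e-9)

  # rigid translation of a static face: amplitude block 0, jitter_abs > 0
  frames <- lapply(0:5, function(i) similarity(fr, tr = c(2 * i, i)))
  mv <- landmark_sequence(frames, "s", "r2", "control", 0.1, SCHEMA)
  vm <- extract_record(mv)
  amp <- vm[grep("__R_[xy]_max$|__cov_rel$", names(vm))]
  expect_lt(max(abs(amp)), 1e-9)
  expect_true(all(vm[grep("__jitter_abs$", names(vm))] > 0))

  # too-short records are rejected with a reason
  sh <- landmark_sequence(rep(list(fr), 4), "s", "r3", "PD", 0.1, SCHEMA)
  expect_error(extract_record(sh), "4 frames < minimum 5")
})

test_that("feature_table has the documented shape and metadata", {
  tab <- small_table()
  expect_equal(ncol(tab), 851)  # 3 metadata + 848 features
  expect_equal(nrow(tab), 6 * 2 * 3)
  expect_identical(names(tab)[1:3], c("record_id", "subject_id", "label"))
  expect_identical(levels(tab$label), c("PD", "control"))
  expect_identical(names(tab)[-(1:3)], feature_column_names(SCHEMA))
})
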
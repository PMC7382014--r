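test_that("cohorts have the configured structure and are reproducible", {
  cfg <- synthetic_config(n_pd = 3, n_ctrl = 2, records_per_subject = 2,
                          frames_per_record = 10, seed = 5)
  co <- generate_cohort(cfg)
  expect_length(co$sequences, (3 + 2) * 2)
  expect_true(all(vapply(co$sequences, n_frames, 1L) == 10))
  expect_true(all(vapply(co$sequences, function(s) dim(s$coords)[2], 1L)
                  == 106))
  expect_equal(sum(co$manifest$label == "PD"), 6)
  expect_equal(nrow(co$manifest), 10)
  # same seed -> bit-identical cohort
  co2 <- generate_cohort(cfg)
  expect_identical(lapply(co$sequences, `[[`, "coords"),
                   lapply(co2$sequences, `[[`, "coords"))
  # different seed -> different cohort
  co3 <- generate_cohort(synthetic_config(n_pd = 3, n_ctrl = 2,
                                          records_per_subject = 2,
                                          frames_per_record = 10, seed = 6))
  expect_false(identical(co$sequences[[1]]$coords, co3$sequences[[1]]$coords))
})

test_that("config validation rejects nonsense", {
  expect_error(synthetic_config(n_pd = 0))
  expect_error(synthetic_config(tremor_sigma_pd = -1))
  expect_error(synthetic_config(head_motion = "teleport"))
})

test_that("effect audit sees the configured contrasts", {
  # 3x tremor contrast -> PD jitter clearly higher
  au <- effect_audit(small_cohort(n = 4, seed = 3))
  expect_gt(au$mean_jitter_abs[au$label == "PD"],
            1.5 * au$mean_jitter_abs[au$label == "control"])

  # equal amplitudes -> group R_y_max means within noise of each other
  co_eq <- generate_cohort(synthetic_config(
    n_pd = 4, n_ctrl = 4, seed = 3, smile_amplitude_pd = 0.2,
    smile_amplitude_ctrl = 0.2, tremor_sigma_pd = 0.3,
    tremor_sigma_ctrl = 0.3))
  au_eq <- effect_audit(co_eq)
  expect_lt(abs(diff(au_eq$mean_R_y_max)) / mean(au_eq$mean_R_y_max), 0.35)

  # fully static world -> jitter exactly zero in both groups
  co0 <- generate_cohort(synthetic_config(
    n_pd = 2, n_ctrl = 2, seed = 1, smile_amplitude_pd = 0,
    smile_amplitude_ctrl = 0, tremor_sigma_pd = 0, tremor_sigma_ctrl = 0,
    head_motion = "none"))
  au0 <- effect_audit(co0)
  expect_equal(au0$mean_jitter_abs, c(0, 0))
})

test_that("head-motion nuisance is invisible to the amplitude block", {
  # deterministic amplitudes (subject_sd = record_sd = 0) so the two
  # cohorts differ only by the rigid motion itself
  mk <- function(hm, mag) generate_cohort(synthetic_config(
    n_pd = 2, n_ctrl = 2, seed = 8, tremor_sigma_pd = 0,
    tremor_sigma_ctrl = 0, subject_sd = 0, record_sd = 0,
    head_motion = hm, head_motion_magnitude = mag))
  still <- mk("none", 0)
  moving <- mk("drift", 12)
  t_still <- feature_table(still$sequences)
  t_move <- feature_table(moving$sequences)
  amp_cols <- grep("__(R_[xy]_max|cov_rel)$", names(t_still), value = TRUE)
  # relative-coordinate amplitude features unchanged by the rigid drift
  expect_equal(as.matrix(t_move[amp_cols]), as.matrix(t_still[amp_cols]),
               tolerance = 1e-9)
  # but absolute-coordinate jitter goes up
  jit_cols <- grep("__jitter_abs$", names(t_still), value = TRUE)
  expect_gt(mean(as.matrix(t_move[jit_cols])),
            mean(as.matrix(t_still[jit_cols])) + 0.05)
})

test_that("raising PD tremor raises jitter-family screening counts", {
  counts_at <- function(sigma_pd) {
    co <- generate_cohort(synthetic_config(
      n_pd = 6, n_ctrl = 6, seed = 19, tremor_sigma_pd = sigma_pd,
      tremor_sigma_ctrl = 0.2, smile_amplitude_pd = 0.25,
      smile_amplitude_ctrl = 0.25))
    rep <- count_significant(feature_table(co$sequences), alphas = 0.05)
    sum(rep$counts[rep$counts$feature %in%
                     c("jitter_abs", "jitter_ppq5", "jitter_rap",
                       "jitter_ddp"), "alpha_0.05"])
  }
  c_lo <- counts_at(0.2)    # null tremor contrast
  c_hi <- counts_at(0.8)
  expect_gt(c_hi, c_lo + 100)
  expect_gt(c_hi, 380)      # near saturation (max 424)
})
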
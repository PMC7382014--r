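toy_diffs <- function(n_per_class = 6, len = 12, channels = 4, seed = 1,
                      shift = 0.8) {
  set.seed(seed)
  out <- list()
  for (k in seq_len(2 * n_per_class)) {
    pd <- k <= n_per_class
    ser <- matrix(rnorm(len * channels, if (pd) shift else -shift, 1),
                  len, channels)
    colnames(ser) <- paste0("ch", seq_len(channels))
    out[[k]] <- structure(
      list(series = ser, label = if (pd) "PD" else "control",
           subject_id = sprintf("s%02d", k), record_id = sprintf("r%02d", k)),
      class = "diff_series")
  }
  out
}

test_that("difference applies the previous-minus-current convention", {
  # build a 3-frame record whose nose_tip x-track is 1, 3, 6
  fr <- random_frame(seed = 2)
  frames <- lapply(c(1, 3, 6), function(v) {
    f <- fr; f["nose_tip", 1] <- f["nose_tip", 1] + v; f
  })
  s <- landmark_sequence(frames, "s", "r", "PD", 0.1, SCHEMA)
  d <- difference(s)   # absolute coordinates: direct check of the formula
  expect_equal(unname(d$series[, "nose_tip__dx"]), c(-2, -3))

  # constant series -> zeros; shape is (N-1) x 212
  st <- landmark_sequence(rep(list(fr), 50), "s", "r", "PD", 0.1, SCHEMA)
  ds <- difference(st)
  expect_equal(dim(ds$series), c(49, 212))
  expect_true(all(ds$series == 0))
  expect_error(difference(landmark_sequence(list(fr), "s", "r", "PD")),
               "at least 2")
})

test_that("differencing inverts by cumulative summation (round trip)", {
  s <- random_sequence(10, seed = 6)
  rel <- to_relative_sequence(s)
  d <- difference(rel)
  rec <- undifference(d, rel$coords[1, , ])
  expect_equal(rec, unname(rel$coords), tolerance = 1e-12,
               ignore_attr = TRUE)
})

numeric_grad <- function(params, X, mask, y01, arch, nm, eps = 1e-5) {
  g <- params[[nm]] * 0
  for (i in seq_along(g)) {
    up <- params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
    g[i] <- (facetremor:::.seq_eval_loss(up, X, mask, y01, arch) -
               facetremor:::.seq_eval_loss(dn, X, mask, y01, arch)) / (2 * eps)
  }
  g
}

test_that("analytic BPTT gradients match numerical gradients", {
  set.seed(5)
  B <- 3; Tn <- 4; C <- 2; H <- 3
  X <- array(rnorm(B * Tn * C), c(B, Tn, C))
  mask <- rbind(c(1, 1, 1, 1), c(1, 1, 1, 0), c(1, 1, 0, 0))  # ragged
  y01 <- c(1, 0, 1)
  for (arch in c("lstm", "rnn")) {
    params <- facetremor:::.init_params(arch, C, H)
    params$Wy <- matrix(rnorm(H * 2, 0, 0.5), H, 2)  # non-zero head
    params$by <- rnorm(2, 0, 0.1)
    lg <- facetremor:::.seq_loss_grad(params, X, mask, y01, arch)
    for (nm in names(params)) {
      gn <- numeric_grad(params, X, mask, y01, arch, nm)
      expect_lt(max(abs(lg$grads[[nm]] - gn)), 1e-6)
    }
  }
})

test_that("zero-epoch model predicts the training majority class", {
  diffs <- toy_diffs(n_per_class = 4)
  diffs <- diffs[-1]  # 3 PD vs 4 control -> majority = control
  m <- fit_sequence_classifier(diffs, "lstm", hidden = 4, epochs = 0,
                               seed = 3)
  expect_true(all(predict(m, diffs) == "control"))
})

test_that("sequence training separates mean-coded classes", {
  diffs <- toy_diffs(n_per_class = 8, len = 20, channels = 6, seed = 9)
  res <- train_sequence_classifier(diffs, "lstm", folds = 4, hidden = 8,
                                   epochs = 50, seed = 2)
  expect_gte(res$report$metrics$f1, 0.8)
  # determinism under a fixed seed
  res2 <- train_sequence_classifier(diffs, "lstm", folds = 4, hidden = 8,
                                    epochs = 50, seed = 2)
  expect_identical(res$report$metrics, res2$report$metrics)
  expect_identical(res$model$params, res2$model$params)
})

test_that("permuted labels leave the sequence model at chance", {
  diffs <- toy_diffs(n_per_class = 8, len = 20, channels = 6, seed = 9)
  set.seed(33)
  labs <- sample(vapply(diffs, `[[`, "", "label"))
  for (i in seq_along(diffs)) diffs[[i]]$label <- labs[i]
  res <- train_sequence_classifier(diffs, "lstm", folds = 4, hidden = 8,
                                   epochs = 30, seed = 4)
  expect_lt(res$report$metrics$f1, 0.8)
})
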
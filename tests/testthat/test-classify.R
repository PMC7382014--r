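test_that("grouped folds keep subjects together and stratify classes", {
  groups <- rep(sprintf("s%02d", 1:20), each = 3)
  labels <- rep(rep(c("PD", "control"), each = 10), each = 3)
  f <- grouped_folds(groups, labels, k = 5, seed = 2)
  expect_true(all(tapply(f, groups, function(v) length(unique(v))) == 1))
  per_fold <- table(f[!duplicated(groups)],
                    labels[!duplicated(groups)])
  expect_true(all(per_fold == 2))  # 2 subjects per class per fold
  expect_error(grouped_folds(c("a", "a"), c("PD", "control"), 2, 1),
               "constant within subject")
})

test_that("classification metrics follow their arithmetic", {
  truth <- c("PD", "PD", "PD", "control", "control")
  pred <- c("PD", "PD", "control", "PD", "control")
  m <- classification_metrics(truth, pred)
  expect_equal(unname(m$confusion), c(2, 1, 1, 1))  # tp fp fn tn
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  # F1 is the harmonic mean of the reported precision and recall
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  mw <- classification_metrics(truth, pred, average = "weighted")
  expect_true(mw$f1 >= 0 && mw$f1 <= 1)
})

test_that("all four algorithms separate a separable cohort perfectly", {
  co <- small_cohort(n = 8, seed = 17)
  tab <- feature_table(co$sequences)
  rep <- evaluate_classifiers(tab, folds = 4, seed = 3, num_trees = 50)
  expect_s3_class(rep, "classification_report")
  expect_equal(rep$metrics$f1, rep(1, 4))
  # metric arithmetic recomputed from stored confusion counts
  for (algo in rep$metrics$algorithm) {
    cf <- rep$confusion[[algo]]
    p <- cf[["tp"]] / (cf[["tp"]] + cf[["fp"]])
    r <- cf[["tp"]] / (cf[["tp"]] + cf[["fn"]])
    expect_equal(rep$metrics$f1[rep$metrics$algorithm == algo],
                 2 * p * r / (p + r), tolerance = 1e-12)
  }
})

test_that("evaluation is deterministic under a fixed seed", {
  tab <- small_table()
  r1 <- evaluate_classifiers(tab, c("lr", "dt"), folds = 3, seed = 11,
                             num_trees = 20)
  r2 <- evaluate_classifiers(tab, c("lr", "dt"), folds = 3, seed = 11,
                             num_trees = 20)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("permuted labels drive F1 to chance", {
  co <- small_cohort(n = 8, seed = 23)
  tab <- feature_table(co$sequences)
  subj <- unique(tab$subject_id)
  # permute at subject level so grouping stays honest; average the
  # permutation null over three draws (single draws are noisy at n = 16)
  f1s <- vapply(1:3, function(ps) {
    set.seed(70 + ps)
    new_lab <- setNames(sample(rep(c("PD", "control"), length(subj) / 2)),
                        subj)
    tab$label <- factor(new_lab[tab$subject_id], levels = c("PD", "control"))
    mean(evaluate_classifiers(tab, c("lr", "svm"), folds = 4,
                              seed = 5)$metrics$f1)
  }, numeric(1))
  expect_lt(mean(f1s), 0.7)
})

test_that("final-model artifacts round-trip and align columns by name", {
  tab <- small_table()
  for (algo in c("lr", "svm", "dt", "rf")) {
    m <- fit_final(tab, algo, seed = 9, num_trees = 20)
    pred0 <- predict(m, tab)
    # serialize / reload
    path <- withr::local_tempfile(fileext = ".rds")
    saveRDS(m, path)
    m2 <- readRDS(path)
    expect_identical(predict(m2, tab), pred0)
    # permuted columns: identical predictions after name-based alignment
    perm <- tab[, c(1:3, sample(4:ncol(tab)))]
    expect_identical(predict(m, perm), pred0)
  }
  expect_error(fit_final(tab, "xgboost"), "'arg'")
  m <- fit_final(tab, "lr")
  expect_error(predict(m, tab[, 1:100]), "lacks")
})
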
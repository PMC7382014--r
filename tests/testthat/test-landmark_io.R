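test_that("Face++-dialect JSON parses into schema order", {
  fr <- random_frame(seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  # shuffle key order on disk: parser must restore schema order
  shuffled <- fr[sample(nrow(fr)), ]
  write_json_frame(shuffled, path)
  got <- read_faceplusplus_json(path, SCHEMA)
  expect_identical(rownames(got), SCHEMA$names)
  expect_equal(got, fr, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("JSON schema errors name the offending keys", {
  fr <- random_frame(seed = 2)
  p1 <- withr::local_tempfile(fileext = ".json")
  write_json_frame(fr, p1, drop = "nose_tip")
  expect_error(read_faceplusplus_json(p1, SCHEMA), "nose_tip")

  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(landmark = setNames(list(), character())), p2)
  expect_error(read_faceplusplus_json(p2, SCHEMA), "missing 106")

  p3 <- withr::local_tempfile(fileext = ".json")
  write_json_frame(fr, p3, extra = list(bogus_point = list(x = 1, y = 2)))
  expect_error(read_faceplusplus_json(p3, SCHEMA), "bogus_point")

  p4 <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", p4)
  expect_error(read_faceplusplus_json(p4, SCHEMA), "malformed JSON")
})

test_that("landmark table write/read round-trips losslessly", {
  for (seed in 1:5) {
    n <- sample(1:12, 1)
    s <- random_sequence(n, seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_landmark_table(s, path)
    back <- read_landmark_table(path, s$subject_id, s$record_id, s$label)
    expect_identical(back$coords, s$coords)
  }
  # 1-frame sequence -> exactly 106 rows
  s1 <- random_sequence(1, seed = 9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(s1, p)
  expect_equal(nrow(data.table::fread(p)), 106)
})

test_that("corrupt landmark tables are rejected", {
  s <- random_sequence(3, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(s, path)
  dt <- as.data.frame(data.table::fread(path))
  data.table::fwrite(rbind(dt, dt[1, ]), path)
  expect_error(read_landmark_table(path), "duplicate")
})

test_that("manifest loading: labels normalized, errors are specific", {
  dir <- withr::local_tempdir()
  s1 <- random_sequence(50, seed = 1, subject = "a", record = "a_r1",
                        label = "PD")
  s2 <- random_sequence(50, seed = 2, subject = "b", record = "b_r1",
                        label = "control")
  write_landmark_table(s1, file.path(dir, "a_r1.csv"))
  write_landmark_table(s2, file.path(dir, "b_r1.csv"))
  mf <- data.frame(subject_id = c("a", "b"), record_id = c("a_r1", "b_r1"),
                   label = c("PD ", "Control"),   # trailing space / case
                   frame_interval = 0.1, path = c("a_r1.csv", "b_r1.csv"))
  mpath <- file.path(dir, "manifest.csv")
  data.table::fwrite(mf, mpath)
  seqs <- load_dataset(mpath)
  expect_length(seqs, 2)
  expect_equal(vapply(seqs, n_frames, 1L), c(50L, 50L))
  expect_equal(vapply(seqs, `[[`, "", "label"), c("PD", "control"))

  mf$label <- c("PD", "parkinsons???")
  data.table::fwrite(mf, mpath)
  expect_error(load_dataset(mpath), "unknown label")

  mf$label <- c("PD", "control")
  mf$path[2] <- "missing_glob_*.json"
  data.table::fwrite(mf, mpath)
  expect_error(load_dataset(mpath), "b_r1")
})

test_that("per-frame JSON globs assemble into a sequence", {
  dir <- withr::local_tempdir()
  s <- random_sequence(4, seed = 3)
  for (i in 1:4) {
    write_json_frame(s$coords[i, , ],
                     file.path(dir, sprintf("f_%03d.json", i)))
  }
  mf <- data.frame(subject_id = "a", record_id = "a_r1", label = "PD",
                   frame_interval = 0.1, path = "f_*.json")
  mpath <- file.path(dir, "manifest.csv")
  data.table::fwrite(mf, mpath)
  seqs <- load_dataset(mpath)
  expect_length(seqs, 1)
  expect_equal(seqs[[1]]$coords, s$coords, tolerance = 1e-12)
})

test_that("sequences with missing points never load partially", {
  dir <- withr::local_tempdir()
  s <- random_sequence(3, seed = 5)
  write_json_frame(s$coords[1, , ], file.path(dir, "f_1.json"))
  write_json_frame(s$coords[2, , ], file.path(dir, "f_2.json"),
                   drop = "mouth_left_corner")  # one bad frame
  write_json_frame(s$coords[3, , ], file.path(dir, "f_3.json"))
  mf <- data.frame(subject_id = "a", record_id = "a_r1", label = "PD",
                   frame_interval = 0.1, path = "f_*.json")
  mpath <- file.path(dir, "manifest.csv")
  data.table::fwrite(mf, mpath)
  expect_error(load_dataset(mpath), "mouth_left_corner")
})
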
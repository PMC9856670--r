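toy_files <- function(dir, time = c(3, 1, 4, 2, 5), cause = c(1, 0, 2, 1, 0),
                      feat_names = c("gA", "gB", "gC")) {
  clin <- data.frame(id = paste0("s", 1:5), time = time, cause = cause,
                     age = c(61, 72, 55, 68, 80),
                     sexM = c(1, 0, 1, 1, 0))
  set.seed(42)
  feat <- data.frame(id = paste0("s", 1:5),
                     matrix(rnorm(15), 5, dimnames = list(NULL, feat_names)),
                     check.names = FALSE)
  cp <- file.path(dir, "clinical.csv"); fp <- file.path(dir, "features.csv")
  write.csv(clin, cp, row.names = FALSE, quote = FALSE)
  write.csv(feat, fp, row.names = FALSE, quote = FALSE)
  list(clinical = cp, features = fp)
}

test_that("reader joins clinical and feature tables and validates", {
  dir <- withr::local_tempdir()
  fl <- toy_files(dir)
  d <- read_cr_dataset(fl$clinical, fl$features)
  expect_s3_class(d, "cr_dataset")
  expect_equal(n_subjects(d), 5)
  expect_equal(ncol(d$X), 3)
  expect_equal(ncol(d$Z), 2)
  expect_equal(colnames(d$X), c("gA", "gB", "gC"))
})

test_that("validation errors name the offending rows/columns", {
  dir <- withr::local_tempdir()
  fl <- toy_files(dir, time = c(3, -1, 4, 2, 5))
  expect_error(read_cr_dataset(fl$clinical, fl$features), "rows: 2")
  fl2 <- toy_files(dir, feat_names = c("gA", "gA", "gC"))
  expect_error(read_cr_dataset(fl2$clinical, fl2$features), "gA")
})

test_that("write/read round-trips times, causes, X and Z exactly", {
  d0 <- make_fixture("tiny")
  dir <- withr::local_tempdir()
  cp <- file.path(dir, "c.tsv"); fp <- file.path(dir, "f.tsv")
  write_cr_dataset(d0, cp, fp)
  d1 <- read_cr_dataset(cp, fp)
  expect_equal(d1$time, d0$time)
  expect_equal(d1$cause, d0$cause)
  expect_equal(d1$X, d0$X, ignore_attr = FALSE)
  expect_equal(d1$Z, d0$Z)
})

test_that("categorical controls become reference-coded indicators", {
  dir <- withr::local_tempdir()
  clin <- data.frame(id = paste0("s", 1:6), time = 1:6,
                     cause = c(1, 0, 2, 1, 0, 1),
                     grade = c("high", "low", "low", "high", "low", "high"))
  feat <- data.frame(id = paste0("s", 1:6), g1 = rnorm(6))
  write.csv(clin, file.path(dir, "c.csv"), row.names = FALSE, quote = FALSE)
  write.csv(feat, file.path(dir, "f.csv"), row.names = FALSE, quote = FALSE)
  d <- read_cr_dataset(file.path(dir, "c.csv"), file.path(dir, "f.csv"))
  expect_equal(colnames(d$Z), "gradelow")
  expect_equal(d$Z[, 1], c(0, 1, 1, 0, 1, 0))
})

test_that("a 4:1 split of 300 subjects yields a 240-subject training cohort", {
  d <- simulate_crdata(sim_config(n = 300, p = 3, p0 = 2, pi_mix = 0.3,
                                  censor_max = 3, seed = 7))
  s <- split_train_test(d, ratio = c(4, 1), seed = 11)
  expect_length(s$train_index, 240)
  expect_length(s$test_index, 60)
  expect_length(intersect(s$train_index, s$test_index), 0)
  expect_setequal(c(s$train_index, s$test_index), 1:300)
})

test_that("split is seed-reproducible and varies across seeds", {
  d <- make_fixture("tiny", seed = 5)
  s1 <- split_train_test(d, c(1, 1), seed = 3)
  s2 <- split_train_test(d, c(1, 1), seed = 3)
  expect_identical(s1$train_index, s2$train_index)
  expect_length(s1$train_index, 4)

  d2 <- simulate_crdata(sim_config(n = 60, p = 2, pi_mix = 0.4,
                                   censor_max = 3, seed = 8))
  parts <- lapply(1:6, function(sd) split_train_test(d2, c(4, 1), seed = sd))
  expect_gt(length(unique(lapply(parts, `[[`, "train_index"))), 1)
})

test_that("strata are allocated at the requested ratio within one subject", {
  # 40 cause-1 / 60 censored, ratio 3:1: train must hold 30 +- 1 cause-1
  set.seed(1)
  d <- cr_dataset(paste0("s", 1:100), runif(100, 1, 10),
                  rep(c(1L, 0L), c(40, 60)),
                  matrix(rnorm(100), ncol = 1))
  for (sd in 1:5) {
    s <- split_train_test(d, c(3, 1), seed = sd)
    expect_true(abs(sum(d$cause[s$train_index] == 1) - 30) <= 1)
  }
  # per-stratum floor/ceil property on a covariate-stratified split
  d2 <- simulate_crdata(sim_config(n = 120, p = 2, p0 = 2, pi_mix = 0.4,
                                   censor_max = 3, seed = 9))
  s2 <- split_train_test(d2, c(4, 1), seed = 2)
  rep2 <- s2$strata_report
  expect_true(all(rep2$train >= floor(rep2$n * 0.8) &
                    rep2$train <= ceiling(rep2$n * 0.8)))
  expect_equal(sum(rep2$train), length(s2$train_index))
})

test_that("degenerate split ratios are rejected", {
  d <- make_fixture("tiny")
  expect_error(split_train_test(d, c(4, 0)), "ratio")
  expect_error(split_train_test(d, c(0, 1)), "ratio")
  expect_length(split_train_test(d, c(4, 0), all_train = TRUE)$test_index, 0)
})
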
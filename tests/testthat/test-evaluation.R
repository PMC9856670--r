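test_that("perfect oracle predictions give zero prediction error", {
  d <- make_fixture("evaluation")
  grid <- c(0.5, 1, 1.5, 2)
  oracle <- vapply(grid, function(t)
    as.numeric(d$time <= t & d$cause == 1L), numeric(n_subjects(d)))
  pe <- brier_cif(d, oracle, grid)
  expect_equal(pe$err, rep(0, 4))
})

test_that("without censoring the curve is the plain mean squared residual", {
  d <- simulate_crdata(sim_config(n = 80, p = 1, p0 = 0, beta1 = 0.4,
                                  pi_mix = 0.5, censor_max = Inf, seed = 21))
  grid <- c(0.3, 0.8, 1.5)
  q <- 0.35
  pe <- brier_cif(d, matrix(q, 80, 3), grid)
  direct <- vapply(grid, function(t)
    mean((as.numeric(d$time <= t & d$cause == 1L) - q)^2), numeric(1))
  expect_equal(pe$err, direct, tolerance = 1e-12)
})

test_that("IPCW Brier matches a spreadsheet-style hand computation", {
  # n=4: cause-1 at 1, censored at 2, cause-2 at 3, still at risk past 4
  d <- cr_dataset(letters[1:4], c(1, 2, 3, 4), c(1L, 0L, 2L, 1L),
                  matrix(0, 4, 1))
  G <- km_censoring(d)
  # censoring KM: single censoring at t=2, risk set {b, c, d} -> G drops 2/3
  expect_equal(eval_step(G, c(2, 2.5)), c(1, 2 / 3))
  f <- c(0.9, 0.2, 0.3, 0.4)
  t <- 2.5
  # N(2.5) = (1,0,0,0); W = (1/G(1-)=1, 0, 1/G(2.5)=3/2 ... c failed at 3>t
  # so c is "still at risk": W_c = 1/G(2.5); same for d
  hand <- ((1 - 0.9)^2 * 1 + 0 + (0 - 0.3)^2 * 1.5 + (0 - 0.4)^2 * 1.5) / 4
  pe <- brier_cif(d, matrix(f, 4, 1), t)
  expect_equal(pe$err, hand, tolerance = 1e-12)
})

test_that("grid points beyond the support of G are truncated with warning", {
  d <- cr_dataset(letters[1:4], c(1, 2, 3, 4), c(1L, 0L, 2L, 0L),
                  matrix(0, 4, 1))
  expect_warning(pe <- brier_cif(d, matrix(0.2, 4, 3), c(1, 2, 5)),
                 "truncated")
  expect_equal(pe$times, c(1, 2))
})

test_that(".632+ blends apparent and bootstrap error by the stated formula", {
  d <- make_fixture("evaluation")
  grid <- c(0.5, 1, 1.5)
  recipe_const <- function(train) function(newdata, times)
    matrix(0.3, n_subjects(newdata), length(times))
  pe <- dot632plus(d, recipe_const, grid, B = 5, seed = 2)
  # the returned curve satisfies the blending identity exactly, including
  # the degenerate branches R=0 (weight .632, err = err_app when
  # err_boot = err_app) and R=1 (weight 1, err = err_boot when
  # err_boot >= err_noinf)
  R <- pmin(pmax((pe$err_boot - pe$err_app) /
                   (pe$err_noinf - pe$err_app), 0), 1)
  R[pe$err_noinf <= pe$err_app] <- 0
  w <- 0.632 / (1 - 0.368 * R)
  expect_equal(pe$weight, w, tolerance = 1e-12)
  expect_equal(pe$err, (1 - w) * pe$err_app + w * pe$err_boot,
               tolerance = 1e-12)
  expect_true(all(pe$weight >= 0.632 & pe$weight <= 1))
  # hence the result always lies between the apparent and bootstrap errors
  expect_true(all(pe$err >= pmin(pe$err_app, pe$err_boot) - 1e-12 &
                    pe$err <= pmax(pe$err_app, pe$err_boot) + 1e-12))
})

test_that(".632+ of a null-model recipe stays near its apparent error", {
  d <- make_fixture("evaluation")
  grid <- c(0.5, 1, 1.5)
  # Aalen-Johansen null recipe: no covariates, hence almost no overfitting
  recipe_null <- function(train) {
    f1 <- aalen_johansen(train)$cif[["1"]]
    function(newdata, times)
      matrix(rep(eval_step(f1, times), each = n_subjects(newdata)),
             nrow = n_subjects(newdata))
  }
  # near-zero overfitting can push err_noinf below err_app (R clamped to 0
  # with a warning); that is the expected branch here
  pe <- suppressWarnings(dot632plus(d, recipe_null, grid, B = 20, seed = 4))
  expect_true(all(abs(pe$err - pe$err_app) / pe$err_app < 0.05))
})

test_that("ROC handles ties, perfect separation, and weighted concordance", {
  d <- simulate_crdata(sim_config(n = 40, p = 1, p0 = 0, beta1 = 0.6,
                                  pi_mix = 0.5, censor_max = 3, seed = 13))
  # constant marker: all ties, AUC exactly 1/2
  r_const <- roc_cif(d, rep(1, 40), horizon = 1)
  expect_equal(r_const$auc, 0.5)
  # uncensored data, marker perfectly separating cases above controls
  d2 <- simulate_crdata(sim_config(n = 30, p = 1, p0 = 0, pi_mix = 0.5,
                                   censor_max = Inf, seed = 14))
  marker <- as.numeric(d2$time <= 1 & d2$cause == 1L)
  r_perf <- roc_cif(d2, marker, horizon = 1)
  expect_equal(r_perf$auc, 1)
  # curve is monotone from (0,0) to (1,1) and AUC equals its trapezoid area
  r <- roc_cif(d, d$X[, 1], horizon = 1)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("AUC equals the all-pairs weighted concordance oracle on small data", {
  for (sd in 1:8) {
    set.seed(sd)
    n <- sample(6:12, 1)
    d <- simulate_crdata(sim_config(n = n, p = 1, p0 = 0, beta1 = 0.8,
                                    pi_mix = 0.6, censor_max = 4,
                                    seed = 400 + sd))
    marker <- round(d$X[, 1], 1)          # rounding forces some ties
    t <- stats::median(d$time)
    r <- tryCatch(roc_cif(d, marker, t), error = function(e) NULL)
    if (is.null(r)) next                  # no cases or controls at horizon
    G <- km_censoring(d)
    gy <- eval_step(G, d$time)
    case_w <- ifelse(d$time <= t & d$cause == 1L, 1 / gy, 0)
    ctrl_w <- ifelse(d$time > t, 1 / eval_step(G, t),
                     ifelse(d$time <= t & d$cause >= 2L, 1 / gy, 0))
    expect_equal(r$auc, auc_pairs_naive(marker, case_w, ctrl_w),
                 tolerance = 1e-12)
  }
})

test_that("curves and ROC results serialize to TSV", {
  d <- make_fixture("evaluation")
  grid <- c(0.5, 1)
  pe <- brier_cif(d, matrix(0.2, n_subjects(d), 2), grid,
                  model_label = "flat")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_pe_curve(pe, p1)
  expect_equal(read.delim(p1)$model, rep("flat", 2))
  r <- roc_cif(d, d$X[, 1], 1)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_roc(r, p2)
  first <- readLines(p2, n = 1)
  expect_match(first, "AUC=")
})
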
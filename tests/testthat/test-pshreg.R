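test_that("log partial likelihood matches hand-computed risk sets", {
  # two cause-1 events at t=1,2 with binary feature, beta=0:
  # l = log(1/2) + log(1/1)
  d <- cr_dataset(c("a", "b"), c(1, 2), c(1L, 1L),
                  matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "x")))
  expect_equal(psh_loglik(0, numeric(0), d), log(1 / 2), tolerance = 1e-12)

  # at beta = gamma = 0, l = -sum over events of log(weighted risk-set size)
  d2 <- make_fixture("tiny")
  w <- fg_weights(d2, km_censoring(d2))
  ev <- which(d2$cause == 1L)
  expected <- -sum(vapply(ev, function(i) {
    t <- d2$time[i]
    wt <- fg_weight_at(w, t)
    wt[d2$cause == 1L & d2$time < t] <- 0
    log(sum(wt))
  }, numeric(1)))
  expect_equal(psh_loglik(numeric(2), numeric(1), d2), expected,
               tolerance = 1e-12)

  # no cause-1 events: empty sum
  d3 <- cr_dataset(c("a", "b", "c"), c(1, 2, 3), c(0L, 2L, 0L),
                   matrix(rnorm(3), ncol = 1))
  expect_equal(psh_loglik(0.7, numeric(0), d3), 0)
})

test_that("with cause in {0,1} the fit equals the Cox maximizer", {
  # independent golden-section oracle on the naive Cox likelihood
  for (sd in c(2, 5, 9)) {
    d <- random_cox_fixture(sd)
    f <- psh_fit(d)
    b_oracle <- cox_mle_naive(d$time, d$cause, d$X[, 1])
    expect_equal(unname(f$beta), b_oracle, tolerance = 1e-6)
  }
  # and equals coxph (Breslow ties) on a larger two-covariate design
  d <- simulate_crdata(sim_config(n = 120, p = 2, p0 = 0,
                                  beta1 = c(0.5, -0.3), pi_mix = 1,
                                  censor_max = 5, seed = 11))
  f <- psh_fit(d)
  cx <- survival::coxph(survival::Surv(d$time, d$cause == 1) ~ d$X,
                        ties = "breslow")
  expect_equal(unname(f$beta), unname(coef(cx)), tolerance = 1e-6)
})

test_that("competing-risks fits agree with the crr reference implementation", {
  d <- simulate_crdata(sim_config(n = 250, p = 2, p0 = 2,
                                  beta1 = c(0.5, -0.5), gamma1 = c(0.3, 0),
                                  pi_mix = 0.4, censor_max = 4, seed = 12))
  f <- psh_fit(d)
  cr <- cmprsk::crr(d$time, d$cause, cbind(d$X, d$Z))
  expect_equal(unname(c(f$beta, f$gamma)), unname(cr$coef), tolerance = 1e-6)
  expect_equal(f$loglik, cr$loglik, tolerance = 1e-8)
})

test_that("score vanishes at the optimum and the likelihood ascends", {
  d <- make_fixture("evaluation")
  f <- psh_fit(d, feature_subset = 1:3)
  expect_true(f$converged)
  expect_lt(max(abs(f$score)), 1e-6)
  # l(beta_hat, gamma_hat) >= l(0, gamma_null_hat) >= l(0, 0)
  f_null <- psh_fit(d, feature_subset = integer(0))
  expect_gte(f$loglik, f_null$loglik - 1e-10)
  expect_gte(f_null$loglik, psh_loglik(numeric(10), numeric(2), d) - 1e-10)
})

test_that("separation raises the divergence flag instead of converging", {
  # single feature perfectly ordering cause-1 events before all others
  d <- cr_dataset(paste0("s", 1:8), c(1, 2, 3, 4, 5, 6, 7, 8),
                  c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
                  matrix(c(8:5, 4:1), ncol = 1, dimnames = list(NULL, "x")))
  f <- psh_fit(d)
  expect_false(f$converged)
  expect_true(f$diverged)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- simulate_crdata(sim_config(n = 80, p = 2, p0 = 0, beta1 = 0.5,
                                  pi_mix = 0.5, censor_max = 4, seed = 17))
  d_const <- d
  d_const$X[, 2] <- 1
  expect_error(psh_fit(d_const), "constant")
  expect_error(psh_fit(cr_dataset(c("a", "b"), 1:2, c(0L, 0L),
                                  matrix(1:2, ncol = 1))), "cause-1")
  # over-saturated design: more covariates than cause-1 events
  tiny <- make_fixture("tiny")
  expect_error(psh_fit(tiny), "cause-1 events")
})

test_that("predicted CIF is a valid monotone curve anchored at zero", {
  d <- make_fixture("evaluation")
  f <- psh_fit(d, feature_subset = 1:2)
  cf <- predict_cif(f, x = c(1, -1), z = c(0.5, 1))
  expect_equal(eval_step(cf, 0), 0)
  vals <- eval_step(cf, seq(0, max(d$time), length.out = 50))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals < 1))
  # covariates at zero: 1 - exp(-H) exactly
  cf0 <- predict_cif(f, x = c(0, 0), z = c(0, 0))
  expect_equal(cf0$values, 1 - exp(-f$baseline$values), tolerance = 1e-12)
  # matrix predictor agrees with the single-subject path
  pm <- predict_cif_matrix(f, matrix(c(1, -1), 1,
                                     dimnames = list(NULL, f$feature_names)),
                           matrix(c(0.5, 1), 1,
                                  dimnames = list(NULL, f$control_names)),
                           c(0.5, 1, 2))
  expect_equal(drop(pm), eval_step(cf, c(0.5, 1, 2)), tolerance = 1e-12)
})

test_that("parameter recovery improves with sample size", {
  est <- function(n, reps, seed0) {
    vapply(seq_len(reps), function(r) {
      d <- simulate_crdata(sim_config(n = n, p = 1, p0 = 0, beta1 = 0.5,
                                      pi_mix = 0.3, censor_max = 3.1,
                                      seed = seed0 + r))
      unname(psh_fit(d)$beta)
    }, numeric(1))
  }
  b250 <- est(250, 30, 5000)
  b1000 <- est(1000, 30, 6000)
  expect_lt(abs(mean(b1000) - 0.5), 0.05)
  rmse <- function(b) sqrt(mean((b - 0.5)^2))
  expect_lt(rmse(b1000), rmse(b250))
})

test_that("fit summaries expose hazard ratios with naive Wald inference", {
  d <- make_fixture("evaluation")
  f <- psh_fit(d, feature_subset = 1:2)
  s <- summary(f)
  expect_named(s, c("term", "coef", "hazard_ratio", "naive_se",
                    "ci_lower", "ci_upper", "p_value"))
  expect_equal(s$hazard_ratio, exp(s$coef))
  expect_true(all(s$ci_lower < s$hazard_ratio & s$hazard_ratio < s$ci_upper))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psh_fit(f, path)
  expect_equal(nrow(read.delim(path)), 4)
})
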
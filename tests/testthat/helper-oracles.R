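# Independent oracles used to validate the likelihood machinery. These are
# deliberately naive direct-translation implementations, sharing no code
# with the package internals.

# Cox partial log-likelihood (Breslow ties) for a single coefficient,
# standard right-censored data (event = cause 1): direct double loop.
cox_loglik_naive <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# golden-section maximizer of the naive Cox likelihood
cox_mle_naive <- function(time, event, x) {
  stats::optimize(function(b) cox_loglik_naive(b, time, event, x),
                  interval = c(-10, 10), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# product-limit estimate of Pr(C >= t) by direct product over censoring
# times s < t; failures at s are out of the risk set at s
km_cens_naive <- function(time, cause, t) {
  g <- 1
  for (s in sort(unique(time[cause == 0]))) {
    if (s >= t) break
    r <- sum(time > s) + sum(time == s & cause == 0)
    g <- g * (1 - sum(time == s & cause == 0) / r)
  }
  g
}

# weighted all-pairs concordance AUC with ties counted 1/2
auc_pairs_naive <- function(marker, case_w, ctrl_w) {
  num <- 0; den <- 0
  for (i in which(case_w > 0)) for (j in which(ctrl_w > 0)) {
    w <- case_w[i] * ctrl_w[j]
    den <- den + w
    if (marker[i] > marker[j]) num <- num + w
    else if (marker[i] == marker[j]) num <- num + w / 2
  }
  num / den
}

# small random right-censored (no competing events) dataset
random_cox_fixture <- function(seed, n = 20) {
  set.seed(seed)
  x <- rnorm(n)
  t_ev <- rexp(n, exp(0.4 * x))
  cens <- rexp(n, 0.3)
  cr_dataset(paste0("s", 1:n), pmin(t_ev, cens),
             ifelse(t_ev <= cens, 1L, 0L),
             matrix(x, ncol = 1, dimnames = list(NULL, "x")))
}
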
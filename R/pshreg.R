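## Fine-Gray PSH regression.
##
## The weighted log partial likelihood is
##   l_n(beta, gamma) = sum over cause-1 events i of
##       [eta_i - log sum_j w_j(Y_i) R_j(Y_i) exp(eta_j)],
## eta = beta'x + gamma'z, with the subdistribution risk set R_j(t) keeping
## subjects whose competing event has already happened (discounted by the
## censoring weights w_j) and dropping cause-1 failures after their event.
## Ties among cause-1 event times use the Breslow approximation (shared
## denominator), so the machinery below works on the K distinct event
## times with multiplicities d_k and a K x n matrix of risk-set weights.

# risk-set structure shared by every likelihood evaluation on a dataset
fg_riskset <- function(data, w = NULL) {
  stopifnot(inherits(data, "cr_dataset"))
  if (is.null(w)) w <- fg_weights(data, km_censoring(data))
  ev <- data$cause == 1L
  tk <- sort(unique(data$time[ev]))
  K <- length(tk)
  n <- n_subjects(data)
  W <- matrix(0, K, n)
  for (k in seq_len(K)) {
    wk <- fg_weight_at(w, tk[k])
    wk[data$cause == 1L & data$time < tk[k]] <- 0  # past cause-1 events leave
    W[k, ] <- wk
  }
  dk <- if (K) as.numeric(table(factor(data$time[ev], levels = tk))) else numeric(0)
  list(W = W, dk = dk, tk = tk, ev_idx = which(ev), n = n, weights = w)
}

# log partial likelihood, score and expected information for eta = V theta + offset
psh_objective <- function(rs, V, theta, offset = NULL, what = "all") {
  n <- rs$n
  q <- ncol(V)
  eta <- if (is.null(offset)) numeric(n) else offset
  if (q) eta <- eta + drop(V %*% theta)
  if (!length(rs$tk)) {        # no cause-1 events: empty sum
    return(list(loglik = 0, score = numeric(q), info = matrix(0, q, q),
                eta = eta, S0 = numeric(0), shift = 0))
  }
  shift <- max(eta)
  E <- exp(eta - shift)
  S0 <- drop(rs$W %*% E)
  ll <- sum(eta[rs$ev_idx] - shift) - sum(rs$dk * log(S0))
  if (what == "loglik" || q == 0)
    return(list(loglik = ll, score = numeric(q), info = matrix(0, q, q),
                eta = eta, S0 = S0, shift = shift))

  pairs_a <- rep(seq_len(q), times = q:1)
  pairs_b <- unlist(lapply(seq_len(q), function(a) a:q))
  M <- E * cbind(V, V[, pairs_a, drop = FALSE] * V[, pairs_b, drop = FALSE])
  A <- rs$W %*% M                       # K x (q + q(q+1)/2)
  mu <- A[, seq_len(q), drop = FALSE] / S0
  score <- colSums(V[rs$ev_idx, , drop = FALSE]) - colSums(rs$dk * mu)
  info <- matrix(0, q, q)
  s2 <- A[, -seq_len(q), drop = FALSE] / S0
  vals <- colSums(rs$dk * (s2 - mu[, pairs_a, drop = FALSE] *
                             mu[, pairs_b, drop = FALSE]))
  info[cbind(pairs_a, pairs_b)] <- vals
  info[cbind(pairs_b, pairs_a)] <- vals
  list(loglik = ll, score = score, info = info, eta = eta, S0 = S0,
       shift = shift)
}

# Newton-Raphson with step halving on the weighted partial likelihood
psh_newton <- function(rs, V, init = NULL, offset = NULL,
                       maxit = 100L, tol = 1e-9) {
  q <- ncol(V)
  theta <- if (is.null(init)) numeric(q) else as.numeric(init)
  obj <- psh_objective(rs, V, theta, offset)
  if (q == 0 || !length(rs$tk))
    return(list(theta = theta, loglik = obj$loglik, score = obj$score,
                info = obj$info, converged = TRUE, n_iter = 0L,
                diverged = FALSE, obj = obj))
  converged <- FALSE; diverged <- FALSE; iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    step <- tryCatch(solve(obj$info, obj$score), error = function(e) NULL)
    if (is.null(step)) {
      bad <- colnames(V)[abs(diag(obj$info)) <= 1e-12]
      stop("singular information matrix",
           if (length(bad)) paste0("; degenerate/collinear columns: ",
                                   paste(bad, collapse = ", ")))
    }
    new_theta <- theta + step
    new_obj <- psh_objective(rs, V, new_theta, offset)
    h <- 0
    while (new_obj$loglik < obj$loglik && h < 30) {
      step <- step / 2; h <- h + 1
      new_theta <- theta + step
      new_obj <- psh_objective(rs, V, new_theta, offset)
    }
    rel_change <- abs(new_obj$loglik - obj$loglik) / (abs(obj$loglik) + tol)
    theta <- new_theta; obj <- new_obj
    if (any(abs(theta) > 30)) { diverged <- TRUE; break }   # separation
    if (rel_change < tol) { converged <- TRUE; break }
  }
  if (diverged) converged <- FALSE
  list(theta = theta, loglik = obj$loglik, score = obj$score,
       info = obj$info, converged = converged, n_iter = iter,
       diverged = diverged, obj = obj)
}

#' Weighted PSH log partial likelihood at given coefficients
#'
#' Evaluates \eqn{l_n(\beta, \gamma)} for the Fine-Gray model on a dataset,
#' using the censoring weights in `weights`. The sum runs over cause-1
#' events; a dataset with no cause-1 events yields 0 (empty sum).
#'
#' @param beta feature coefficients (length `ncol(data$X)`); may be length
#'   0 if the dataset carries no features to be used.
#' @param gamma control coefficients (length `ncol(data$Z)`).
#' @param data a [cr_dataset()].
#' @param weights an [fg_weights()] schedule (defaults to weights from the
#'   dataset's own censoring KM).
#' @return The scalar log partial likelihood.
#' @export
psh_loglik <- function(beta, gamma, data, weights = NULL) {
  stopifnot(inherits(data, "cr_dataset"))
  rs <- fg_riskset(data, weights)
  V <- cbind(data$X, data$Z)
  theta <- c(beta, gamma)
  if (length(theta) != ncol(V))
    stop("beta/gamma dimensions do not match X/Z")
  psh_objective(rs, V, theta, what = "loglik")$loglik
}

#' Fit a Fine-Gray proportional subdistribution hazards model
#'
#' Maximizes the censoring-weighted log partial likelihood by
#' Newton-Raphson with analytic score and information and step-halving,
#' starting from zero (or `init`). Censoring weights are computed once from
#' the dataset's censoring Kaplan-Meier and held fixed during optimization.
#' The Breslow estimator of the cumulative baseline subdistribution hazard
#' is returned with a jump \eqn{d(t) / \sum_j w_j(t) R_j(t) e^{\hat\eta_j}}
#' at each distinct cause-1 event time.
#'
#' @param data a [cr_dataset()].
#' @param feature_subset integer or character index of the feature columns
#'   to include (default: all columns of `X`; use `integer(0)` for a
#'   controls-only model).
#' @param init optional start value for `c(beta, gamma)`.
#' @param maxit,tol Newton-Raphson controls: at most `maxit` iterations,
#'   convergence when the relative log-likelihood change drops below `tol`.
#' @param weights optional pre-computed [fg_weights()] (e.g. from a
#'   reference training dataset).
#' @return An object of class `psh_fit`: coefficients `beta` and `gamma`,
#'   `loglik`, `converged` flag (FALSE with `diverged = TRUE` under
#'   monotone likelihood/separation), the negative Hessian `info_matrix`,
#'   its inverse `vcov` (naive covariance: it ignores the estimation of
#'   \eqn{\hat G}), and the `baseline` cumulative hazard step function.
#' @export
psh_fit <- function(data, feature_subset = NULL, init = NULL,
                    maxit = 100L, tol = 1e-9, weights = NULL) {
  stopifnot(inherits(data, "cr_dataset"))
  if (is.null(feature_subset)) feature_subset <- seq_len(ncol(data$X))
  Xs <- data$X[, feature_subset, drop = FALSE]
  V <- cbind(Xs, data$Z)
  q <- ncol(V)
  n_events <- sum(data$cause == 1L)
  if (n_events == 0) stop("no cause-1 events: PSH model is not estimable")
  if (q >= n_events)
    stop("covariate count (", q, ") must be below the number of cause-1 ",
         "events (", n_events, ") for a stable fit")
  const <- which(apply(V, 2, function(v) diff(range(v)) == 0))
  if (length(const))
    stop("constant covariate column(s): ",
         paste(colnames(V)[const], collapse = ", "))

  rs <- fg_riskset(data, weights)
  res <- psh_newton(rs, V, init = init, maxit = maxit, tol = tol)

  p_used <- ncol(Xs)
  beta <- res$theta[seq_len(p_used)]
  gamma <- if (q > p_used) res$theta[(p_used + 1):q] else numeric(0)
  names(beta) <- colnames(Xs)
  names(gamma) <- colnames(data$Z)

  # Breslow baseline: undo the overflow shift used inside the objective
  base_jumps <- if (length(rs$tk))
    rs$dk / (res$obj$S0 * exp(res$obj$shift)) else numeric(0)
  baseline <- step_function(rs$tk, cumsum(base_jumps), 0, continuity = "right")

  vc <- if (q && res$converged)
    tryCatch(solve(res$info), error = function(e) matrix(NA_real_, q, q))
  else matrix(NA_real_, q, q)

  structure(
    list(beta = beta, gamma = gamma, loglik = res$loglik,
         n_iter = res$n_iter, converged = res$converged,
         diverged = res$diverged, info_matrix = res$info, vcov = vc,
         baseline = baseline, feature_names = colnames(Xs),
         control_names = colnames(data$Z), n = n_subjects(data),
         n_events = n_events, score = res$score),
    class = "psh_fit"
  )
}

#' @export
coef.psh_fit <- function(object, ...) c(object$beta, object$gamma)

#' @export
print.psh_fit <- function(x, ...) {
  cat(sprintf("<psh_fit: %d features + %d controls, n=%d, %d cause-1 events>\n",
              length(x$beta), length(x$gamma), x$n, x$n_events))
  cat(sprintf("  loglik %.4f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged"
              else if (x$diverged) "DIVERGED: monotone likelihood/separation"
              else "NOT converged"))
  if (length(coef(x))) print(round(coef(x), 4))
  invisible(x)
}

#' Summarize a PSH fit as a coefficient table
#'
#' Hazard ratios with naive Wald confidence intervals and p-values; "naive"
#' because the covariance is the inverse negative Hessian and does not
#' propagate the estimation of the censoring distribution.
#'
#' @param object a [psh_fit()].
#' @param conf_level confidence level for the intervals.
#' @param ... unused.
#' @return `data.frame` with term, coefficient, hazard ratio, naive SE,
#'   confidence bounds and p-value.
#' @export
summary.psh_fit <- function(object, conf_level = 0.95, ...) {
  est <- coef(object)
  se <- sqrt(diag(object$vcov))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    term = names(est),
    coef = as.numeric(est),
    hazard_ratio = exp(as.numeric(est)),
    naive_se = se,
    ci_lower = exp(est - zq * se),
    ci_upper = exp(est + zq * se),
    p_value = 2 * stats::pnorm(-abs(est / se)),
    row.names = NULL
  )
}

#' Write a PSH fit summary as TSV
#' @param fit a [psh_fit()].
#' @param path output path.
#' @export
write_psh_fit <- function(fit, path) {
  utils::write.table(summary(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Predicted cumulative incidence function from a PSH fit
#'
#' \eqn{\hat F_1(t \mid x, z) = 1 - \exp\{-\hat H_{1,0}(t)
#' e^{\hat\beta' x + \hat\gamma' z}\}}: non-decreasing, 0 at \eqn{t = 0},
#' bounded below 1.
#'
#' @param fit a converged [psh_fit()].
#' @param x feature values (length matching `fit$beta`).
#' @param z control values (length matching `fit$gamma`).
#' @return A right-continuous [step_function()] for \eqn{\hat F_1(\cdot)}.
#' @export
predict_cif <- function(fit, x = numeric(0), z = numeric(0)) {
  stopifnot(inherits(fit, "psh_fit"))
  if (!fit$converged) stop("predict_cif requires a converged fit")
  if (length(x) != length(fit$beta) || length(z) != length(fit$gamma))
    stop("covariate dimensions do not match the fit")
  lp <- sum(fit$beta * x) + sum(fit$gamma * z)
  H <- fit$baseline
  step_function(H$jump_times, 1 - exp(-H$values * exp(lp)), 0,
                continuity = "right")
}

#' Predicted CIF for many subjects over a time grid
#'
#' @param fit a converged [psh_fit()].
#' @param X feature matrix (columns matching `fit$beta`; may have 0 cols).
#' @param Z control matrix (columns matching `fit$gamma`).
#' @param times evaluation grid.
#' @return Matrix, subjects x times, of \eqn{\hat F_1(t \mid x_i, z_i)}.
#' @export
predict_cif_matrix <- function(fit, X, Z, times) {
  stopifnot(inherits(fit, "psh_fit"))
  if (!fit$converged) stop("prediction requires a converged fit")
  X <- as.matrix(X); Z <- as.matrix(Z)
  lp <- numeric(nrow(X))
  if (length(fit$beta)) lp <- lp + drop(X[, fit$feature_names, drop = FALSE] %*% fit$beta)
  if (length(fit$gamma)) lp <- lp + drop(Z[, fit$control_names, drop = FALSE] %*% fit$gamma)
  H <- eval_step(fit$baseline, times)
  1 - exp(-outer(exp(lp), H))
}
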
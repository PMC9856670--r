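## Component-wise likelihood boosting for the PSH model.
##
## Each boosting step updates a single feature coefficient by a penalized
## Newton step on the weighted partial likelihood, keeping the clinical
## controls unpenalized: the controls get a full (one-step) Newton refresh
## after every boosting update, with the accumulated feature contribution
## held as an offset.

# first and (negative) second derivative of l_n w.r.t. each beta_j at eta
psh_componentwise_score <- function(rs, X, eta) {
  shift <- max(eta)
  E <- exp(eta - shift)
  S0 <- drop(rs$W %*% E)
  S1 <- rs$W %*% (E * X)
  S2 <- rs$W %*% (E * X * X)
  mu <- S1 / S0
  U <- colSums(X[rs$ev_idx, , drop = FALSE]) - colSums(rs$dk * mu)
  I <- colSums(rs$dk * (S2 / S0 - mu * mu))
  list(U = U, I = I)
}

#' Component-wise likelihood boosting with mandatory controls
#'
#' Starts from \eqn{\beta = 0} and \eqn{\gamma} equal to the controls-only
#' PSH fit. In each of `steps` rounds, the candidate update for feature
#' \eqn{j} is the penalized Newton step \eqn{\delta_j = U_j / (I_j +
#' \lambda)} (score \eqn{U_j} and information \eqn{I_j} of the weighted
#' partial likelihood at the current linear predictor); the feature
#' maximizing the penalized score statistic \eqn{U_j^2 / (I_j + \lambda)}
#' receives its update, after which the unpenalized controls are refreshed
#' by one Newton step. Large \eqn{\lambda} means heavy per-step shrinkage
#' and a slow, sparse path.
#'
#' @param data a [cr_dataset()] (training cohort).
#' @param features integer/character index of candidate feature columns
#'   (default all).
#' @param steps number of boosting steps M (>= 0).
#' @param penalty ridge penalty \eqn{\lambda > 0}; default
#'   `9 * (number of cause-1 events)`, giving per-step shrinkage of roughly
#'   one tenth of the unpenalized Newton step.
#' @param weights optional pre-computed [fg_weights()].
#' @return An object of class `boost_fit`: `coef_path` (steps+1 rows of
#'   cumulative beta, row 1 = step 0), `gamma_path`, final `beta`/`gamma`,
#'   `penalty`, `loglik_path`, and the training riskset metadata needed to
#'   rebuild the Breslow baseline (see [boost_as_psh_fit()]).
#' @export
boost_fit <- function(data, features = NULL, steps = 100L, penalty = NULL,
                      weights = NULL) {
  stopifnot(inherits(data, "cr_dataset"))
  if (is.null(features)) features <- seq_len(ncol(data$X))
  X <- data$X[, features, drop = FALSE]
  Z <- data$Z
  n_events <- sum(data$cause == 1L)
  if (n_events == 0) stop("no cause-1 events: boosting has no information")
  if (is.null(penalty)) penalty <- 9 * n_events
  if (!(penalty > 0)) stop("penalty must be positive")
  if (steps < 0) stop("steps must be >= 0")

  rs <- fg_riskset(data, weights)
  p <- ncol(X); p0 <- ncol(Z)
  null_fit <- psh_newton(rs, Z)
  gamma <- null_fit$theta
  beta <- numeric(p)

  coef_path <- matrix(0, steps + 1L, p, dimnames = list(NULL, colnames(X)))
  gamma_path <- matrix(0, steps + 1L, max(p0, 1))[, seq_len(p0), drop = FALSE]
  colnames(gamma_path) <- colnames(Z)
  if (p0) gamma_path[1, ] <- gamma
  loglik_path <- numeric(steps + 1L)
  loglik_path[1] <- null_fit$loglik

  eta_x <- numeric(rs$n)
  eta_z <- if (p0) drop(Z %*% gamma) else numeric(rs$n)

  for (m in seq_len(steps)) {
    sc <- psh_componentwise_score(rs, X, eta_x + eta_z)
    if (all(sc$I <= 0)) stop("no information in any candidate feature")
    stat <- sc$U^2 / (sc$I + penalty)
    j <- which.max(stat)
    delta <- sc$U[j] / (sc$I[j] + penalty)
    beta[j] <- beta[j] + delta
    eta_x <- eta_x + delta * X[, j]
    if (p0) {            # one unpenalized Newton step for the controls
      refreshed <- psh_newton(rs, Z, init = gamma, offset = eta_x, maxit = 1L)
      gamma <- refreshed$theta
      eta_z <- drop(Z %*% gamma)
    }
    coef_path[m + 1L, ] <- beta
    if (p0) gamma_path[m + 1L, ] <- gamma
    loglik_path[m + 1L] <- psh_objective(rs, Z, gamma, offset = eta_x,
                                         what = "loglik")$loglik
  }

  structure(
    list(coef_path = coef_path, gamma_path = gamma_path,
         beta = stats::setNames(beta, colnames(X)),
         gamma = stats::setNames(gamma, colnames(Z)),
         penalty = penalty, steps = steps, loglik_path = loglik_path,
         features = features, feature_names = colnames(X),
         control_names = colnames(Z)),
    class = "boost_fit"
  )
}

#' @export
print.boost_fit <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("<boost_fit: %d steps, lambda=%.3g, %d/%d features nonzero>\n",
              x$steps, x$penalty, nz, length(x$beta)))
  if (!is.null(x$selected_steps))
    cat(sprintf("  CV-selected steps M* = %d (of 0..%d candidates)\n",
                x$selected_steps, length(x$cv_curve) - 1L))
  invisible(x)
}

# held-out weighted partial loglik of a coefficient path on a fold
fold_loglik_path <- function(fold_data, coef_path, gamma_path, features) {
  rs_f <- fg_riskset(fold_data)
  Xf <- fold_data$X[, features, drop = FALSE]
  Zf <- fold_data$Z
  vapply(seq_len(nrow(coef_path)), function(m) {
    eta <- drop(Xf %*% coef_path[m, ])
    if (ncol(Zf)) eta <- eta + drop(Zf %*% gamma_path[m, ])
    psh_objective(rs_f, matrix(numeric(0), nrow(Xf), 0), numeric(0),
                  offset = eta, what = "loglik")$loglik
  }, numeric(1))
}

#' Cross-validated component-wise boosting
#'
#' Tunes the number of boosting steps by K-fold cross-validation: folds are
#' assigned stratified by cause code; for every candidate step count
#' \eqn{M \in 0..}`max_steps` the mean held-out weighted partial
#' log-likelihood is computed (each held-out fold evaluated under its own
#' censoring KM), \eqn{M^*} is the maximizer (smallest M on ties), and the
#' final model is refit on all data with \eqn{M^*} steps.
#'
#' @inheritParams boost_fit
#' @param max_steps largest candidate step count.
#' @param folds number of CV folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return A `boost_fit` (refit at \eqn{M^*}) with extra fields
#'   `selected_steps` (M*), `cv_curve` (mean held-out log-likelihood per
#'   candidate M) and `fold_id`.
#' @export
cv_boost <- function(data, features = NULL, max_steps = 100L, penalty = NULL,
                     folds = 10L, seed = 1L, weights = NULL) {
  stopifnot(inherits(data, "cr_dataset"))
  if (folds < 2) stop("folds must be >= 2")
  if (is.null(features)) features <- seq_len(ncol(data$X))
  n <- n_subjects(data)

  fold_id <- NULL
  with_seed(seed, {
    for (attempt in seq_len(10L)) {
      id <- integer(n)
      for (cc in unique(data$cause)) {       # stratified by cause code
        idx <- which(data$cause == cc)
        id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      ok <- all(vapply(seq_len(folds), function(f)
        sum(data$cause[id == f] == 1L) >= 1, logical(1)))
      if (ok) { fold_id <- id; break }
    }
  })
  if (is.null(fold_id))
    stop("could not build ", folds, " folds each containing a cause-1 event")

  cv_mat <- matrix(NA_real_, folds, max_steps + 1L)
  for (f in seq_len(folds)) {
    train_f <- data[fold_id != f]
    test_f <- data[fold_id == f]
    bf <- boost_fit(train_f, features = features, steps = max_steps,
                    penalty = penalty)
    cv_mat[f, ] <- fold_loglik_path(test_f, bf$coef_path, bf$gamma_path,
                                    features)
  }
  cv_curve <- colMeans(cv_mat)
  m_star <- which.max(cv_curve) - 1L       # which.max takes the first max

  final <- boost_fit(data, features = features, steps = m_star,
                     penalty = penalty, weights = weights)
  final$selected_steps <- m_star
  final$cv_curve <- cv_curve
  final$fold_id <- fold_id
  final$seed <- seed
  final
}

#' View a boosted model as a PSH fit for prediction
#'
#' Packages the boosted coefficients (nonzero features plus controls) with
#' the Breslow baseline evaluated at the boosted linear predictor, so
#' [predict_cif()] / [predict_cif_matrix()] apply unchanged.
#'
#' @param bf a [boost_fit()] / [cv_boost()] result.
#' @param data the training dataset the model was fit on.
#' @return A `psh_fit`-classed object (coefficients are the boosted ones,
#'   not a maximum-likelihood refit).
#' @export
boost_as_psh_fit <- function(bf, data) {
  stopifnot(inherits(bf, "boost_fit"), inherits(data, "cr_dataset"))
  keep <- which(bf$beta != 0)
  rs <- fg_riskset(data)
  X <- data$X[, bf$features, drop = FALSE]
  eta <- drop(X %*% bf$beta)
  if (ncol(data$Z)) eta <- eta + drop(data$Z %*% bf$gamma)
  obj <- psh_objective(rs, matrix(numeric(0), rs$n, 0), numeric(0),
                       offset = eta, what = "loglik")
  jumps <- if (length(rs$tk)) rs$dk / (obj$S0 * exp(obj$shift)) else numeric(0)
  structure(
    list(beta = bf$beta[keep], gamma = bf$gamma, loglik = obj$loglik,
         n_iter = bf$steps, converged = TRUE, diverged = FALSE,
         info_matrix = NULL, vcov = NULL,
         baseline = step_function(rs$tk, cumsum(jumps), 0, "right"),
         feature_names = bf$feature_names[keep],
         control_names = bf$control_names, n = n_subjects(data),
         n_events = sum(data$cause == 1L), score = NULL),
    class = "psh_fit"
  )
}

#' Write a boosting coefficient path as TSV (step, feature, coefficient)
#' @param bf a [boost_fit()].
#' @param path output path.
#' @export
write_boost_path <- function(bf, path) {
  stopifnot(inherits(bf, "boost_fit"))
  steps <- nrow(bf$coef_path) - 1L
  df <- data.frame(
    step = rep(0:steps, each = ncol(bf$coef_path)),
    feature = rep(colnames(bf$coef_path), steps + 1L),
    coefficient = as.vector(t(bf$coef_path))
  )
  df <- df[df$coefficient != 0 | df$step == steps, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
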
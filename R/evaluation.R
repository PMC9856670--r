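## IPCW evaluation of predicted cumulative incidence.

# IPCW observation weights W_i(t):
#   subjects failed (any cause) by t contribute 1/G(Y_i-), subjects still
#   under observation contribute 1/G(t), subjects censored by t contribute 0.
ipcw_obs_weights <- function(data, G, t) {
  g_at_y <- eval_step(G, data$time)   # left-continuous: Pr(C >= Y_i) = G(Y_i-)
  w <- numeric(n_subjects(data))
  failed <- data$time <= t & data$cause != 0L
  w[failed] <- ifelse(g_at_y[failed] > 0, 1 / g_at_y[failed], 0)
  atrisk <- data$time > t
  gt <- eval_step(G, t)
  w[atrisk] <- if (gt > 0) 1 / gt else 0
  w
}

#' IPCW prediction-error (Brier) curve for the cumulative incidence
#'
#' \deqn{Err(t) = \frac1n \sum_i \{N_i(t) - \hat F_1(t \mid X_i, Z_i)\}^2
#' W_i(t)} with \eqn{N_i(t) = I(Y_i \le t, \epsilon_i = 1)} and the inverse
#' probability of censoring weights \eqn{W_i(t) = I(Y_i \le t,
#' \epsilon_i \ne 0)/\hat G(Y_i-) + I(Y_i > t)/\hat G(t)} built from the
#' marginal censoring Kaplan-Meier. Grid points where \eqn{\hat G(t) = 0}
#' are dropped with a warning (the weights are undefined there).
#'
#' @param data a [cr_dataset()] (the evaluation cohort).
#' @param predictions matrix, subjects x `length(times)`, of predicted
#'   \eqn{\hat F_1(t \mid X_i, Z_i)} (e.g. from [predict_cif_matrix()]).
#' @param G censoring survival [step_function()]; defaults to the cohort's
#'   own [km_censoring()].
#' @param times evaluation grid.
#' @param model_label,estimator labels carried into the result.
#' @return An object of class `pe_curve` with `times`, `err`, labels.
#' @export
brier_cif <- function(data, predictions, times, G = NULL,
                      model_label = "model", estimator = "apparent") {
  stopifnot(inherits(data, "cr_dataset"))
  if (is.null(G)) G <- km_censoring(data)
  predictions <- as.matrix(predictions)
  if (nrow(predictions) != n_subjects(data) ||
      ncol(predictions) != length(times))
    stop("predictions must be a subjects x times matrix")
  gt <- eval_step(G, times)
  keep <- gt > 0
  if (!all(keep)) {
    warning("curve truncated: G(t)=0 at ", sum(!keep), " grid point(s)")
    times <- times[keep]
    predictions <- predictions[, keep, drop = FALSE]
  }
  err <- vapply(seq_along(times), function(k) {
    t <- times[k]
    N <- as.numeric(data$time <= t & data$cause == 1L)
    w <- ipcw_obs_weights(data, G, t)
    mean((N - predictions[, k])^2 * w)
  }, numeric(1))
  structure(list(times = times, err = err, model_label = model_label,
                 estimator = estimator, ipcw_source = G),
            class = "pe_curve")
}

#' @export
print.pe_curve <- function(x, ...) {
  cat(sprintf("<pe_curve '%s' (%s): %d grid points, mean Err %.4f>\n",
              x$model_label, x$estimator, length(x$times), mean(x$err)))
  invisible(x)
}

#' Bootstrap .632+ prediction error for a refittable model recipe
#'
#' Blends the apparent error of the model fit to all data with the
#' out-of-bag bootstrap error: per grid time,
#' \eqn{\hat R = \mathrm{clamp}\{(err_{boot} - err_{app}) /
#' (err_{noinf} - err_{app}), 0, 1\}},
#' \eqn{\hat w = .632/(1 - .368 \hat R)}, result
#' \eqn{(1-\hat w)\, err_{app} + \hat w\, err_{boot}}. The no-information
#' error permutes predictions over subjects:
#' \eqn{err_{noinf}(t) = n^{-2} \sum_i \sum_j \{N_i(t) -
#' \hat F_1(t \mid X_j, Z_j)\}^2 W_i(t)}. Bootstrap draws resample
#' subjects with replacement; each draw's out-of-bag subjects form the test
#' set, with \eqn{\hat G} re-estimated on them.
#'
#' @param data a [cr_dataset()].
#' @param model_recipe function `(train_data) -> function(newdata, times)`
#'   returning a subjects x times prediction matrix; must be deterministic
#'   given its inputs.
#' @param times evaluation grid.
#' @param B number of bootstrap draws (>= 2).
#' @param seed integer seed for the resampling.
#' @param model_label label carried into the result.
#' @return A `pe_curve` with `estimator = "dot632plus"` and components
#'   `err_app`, `err_boot`, `err_noinf`, `weight` alongside `err`.
#' @export
dot632plus <- function(data, model_recipe, times, B = 100L, seed = 1L,
                       model_label = "model") {
  stopifnot(inherits(data, "cr_dataset"), B >= 2)
  n <- n_subjects(data)
  G <- km_censoring(data)
  predict_full <- model_recipe(data)
  pred_app <- as.matrix(predict_full(data, times))
  app <- brier_cif(data, pred_app, times, G = G)
  times <- app$times                      # possibly truncated
  pred_app <- pred_app[, seq_along(times), drop = FALSE]

  boot_sum <- numeric(length(times))
  boot_cnt <- numeric(length(times))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) < 2 || !any(data$cause[idx] == 1L)) next
      fit_b <- model_recipe(data[idx])
      test_b <- data[oob]
      pred_b <- as.matrix(fit_b(test_b, times))
      eb <- brier_cif(test_b, pred_b, times, G = km_censoring(test_b))
      hit <- match(eb$times, times)
      boot_sum[hit] <- boot_sum[hit] + eb$err
      boot_cnt[hit] <- boot_cnt[hit] + 1
    }
  })
  if (any(boot_cnt == 0)) stop("no usable bootstrap draw at some grid times")
  err_boot <- boot_sum / boot_cnt

  # no-information error: all subject/prediction pairings
  err_noinf <- vapply(seq_along(times), function(k) {
    t <- times[k]
    N <- as.numeric(data$time <= t & data$cause == 1L)
    w <- ipcw_obs_weights(data, G, t)
    f <- pred_app[, k]
    mean(w * (N^2 - 2 * N * mean(f) + mean(f^2)))
  }, numeric(1))

  err_app <- app$err
  denom <- err_noinf - err_app
  R <- ifelse(denom > 0, pmin(pmax((err_boot - err_app) / denom, 0), 1), 0)
  if (any(denom <= 0 & err_boot > err_app))
    warning("no-information error <= apparent error at some times; R set to 0")
  wgt <- 0.632 / (1 - 0.368 * R)
  err <- (1 - wgt) * err_app + wgt * err_boot

  structure(list(times = times, err = err, model_label = model_label,
                 estimator = "dot632plus", ipcw_source = G,
                 err_app = err_app, err_boot = err_boot,
                 err_noinf = err_noinf, weight = wgt, B = B, seed = seed),
            class = "pe_curve")
}

#' Time-dependent ROC curve and AUC for a risk marker under competing risks
#'
#' At horizon \eqn{t}, cases are subjects with a cause-1 event by \eqn{t}
#' (IPCW weight \eqn{1/\hat G(Y_i-)}); controls are subjects still event
#' free at \eqn{t} (weight \eqn{1/\hat G(t)}) together with subjects who
#' failed from a competing cause by \eqn{t} (weight \eqn{1/\hat G(Y_i-)}) —
#' the latter are known to be free of the event of interest at the horizon.
#' TPR/FPR are weighted exceedance fractions over marker thresholds; the
#' AUC is the trapezoidal area, which equals the weighted concordance
#' probability with ties counted 1/2.
#'
#' @param data a [cr_dataset()].
#' @param marker per-subject real risk score (higher = riskier).
#' @param horizon scalar evaluation time.
#' @param G censoring survival (defaults to the cohort's own KM).
#' @return An object of class `roc_result`: `fpr`, `tpr` (from (0,0) to
#'   (1,1)), `auc`, `horizon`, unweighted `n_cases`, `n_controls`.
#' @export
roc_cif <- function(data, marker, horizon, G = NULL) {
  stopifnot(inherits(data, "cr_dataset"), length(horizon) == 1)
  if (length(marker) != n_subjects(data))
    stop("marker must have one value per subject")
  if (is.null(G)) G <- km_censoring(data)
  g_at_y <- eval_step(G, data$time)
  gt <- eval_step(G, horizon)

  is_case <- data$time <= horizon & data$cause == 1L
  is_ctrl_late <- data$time > horizon
  is_ctrl_cmp <- data$time <= horizon & data$cause >= 2L
  w <- numeric(n_subjects(data))
  w[is_case | is_ctrl_cmp] <- ifelse(g_at_y[is_case | is_ctrl_cmp] > 0,
                                     1 / g_at_y[is_case | is_ctrl_cmp], 0)
  if (any(is_ctrl_late)) {
    if (gt <= 0) stop("G(t)=0 at horizon ", horizon)
    w[is_ctrl_late] <- 1 / gt
  }
  case_w <- ifelse(is_case, w, 0)
  ctrl_w <- ifelse(is_ctrl_late | is_ctrl_cmp, w, 0)
  if (sum(case_w) == 0) stop("no cases at horizon ", horizon)
  if (sum(ctrl_w) == 0) stop("no controls at horizon ", horizon)

  ord <- order(marker, decreasing = TRUE)
  m_sorted <- marker[ord]
  grp <- cumsum(!duplicated(m_sorted))     # tied markers move together
  tp <- rowsum(case_w[ord], grp)
  fp <- rowsum(ctrl_w[ord], grp)
  tpr <- c(0, cumsum(tp) / sum(case_w))
  fpr <- c(0, cumsum(fp) / sum(ctrl_w))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  structure(list(horizon = horizon, fpr = fpr, tpr = tpr, auc = auc,
                 n_cases = sum(is_case),
                 n_controls = sum(is_ctrl_late | is_ctrl_cmp)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result at t=%.3g: AUC %.4f (%d cases, %d controls)>\n",
              x$horizon, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' Write a prediction-error curve as TSV (time, value, model, estimator)
#' @param pe a `pe_curve`.
#' @param path output path.
#' @param append append to an existing file (no header repetition).
#' @export
write_pe_curve <- function(pe, path, append = FALSE) {
  stopifnot(inherits(pe, "pe_curve"))
  df <- data.frame(time = pe$times, value = pe$err,
                   model = pe$model_label, estimator = pe$estimator)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !append, append = append)
  invisible(path)
}

#' Write an ROC curve as TSV with an AUC summary line
#' @param roc a `roc_result`.
#' @param path output path.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# horizon=%g AUC=%.6f cases=%d controls=%d",
                     roc$horizon, roc$auc, roc$n_cases, roc$n_controls), con)
  utils::write.table(data.frame(fpr = roc$fpr, tpr = roc$tpr), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
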
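#' Kaplan-Meier estimate of the censoring survival function
#'
#' Product-limit estimate of \eqn{G(t) = \Pr(C \ge t)}, obtained by
#' treating censorings (cause 0) as the events and all observed failures as
#' censored observations. Two conventions are built in:
#' the returned curve is left-continuous (the drop at a censoring time
#' takes effect strictly after it, matching the "\eqn{\ge}" in the
#' definition of G), and at tied times failures precede censorings, so a
#' subject failing at \eqn{t} is not part of the risk set of a censoring
#' occurring at the same \eqn{t}.
#'
#' @param data a [cr_dataset()].
#' @return A left-continuous [step_function()] with \eqn{\hat G(0) = 1}.
#' @export
km_censoring <- function(data) {
  stopifnot(inherits(data, "cr_dataset"))
  y <- data$time
  cens <- data$cause == 0L
  ct <- sort(unique(y[cens]))
  if (!length(ct))
    return(step_function(numeric(0), numeric(0), 1, continuity = "left"))
  surv <- numeric(length(ct))
  g <- 1
  for (k in seq_along(ct)) {
    t <- ct[k]
    # failures at exactly t have already left the risk set
    at_risk <- sum(y > t) + sum(y == t & cens)
    d <- sum(y == t & cens)
    g <- g * (1 - d / at_risk)
    surv[k] <- g
  }
  step_function(ct, surv, 1, continuity = "left")
}

#' Fine-Gray time-dependent risk-set weights
#'
#' The censoring weights
#' \eqn{w_i(t) = I(C_i \ge Y_i \wedge t)\, \hat G(t) / \hat G(Y_i \wedge t)}
#' that keep subjects with an observed competing event in the
#' subdistribution risk set, discounted for the censoring they can no
#' longer experience. The indicator is resolved from observables: it is 1
#' whenever \eqn{t \le Y_i}, and for \eqn{t > Y_i} it is 1 iff the subject
#' was observed to fail (cause != 0).
#'
#' @param data a [cr_dataset()].
#' @param G censoring survival from [km_censoring()] (typically on the same
#'   or a reference training dataset).
#' @return An object of class `fg_weights` holding per-subject quantities;
#'   evaluate with [fg_weight_at()]. `$degenerate` flags subjects with
#'   \eqn{\hat G(Y_i) = 0} but an observed failure, whose late weights are
#'   set to 0 (a warning is recorded on creation).
#' @export
fg_weights <- function(data, G) {
  stopifnot(inherits(data, "cr_dataset"), inherits(G, "step_function"))
  G_at_y <- eval_step(G, data$time)
  degenerate <- data$cause >= 2L & G_at_y <= 0
  if (any(degenerate))
    warning(sum(degenerate), " competing-event subject(s) with G(Y)=0;",
            " their late risk-set weights are set to 0")
  structure(
    list(time = data$time, cause = data$cause, G = G, G_at_y = G_at_y,
         degenerate = degenerate),
    class = "fg_weights"
  )
}

#' Evaluate Fine-Gray weights at a time point
#'
#' @param w an [fg_weights()] schedule.
#' @param t scalar evaluation time.
#' @return Numeric vector of \eqn{w_i(t)}, one per subject: 1 for
#'   \eqn{t \le Y_i}; 0 for subjects censored before \eqn{t};
#'   \eqn{\hat G(t)/\hat G(Y_i)} for subjects who failed before \eqn{t}.
#' @export
fg_weight_at <- function(w, t) {
  stopifnot(inherits(w, "fg_weights"), length(t) == 1)
  out <- numeric(length(w$time))
  early <- t <= w$time
  out[early] <- 1
  late_fail <- !early & w$cause != 0L
  if (any(late_fail)) {
    gt <- eval_step(w$G, t)
    out[late_fail] <- ifelse(w$G_at_y[late_fail] > 0,
                             gt / w$G_at_y[late_fail], 0)
  }
  out
}
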
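#' Aalen-Johansen cumulative incidence estimates
#'
#' Nonparametric per-cause CIFs
#' \eqn{\hat F_k(t) = \sum_{s \le t} \hat S(s-)\, d_k(s)/n(s)} together
#' with the all-cause Kaplan-Meier survival \eqn{\hat S}, computed through
#' the multi-state machinery of \pkg{survival}. At every event time the
#' estimates satisfy \eqn{\sum_k \hat F_k(t) + \hat S(t) = 1}.
#'
#' @param data a [cr_dataset()].
#' @param group_label optional label carried into the result.
#' @return An object of class `cif_estimate`: `cif` (named list of
#'   right-continuous [step_function()]s, one per observed cause), `surv`
#'   (the event-free survival), `group_label`.
#' @export
aalen_johansen <- function(data, group_label = "all") {
  stopifnot(inherits(data, "cr_dataset"))
  causes <- sort(unique(data$cause[data$cause != 0L]))
  state <- factor(data$cause, levels = c(0L, causes),
                  labels = c("censor", paste0("cause", causes)))
  if (!length(causes)) {                  # no events at all
    km <- survival::survfit(survival::Surv(data$time, rep(0, length(data$time))) ~ 1)
    return(structure(list(cif = list(),
                          surv = step_function(numeric(0), numeric(0), 1, "right"),
                          group_label = group_label), class = "cif_estimate"))
  }
  fit <- survival::survfit(survival::Surv(data$time, state) ~ 1)
  tt <- fit$time
  ps <- fit$pstate
  colnames(ps) <- fit$states
  cif <- lapply(paste0("cause", causes), function(st) {
    step_function(tt, ps[, st], 0, continuity = "right")
  })
  names(cif) <- as.character(causes)
  surv <- step_function(tt, ps[, "(s0)"], 1, continuity = "right")
  structure(list(cif = cif, surv = surv, group_label = group_label),
            class = "cif_estimate")
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat(sprintf("<cif_estimate '%s': causes %s>\n", x$group_label,
              paste(names(x$cif), collapse = ", ")))
  invisible(x)
}

#' Gray's K-sample test for equality of cause-1 cumulative incidence
#'
#' The unweighted (rho = 0) K-sample test of Gray (1988), comparing
#' subdistribution hazards across groups; computed through
#' \code{\link[cmprsk]{cuminc}}, the implementation the field standardly
#' uses. The statistic is asymptotically chi-square with K-1 degrees of
#' freedom under the null of equal cause-1 CIFs.
#'
#' @param data a [cr_dataset()].
#' @param group per-subject group labels (>= 2 non-empty groups).
#' @param cause cause of interest (default 1).
#' @return An object of class `gray_test_result`: `statistic`, `df`,
#'   `p_value`.
#' @export
gray_test <- function(data, group, cause = 1) {
  stopifnot(inherits(data, "cr_dataset"))
  if (length(group) != n_subjects(data))
    stop("group must have one label per subject")
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2)
    stop("Gray's test needs at least 2 groups (got ", nlevels(group), ")")
  if (any(table(group) == 0)) stop("every group needs at least one subject")
  ci <- cmprsk::cuminc(ftime = data$time, fstatus = data$cause,
                       group = group, cencode = 0)
  tests <- ci$Tests
  row <- match(as.character(cause), rownames(tests))
  if (is.na(row)) stop("no events of cause ", cause, " to test")
  structure(list(statistic = unname(tests[row, "stat"]),
                 df = unname(tests[row, "df"]),
                 p_value = unname(tests[row, "pv"]),
                 cause = cause, groups = levels(group)),
            class = "gray_test_result")
}

#' @export
print.gray_test_result <- function(x, ...) {
  cat(sprintf("Gray's test (cause %s): chi-square = %.4f, df = %d, p = %.4g\n",
              x$cause, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Median-cutoff risk stratification
#'
#' Splits subjects into high/low risk at the median of the *training*
#' scores; the frozen training cutoff is applied unchanged to the test
#' scores. Scores strictly greater than the cutoff are high risk (a score
#' equal to the cutoff is low risk). With an even training count the
#' median is the midpoint of the two central order statistics.
#'
#' @param train_scores non-empty numeric vector of training risk scores.
#' @param test_scores numeric vector of test scores (may be empty).
#' @return An object of class `risk_stratification`: `cutoff`,
#'   `train_group`, `test_group` (factors with levels low/high). A warning
#'   is issued when score ties make the training groups imbalanced by more
#'   than one subject.
#' @export
stratify <- function(train_scores, test_scores = numeric(0)) {
  if (!length(train_scores)) stop("train_scores must be non-empty")
  if (diff(range(train_scores)) == 0)
    stop("all training scores identical: no stratification possible")
  cutoff <- stats::median(train_scores)
  lab <- function(s) factor(ifelse(s > cutoff, "high", "low"),
                            levels = c("low", "high"))
  train_group <- lab(train_scores)
  if (abs(sum(train_group == "high") - sum(train_group == "low")) > 1)
    warning("tied scores at the median make the training groups imbalanced (",
            sum(train_group == "low"), " low / ",
            sum(train_group == "high"), " high)")
  structure(list(cutoff = cutoff, train_group = train_group,
                 test_group = lab(test_scores)),
            class = "risk_stratification")
}

#' Write per-group, per-cause CIF curves as TSV
#' @param cifs list of `cif_estimate` objects (e.g. one per risk group).
#' @param path output path.
#' @export
write_cif_curves <- function(cifs, path) {
  if (inherits(cifs, "cif_estimate")) cifs <- list(cifs)
  rows <- do.call(rbind, lapply(cifs, function(ce) {
    do.call(rbind, lapply(names(ce$cif), function(k) {
      df <- as.data.frame(ce$cif[[k]])
      df$cause <- k; df$group <- ce$group_label
      df
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
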
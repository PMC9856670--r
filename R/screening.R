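#' Conventional screening model sizes
#'
#' The customary choices of the retained model size \eqn{d} for
#' sure-independence screening: \eqn{[n/\log n]}, \eqn{2[n/\log n]},
#' \eqn{3[n/\log n]} (with \eqn{[\cdot]} the floor and natural log) and
#' \eqn{n - p_0 - 1}, the largest size that leaves the downstream
#' regression identifiable after the intercept-free controls.
#'
#' @param n training sample size (>= 3).
#' @param p0 number of control covariates.
#' @param rule one of `"n_over_logn"`, `"2n_over_logn"`, `"3n_over_logn"`,
#'   `"n_minus_p0_minus_1"`.
#' @return Integer model size (errors if the rule gives a value < 1).
#' @export
default_model_size <- function(n, p0 = 0,
                               rule = c("n_minus_p0_minus_1", "n_over_logn",
                                        "2n_over_logn", "3n_over_logn")) {
  rule <- match.arg(rule)
  if (n < 3) stop("n must be at least 3")
  d <- switch(rule,
              n_over_logn = floor(n / log(n)),
              `2n_over_logn` = 2 * floor(n / log(n)),
              `3n_over_logn` = 3 * floor(n / log(n)),
              n_minus_p0_minus_1 = n - p0 - 1)
  d <- as.integer(d)
  if (d < 1) stop("model-size rule '", rule, "' gives a non-positive size (",
                  d, ") for n=", n, ", p0=", p0)
  d
}

#' PSH-CSIS: conditional sure-independence screening for the Fine-Gray model
#'
#' For each feature \eqn{X_j}, fits the PSH model containing \eqn{X_j} plus
#' the mandatory controls \eqn{Z} and records the maximized log partial
#' likelihood \eqn{\hat u_j}. Because the controls-only maximum is a common
#' constant, \eqn{\hat u_j} ranks features by their marginal contribution
#' to the outcome after adjusting for \eqn{Z}; the top `d` are recruited.
#' Features whose one-dimensional fit fails (constant column, separation,
#' singularity) are demoted to the null log-likelihood and flagged rather
#' than propagated as errors, so screening is robust to a few degenerate
#' columns among thousands. Every per-feature fit is warm-started at the
#' null fit's \eqn{\hat\gamma}; the fits are mutually independent, so the
#' result does not depend on evaluation order.
#'
#' @param data a [cr_dataset()] (the training cohort).
#' @param d model size; defaults to `n - p0 - 1`.
#' @param weights optional pre-computed [fg_weights()].
#' @return An object of class `screening_result`: per-feature `u`, the
#'   descending-`u` `rank` permutation (ties broken by ascending feature
#'   index), `selected` (first `d` of the ranking), `d`, `null_loglik`
#'   (\eqn{\max_\gamma l_n(0, \gamma)}), and per-feature `converged` flags.
#' @export
psh_csis <- function(data, d = NULL, weights = NULL) {
  stopifnot(inherits(data, "cr_dataset"))
  p <- ncol(data$X)
  p0 <- ncol(data$Z)
  if (is.null(d)) d <- default_model_size(n_subjects(data), p0)
  d <- as.integer(d)
  if (d < 1 || d > p) stop("d must lie in 1..p (p = ", p, ", got ", d, ")")
  if (!any(data$cause == 1L)) stop("no cause-1 events: nothing to screen on")

  rs <- fg_riskset(data, weights)
  null_fit <- psh_newton(rs, data$Z)
  null_loglik <- null_fit$loglik
  gamma_warm <- null_fit$theta

  u <- rep(null_loglik, p)
  converged <- logical(p)
  for (j in seq_len(p)) {
    xj <- data$X[, j]
    if (diff(range(xj)) == 0) next          # constant: no contribution
    fit_j <- tryCatch(
      psh_newton(rs, cbind(xj = xj, data$Z), init = c(0, gamma_warm)),
      error = function(e) NULL
    )
    if (!is.null(fit_j) && fit_j$converged) {
      u[j] <- fit_j$loglik
      converged[j] <- TRUE
    }
  }

  rank_perm <- order(-u, seq_len(p))       # ties by ascending feature index
  selected <- rank_perm[seq_len(d)]
  structure(
    list(u = stats::setNames(u, colnames(data$X)), rank = rank_perm,
         selected = selected, d = d, null_loglik = null_loglik,
         converged = converged, p = p),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result: %d of %d features selected (null loglik %.3f)>\n",
              x$d, x$p, x$null_loglik))
  top <- utils::head(x$rank, min(5, x$d))
  cat("  top features: ",
      paste(sprintf("%s (u=%.3f)", names(x$u)[top], x$u[top]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a screening table as TSV
#'
#' Columns: feature, u, delta_loglik (u minus the null maximum), rank,
#' selected flag — in original feature order.
#'
#' @param sr a [psh_csis()] result.
#' @param path output path.
#' @export
write_screening <- function(sr, path) {
  stopifnot(inherits(sr, "screening_result"))
  rk <- integer(sr$p); rk[sr$rank] <- seq_len(sr$p)
  df <- data.frame(feature = names(sr$u), u = as.numeric(sr$u),
                   delta_loglik = as.numeric(sr$u) - sr$null_loglik,
                   rank = rk, selected = seq_len(sr$p) %in% sr$selected)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
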
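#' Step functions with an explicit continuity convention
#'
#' Light-weight container for the right- or left-continuous step curves that
#' arise throughout competing-risks analysis: the censoring survival
#' \eqn{\hat G(t)}, cumulative baseline subdistribution hazards, and
#' cumulative incidence functions. A left-continuous curve takes its
#' pre-jump value *at* each jump time (the drop takes effect strictly after
#' it), which is the natural convention for survival functions of the form
#' \eqn{\Pr(C \ge t)}; a right-continuous curve jumps at the jump time
#' itself, the convention for cumulative hazards and CIFs.
#'
#' @param jump_times strictly increasing, finite, non-negative jump times.
#' @param values function value in force *after* each jump.
#' @param initial_value value before the first jump.
#' @param continuity `"right"` or `"left"` (see Details).
#' @return An object of class `step_function`.
#' @export
step_function <- function(jump_times, values, initial_value,
                          continuity = c("right", "left")) {
  continuity <- match.arg(continuity)
  jump_times <- as.numeric(jump_times)
  values <- as.numeric(values)
  if (length(jump_times) != length(values))
    stop("jump_times and values must have equal length")
  if (length(jump_times) && (any(!is.finite(jump_times)) || any(jump_times < 0)))
    stop("jump times must be finite and non-negative")
  if (length(jump_times) > 1 && any(diff(jump_times) <= 0))
    stop("jump times must be strictly increasing")
  structure(
    list(jump_times = jump_times, values = values,
         initial_value = as.numeric(initial_value), continuity = continuity),
    class = "step_function"
  )
}

#' Evaluate a step function
#'
#' @param f a [step_function()].
#' @param t numeric vector of evaluation points.
#' @return Numeric vector `f(t)` under the function's continuity convention.
#' @export
eval_step <- function(f, t) {
  stopifnot(inherits(f, "step_function"))
  idx <- findInterval(t, f$jump_times, left.open = (f$continuity == "left"))
  c(f$initial_value, f$values)[idx + 1L]
}

#' @export
print.step_function <- function(x, ...) {
  cat(sprintf("<step_function: %d jumps, %s-continuous, start %.4g>\n",
              length(x$jump_times), x$continuity, x$initial_value))
  invisible(x)
}

#' @export
as.data.frame.step_function <- function(x, ...) {
  data.frame(time = x$jump_times, value = x$values)
}

#' Write a step function as a two-column TSV (time, value)
#'
#' The initial value is recorded as a row at time = 0 when 0 precedes the
#' first jump.
#'
#' @param f a [step_function()].
#' @param path output file path.
#' @export
write_step_function <- function(f, path) {
  stopifnot(inherits(f, "step_function"))
  df <- as.data.frame(f)
  if (!length(df$time) || df$time[1] > 0)
    df <- rbind(data.frame(time = 0, value = f$initial_value), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
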
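# Observed / simulated cumulative-release series.

#' Cumulative-release curve
#'
#' Container for an observed or simulated release series: strictly increasing
#' nonnegative times and the corresponding fraction of the initial drug load
#' released, with optional per-point standard deviations.  Fractions may
#' slightly exceed 1 (noisy data); values far outside `[0, 1.05]` draw a
#' warning but are kept.
#'
#' @param times Strictly increasing, nonnegative times.
#' @param released Released fractions, same length as `times`.
#' @param sd Optional per-point standard deviations (carried, used only by
#'   weighted fitting).
#' @param time_unit `"minute"`, `"hour"` or `"day"`.
#' @param label Free-text label.
#' @return Object of class `release_curve`.
#' @export
release_curve <- function(times, released, sd = NULL, time_unit = "hour",
                          label = "") {
  time_unit <- match_time_unit(time_unit)
  stopifnot(is.numeric(times), is.numeric(released),
            length(times) == length(released), length(times) >= 2L)
  if (!all(is.finite(times)) || !all(is.finite(released))) {
    stop("times and released fractions must be finite", call. = FALSE)
  }
  if (any(times < 0)) stop("negative times are not allowed", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(released < -0.05) || any(released > 1.25)) {
    warning("released fractions far outside [0, 1]; check normalization")
  }
  if (!is.null(sd)) {
    stopifnot(is.numeric(sd), length(sd) == length(times), all(sd >= 0))
  }
  structure(list(times = as.numeric(times), released = as.numeric(released),
                 sd = if (is.null(sd)) NULL else as.numeric(sd),
                 time_unit = time_unit, label = as.character(label)[1]),
            class = "release_curve")
}

#' @export
length.release_curve <- function(x) length(x$times)

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("Release curve%s: %d points over [%g, %g] %ss\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$times), min(x$times), max(x$times), x$time_unit))
  cat(sprintf("  released fraction range: %.4g .. %.4g%s\n",
              min(x$released), max(x$released),
              if (is.null(x$sd)) "" else " (with point SDs)"))
  invisible(x)
}

#' @export
as.data.frame.release_curve <- function(x, ...) {
  d <- data.frame(time = x$times, released = x$released)
  if (!is.null(x$sd)) d$sd <- x$sd
  d
}
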
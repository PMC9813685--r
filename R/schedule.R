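#' Periodic parameter schedule
#'
#' The flipping and threshold parameters are varied periodically across
#' iteration cycles so the search does not stall in local minima: at cycle
#' `j` the parameter takes the value `mean + width * w(j / period)` where
#' `w` is a unit-amplitude periodic waveform.  The default waveform is a
#' sine; triangle and square waves are available since only "changed
#' periodically between mean - width and mean + width" is essential.
#'
#' @param mean central value of the parameter.
#' @param width half-amplitude of the variation; `mean - width` must remain
#'   >= 0 (both driven parameters are non-negative).
#' @param period cycle length in iterations (positive integer).
#' @param waveform `"sine"` (default), `"triangle"` or `"square"`.
#' @return an object of class `"schedule_spec"`.
#' @examples
#' s <- schedule_spec(0.75, 0.25, 13)
#' schedule_value(s, 0:12)
#' @export
schedule_spec <- function(mean, width, period,
                          waveform = c("sine", "triangle", "square")) {
  waveform <- match.arg(waveform)
  if (!is.finite(mean) || !is.finite(width) || width < 0)
    stop("mean and width must be finite, width >= 0")
  if (!is.finite(period) || period < 1 || period != round(period))
    stop("period must be a positive integer")
  if (mean - width < 0)
    stop("mean - width must stay >= 0 (k_f and k_t are non-negative)")
  structure(list(mean = as.numeric(mean), width = as.numeric(width),
                 period = as.integer(period), waveform = waveform),
            class = "schedule_spec")
}

#' @export
print.schedule_spec <- function(x, ...) {
  cat(sprintf("Schedule: %g +/- %g, period %d (%s wave)\n",
              x$mean, x$width, x$period, x$waveform))
  invisible(x)
}

#' Evaluate a schedule at iteration indices
#'
#' @param spec a [schedule_spec()].
#' @param j iteration index (0-based; vectorised).
#' @return numeric vector of parameter values, `period`-periodic in `j`,
#'   ranging over exactly `[mean - width, mean + width]`.
#' @export
schedule_value <- function(spec, j) {
  stopifnot(inherits(spec, "schedule_spec"))
  if (any(j < 0)) stop("iteration index must be >= 0")
  t <- (j %% spec$period) / spec$period
  w <- switch(spec$waveform,
    sine = sin(2 * pi * t),
    triangle = {
      # sine-like phase: 0 at j = 0, peak at period/4, trough at 3*period/4
      s <- (t + 0.75) %% 1
      4 * abs(s - 0.5) - 1
    },
    square = ifelse(t < 0.5, 1, -1))
  spec$mean + spec$width * w
}
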
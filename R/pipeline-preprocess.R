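#' Remove a linear background trend
#'
#' Fits an ordinary-least-squares line to the whole trace and subtracts it
#' (slope and intercept), yielding a zero-trend trace. Downstream detection
#' is therefore invariant to any affine drift in the raw signal.
#'
#' @param trace a [FluorTrace] (length >= 2).
#' @return the detrended [FluorTrace].
#' @export
subtractBackground <- function(trace) {
  validObject(trace)
  v <- trace@values
  if (length(v) < 2) stop("need at least 2 samples to fit a background line")
  t <- traceTimes(trace)
  tm <- mean(t); vm <- mean(v)
  slope <- sum((t - tm) * (v - vm)) / sum((t - tm)^2)
  FluorTrace(values = v - (vm + slope * (t - tm)), dt = trace@dt, t0 = trace@t0)
}

#' Smooth a trace with a short centered moving mean
#'
#' Three- or five-point centered moving average; edge windows shrink rather
#' than inventing padding values. \code{points = 1} returns the trace
#' unchanged.
#'
#' @param trace a [FluorTrace].
#' @param points window width in frames: 1, 3 or 5.
#' @return the smoothed [FluorTrace].
#' @export
smoothTrace <- function(trace, points = 3) {
  validObject(trace)
  if (!(points %in% c(1, 3, 5))) stop("points must be 1, 3 or 5")
  FluorTrace(values = centeredMean(trace@values, points), dt = trace@dt,
             t0 = trace@t0)
}
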
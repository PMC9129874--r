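#' Event table of an EventList
#' @param x an [EventList].
#' @return the underlying data.frame.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname events
#' @export
setMethod("events", "EventList", function(x) x@events)

#' Trace values
#' @param x a [FluorTrace].
#' @return numeric vector of per-frame fluorescence (a.u.).
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname traceValues
#' @export
setMethod("traceValues", "FluorTrace", function(x) x@values)

#' Frame timestamps of a trace
#' @param x a [FluorTrace].
#' @return numeric vector of frame times (s).
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname traceTimes
#' @export
setMethod("traceTimes", "FluorTrace",
          function(x) x@t0 + (seq_along(x@values) - 1) * x@dt)

#' @export
setMethod("length", "FluorTrace", function(x) length(x@values))

#' @export
setMethod("length", "EventList", function(x) nrow(x@events))

#' @export
setMethod("length", "ROISet", function(x) nrow(x@centers))

#' @export
setMethod("length", "PointPattern", function(x) nrow(x@points))

#' @export
setMethod("as.data.frame", "EventList", function(x, ...) x@events)

#' @export
setMethod("as.data.frame", "PointPattern", function(x, ...) {
  df <- data.frame(x_nm = x@points[, 1], y_nm = x@points[, 2])
  if (length(x@marks)) df$mark <- x@marks
  df
})

setMethod("show", "FluorTrace", function(object) {
  n <- length(object@values)
  cat(sprintf("FluorTrace: %d frames at %.4g Hz (%.4g s), t0 = %.4g s\n",
              n, 1 / object@dt, n * object@dt, object@t0))
  if (n) cat(sprintf("  range [%.4g, %.4g] a.u.\n",
                     min(object@values), max(object@values)))
})

setMethod("show", "EventList", function(object) {
  ev <- object@events
  cat(sprintf("EventList: %d events (%d evoked, %d spontaneous)\n",
              nrow(ev), sum(ev$kind == "evoked"), sum(ev$kind == "spontaneous")))
  if (nrow(ev)) print(utils::head(ev, 5))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d circular ROIs, diameter %.3g um\n",
              nrow(object@centers), object@diameter))
})

setMethod("show", "FRAPCurve", function(object) {
  cat(sprintf("FRAPCurve: %d samples (%d pre-bleach), span %.4g s\n",
              length(object@times), object@bleachEnd - 1L,
              diff(range(object@times))))
})

setMethod("show", "FRAPFit", function(object) {
  if (!object@converged) {
    cat("FRAPFit: NOT CONVERGED --", object@message, "\n")
  } else {
    cat(sprintf(
      "FRAPFit: tau = %.4g s, F0 = %.4g, Finf = %.4g, mobile = %.4g, immobile = %.4g (R2 = %.4g)\n",
      object@tau, object@F0, object@Finf, object@mobileFraction,
      object@immobileFraction, object@rSquared))
  }
})

setMethod("show", "PointPattern", function(object) {
  cat(sprintf("PointPattern: %d points in %.4g x %.4g nm field\n",
              nrow(object@points), object@field[1], object@field[2]))
})

setMethod("show", "PoolState", function(object) {
  cat(sprintf(
    "PoolState at t = %.4g s: evoked_site %.4g, synaptic_general %.4g, reservoir %.4g\n",
    object@t, object@u[["evoked_site"]], object@u[["synaptic_general"]],
    object@u[["reservoir"]]))
})

setMethod("show", "BleachProtocol", function(object) {
  cat(sprintf("BleachProtocol: %d segments, total %.4g s\n",
              nrow(object@segments), sum(object@segments$duration)))
  if (nrow(object@segments)) print(object@segments)
})
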
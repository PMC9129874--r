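# Shared detection context: the detectors take a background-subtracted
# trace, smooth it internally, track a trailing moving-average baseline on
# the smoothed trace, and estimate the noise scale robustly from the RAW
# (unsmoothed) residuals over the same trailing window -- so the threshold
# reflects true frame noise while smoothing suppresses it in the detection
# trace. The robust scale is 1.4826 x trailing median of |x - trailing
# median(x)| (a running-window MAD).
.detectionContext <- function(trace, params) {
  validObject(trace); validObject(params)
  x <- trace@values
  dt <- trace@dt
  w <- oddWindowFrames(params@baselineWindow, dt)
  if (length(x) < 2L * w + 2L)
    stop("trace shorter than required detection history (",
         format((2 * w + 2) * dt), " s)")
  y <- centeredMean(x, params@smoothPoints)
  m <- trailingMedian(x, w)
  d <- abs(x - m)
  list(x = x, y = y, dt = dt, w = w,
       baseline = trailingMean(y, w),
       noiseSd = 1.4826 * trailingMedian(d, w),
       d = d)
}

# Merge events closer than the refractory interval, keeping the larger peak.
.mergeRefractory <- function(times, amps, idx, refractory) {
  while (length(times) > 1 && any(diff(times) < refractory)) {
    j <- which(diff(times) < refractory)[1]
    drop <- if (amps[j] >= amps[j + 1]) j + 1 else j
    times <- times[-drop]; amps <- amps[-drop]; idx <- idx[-drop]
  }
  list(times = times, amps = amps, idx = idx)
}

#' Detect spontaneous release events in a trace
#'
#' Samples of the smoothed trace exceeding the trailing moving-average
#' baseline by \code{k} robust noise SDs (both computed over the trailing
#' \code{baselineWindow} ending at the previous frame) are grouped into
#' runs; each run yields one event at its maximum, events closer than the
#' refractory interval are merged (larger peak kept), and the amplitude is
#' the peak minus the baseline at the peak. Detection starts once two full
#' baseline windows of history exist.
#'
#' @param trace a background-subtracted [FluorTrace] (see
#'   [subtractBackground()]); smoothing is applied internally per
#'   \code{params}.
#' @param params a [DetectionParams].
#' @param synapseId id recorded in the output events.
#' @return an [EventList] of kind "spontaneous".
#' @export
detectSpontaneous <- function(trace, params = DetectionParams(),
                              synapseId = 1L) {
  ctx <- .detectionContext(trace, params)
  n <- length(ctx$x)
  start <- 2L * ctx$w
  i <- start:n
  thr <- ctx$baseline[i - 1L] + params@k * ctx$noiseSd[i - 1L]
  cand <- i[ctx$y[i] > thr]
  if (!length(cand)) return(EventList())
  runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
  peakIdx <- vapply(runs, function(r) r[which.max(ctx$y[r])], integer(1))
  times <- trace@t0 + (peakIdx - 1L) * ctx$dt
  amps <- ctx$y[peakIdx] - ctx$baseline[peakIdx - 1L]
  mg <- .mergeRefractory(times, amps, peakIdx, params@refractory)
  ok <- mg$amps > 0
  EventList(events = data.frame(
    time_s = mg$times[ok], amplitude = mg$amps[ok], kind = "spontaneous",
    synapse_id = as.integer(synapseId), stringsAsFactors = FALSE))
}

#' Detect evoked release successes time-locked to stimuli
#'
#' For each stimulus, the response window is \code{(stim, stim +
#' evokedWindow]}; the baseline and robust noise SD are computed over the
#' trailing \code{baselineWindow} ending at the stimulus frame, so the
#' response window itself never contaminates its own threshold. A stimulus
#' is a success when the smoothed trace's maximum in the window exceeds
#' baseline + k SD; the event is placed at that maximum with amplitude
#' peak minus baseline.
#'
#' @param trace a background-subtracted [FluorTrace].
#' @param stimTimes stimulus times (s), strictly increasing, within the
#'   trace; inter-stimulus intervals must exceed \code{evokedWindow}.
#' @param params a [DetectionParams].
#' @param synapseId id recorded in the output events.
#' @return an [EventList] of kind "evoked" with a \code{stim_s} column
#'   mapping each success to its stimulus.
#' @export
detectEvoked <- function(trace, stimTimes, params = DetectionParams(),
                         synapseId = 1L) {
  if (!length(stimTimes)) stop("stimTimes must be non-empty")
  if (any(diff(stimTimes) <= params@evokedWindow))
    stop("overlapping response windows: inter-stimulus interval below evokedWindow")
  ctx <- .detectionContext(trace, params)
  n <- length(ctx$x)
  tt <- traceTimes(trace)
  if (any(stimTimes < tt[1]) || any(stimTimes > tt[n]))
    stop("stimTimes outside the trace span")
  nWin <- max(1L, round(params@evokedWindow / ctx$dt))
  rows <- vector("list", length(stimTimes))
  for (j in seq_along(stimTimes)) {
    iStim <- max(which(tt <= stimTimes[j] + 1e-9))
    if (iStim < 2L * ctx$w - 1L)
      stop("first stimulus needs at least ", format((2 * ctx$w) * ctx$dt),
           " s of baseline history")
    win <- (iStim + 1L):min(n, iStim + nWin)
    b <- ctx$baseline[iStim]
    s <- 1.4826 * stats::median(ctx$d[(iStim - ctx$w + 1L):iStim])
    pk <- win[which.max(ctx$y[win])]
    if (ctx$y[pk] > b + params@k * s && ctx$y[pk] - b > 0) {
      rows[[j]] <- data.frame(time_s = tt[pk], amplitude = ctx$y[pk] - b,
                              kind = "evoked",
                              synapse_id = as.integer(synapseId),
                              stim_s = stimTimes[j], stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(
    EventList(events = data.frame(time_s = numeric(0), amplitude = numeric(0),
                                  kind = character(0), synapse_id = integer(0),
                                  stim_s = numeric(0), stringsAsFactors = FALSE)))
  EventList(events = do.call(rbind, rows))
}
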
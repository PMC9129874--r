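#' @import methods
NULL

.scalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Synapse configuration
#'
#' Parameters of a single simulated synapse: release probability per action
#' potential, spontaneous fusion rate, quantal fluorescence amplitude and its
#' coefficient of variation, and the event kernel time constants.
#'
#' @slot pr per-stimulus release (fusion) probability, in [0, 1].
#' @slot spontRate spontaneous fusion rate (events/s, homogeneous Poisson).
#' @slot quantalAmp mean fluorescence amplitude of a single quantal event (a.u.).
#' @slot ampCv coefficient of variation of event amplitudes; 0 means all
#'   events have exactly \code{quantalAmp}.
#' @slot riseTau rise time constant of the event kernel (s); 0 means an
#'   instantaneous rise.
#' @slot decayTau decay time constant of the event kernel (s).
#' @slot evokedDelay latency from stimulus to the evoked event peak (s).
#' @export SynapseConfig
#' @exportClass SynapseConfig
SynapseConfig <- setClass("SynapseConfig",
  representation(pr = "numeric", spontRate = "numeric", quantalAmp = "numeric",
                 ampCv = "numeric", riseTau = "numeric", decayTau = "numeric",
                 evokedDelay = "numeric"),
  prototype(pr = 0.5, spontRate = 0.015, quantalAmp = 1, ampCv = 0.25,
            riseTau = 0, decayTau = 0.1, evokedDelay = 0.02))

setValidity("SynapseConfig", function(object) {
  msg <- character()
  if (!.scalarNum(object@pr) || object@pr < 0 || object@pr > 1)
    msg <- c(msg, "pr must be a single value in [0, 1]")
  if (!.scalarNum(object@spontRate) || object@spontRate < 0)
    msg <- c(msg, "spontRate must be >= 0")
  if (!.scalarNum(object@quantalAmp) || object@quantalAmp <= 0)
    msg <- c(msg, "quantalAmp must be > 0")
  if (!.scalarNum(object@ampCv) || object@ampCv < 0)
    msg <- c(msg, "ampCv must be >= 0")
  if (!.scalarNum(object@riseTau) || object@riseTau < 0)
    msg <- c(msg, "riseTau must be >= 0")
  if (!.scalarNum(object@decayTau) || object@decayTau <= 0)
    msg <- c(msg, "decayTau must be > 0")
  if (!.scalarNum(object@evokedDelay) || object@evokedDelay < 0)
    msg <- c(msg, "evokedDelay must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Recording protocol
#'
#' Timing of a simulated recording: total duration, sampling rate (50 Hz by
#' default, matching fast glutamate-sensor imaging) and the stimulus times.
#'
#' @slot duration recording length (s).
#' @slot sampleRate frames per second (Hz).
#' @slot stimTimes strictly increasing stimulus (field-pulse) times in
#'   [0, duration]; may be empty.
#' @export RecordingProtocol
#' @exportClass RecordingProtocol
RecordingProtocol <- setClass("RecordingProtocol",
  representation(duration = "numeric", sampleRate = "numeric",
                 stimTimes = "numeric"),
  prototype(duration = 60, sampleRate = 50, stimTimes = numeric(0)))

setValidity("RecordingProtocol", function(object) {
  msg <- character()
  if (!.scalarNum(object@duration) || object@duration <= 0)
    msg <- c(msg, "duration must be > 0")
  if (!.scalarNum(object@sampleRate) || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be > 0")
  st <- object@stimTimes
  if (length(st)) {
    if (any(!is.finite(st)) || any(st < 0) || any(st > object@duration))
      msg <- c(msg, "stimTimes must lie within [0, duration]")
    if (length(st) > 1 && any(diff(st) <= 0))
      msg <- c(msg, "stimTimes must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Imaging noise model
#'
#' Additive frame noise and an affine baseline drift, applied after event
#' kernels are superposed.
#'
#' @slot sigma standard deviation of i.i.d. Gaussian frame noise (a.u.).
#' @slot baselineOffset constant baseline (a.u.).
#' @slot baselineSlope linear baseline drift (a.u./s).
#' @export NoiseModel
#' @exportClass NoiseModel
NoiseModel <- setClass("NoiseModel",
  representation(sigma = "numeric", baselineOffset = "numeric",
                 baselineSlope = "numeric"),
  prototype(sigma = 0, baselineOffset = 0, baselineSlope = 0))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (!.scalarNum(object@sigma) || object@sigma < 0)
    msg <- c(msg, "sigma must be >= 0")
  if (!.scalarNum(object@baselineOffset)) msg <- c(msg, "baselineOffset must be a number")
  if (!.scalarNum(object@baselineSlope)) msg <- c(msg, "baselineSlope must be a number")
  if (length(msg)) msg else TRUE
})

#' Imaging scene
#'
#' Geometry of a simulated field of view: field size, pixel size, synapse
#' positions and the Gaussian point-spread width used to render them.
#'
#' @slot fieldSize width and height of the field (um).
#' @slot pixelSize pixel pitch (um/px).
#' @slot positions n x 2 matrix of synapse (x, y) positions (um).
#' @slot psfSigma isotropic Gaussian point-spread sigma (um).
#' @export Scene
#' @exportClass Scene
Scene <- setClass("Scene",
  representation(fieldSize = "numeric", pixelSize = "numeric",
                 positions = "matrix", psfSigma = "numeric"),
  prototype(fieldSize = c(20, 20), pixelSize = 0.2,
            positions = matrix(numeric(0), ncol = 2), psfSigma = 0.5))

setValidity("Scene", function(object) {
  msg <- character()
  if (length(object@fieldSize) != 2 || any(object@fieldSize <= 0))
    msg <- c(msg, "fieldSize must be two positive lengths (um)")
  if (!.scalarNum(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be > 0")
  if (ncol(object@positions) != 2)
    msg <- c(msg, "positions must be an n x 2 matrix")
  else if (nrow(object@positions) > 0) {
    ok <- object@positions[, 1] >= 0 & object@positions[, 1] <= object@fieldSize[1] &
          object@positions[, 2] >= 0 & object@positions[, 2] <= object@fieldSize[2]
    if (!all(ok)) msg <- c(msg, "all synapse positions must lie inside the field")
  }
  if (!.scalarNum(object@psfSigma) || object@psfSigma <= 0)
    msg <- c(msg, "psfSigma must be > 0")
  if (length(msg)) msg else TRUE
})

#' Uniformly sampled fluorescence trace
#'
#' The pipeline's atomic data object: one ROI's fluorescence over time at a
#' fixed frame interval. Frame i (1-based) is stamped at
#' \code{t0 + (i - 1) * dt}, the acquisition start of the frame.
#'
#' @slot values fluorescence per frame (a.u.), all finite.
#' @slot dt frame interval (s).
#' @slot t0 time of the first frame (s).
#' @export FluorTrace
#' @exportClass FluorTrace
FluorTrace <- setClass("FluorTrace",
  representation(values = "numeric", dt = "numeric", t0 = "numeric"),
  prototype(values = numeric(0), dt = 0.02, t0 = 0))

setValidity("FluorTrace", function(object) {
  msg <- character()
  if (!.scalarNum(object@dt) || object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (!.scalarNum(object@t0)) msg <- c(msg, "t0 must be a number")
  if (length(object@values) && any(!is.finite(object@values)))
    msg <- c(msg, "all trace values must be finite")
  if (length(msg)) msg else TRUE
})

#' List of quantal release events
#'
#' Detected or ground-truth events. The underlying data.frame always has
#' columns \code{time_s}, \code{amplitude}, \code{kind} ("spontaneous" or
#' "evoked") and \code{synapse_id}; detectors may append extra columns (e.g.
#' the stimulus time an evoked success is locked to).
#'
#' @slot events the event table.
#' @export EventList
#' @exportClass EventList
EventList <- setClass("EventList",
  representation(events = "data.frame"),
  prototype(events = data.frame(time_s = numeric(0), amplitude = numeric(0),
                                kind = character(0), synapse_id = integer(0),
                                stringsAsFactors = FALSE)))

setValidity("EventList", function(object) {
  ev <- object@events
  need <- c("time_s", "amplitude", "kind", "synapse_id")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(ev)) {
    if (any(!is.finite(ev$time_s))) msg <- c(msg, "event times must be finite")
    if (any(!is.finite(ev$amplitude) | ev$amplitude <= 0))
      msg <- c(msg, "event amplitudes must be > 0")
    if (!all(ev$kind %in% c("spontaneous", "evoked")))
      msg <- c(msg, "kind must be 'spontaneous' or 'evoked'")
  }
  if (length(msg)) msg else TRUE
})

#' Set of circular regions of interest
#'
#' Circular ROIs centered on synaptic fluorescence maxima; 2 um diameter by
#' default (1 um is typical for FRAP regions).
#'
#' @slot centers n x 2 matrix of (x, y) centers (um).
#' @slot diameter ROI diameter (um).
#' @export ROISet
#' @exportClass ROISet
ROISet <- setClass("ROISet",
  representation(centers = "matrix", diameter = "numeric"),
  prototype(centers = matrix(numeric(0), ncol = 2), diameter = 2))

setValidity("ROISet", function(object) {
  msg <- character()
  if (ncol(object@centers) != 2) msg <- c(msg, "centers must be an n x 2 matrix")
  if (!.scalarNum(object@diameter) || object@diameter <= 0)
    msg <- c(msg, "diameter must be > 0")
  if (length(msg)) msg else TRUE
})

#' Event detection parameters
#'
#' Threshold rule of the detection pipeline: events must exceed a trailing
#' moving-average baseline by \code{k} robust noise SDs; evoked successes
#' must additionally be time-locked within \code{evokedWindow} of a stimulus.
#'
#' @slot k threshold in noise SD multiples.
#' @slot baselineWindow trailing baseline window length (s).
#' @slot evokedWindow response window after each stimulus (s).
#' @slot smoothPoints centered moving-average width (frames): 1 (off), 3 or 5.
#' @slot refractory minimum separation between detected events (s); closer
#'   peaks are merged, keeping the larger.
#' @export DetectionParams
#' @exportClass DetectionParams
DetectionParams <- setClass("DetectionParams",
  representation(k = "numeric", baselineWindow = "numeric",
                 evokedWindow = "numeric", smoothPoints = "numeric",
                 refractory = "numeric"),
  prototype(k = 3, baselineWindow = 4, evokedWindow = 0.3, smoothPoints = 3,
            refractory = 0.1))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (!.scalarNum(object@k) || object@k <= 0) msg <- c(msg, "k must be > 0")
  if (!.scalarNum(object@baselineWindow) || object@baselineWindow <= 0)
    msg <- c(msg, "baselineWindow must be > 0")
  if (!.scalarNum(object@evokedWindow) || object@evokedWindow <= 0)
    msg <- c(msg, "evokedWindow must be > 0")
  if (!(object@smoothPoints %in% c(1, 3, 5)))
    msg <- c(msg, "smoothPoints must be 1, 3 or 5")
  if (!.scalarNum(object@refractory) || object@refractory < 0)
    msg <- c(msg, "refractory must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Raw FRAP curve (ROI / reference / background triplet)
#'
#' @slot times sample times (s).
#' @slot roiRaw raw intensity of the bleached ROI (a.u.).
#' @slot refRaw raw intensity of an unbleached reference region (a.u.),
#'   correcting for acquisition photobleaching.
#' @slot bgRaw raw background intensity (a.u.).
#' @slot bleachEnd 1-based index of the first post-bleach sample.
#' @slot truth list of generating parameters for synthetic curves (empty for
#'   measured data).
#' @export FRAPCurve
#' @exportClass FRAPCurve
FRAPCurve <- setClass("FRAPCurve",
  representation(times = "numeric", roiRaw = "numeric", refRaw = "numeric",
                 bgRaw = "numeric", bleachEnd = "integer", truth = "list"),
  prototype(truth = list()))

setValidity("FRAPCurve", function(object) {
  n <- length(object@times)
  msg <- character()
  if (length(object@roiRaw) != n || length(object@refRaw) != n ||
      length(object@bgRaw) != n)
    msg <- c(msg, "times, roiRaw, refRaw, bgRaw must have equal length")
  if (length(object@bleachEnd) != 1L || is.na(object@bleachEnd) ||
      object@bleachEnd < 2L || object@bleachEnd > n)
    msg <- c(msg, "bleachEnd must index a sample after a non-empty pre-bleach segment")
  else if (all(lengths(list(object@roiRaw, object@refRaw, object@bgRaw)) == n) &&
           any(object@refRaw <= object@bgRaw))
    msg <- c(msg, "reference intensity must exceed background pointwise")
  if (length(msg)) msg else TRUE
})

#' Single-exponential FRAP fit
#'
#' Result of fitting F(t) = Finf - (Finf - F0) * exp(-(t - t_bleach)/tau) to
#' the post-bleach part of a double-normalized recovery curve. The mobile
#' fraction is (Finf - F0)/(1 - F0) on the double-normalized scale; the
#' immobile fraction is its complement (they sum to 1 exactly).
#'
#' @slot tau recovery time constant (s).
#' @slot F0 first post-bleach normalized fluorescence.
#' @slot Finf fitted recovery asymptote.
#' @slot mobileFraction,immobileFraction probe mobility fractions.
#' @slot rSquared coefficient of determination of the fit.
#' @slot converged did the optimizer converge.
#' @slot message diagnostic message for flagged fits.
#' @export FRAPFit
#' @exportClass FRAPFit
FRAPFit <- setClass("FRAPFit",
  representation(tau = "numeric", F0 = "numeric", Finf = "numeric",
                 mobileFraction = "numeric", immobileFraction = "numeric",
                 rSquared = "numeric", converged = "logical",
                 message = "character"),
  prototype(converged = FALSE, message = ""))

#' 2D localization point pattern
#'
#' @slot points n x 2 matrix of (x, y) localizations (nm).
#' @slot field width and height of the observation rectangle (nm), with
#'   origin at (0, 0).
#' @slot marks integer ground-truth mark per point for synthetic patterns
#'   (parent cluster index, or -1 for background); may be empty.
#' @export PointPattern
#' @exportClass PointPattern
PointPattern <- setClass("PointPattern",
  representation(points = "matrix", field = "numeric", marks = "integer"),
  prototype(points = matrix(numeric(0), ncol = 2), field = c(1000, 1000),
            marks = integer(0)))

setValidity("PointPattern", function(object) {
  msg <- character()
  if (ncol(object@points) != 2) msg <- c(msg, "points must be an n x 2 matrix")
  if (length(object@field) != 2 || any(object@field <= 0))
    msg <- c(msg, "field must be two positive lengths (nm)")
  else if (ncol(object@points) == 2 && nrow(object@points)) {
    ok <- object@points[, 1] >= 0 & object@points[, 1] <= object@field[1] &
          object@points[, 2] >= 0 & object@points[, 2] <= object@field[2]
    if (!all(ok)) msg <- c(msg, "all points must lie inside the field")
  }
  if (length(object@marks) && length(object@marks) != nrow(object@points))
    msg <- c(msg, "marks must be empty or one per point")
  if (length(msg)) msg else TRUE
})

#' Photobleaching pool parameters
#'
#' Compartmental model of use-dependent photobleaching. Three well-mixed
#' probe pools: \code{evoked_site} (diffusion-restricted probes at evoked
#' release sites), \code{synaptic_general} (freely exchanging synaptic
#' probes) and \code{reservoir} (the extrasynaptic surface pool, treated as
#' effectively infinite). Each finite-\code{tauExchange} compartment relaxes
#' toward the reservoir's unbleached fraction; only activated (fluorescent)
#' probes can be bleached.
#'
#' @slot tauExchange named exchange time constants (s) for
#'   \code{evoked_site}, \code{synaptic_general}, \code{reservoir}
#'   (reservoir is Inf).
#' @slot kBleach bleaching hazard of a fully activated probe at unit
#'   relative illumination (1/s).
#' @slot aTonic tonic (ambient glutamate) activation fraction of synaptic
#'   compartments, in [0, 1].
#' @slot aTonicReservoir tonic activation of the reservoir pool (default 0:
#'   ambient glutamate is synaptic and much of the reservoir surface lies
#'   outside the illuminated field).
#' @slot eventActivation fraction of a compartment's probes activated by one
#'   release event.
#' @slot eventDuration duration of event-driven activation (s).
#' @export PoolParams
#' @exportClass PoolParams
PoolParams <- setClass("PoolParams",
  representation(tauExchange = "numeric", kBleach = "numeric",
                 aTonic = "numeric", aTonicReservoir = "numeric",
                 eventActivation = "numeric", eventDuration = "numeric"),
  prototype(tauExchange = c(evoked_site = 6 * 3600, synaptic_general = 10,
                            reservoir = Inf),
            kBleach = 0.14, aTonic = 0.05, aTonicReservoir = 0,
            eventActivation = 0.3, eventDuration = 0.5))

.poolNames <- c("evoked_site", "synaptic_general", "reservoir")

setValidity("PoolParams", function(object) {
  msg <- character()
  te <- object@tauExchange
  if (!identical(sort(names(te)), sort(.poolNames)))
    msg <- c(msg, "tauExchange must be named evoked_site, synaptic_general, reservoir")
  else {
    if (any(te <= 0)) msg <- c(msg, "tauExchange values must be > 0 (Inf allowed)")
    if (is.finite(te[["reservoir"]]))
      msg <- c(msg, "reservoir tauExchange must be Inf")
  }
  if (!.scalarNum(object@kBleach) || object@kBleach < 0)
    msg <- c(msg, "kBleach must be >= 0")
  for (sl in c("aTonic", "aTonicReservoir", "eventActivation")) {
    v <- slot(object, sl)
    if (!.scalarNum(v) || v < 0 || v > 1) msg <- c(msg, paste(sl, "must be in [0, 1]"))
  }
  if (!.scalarNum(object@eventDuration) || object@eventDuration <= 0)
    msg <- c(msg, "eventDuration must be > 0")
  if (length(msg)) msg else TRUE
})

#' Unbleached-fraction state of the probe pools
#'
#' @slot u named unbleached fractions in [0, 1] for \code{evoked_site},
#'   \code{synaptic_general}, \code{reservoir}.
#' @slot t model time (s).
#' @export PoolState
#' @exportClass PoolState
PoolState <- setClass("PoolState",
  representation(u = "numeric", t = "numeric"),
  prototype(u = c(evoked_site = 1, synaptic_general = 1, reservoir = 1), t = 0))

setValidity("PoolState", function(object) {
  msg <- character()
  if (!identical(sort(names(object@u)), sort(.poolNames)))
    msg <- c(msg, "u must be named evoked_site, synaptic_general, reservoir")
  else if (any(object@u < -1e-9 | object@u > 1 + 1e-9))
    msg <- c(msg, "unbleached fractions must lie in [0, 1]")
  if (!.scalarNum(object@t)) msg <- c(msg, "t must be a number")
  if (length(msg)) msg else TRUE
})

#' Illumination / stimulation protocol for the photobleaching model
#'
#' An ordered, contiguous list of segments. Each segment has a duration (s),
#' a relative illumination intensity (0 dark, ~0.02 imaging, 1 full-power
#' bleaching), a field-stimulation rate (Hz) and a glutamate-perfusion flag
#' (perfusion saturates activation of every compartment).
#'
#' @slot segments data.frame with columns \code{duration}, \code{intensity},
#'   \code{stim_rate}, \code{glutamate_perfusion}.
#' @export BleachProtocol
#' @exportClass BleachProtocol
BleachProtocol <- setClass("BleachProtocol",
  representation(segments = "data.frame"),
  prototype(segments = data.frame(duration = numeric(0), intensity = numeric(0),
                                  stim_rate = numeric(0),
                                  glutamate_perfusion = logical(0))))

setValidity("BleachProtocol", function(object) {
  sg <- object@segments
  need <- c("duration", "intensity", "stim_rate", "glutamate_perfusion")
  if (!all(need %in% names(sg)))
    return(paste("segments must have columns", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(sg)) {
    if (any(sg$duration <= 0)) msg <- c(msg, "segment durations must be > 0")
    if (any(sg$intensity < 0)) msg <- c(msg, "intensities must be >= 0")
    if (any(sg$stim_rate < 0)) msg <- c(msg, "stim rates must be >= 0")
    if (!is.logical(sg$glutamate_perfusion))
      msg <- c(msg, "glutamate_perfusion must be logical")
  }
  if (length(msg)) msg else TRUE
})

#' Build a protocol segment
#'
#' @param duration segment length (s).
#' @param intensity relative illumination (0 dark, ~0.02 imaging, 1 bleach).
#' @param stimRate field stimulation rate (Hz).
#' @param glutamatePerfusion logical; saturate probe activation.
#' @return one-row data.frame usable in [BleachProtocol()].
#' @export
bleachSegment <- function(duration, intensity = 0, stimRate = 0,
                          glutamatePerfusion = FALSE) {
  data.frame(duration = duration, intensity = intensity, stim_rate = stimRate,
             glutamate_perfusion = glutamatePerfusion)
}
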
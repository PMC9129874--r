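#' Simulate a FRAP triplet (ROI / reference / background)
#'
#' Builds a raw FRAP curve with known ground truth. The ideal normalized
#' recovery is 1 pre-bleach, drops to \code{F0 = 1 - bleachDepth} at the
#' first post-bleach sample and recovers as
#' \code{F(t) = Finf - (Finf - F0) * exp(-(t - t_bleach)/tau)} with
#' \code{Finf = F0 + (1 - immobileFraction) * (1 - F0)}: only the mobile
#' complement of the immobile fraction is replenished by diffusion. The
#' triplet is generated consistently: the reference channel is constant
#' unless an acquisition-bleach rate is requested, in which case ROI and
#' reference decay by the same multiplicative factor (which double
#' normalization cancels).
#'
#' @param tau recovery time constant (s), > 0.
#' @param immobileFraction fraction of the bleached signal that never
#'   recovers, in [0, 1].
#' @param bleachDepth normalized drop at the first post-bleach frame, in
#'   (0, 1].
#' @param preFrames number of pre-bleach samples (>= 1).
#' @param postDuration post-bleach duration (s).
#' @param sampleRate sampling rate (Hz).
#' @param noiseSigma Gaussian noise SD added to each raw channel (a.u.).
#' @param seed integer seed.
#' @param roiGain,refLevel,bgLevel raw-intensity scales of the three
#'   channels (a.u.).
#' @param acqBleachRate exponential acquisition-photobleaching rate applied
#'   to ROI and reference (1/s); 0 for a constant reference.
#' @return a [FRAPCurve]; \code{truth} holds the generating parameters.
#' @examples
#' crv <- generateFrapCurve(tau = 10, immobileFraction = 0.25)
#' fitFrap(crv)
#' @export
generateFrapCurve <- function(tau, immobileFraction, bleachDepth = 0.8,
                              preFrames = 10L, postDuration = 60,
                              sampleRate = 1, noiseSigma = 0, seed = 1L,
                              roiGain = 100, refLevel = 100, bgLevel = 10,
                              acqBleachRate = 0) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  if (immobileFraction < 0 || immobileFraction > 1)
    stop("immobileFraction must be in [0, 1]")
  if (bleachDepth <= 0 || bleachDepth > 1)
    stop("bleachDepth must be in (0, 1]")
  if (preFrames < 1) stop("need a non-empty pre-bleach segment")
  dt <- 1 / sampleRate
  nPost <- max(5L, floor(postDuration * sampleRate))
  times <- (seq_len(preFrames + nPost) - 1) * dt
  bleachEnd <- as.integer(preFrames + 1L)
  tBleach <- times[bleachEnd]

  F0 <- 1 - bleachDepth
  Finf <- F0 + (1 - immobileFraction) * (1 - F0)
  Fid <- rep(1, length(times))
  post <- bleachEnd:length(times)
  Fid[post] <- Finf - (Finf - F0) * exp(-(times[post] - tBleach) / tau)

  g <- exp(-acqBleachRate * times)
  noise <- withSeed(seed, {
    if (noiseSigma > 0) matrix(stats::rnorm(3 * length(times), 0, noiseSigma), ncol = 3)
    else matrix(0, length(times), 3)
  })
  FRAPCurve(times = times,
            roiRaw = bgLevel + roiGain * Fid * g + noise[, 1],
            refRaw = bgLevel + refLevel * g + noise[, 2],
            bgRaw = bgLevel + noise[, 3],
            bleachEnd = bleachEnd,
            truth = list(tau = tau, immobileFraction = immobileFraction,
                         bleachDepth = bleachDepth, F0 = F0, Finf = Finf))
}
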
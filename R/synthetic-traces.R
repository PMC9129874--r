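#' Simulate a single-synapse fluorescence trace with ground truth
#'
#' Generates one ROI trace at the recording's frame rate. Evoked events are
#' drawn Bernoulli(\code{pr}) at each stimulus (peaking \code{evokedDelay}
#' after the pulse); spontaneous events follow a homogeneous Poisson process
#' at \code{spontRate}. Each event adds the kernel
#' \code{A * (1 - exp(-s/riseTau)) * exp(-s/decayTau)} (instantaneous rise
#' when \code{riseTau = 0}); event times are snapped to the frame grid so
#' the sampled peak equals the drawn amplitude. Amplitudes are lognormal
#' with mean \code{quantalAmp} and CV \code{ampCv} (all equal when
#' \code{ampCv = 0}). If \code{pools} is given, each event's amplitude is
#' scaled by the unbleached fraction of its compartment at the event time
#' (evoked events draw on \code{evoked_site}, spontaneous on
#' \code{synaptic_general}). Gaussian frame noise and an affine baseline are
#' added last.
#'
#' @param cfg a [SynapseConfig].
#' @param proto a [RecordingProtocol].
#' @param noise a [NoiseModel].
#' @param pools \code{NULL}, a [PoolState] (static unbleached fractions), or
#'   a pool trajectory data.frame with columns \code{time_s},
#'   \code{u_evoked}, \code{u_spont} (linearly interpolated at event times).
#' @param seed integer seed; fixes all randomness.
#' @param synapseId id recorded in the ground-truth events.
#' @return list with elements \code{trace} ([FluorTrace]) and \code{events}
#'   (ground-truth [EventList] with exact times, amplitudes and kinds).
#' @examples
#' cfg <- SynapseConfig(pr = 1, ampCv = 0)
#' proto <- RecordingProtocol(duration = 30, stimTimes = seq(5, 25, by = 5))
#' sim <- generateTrace(cfg, proto, NoiseModel(sigma = 0), seed = 1)
#' length(events(sim$events)$time_s)  # 5 evoked events
#' @export
generateTrace <- function(cfg, proto, noise = NoiseModel(), pools = NULL,
                          seed = 1L, synapseId = 1L) {
  validObject(cfg); validObject(proto); validObject(noise)
  dt <- 1 / proto@sampleRate
  if (proto@sampleRate <= 2 / cfg@decayTau)
    stop("sampleRate must exceed 2/decayTau to sample events faithfully")
  n <- max(2L, floor(proto@duration * proto@sampleRate))
  times <- (seq_len(n) - 1) * dt

  draws <- withSeed(seed, {
    nStim <- length(proto@stimTimes)
    evokedHit <- if (nStim) stats::rbinom(nStim, 1L, cfg@pr) == 1L else logical(0)
    nSpont <- stats::rpois(1L, cfg@spontRate * proto@duration)
    spontT <- sort(stats::runif(nSpont, 0, proto@duration))
    nEv <- sum(evokedHit) + nSpont
    amps <- if (nEv == 0L) {
      numeric(0)
    } else if (cfg@ampCv == 0) {
      rep(cfg@quantalAmp, nEv)
    } else {
      s2 <- log(1 + cfg@ampCv^2)
      stats::rlnorm(nEv, meanlog = log(cfg@quantalAmp) - s2 / 2, sdlog = sqrt(s2))
    }
    frameNoise <- if (noise@sigma > 0) stats::rnorm(n, 0, noise@sigma) else numeric(0)
    list(evokedHit = evokedHit, spontT = spontT, amps = amps,
         frameNoise = frameNoise)
  })

  snap <- function(t) pmin(n - 1L, pmax(0L, round(t / dt))) * dt
  evTime <- c(snap(proto@stimTimes[draws$evokedHit] + cfg@evokedDelay),
              snap(draws$spontT))
  evKind <- c(rep("evoked", sum(draws$evokedHit)),
              rep("spontaneous", length(draws$spontT)))
  evStim <- c(proto@stimTimes[draws$evokedHit],
              rep(NA_real_, length(draws$spontT)))
  amps <- draws$amps

  # use-dependent bleaching: scale by the compartment's unbleached fraction
  if (!is.null(pools) && length(evTime)) {
    uAt <- poolFractionAt(pools, evTime)
    u <- ifelse(evKind == "evoked", uAt$u_evoked, uAt$u_spont)
    amps <- amps * u
  }

  values <- noise@baselineOffset + noise@baselineSlope * times
  keep <- rep(TRUE, length(evTime))
  if (length(evTime)) {
    span <- ceiling((12 * cfg@riseTau + 25 * cfg@decayTau) / dt)
    for (j in seq_along(evTime)) {
      if (amps[j] <= 0) { keep[j] <- FALSE; next }  # fully bleached compartment
      i0 <- round(evTime[j] / dt) + 1L
      idx <- i0:min(n, i0 + span)
      s <- times[idx] - evTime[j]
      rise <- if (cfg@riseTau > 0) (1 - exp(-s / cfg@riseTau)) else 1
      values[idx] <- values[idx] + amps[j] * rise * exp(-s / cfg@decayTau)
    }
  }
  if (noise@sigma > 0) values <- values + draws$frameNoise

  ord <- order(evTime[keep])
  nKeep <- sum(keep)
  ev <- data.frame(time_s = evTime[keep][ord], amplitude = amps[keep][ord],
                   kind = evKind[keep][ord],
                   synapse_id = rep(as.integer(synapseId), nKeep),
                   stim_s = evStim[keep][ord], stringsAsFactors = FALSE)
  list(trace = FluorTrace(values = values, dt = dt, t0 = 0),
       events = EventList(events = ev))
}

# Unbleached fractions at given times from a PoolState or trajectory.
poolFractionAt <- function(pools, at) {
  if (is(pools, "PoolState")) {
    data.frame(u_evoked = rep(pools@u[["evoked_site"]], length(at)),
               u_spont = rep(pools@u[["synaptic_general"]], length(at)))
  } else if (is.data.frame(pools) &&
             all(c("time_s", "u_evoked", "u_spont") %in% names(pools))) {
    data.frame(
      u_evoked = stats::approx(pools$time_s, pools$u_evoked, at, rule = 2)$y,
      u_spont = stats::approx(pools$time_s, pools$u_spont, at, rule = 2)$y)
  } else {
    stop("pools must be a PoolState or a trajectory data.frame with ",
         "columns time_s, u_evoked, u_spont")
  }
}

#' Simulate a time-lapse movie of a synapse field
#'
#' Renders each synapse as an isotropic 2D Gaussian of width
#' \code{psfSigma}, with the time course of its own [generateTrace()]
#' simulation (one independent RNG substream per synapse, derived from
#' \code{seed}, so adding synapses does not perturb earlier ones). Baseline
#' and Gaussian pixel noise are added at the frame level.
#'
#' @param scene a [Scene]; one synapse per row of \code{positions}.
#' @param configs a single [SynapseConfig] (recycled) or a list with one per
#'   synapse.
#' @param proto a [RecordingProtocol].
#' @param noise a [NoiseModel] (sigma applied per pixel per frame).
#' @param seed integer master seed.
#' @return numeric array of dimension (frames, y, x) with attributes
#'   \code{dt}, \code{pixel_size} and \code{ground_truth} (the combined
#'   ground-truth event table).
#' @export
generateMovie <- function(scene, configs, proto, noise = NoiseModel(),
                          seed = 1L) {
  validObject(scene); validObject(proto); validObject(noise)
  nSyn <- nrow(scene@positions)
  if (is(configs, "SynapseConfig")) configs <- rep(list(configs), nSyn)
  if (length(configs) != nSyn)
    stop("need one SynapseConfig per synapse position")
  nx <- ceiling(scene@fieldSize[1] / scene@pixelSize)
  ny <- ceiling(scene@fieldSize[2] / scene@pixelSize)
  nFrames <- max(2L, floor(proto@duration * proto@sampleRate))
  seeds <- substreamSeeds(seed, nSyn + 1L)

  px <- scene@pixelSize
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  frames <- matrix(0, nFrames, ny * nx)
  evAll <- list()
  quiet <- NoiseModel(sigma = 0, baselineOffset = 0, baselineSlope = 0)
  for (s in seq_len(nSyn)) {
    sim <- generateTrace(configs[[s]], proto, quiet, seed = seeds[s],
                         synapseId = s)
    w <- outer(yc, xc, function(y, x) {
      exp(-((x - scene@positions[s, 1])^2 + (y - scene@positions[s, 2])^2) /
            (2 * scene@psfSigma^2))
    })
    frames <- frames + tcrossprod(sim$trace@values, as.vector(w))
    evAll[[s]] <- sim$events@events
  }
  tFrame <- (seq_len(nFrames) - 1) / proto@sampleRate
  frames <- frames + noise@baselineOffset + noise@baselineSlope * tFrame
  if (noise@sigma > 0) {
    frames <- frames + withSeed(seeds[nSyn + 1L],
      matrix(stats::rnorm(nFrames * ny * nx, 0, noise@sigma), nFrames))
  }
  stack <- array(frames, dim = c(nFrames, ny, nx))
  attr(stack, "dt") <- 1 / proto@sampleRate
  attr(stack, "pixel_size") <- px
  attr(stack, "ground_truth") <- if (length(evAll)) do.call(rbind, evAll) else
    EventList()@events
  stack
}
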
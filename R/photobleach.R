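#' Per-compartment activation fractions for a protocol segment
#'
#' Only activated (glutamate-bound, fluorescent) probes can be bleached.
#' Under glutamate perfusion every compartment is fully activated. Otherwise
#' the synaptic compartments carry the tonic (ambient glutamate) activation
#' plus the duty-cycle average of event-driven activation pulses: each
#' release event activates \code{eventActivation} of its compartment for
#' \code{eventDuration}, so a pulse train at rate r contributes
#' \code{r * eventActivation * eventDuration}. Evoked events (rate
#' \code{pr * stim_rate}) drive \code{evoked_site}; spontaneous events (rate
#' \code{spontRate}) drive \code{synaptic_general}. The reservoir carries
#' its own tonic activation. All values are clamped to [0, 1].
#'
#' @param params a [PoolParams].
#' @param segment one-row segment data.frame (see [bleachSegment()]).
#' @param pr release probability governing evoked activation.
#' @param spontRate spontaneous event rate (Hz).
#' @return named activation vector over the three compartments.
#' @export
activationFractions <- function(params, segment, pr = 0, spontRate = 0) {
  validObject(params)
  if (isTRUE(segment$glutamate_perfusion))
    return(c(evoked_site = 1, synaptic_general = 1, reservoir = 1))
  duty <- params@eventActivation * params@eventDuration
  a <- c(evoked_site = params@aTonic + pr * segment$stim_rate * duty,
         synaptic_general = params@aTonic + spontRate * duty,
         reservoir = params@aTonicReservoir)
  pmin(pmax(a, 0), 1)
}

#' Integrate the photobleaching pool dynamics over a protocol
#'
#' Each compartment's unbleached fraction obeys
#' \deqn{du_c/dt = -k_{bleach} I(t) a_c(t) u_c + (u_{res} - u_c)/\tau_c,}
#' i.e. activated probes bleach under illumination while lateral exchange
#' relaxes the compartment toward the reservoir. The reservoir is treated as
#' an effectively infinite pool that evolves only by its own tonic
#' bleaching. Integration uses a per-step exponential update with activation
#' and the reservoir level frozen within each step (locally exact for the
#' bleaching term, O(dt^2) overall).
#'
#' @param state initial [PoolState].
#' @param params a [PoolParams].
#' @param protocol a [BleachProtocol].
#' @param dt integration step (s); must be at most one tenth of the
#'   smallest finite exchange time constant and at most half the event
#'   duration.
#' @param pr,spontRate release statistics passed to
#'   [activationFractions()].
#' @param recordEvery keep every k-th step in the returned trajectory
#'   (segment boundaries are always kept); default caps the trajectory near
#'   20000 rows.
#' @return data.frame trajectory with columns \code{time_s},
#'   \code{u_evoked}, \code{u_spont}, \code{u_reservoir}, \code{segment};
#'   the first row is the initial state. Attribute \code{final_state} holds
#'   the end-of-protocol [PoolState].
#' @export
evolvePools <- function(state, params, protocol, dt = 0.1, pr = 0,
                        spontRate = 0, recordEvery = NULL) {
  validObject(state); validObject(params); validObject(protocol)
  finiteTau <- params@tauExchange[is.finite(params@tauExchange)]
  if (length(finiteTau) && dt > min(finiteTau) / 10)
    stop("dt too coarse: must be <= min(tauExchange)/10 = ",
         format(min(finiteTau) / 10), " s")
  if (dt > params@eventDuration / 2)
    stop("dt too coarse: must be <= eventDuration/2 = ",
         format(params@eventDuration / 2), " s")
  sg <- protocol@segments
  totSteps <- sum(pmax(1, round(sg$duration / dt)))
  if (is.null(recordEvery))
    recordEvery <- max(1L, ceiling(totSteps / 20000))

  uE <- state@u[["evoked_site"]]
  uS <- state@u[["synaptic_general"]]
  uR <- state@u[["reservoir"]]
  tauE <- params@tauExchange[["evoked_site"]]
  tauS <- params@tauExchange[["synaptic_general"]]
  t0 <- state@t

  out <- list(data.frame(time_s = t0, u_evoked = uE, u_spont = uS,
                         u_reservoir = uR, segment = 0L))
  tCur <- t0
  for (k in seq_len(nrow(sg))) {
    seg <- sg[k, ]
    a <- activationFractions(params, seg, pr = pr, spontRate = spontRate)
    b <- params@kBleach * seg$intensity * a
    nStep <- max(1L, round(seg$duration / dt))
    h <- seg$duration / nStep
    # reservoir: closed-form tonic decay within the segment
    uRstart <- uR * exp(-b[["reservoir"]] * h * (seq_len(nStep) - 1))
    uRend <- uR * exp(-b[["reservoir"]] * h * seq_len(nStep))
    step1 <- function(u0, bc, tauc) {
      lam <- bc + 1 / tauc
      if (lam <= 0) return(rep(u0, nStep))
      alpha <- exp(-lam * h)
      ustar <- (uRstart / tauc) / lam
      as.numeric(stats::filter((1 - alpha) * ustar, alpha,
                               method = "recursive", init = u0))
    }
    uEv <- step1(uE, b[["evoked_site"]], tauE)
    uSv <- step1(uS, b[["synaptic_general"]], tauS)
    uE <- uEv[nStep]; uS <- uSv[nStep]; uR <- uRend[nStep]
    keep <- unique(c(seq(recordEvery, nStep, by = recordEvery), nStep))
    out[[k + 1L]] <- data.frame(time_s = tCur + h * keep, u_evoked = uEv[keep],
                                u_spont = uSv[keep], u_reservoir = uRend[keep],
                                segment = k)
    tCur <- tCur + seg$duration
  }
  traj <- do.call(rbind, out)
  ucols <- c("u_evoked", "u_spont", "u_reservoir")
  if (any(unlist(traj[ucols]) < -1e-9 | unlist(traj[ucols]) > 1 + 1e-9))
    stop("internal error: unbleached fraction left [0, 1]")
  traj[ucols] <- lapply(traj[ucols], function(v) pmin(pmax(v, 0), 1))
  attr(traj, "final_state") <- PoolState(
    u = c(evoked_site = max(0, min(1, uE)),
          synaptic_general = max(0, min(1, uS)),
          reservoir = max(0, min(1, uR))),
    t = tCur)
  traj
}

#' Final pool state of a trajectory
#' @param traj trajectory from [evolvePools()].
#' @return the [PoolState] at the end of the protocol.
#' @export
finalPoolState <- function(traj) {
  st <- attr(traj, "final_state")
  if (is.null(st)) {
    last <- traj[nrow(traj), ]
    st <- PoolState(u = c(evoked_site = last$u_evoked,
                          synaptic_general = last$u_spont,
                          reservoir = last$u_reservoir),
                    t = last$time_s)
  }
  st
}

#' Event detectability given bleached pools
#'
#' Relative evoked amplitude equals the unbleached fraction of
#' \code{evoked_site}; relative spontaneous amplitude that of
#' \code{synaptic_general}. An event is detectable when its scaled quantal
#' amplitude still clears the threshold of \code{k} noise SDs.
#'
#' @param state a [PoolState].
#' @param cfg a [SynapseConfig].
#' @param noise a [NoiseModel].
#' @param k detection threshold in noise SDs.
#' @return data.frame with one row per mode: \code{mode},
#'   \code{rel_amplitude}, \code{detectable}.
#' @export
detectability <- function(state, cfg, noise, k = 3) {
  validObject(state); validObject(cfg); validObject(noise)
  u <- c(evoked = state@u[["evoked_site"]],
         spontaneous = state@u[["synaptic_general"]])
  amp <- cfg@quantalAmp * u
  data.frame(mode = names(u), rel_amplitude = as.numeric(u),
             detectable = amp >= k * noise@sigma & amp > 0,
             row.names = NULL)
}

# Probability that a quantal peak of scaled amplitude amp*u clears the
# baseline + k*sigma threshold under unit-SD Gaussian peak noise.
.detectProb <- function(u, quantalAmp, sigma, k) {
  if (sigma <= 0) return(as.numeric(quantalAmp * u > 0))
  stats::pnorm((quantalAmp * u - k * sigma) / sigma)
}

#' Model-predicted relative release metrics over a bleaching protocol
#'
#' Integrates the pool model through \code{protocol} plus a final dark
#' recovery segment, and converts the unbleached fractions into relative
#' (post/pre) detection metrics: \code{rel_amp_evoked} and
#' \code{rel_amp_spont} are the unbleached fractions themselves, while
#' \code{rel_pr} and \code{rel_freq} are detection probabilities under the
#' \code{k}-SD threshold, normalized to the unbleached state.
#'
#' @param params a [PoolParams].
#' @param cfg a [SynapseConfig] (supplies pr, spontaneous rate and quantal
#'   amplitude).
#' @param noise a [NoiseModel].
#' @param protocol a [BleachProtocol] (may be empty).
#' @param recoveryHorizon duration of the appended dark recovery segment
#'   (s); 0 for none.
#' @param k detection threshold in noise SDs.
#' @param dt integration step (s).
#' @return trajectory data.frame with columns \code{time_s},
#'   \code{u_evoked}, \code{u_spont}, \code{rel_pr}, \code{rel_freq},
#'   \code{rel_amp_evoked}, \code{rel_amp_spont}.
#' @export
runProtocol <- function(params, cfg, noise, protocol, recoveryHorizon = 0,
                        k = 3, dt = 0.1) {
  validObject(cfg); validObject(noise)
  sg <- protocol@segments
  if (recoveryHorizon > 0)
    sg <- rbind(sg, bleachSegment(recoveryHorizon, intensity = 0))
  state <- PoolState()
  if (nrow(sg) == 0) {
    traj <- data.frame(time_s = 0, u_evoked = 1, u_spont = 1,
                       u_reservoir = 1, segment = 0L)
  } else {
    traj <- evolvePools(state, params, BleachProtocol(segments = sg), dt = dt,
                        pr = cfg@pr, spontRate = cfg@spontRate)
  }
  p1 <- .detectProb(1, cfg@quantalAmp, noise@sigma, k)
  rel <- function(u) .detectProb(u, cfg@quantalAmp, noise@sigma, k) / p1
  data.frame(time_s = traj$time_s, u_evoked = traj$u_evoked,
             u_spont = traj$u_spont,
             rel_pr = rel(traj$u_evoked),
             rel_freq = rel(traj$u_spont),
             rel_amp_evoked = traj$u_evoked,
             rel_amp_spont = traj$u_spont)
}
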
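#' Run a simulated photobleaching experiment end to end
#'
#' Reproduces the pre/bleach/post paradigm on synthetic data: every synapse
#' is recorded before bleaching (spontaneous recording, then a stimulus
#' train), the compartmental photobleaching model is integrated through the
#' bleach and a dark recovery wait, post-bleach recordings are simulated
#' with event amplitudes scaled by the evolving unbleached pool fractions,
#' both recordings are run through the detection pipeline, and per-synapse
#' relative metrics plus per-coverslip averages are written alongside the
#' model's predicted pool trajectory and a reproducibility manifest.
#'
#' @param config path to a YAML configuration or an equivalent named list.
#'   Required blocks: \code{synapses} (n, pr, quantal_amp, ...), \code{noise}
#'   (sigma), \code{recording} (spont_duration, n_stims, stim_interval,
#'   lead_in), \code{bleach} (duration, intensity, glutamate_perfusion,
#'   recovery_wait); optional \code{model}, \code{detection},
#'   \code{coverslips}, \code{seed}.
#' @param outDir output directory (created); NULL for a tempdir.
#' @param seed overrides the config seed.
#' @return invisibly, a list with the output directory, the per-synapse
#'   relative metrics, the coverslip summary and the pool trajectory.
#' @export
runExperiment <- function(config, outDir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfgErrs <- .validateExperimentConfig(config)
  if (length(cfgErrs))
    stop("invalid experiment config:\n  - ", paste(cfgErrs, collapse = "\n  - "))
  if (is.null(seed)) seed <- config$seed
  if (is.null(outDir)) outDir <- tempfile("gluSynapse_run_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  sc <- config$synapses
  n <- sc$n
  prVec <- rep(sc$pr, length.out = n)
  mkCfg <- function(pr) SynapseConfig(
    pr = pr,
    spontRate = .orDefault(sc$spont_rate, 0.015),
    quantalAmp = .orDefault(sc$quantal_amp, 8),
    ampCv = .orDefault(sc$amp_cv, 0.25),
    decayTau = .orDefault(sc$decay_tau, 0.1))
  noise <- NoiseModel(sigma = .orDefault(config$noise$sigma, 1))
  det <- config$detection
  params <- DetectionParams(
    k = .orDefault(det$k, 3),
    baselineWindow = .orDefault(det$baseline_window, 4),
    evokedWindow = .orDefault(det$evoked_window, 0.3),
    smoothPoints = .orDefault(det$smooth_points, 3),
    refractory = .orDefault(det$refractory, 0.1))

  rec <- config$recording
  stimTimes <- rec$lead_in + (seq_len(rec$n_stims) - 1) * rec$stim_interval
  evokedDur <- rec$lead_in + rec$n_stims * rec$stim_interval
  protoSpont <- RecordingProtocol(duration = rec$spont_duration)
  protoEvoked <- RecordingProtocol(duration = evokedDur, stimTimes = stimTimes)

  # photobleaching model through bleach + dark wait + post imaging
  bl <- config$bleach
  poolParams <- .poolParamsFromConfig(config$model)
  segs <- list()
  if (bl$duration > 0)
    segs <- c(segs, list(bleachSegment(bl$duration,
                                       intensity = .orDefault(bl$intensity, 1),
                                       glutamatePerfusion = isTRUE(bl$glutamate_perfusion))))
  wait <- .orDefault(bl$recovery_wait, 0)
  if (wait > 0) segs <- c(segs, list(bleachSegment(wait, intensity = 0)))
  imagingI <- .orDefault(bl$imaging_intensity, 0.02)
  segs <- c(segs, list(bleachSegment(rec$spont_duration + evokedDur,
                                     intensity = imagingI)))
  protocol <- BleachProtocol(segments = do.call(rbind, segs))
  meanCfg <- mkCfg(mean(prVec))
  traj <- evolvePools(PoolState(), poolParams, protocol, dt = 0.1,
                      pr = meanCfg@pr, spontRate = meanCfg@spontRate)
  tPost <- sum(vapply(segs, function(s) s$duration, numeric(1))) -
    (rec$spont_duration + evokedDur)
  poolsSpont <- data.frame(time_s = traj$time_s - tPost,
                           u_evoked = traj$u_evoked, u_spont = traj$u_spont)
  poolsEvoked <- data.frame(time_s = traj$time_s - tPost - rec$spont_duration,
                            u_evoked = traj$u_evoked, u_spont = traj$u_spont)

  seeds <- matrix(substreamSeeds(seed, 4L * n), ncol = 4)
  onePhase <- function(i, pools, col0) {
    cfg <- mkCfg(prVec[i])
    simS <- generateTrace(cfg, protoSpont, noise,
                          pools = if (is.null(pools)) NULL else pools$spont,
                          seed = seeds[i, col0], synapseId = i)
    simE <- generateTrace(cfg, protoEvoked, noise,
                          pools = if (is.null(pools)) NULL else pools$evoked,
                          seed = seeds[i, col0 + 1L], synapseId = i)
    spEv <- detectSpontaneous(subtractBackground(simS$trace), params,
                              synapseId = i)
    evEv <- detectEvoked(subtractBackground(simE$trace), stimTimes, params,
                         synapseId = i)
    summarizeSynapse(evEv, stimTimes, spEv, rec$spont_duration, synapseId = i)
  }
  pre <- do.call(rbind, lapply(seq_len(n), onePhase, pools = NULL, col0 = 1L))
  post <- do.call(rbind, lapply(seq_len(n), onePhase,
                                pools = list(spont = poolsSpont,
                                             evoked = poolsEvoked),
                                col0 = 3L))
  relative <- comparePrePost(pre, post)
  nCov <- .orDefault(config$coverslips, 1)
  grouping <- rep(seq_len(nCov), length.out = n)
  coverslip <- coverslipSummarize(relative[, c("relative_pr", "relative_freq",
                                               "relative_amp")], grouping)

  paths <- c(pre = "per_synapse_pre.csv", post = "per_synapse_post.csv",
             relative = "relative_metrics.csv",
             coverslip = "coverslip_summary.csv",
             pools = "pool_trajectory.csv")
  utils::write.csv(pre, file.path(outDir, paths["pre"]), row.names = FALSE)
  utils::write.csv(post, file.path(outDir, paths["post"]), row.names = FALSE)
  utils::write.csv(relative, file.path(outDir, paths["relative"]),
                   row.names = FALSE)
  utils::write.csv(coverslip, file.path(outDir, paths["coverslip"]),
                   row.names = FALSE)
  utils::write.csv(traj, file.path(outDir, paths["pools"]), row.names = FALSE)
  manifest <- list(
    config = config, seed = seed,
    package = list(name = "gluSynapse",
                   version = as.character(utils::packageVersion("gluSynapse"))),
    outputs = as.list(tools::md5sum(file.path(outDir, paths))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(outDir = outDir, pre = pre, post = post, relative = relative,
                 coverslip = coverslip, trajectory = traj))
}

.orDefault <- function(x, default) if (is.null(x)) default else x

.poolParamsFromConfig <- function(model) {
  p <- PoolParams()
  if (is.null(model)) return(p)
  if (!is.null(model$k_bleach)) p@kBleach <- model$k_bleach
  if (!is.null(model$a_tonic)) p@aTonic <- model$a_tonic
  if (!is.null(model$a_tonic_reservoir)) p@aTonicReservoir <- model$a_tonic_reservoir
  if (!is.null(model$event_activation)) p@eventActivation <- model$event_activation
  if (!is.null(model$event_duration)) p@eventDuration <- model$event_duration
  if (!is.null(model$tau_exchange_evoked))
    p@tauExchange[["evoked_site"]] <- model$tau_exchange_evoked
  if (!is.null(model$tau_exchange_spont))
    p@tauExchange[["synaptic_general"]] <- model$tau_exchange_spont
  validObject(p)
  p
}

# Collect every schema violation so the user sees them all at once.
.validateExperimentConfig <- function(config) {
  errs <- character()
  req <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  req(is.list(config), "config must be a list or YAML path")
  if (!is.list(config)) return(errs)
  req(!is.null(config$seed) && is.numeric(config$seed), "seed: integer required")
  sc <- config$synapses
  req(is.list(sc), "synapses: block required")
  if (is.list(sc)) {
    req(is.numeric(sc$n) && sc$n >= 1, "synapses$n: count >= 1 required")
    req(is.numeric(sc$pr) && all(sc$pr >= 0 & sc$pr <= 1),
        "synapses$pr: probability in [0,1] required")
  }
  req(is.list(config$noise) && is.numeric(config$noise$sigma) &&
        config$noise$sigma >= 0, "noise$sigma: value >= 0 required")
  rec <- config$recording
  req(is.list(rec), "recording: block required")
  if (is.list(rec)) {
    req(is.numeric(rec$spont_duration) && rec$spont_duration > 0,
        "recording$spont_duration: seconds > 0 required")
    req(is.numeric(rec$n_stims) && rec$n_stims >= 1,
        "recording$n_stims: count >= 1 required")
    req(is.numeric(rec$stim_interval) && rec$stim_interval > 0,
        "recording$stim_interval: seconds > 0 required")
    req(is.numeric(rec$lead_in) && rec$lead_in > 0,
        "recording$lead_in: seconds > 0 required")
  }
  bl <- config$bleach
  req(is.list(bl), "bleach: block required")
  if (is.list(bl)) {
    req(is.numeric(bl$duration) && bl$duration >= 0,
        "bleach$duration: seconds >= 0 required")
  }
  errs
}
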
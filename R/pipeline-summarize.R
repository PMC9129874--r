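#' Release probability by failure analysis
#'
#' The number of detected evoked successes divided by the number of
#' stimulations -- an exact ratio of integers.
#'
#' @param evoked an [EventList] of evoked successes (at most one per
#'   stimulus).
#' @param stimTimes the delivered stimulus times.
#' @return release probability in [0, 1].
#' @export
releaseProbability <- function(evoked, stimTimes) {
  if (length(stimTimes) == 0) stop("zero stimulations: Pr undefined")
  nSucc <- length(evoked)
  if (nSucc > length(stimTimes))
    stop("more successes than stimulations: events do not map to stimuli")
  nSucc / length(stimTimes)
}

#' Spontaneous event frequency
#'
#' @param events an [EventList] of spontaneous events.
#' @param duration recording duration (s), > 0.
#' @return event rate (Hz).
#' @export
spontaneousFrequency <- function(events, duration) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  length(events) / duration
}

#' Summarize one synapse's recording
#'
#' @param evoked evoked [EventList] (may be empty).
#' @param stimTimes stimulus train (may be empty, in which case pr is NA).
#' @param spont spontaneous [EventList] (may be empty).
#' @param duration spontaneous-recording duration (s).
#' @param synapseId synapse identifier.
#' @return one-row data.frame with \code{synapse_id}, \code{pr},
#'   \code{spont_freq}, \code{mean_amp} (all events),
#'   \code{mean_amp_evoked}, \code{mean_amp_spont}, \code{n_stims},
#'   \code{duration}.
#' @export
summarizeSynapse <- function(evoked = EventList(), stimTimes = numeric(0),
                             spont = EventList(), duration = NA_real_,
                             synapseId = 1L) {
  ampsE <- events(evoked)$amplitude
  ampsS <- events(spont)$amplitude
  amps <- c(ampsE, ampsS)
  data.frame(
    synapse_id = as.integer(synapseId),
    pr = if (length(stimTimes)) releaseProbability(evoked, stimTimes) else NA_real_,
    spont_freq = if (is.finite(duration)) spontaneousFrequency(spont, duration)
                 else NA_real_,
    mean_amp = if (length(amps)) mean(amps) else NA_real_,
    mean_amp_evoked = if (length(ampsE)) mean(ampsE) else NA_real_,
    mean_amp_spont = if (length(ampsS)) mean(ampsS) else NA_real_,
    n_stims = length(stimTimes),
    duration = duration)
}

.ratioOrExcluded <- function(post, pre) {
  excluded <- !is.finite(pre) | pre == 0
  r <- ifelse(excluded, NA_real_, ifelse(is.finite(post), post / pre, NA_real_))
  # a post recording with zero events is a genuine 0, not an exclusion
  r[!excluded & !is.finite(post)] <- 0
  list(ratio = r, excluded = excluded)
}

#' Relative (post/pre) release metrics per synapse
#'
#' Normalizes each synapse's post-bleach metrics to its own pre-bleach
#' values, accounting for between-synapse differences in release. Synapses
#' with a zero (or undefined) pre-value for a metric are flagged as
#' excluded for that ratio rather than dividing by zero; a post value of
#' zero events yields a genuine ratio of 0.
#'
#' @param pre,post per-synapse summary data.frames from
#'   [summarizeSynapse()] (matched on \code{synapse_id}).
#' @return data.frame with \code{synapse_id}, \code{relative_pr},
#'   \code{relative_freq}, \code{relative_amp} and per-metric
#'   \code{excluded_*} flags.
#' @export
comparePrePost <- function(pre, post) {
  m <- merge(pre, post, by = "synapse_id", suffixes = c("_pre", "_post"))
  if (!nrow(m)) stop("no matching synapse_id between pre and post")
  ampPre <- ifelse(is.finite(m$mean_amp_pre), m$mean_amp_pre, 0)
  ampPost <- ifelse(is.finite(m$mean_amp_post), m$mean_amp_post, 0)
  rp <- .ratioOrExcluded(m$pr_post, m$pr_pre)
  rf <- .ratioOrExcluded(m$spont_freq_post, m$spont_freq_pre)
  ra <- .ratioOrExcluded(ampPost, ampPre)
  data.frame(synapse_id = m$synapse_id,
             relative_pr = rp$ratio, excluded_pr = rp$excluded,
             relative_freq = rf$ratio, excluded_freq = rf$excluded,
             relative_amp = ra$ratio, excluded_amp = ra$excluded)
}

#' Average per-synapse metrics within coverslips
#'
#' Statistics downstream are computed on coverslip averages rather than
#' pooled synapses, so each culture contributes one value per metric.
#'
#' @param summaries per-synapse data.frame (any numeric metric columns).
#' @param grouping coverslip assignment, one value per row.
#' @return data.frame of unweighted per-coverslip means plus
#'   \code{n_synapses}; empty groups are dropped with a warning.
#' @export
coverslipSummarize <- function(summaries, grouping) {
  if (nrow(summaries) != length(grouping))
    stop("grouping must assign each synapse to a coverslip")
  g <- if (is.factor(grouping)) grouping else factor(grouping)
  empty <- setdiff(levels(g), unique(as.character(g[!is.na(g)])))
  if (length(empty))
    warning("empty coverslip group(s) excluded: ", paste(empty, collapse = ", "))
  num <- vapply(summaries, is.numeric, logical(1))
  num[names(num) == "synapse_id"] <- FALSE
  agg <- stats::aggregate(summaries[num], by = list(coverslip = g),
                          FUN = function(v) mean(v, na.rm = TRUE), drop = TRUE)
  counts <- as.integer(table(g)[as.character(agg$coverslip)])
  agg$n_synapses <- counts
  agg
}
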
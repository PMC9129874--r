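#' Double-normalize a FRAP curve
#'
#' Background-subtracts the ROI and reference channels, then normalizes the
#' ROI by its pre-bleach mean while correcting for acquisition
#' photobleaching with the reference:
#' \deqn{F(t) = \frac{\overline{ref'}_{pre}}{ref'(t)} \cdot
#'       \frac{roi'(t)}{\overline{roi'}_{pre}}.}
#' The pre-bleach mean of F is 1 by construction, and any common
#' multiplicative decay of ROI and reference cancels.
#'
#' @param curve a [FRAPCurve].
#' @return data.frame with columns \code{time_s} and \code{F}; attribute
#'   \code{bleach_end} carries the first post-bleach index.
#' @export
doubleNormalize <- function(curve) {
  validObject(curve)
  roi <- curve@roiRaw - curve@bgRaw
  ref <- curve@refRaw - curve@bgRaw
  if (any(ref <= 0))
    stop("background-subtracted reference is <= 0 somewhere; cannot normalize")
  pre <- seq_len(curve@bleachEnd - 1L)
  Fn <- (mean(ref[pre]) / ref) * (roi / mean(roi[pre]))
  out <- data.frame(time_s = curve@times, F = Fn)
  attr(out, "bleach_end") <- curve@bleachEnd
  out
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Least-squares fit of
#' \code{F(t) = Finf - (Finf - F0) * exp(-(t - t_bleach)/tau)} to the
#' post-bleach samples. Initialization: F0 = first post-bleach sample,
#' Finf = mean of the last 10\% of samples, tau = time to half recovery /
#' ln 2; bounds tau in (0, 10 x span], Finf in [F0, 1.5]. The mobile
#' fraction is (Finf - F0)/(1 - F0) on the double-normalized scale and the
#' immobile fraction is its complement (the gap between the pre-bleach
#' level and the recovery asymptote).
#'
#' @param x a [FRAPCurve] (normalized internally via [doubleNormalize()]),
#'   or the data.frame / numeric vector of normalized fluorescence.
#' @param times sample times (s); required when \code{x} is numeric.
#' @param bleachEnd 1-based index of the first post-bleach sample; required
#'   when \code{x} is numeric.
#' @param ... unused.
#' @return a [FRAPFit]. Non-convergence yields a flagged fit
#'   (\code{converged = FALSE}) with a diagnostic message, not an error.
#' @examples
#' crv <- generateFrapCurve(tau = 10, immobileFraction = 0.25)
#' fit <- fitFrap(crv)
#' fit@tau
#' @export
setGeneric("fitFrap", function(x, ...) standardGeneric("fitFrap"))

#' @rdname fitFrap
#' @export
setMethod("fitFrap", "FRAPCurve", function(x, ...) {
  nf <- doubleNormalize(x)
  fitFrap(nf$F, times = nf$time_s, bleachEnd = x@bleachEnd)
})

#' @rdname fitFrap
#' @export
setMethod("fitFrap", "data.frame", function(x, bleachEnd = attr(x, "bleach_end"), ...) {
  fitFrap(x$F, times = x$time_s, bleachEnd = bleachEnd)
})

#' @rdname fitFrap
#' @export
setMethod("fitFrap", "numeric", function(x, times, bleachEnd, ...) {
  if (length(times) != length(x)) stop("times and F must have equal length")
  if (is.null(bleachEnd) || bleachEnd < 2 || bleachEnd > length(x))
    stop("bleachEnd must index the first post-bleach sample")
  post <- bleachEnd:length(x)
  if (length(post) < 5) stop("need at least 5 post-bleach samples")
  Fp <- x[post]
  tp <- times[post] - times[bleachEnd]
  F0init <- Fp[1]
  if (F0init >= 1) stop("first post-bleach value >= 1: no bleach to fit")
  if (diff(range(Fp)) < 1e-10) {
    # fully immobile pool: no recovery to fit, tau is unidentified
    return(FRAPFit(tau = NA_real_, F0 = F0init, Finf = F0init,
                   mobileFraction = 0, immobileFraction = 1, rSquared = 1,
                   converged = TRUE, message = "flat recovery (no mobile pool)"))
  }
  FinfInit <- mean(Fp[tp >= stats::quantile(tp, 0.9)])
  half <- F0init + (FinfInit - F0init) / 2
  iHalf <- which(Fp >= half)[1]
  tauInit <- if (!is.na(iHalf) && tp[iHalf] > 0) tp[iHalf] / log(2) else
    max(tp) / 4
  tauInit <- min(max(tauInit, max(tp) * 1e-3), 10 * max(tp))
  span <- max(tp)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      Fp ~ Finf - (Finf - F0) * exp(-tp / tau),
      start = list(Finf = max(FinfInit, F0init + 1e-6), F0 = F0init,
                   tau = tauInit),
      lower = c(Finf = F0init, F0 = -Inf, tau = span * 1e-8),
      upper = c(Finf = 1.5, F0 = 1, tau = 10 * span),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(FRAPFit(tau = NA_real_, F0 = F0init, Finf = NA_real_,
                   mobileFraction = NA_real_, immobileFraction = NA_real_,
                   rSquared = NA_real_, converged = FALSE,
                   message = conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  resid <- Fp - stats::predict(fit)
  ssTot <- sum((Fp - mean(Fp))^2)
  r2 <- if (ssTot > 0) 1 - sum(resid^2) / ssTot else 1
  mobile <- (cf[["Finf"]] - cf[["F0"]]) / (1 - cf[["F0"]])
  FRAPFit(tau = cf[["tau"]], F0 = cf[["F0"]], Finf = cf[["Finf"]],
          mobileFraction = mobile, immobileFraction = 1 - mobile,
          rSquared = r2, converged = TRUE, message = "")
})

#' FRAP quality metrics
#'
#' \code{bleach_depth} is the normalized fluorescence drop at the first
#' post-bleach frame (1 - F at that frame). \code{gap_ratio} compares the
#' background-subtracted reference-region intensity after versus before the
#' bleach, quantifying how much of the total probe pool the bleach
#' consumed (1 when the unbleached pool is untouched).
#'
#' @param curve a [FRAPCurve].
#' @return list with \code{bleach_depth} and \code{gap_ratio}.
#' @export
frapQualityMetrics <- function(curve) {
  nf <- doubleNormalize(curve)
  ref <- curve@refRaw - curve@bgRaw
  pre <- seq_len(curve@bleachEnd - 1L)
  post <- curve@bleachEnd:length(curve@times)
  list(bleach_depth = 1 - nf$F[curve@bleachEnd],
       gap_ratio = mean(ref[post]) / mean(ref[pre]))
}

#' Rescale a normalized recovery curve to full scale
#'
#' Maps the first post-bleach value to 0 while keeping the pre-bleach level
#' at 1 (reported alongside the double-normalized curve; mobility fractions
#' are defined on the double-normalized scale).
#'
#' @param Fn normalized fluorescence (from [doubleNormalize()]).
#' @param bleachEnd index of the first post-bleach sample.
#' @return numeric vector of full-scale normalized fluorescence.
#' @export
fullScaleNormalize <- function(Fn, bleachEnd) {
  if (is.data.frame(Fn)) {
    if (is.null(bleachEnd)) bleachEnd <- attr(Fn, "bleach_end")
    Fn <- Fn$F
  }
  F0 <- Fn[bleachEnd]
  if (F0 >= 1) stop("first post-bleach value >= 1: no bleach")
  (Fn - F0) / (1 - F0)
}
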
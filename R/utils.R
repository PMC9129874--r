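# Internal numerical helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so simulation calls do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive n independent substream seeds from one master seed. Draws are
# sequential, so the first k substreams are unchanged when n grows: adding
# synapses to a scene does not perturb earlier ones.
substreamSeeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Trailing moving mean: out[i] = mean(x[(i-w+1):i]); NA while the window is
# incomplete.
trailingMean <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  cs <- cumsum(x)
  idx <- w:n
  out[idx] <- (cs[idx] - c(0, cs)[idx - w + 1L]) / w
  out
}

# Trailing moving median via the centered running median (C implementation):
# out[i] = median(x[(i-w+1):i]) for i >= w (w odd), NA before.
trailingMedian <- function(x, w) {
  stopifnot(w %% 2 == 1, w >= 1)
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  if (w == 1) return(x)
  k2 <- (w - 1L) / 2L
  r <- stats::runmed(x, w, endrule = "keep")
  idx <- w:n
  out[idx] <- r[idx - k2]
  out
}

# Centered moving mean with shrunken edge windows (no invented padding).
centeredMean <- function(x, points) {
  if (points == 1) return(x)
  n <- length(x)
  h <- (points - 1L) / 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Force an odd number of frames for a window given in seconds.
oddWindowFrames <- function(windowS, dt) {
  w <- max(1L, round(windowS / dt))
  if (w %% 2 == 0) w <- w + 1L
  as.integer(w)
}
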
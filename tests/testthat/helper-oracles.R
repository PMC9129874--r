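# Independent reference implementations used to cross-check the package.
# These are written as plain, literal loops over the rule definitions and
# deliberately share no code with the package internals.

# Spontaneous-event detection: literal restatement of the threshold rule
# (smoothed trace vs trailing baseline + k x robust SD of raw residuals).
oracleDetectSpontaneous <- function(x, dt, k = 3, baselineWindow = 4,
                                    smoothPoints = 3, refractory = 0.1) {
  n <- length(x)
  w <- round(baselineWindow / dt)
  if (w %% 2 == 0) w <- w + 1
  h <- (smoothPoints - 1) / 2
  y <- vapply(seq_len(n),
              function(i) mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
  m <- rep(NA_real_, n)
  for (i in w:n) m[i] <- median(x[(i - w + 1):i])
  d <- abs(x - m)
  s <- rep(NA_real_, n)
  for (i in (2 * w - 1):n) s[i] <- 1.4826 * median(d[(i - w + 1):i])
  b <- rep(NA_real_, n)
  for (i in w:n) b[i] <- mean(y[(i - w + 1):i])
  cand <- integer(0)
  for (i in (2 * w):n) {
    if (y[i] > b[i - 1] + k * s[i - 1]) cand <- c(cand, i)
  }
  if (!length(cand)) {
    return(data.frame(time_s = numeric(0), amplitude = numeric(0)))
  }
  peaks <- integer(0)
  runStart <- 1
  for (j in seq_along(cand)) {
    endOfRun <- j == length(cand) || cand[j + 1] != cand[j] + 1
    if (endOfRun) {
      run <- cand[runStart:j]
      peaks <- c(peaks, run[which.max(y[run])])
      runStart <- j + 1
    }
  }
  times <- (peaks - 1) * dt
  amps <- y[peaks] - b[peaks - 1]
  while (length(times) > 1 && any(diff(times) < refractory)) {
    j <- which(diff(times) < refractory)[1]
    drop <- if (amps[j] >= amps[j + 1]) j + 1 else j
    times <- times[-drop]; amps <- amps[-drop]
  }
  keep <- amps > 0
  data.frame(time_s = times[keep], amplitude = amps[keep])
}

# DBSCAN by brute force: boolean transitive closure over core-core
# reachability; border points claimed by the lowest-numbered cluster with a
# core point in range (matching deterministic input-order claiming).
oracleDbscan <- function(pts, eps, minPts) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= minPts,
                 logical(1))
  A <- (d <= eps) & outer(core, core, "&")
  diag(A) <- core
  repeat {
    A2 <- A | ((A %*% A) > 0)
    if (identical(A2, A)) break
    A <- A2
  }
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (core[i] && labels[i] == -1L) {
      cl <- cl + 1L
      labels[A[i, ]] <- cl
    }
  }
  for (i in seq_len(n)) {
    if (!core[i]) {
      claimers <- labels[core & d[i, ] <= eps]
      if (length(claimers)) labels[i] <- min(claimers)
    }
  }
  labels
}

# Fine-step forward-Euler reference for the pool ODE over one constant
# segment (activation vector a, relative intensity I).
oracleEvolveSegment <- function(u0, params, a, intensity, duration,
                                dt = 5e-4) {
  kB <- params@kBleach
  tauE <- params@tauExchange[["evoked_site"]]
  tauS <- params@tauExchange[["synaptic_general"]]
  uE <- u0[["evoked_site"]]; uS <- u0[["synaptic_general"]]
  uR <- u0[["reservoir"]]
  nStep <- round(duration / dt)
  for (i in seq_len(nStep)) {
    duE <- -kB * intensity * a[["evoked_site"]] * uE + (uR - uE) / tauE
    duS <- -kB * intensity * a[["synaptic_general"]] * uS + (uR - uS) / tauS
    duR <- -kB * intensity * a[["reservoir"]] * uR
    uE <- uE + dt * duE; uS <- uS + dt * duS; uR <- uR + dt * duR
  }
  c(evoked_site = uE, synaptic_general = uS, reservoir = uR)
}

# Event-kernel superposition reconstructed literally from a ground-truth
# event table.
oracleReconstruct <- function(ev, n, dt, riseTau, decayTau) {
  v <- numeric(n)
  tt <- (seq_len(n) - 1) * dt
  for (j in seq_len(nrow(ev))) {
    s <- tt - ev$time_s[j]
    kern <- ifelse(s >= 0, exp(-s / decayTau), 0)
    if (riseTau > 0) kern <- kern * ifelse(s >= 0, 1 - exp(-s / riseTau), 0)
    v <- v + ev$amplitude[j] * kern
  }
  v
}
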
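defaultParams <- PoolParams()

test_that("activation saturates under glutamate perfusion and clamps at 1", {
  seg <- bleachSegment(60, intensity = 1, glutamatePerfusion = TRUE)
  expect_equal(activationFractions(defaultParams, seg),
               c(evoked_site = 1, synaptic_general = 1, reservoir = 1))
  dark <- bleachSegment(60, intensity = 0)
  a <- activationFractions(defaultParams, dark)
  expect_equal(unname(a[c("evoked_site", "synaptic_general")]), c(0.05, 0.05))
  expect_equal(unname(a[["reservoir"]]), 0)
  # heavy event-driven activation clamps to 1
  busy <- bleachSegment(60, intensity = 1, stimRate = 100)
  a2 <- activationFractions(defaultParams, busy, pr = 1)
  expect_equal(unname(a2[["evoked_site"]]), 1)
})

test_that("fully activated bleaching follows the exponential closed form", {
  p <- PoolParams(tauExchange = c(evoked_site = Inf, synaptic_general = Inf,
                                  reservoir = Inf))
  prot <- BleachProtocol(segments = bleachSegment(30, intensity = 1,
                                                  glutamatePerfusion = TRUE))
  traj <- evolvePools(PoolState(), p, prot, dt = 0.1)
  expected <- exp(-p@kBleach * traj$time_s)
  expect_lt(max(abs(traj$u_evoked - expected) / expected), 1e-6)
  expect_lt(max(abs(traj$u_spont - expected) / expected), 1e-6)
})

test_that("darkness relaxes bleached pools toward the reservoir with tau_exchange", {
  st <- PoolState(u = c(evoked_site = 0.2, synaptic_general = 0.2,
                        reservoir = 1))
  prot <- BleachProtocol(segments = bleachSegment(60, intensity = 0))
  traj <- evolvePools(st, defaultParams, prot, dt = 0.05)
  tauS <- defaultParams@tauExchange[["synaptic_general"]]
  expected <- 1 + (0.2 - 1) * exp(-traj$time_s / tauS)
  expect_lt(max(abs(traj$u_spont - expected)), 1e-6)
  expect_true(all(diff(traj$u_spont) >= 0))
  expect_true(all(diff(traj$u_evoked) >= 0))
})

test_that("the integrator matches a fine-step reference on a bleach segment", {
  a <- activationFractions(defaultParams, bleachSegment(60, intensity = 1))
  ref <- oracleEvolveSegment(PoolState()@u, defaultParams, a, 1, 60)
  prot <- BleachProtocol(segments = bleachSegment(60, intensity = 1))
  got <- finalPoolState(evolvePools(PoolState(), defaultParams, prot,
                                    dt = 0.05))
  expect_lt(abs(got@u[["evoked_site"]] - ref[["evoked_site"]]), 1e-3)
  expect_lt(abs(got@u[["synaptic_general"]] - ref[["synaptic_general"]]), 1e-3)
})

test_that("unbleached fractions stay within [0, 1] and halving dt converges", {
  prot <- BleachProtocol(segments = rbind(
    bleachSegment(600, intensity = 1),
    bleachSegment(300, intensity = 0),
    bleachSegment(120, intensity = 1, glutamatePerfusion = TRUE)))
  t1 <- evolvePools(PoolState(), defaultParams, prot, dt = 0.2)
  t2 <- evolvePools(PoolState(), defaultParams, prot, dt = 0.1)
  u1 <- finalPoolState(t1)@u; u2 <- finalPoolState(t2)@u
  expect_true(all(unlist(t1[c("u_evoked", "u_spont", "u_reservoir")]) >= 0))
  expect_true(all(unlist(t1[c("u_evoked", "u_spont", "u_reservoir")]) <= 1))
  expect_lt(max(abs(u1 - u2)), 1e-4)
})

test_that("longer bleaching depletes pools monotonically", {
  ends <- vapply(c(10, 30, 60, 120), function(dur) {
    prot <- BleachProtocol(segments = bleachSegment(dur, intensity = 1))
    u <- finalPoolState(evolvePools(PoolState(), defaultParams, prot,
                                    dt = 0.1))@u
    c(u[["evoked_site"]], u[["synaptic_general"]])
  }, numeric(2))
  expect_true(all(diff(ends[1, ]) < 0))
  expect_true(all(diff(ends[2, ]) < 0))
})

test_that("bleaching is strictly use-dependent", {
  p <- PoolParams(aTonic = 0, aTonicReservoir = 0)
  prot <- BleachProtocol(segments = bleachSegment(600, intensity = 1))
  traj <- evolvePools(PoolState(), p, prot, dt = 0.1, pr = 0, spontRate = 0)
  expect_true(all(traj$u_evoked == 1))
  expect_true(all(traj$u_spont == 1))
  expect_true(all(traj$u_reservoir == 1))
})

test_that("a 10-min bleach differentially depletes the evoked site, which recovers on an hours scale", {
  bleach <- BleachProtocol(segments = bleachSegment(600, intensity = 1))
  uEnd <- finalPoolState(evolvePools(PoolState(), defaultParams, bleach,
                                     dt = 0.1))@u
  expect_lt(uEnd[["evoked_site"]], uEnd[["synaptic_general"]])
  expect_lt(uEnd[["evoked_site"]], 0.1)
  expect_gt(uEnd[["synaptic_general"]], 0.8)

  dark <- BleachProtocol(segments = bleachSegment(60000, intensity = 0))
  st <- PoolState(u = uEnd, t = 0)
  rec <- evolvePools(st, defaultParams, dark, dt = 0.25)
  tSpont <- rec$time_s[which(rec$u_spont >= 0.9)[1]]
  tEvoked <- rec$time_s[which(rec$u_evoked >= 0.9)[1]]
  expect_lt(tSpont, 600)
  expect_gt(tEvoked, 3600)
  # near-full recovery of the evoked site within 24 h in the dark
  day <- BleachProtocol(segments = bleachSegment(86400, intensity = 0))
  uDay <- finalPoolState(evolvePools(st, defaultParams, day, dt = 0.25))@u
  expect_gt(uDay[["evoked_site"]], 0.95)
})

test_that("glutamate perfusion during bleaching ablates the spontaneous pool persistently", {
  mk <- function(perf) BleachProtocol(segments = rbind(
    bleachSegment(120, intensity = 1, glutamatePerfusion = perf),
    bleachSegment(300, intensity = 0)))
  uNo <- finalPoolState(evolvePools(PoolState(), defaultParams, mk(FALSE),
                                    dt = 0.1))@u
  uPerf <- finalPoolState(evolvePools(PoolState(), defaultParams, mk(TRUE),
                                      dt = 0.1))@u
  expect_lt(uPerf[["synaptic_general"]], uNo[["synaptic_general"]])
  expect_lt(uPerf[["synaptic_general"]], 0.01)  # no pool left to recover from
  expect_gt(uNo[["synaptic_general"]], 0.9)
})

test_that("detectability couples pool state to the threshold rule", {
  cfg <- SynapseConfig(quantalAmp = 10)
  noise <- NoiseModel(sigma = 1)
  full <- detectability(PoolState(), cfg, noise, k = 3)
  expect_true(all(full$detectable))
  expect_equal(full$rel_amplitude, c(1, 1))
  dead <- detectability(PoolState(u = c(evoked_site = 0, synaptic_general = 0,
                                        reservoir = 0)), cfg, noise, k = 3)
  expect_false(any(dead$detectable))
  mixed <- detectability(PoolState(u = c(evoked_site = 0.1,
                                         synaptic_general = 0.8,
                                         reservoir = 1)), cfg, noise, k = 3)
  expect_equal(mixed$detectable,
               c(FALSE, TRUE))  # 1 < 3 sigma <= 8
})

test_that("runProtocol reports unit metrics with no bleach and coarse dt is rejected", {
  cfg <- SynapseConfig(quantalAmp = 8)
  noise <- NoiseModel(sigma = 1)
  rep0 <- runProtocol(defaultParams, cfg, noise,
                      BleachProtocol(), recoveryHorizon = 0)
  expect_equal(rep0$rel_pr, 1)
  expect_equal(rep0$rel_freq, 1)
  expect_error(evolvePools(PoolState(), defaultParams,
                           BleachProtocol(segments = bleachSegment(10, 1)),
                           dt = 5),
               "too coarse")
})

test_that("runProtocol predicts evoked loss exceeding spontaneous loss after a long bleach", {
  cfg <- SynapseConfig(quantalAmp = 8)
  noise <- NoiseModel(sigma = 1)
  prot <- BleachProtocol(segments = bleachSegment(600, intensity = 1))
  rep1 <- runProtocol(defaultParams, cfg, noise, prot, recoveryHorizon = 60,
                      dt = 0.1)
  final <- rep1[nrow(rep1), ]
  endOfBleach <- rep1[max(which(rep1$time_s <= 600)), ]
  expect_lt(endOfBleach$rel_pr, endOfBleach$rel_freq)
  expect_lt(endOfBleach$rel_amp_evoked, endOfBleach$rel_amp_spont)
  expect_gt(final$rel_freq, 0.99)  # spontaneous recovers within a minute
  expect_lt(final$rel_pr, 0.01)    # evoked still dark
})
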
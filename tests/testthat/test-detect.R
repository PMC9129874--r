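test_that("a flat trace yields no spontaneous events and short traces are rejected", {
  expect_equal(length(detectSpontaneous(FluorTrace(values = rep(0, 1000),
                                                   dt = 0.02))), 0L)
  expect_error(detectSpontaneous(FluorTrace(values = rep(0, 100), dt = 0.02)),
               "shorter")
})

test_that("a noiseless kernel event is found at the right frame with the right amplitude", {
  cfg <- SynapseConfig(pr = 0, spontRate = 0, quantalAmp = 10, ampCv = 0)
  proto <- RecordingProtocol(duration = 30)
  sim <- generateTrace(cfg, proto, NoiseModel(sigma = 0), seed = 1)
  tr <- sim$trace
  tr@values <- tr@values + 10 * exp(-pmax(0, traceTimes(tr) - 15) / 0.1) *
    (traceTimes(tr) >= 15)
  ev <- events(detectSpontaneous(tr, DetectionParams(smoothPoints = 1)))
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$time_s - 15), 0.02 + 1e-9)
  expect_lt(abs(ev$amplitude - 10) / 10, 0.02)
})

test_that("the spontaneous detector agrees event-for-event with a literal oracle", {
  params <- DetectionParams()
  for (s in 1:8) {
    # pure noise: false events must agree exactly with the oracle rule
    x <- withr::with_seed(s, rnorm(6000))
    got <- events(detectSpontaneous(FluorTrace(values = x, dt = 0.02), params))
    want <- oracleDetectSpontaneous(x, 0.02)
    expect_equal(got$time_s, want$time_s)
    expect_equal(got$amplitude, want$amplitude, tolerance = 1e-12)
  }
  # noise plus real events: still rule-identical
  cfg <- SynapseConfig(pr = 0, spontRate = 0.05, quantalAmp = 8, ampCv = 0.25)
  for (s in 1:4) {
    sim <- generateTrace(cfg, RecordingProtocol(duration = 120),
                         NoiseModel(sigma = 1), seed = s)
    got <- events(detectSpontaneous(sim$trace, params))
    want <- oracleDetectSpontaneous(sim$trace@values, 0.02)
    expect_equal(got$time_s, want$time_s)
  }
})

test_that("false-positive rate is negligible and sensitivity at SNR 8 exceeds 0.95", {
  nFalse <- 0
  for (s in 1:10) {
    x <- withr::with_seed(100 + s, rnorm(15000))  # 300 s of pure noise
    nFalse <- nFalse + length(detectSpontaneous(FluorTrace(values = x,
                                                           dt = 0.02)))
  }
  expect_lt(nFalse / (10 * 300), 0.002)  # well under the true 0.01-0.02 Hz

  cfg <- SynapseConfig(pr = 0, spontRate = 0.05, quantalAmp = 8, ampCv = 0)
  nTrue <- 0; nHit <- 0
  for (s in 1:10) {
    sim <- generateTrace(cfg, RecordingProtocol(duration = 300),
                         NoiseModel(sigma = 1), seed = s)
    truth <- events(sim$events)$time_s
    truth <- truth[truth > 10]  # detector needs two baseline windows
    det <- events(detectSpontaneous(sim$trace))$time_s
    nTrue <- nTrue + length(truth)
    nHit <- nHit + sum(vapply(truth, function(t0)
      any(abs(det - t0) <= 0.06), logical(1)))
  }
  expect_gt(nTrue, 100)
  expect_gte(nHit / nTrue, 0.95)
})

test_that("noiseless evoked detection recovers exactly the fused stimuli", {
  stims <- 10 + (0:4) * 5
  cfg <- SynapseConfig(pr = 0, spontRate = 0, quantalAmp = 6, ampCv = 0)
  proto <- RecordingProtocol(duration = 40, stimTimes = stims)
  sim <- generateTrace(cfg, proto, NoiseModel(sigma = 0), seed = 1)
  tr <- sim$trace
  tt <- traceTimes(tr)
  for (t0 in stims[c(1, 3, 5)] + 0.02)  # events at stims 1, 3, 5
    tr@values <- tr@values + 6 * exp(-pmax(0, tt - t0) / 0.1) * (tt >= t0)
  ev <- events(detectEvoked(tr, stims, DetectionParams(smoothPoints = 1)))
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$stim_s, stims[c(1, 3, 5)])
  expect_equal(ev$time_s, stims[c(1, 3, 5)] + 0.02, tolerance = 1e-9)
  expect_lt(max(abs(ev$amplitude - 6) / 6), 0.02)

  none <- detectEvoked(sim$trace, stims)
  expect_equal(length(none), 0L)
})

test_that("evoked success calls match ground-truth fusion outcomes at SNR 8", {
  stims <- 10 + (0:39) * 5
  proto <- RecordingProtocol(duration = 212, stimTimes = stims)
  cfg <- SynapseConfig(pr = 0.5, spontRate = 0, quantalAmp = 8, ampCv = 0)
  nCalls <- 0; nWrong <- 0
  for (s in 1:50) {
    sim <- generateTrace(cfg, proto, NoiseModel(sigma = 1), seed = s)
    truthStims <- events(sim$events)$stim_s
    det <- detectEvoked(subtractBackground(sim$trace), stims)
    called <- stims %in% events(det)$stim_s
    truth <- stims %in% truthStims
    nCalls <- nCalls + length(stims)
    nWrong <- nWrong + sum(called != truth)
  }
  expect_lt(nWrong / nCalls, 0.01)
})

test_that("overlapping response windows and out-of-span stimuli are rejected", {
  tr <- FluorTrace(values = rep(0, 1000), dt = 0.02)
  expect_error(detectEvoked(tr, c(10, 10.2)), "overlapping")
  expect_error(detectEvoked(tr, c(10, 30)), "span")
})
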
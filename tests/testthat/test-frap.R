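test_that("frozen mobile pool keeps the post-bleach curve at F0", {
  crv <- generateFrapCurve(tau = 10, immobileFraction = 1, bleachDepth = 0.8)
  nf <- doubleNormalize(crv)
  post <- crv@bleachEnd:length(crv@times)
  expect_equal(nf$F[post], rep(0.2, length(post)), tolerance = 1e-12)
})

test_that("noiseless recovery has the closed-form value at t = tau", {
  tau <- 8; f0 <- 0.3
  crv <- generateFrapCurve(tau = tau, immobileFraction = 0.4,
                           bleachDepth = 1 - f0, sampleRate = 2,
                           postDuration = 40)
  nf <- doubleNormalize(crv)
  tb <- crv@times[crv@bleachEnd]
  finf <- f0 + 0.6 * (1 - f0)
  idx <- which(abs(crv@times - (tb + tau)) < 1e-9)
  expect_equal(nf$F[idx], finf - (finf - f0) * exp(-1), tolerance = 1e-12)
})

test_that("double normalization is exactly 1 for constant channels and cancels shared decay", {
  n <- 30
  crv <- FRAPCurve(times = 0:(n - 1), roiRaw = rep(60, n), refRaw = rep(110, n),
                   bgRaw = rep(10, n), bleachEnd = 11L)
  expect_equal(doubleNormalize(crv)$F, rep(1, n), tolerance = 1e-12)
  # 10% linear acquisition decay shared by ROI and reference cancels
  g <- seq(1, 0.9, length.out = n)
  crv2 <- FRAPCurve(times = 0:(n - 1), roiRaw = 50 * g, refRaw = 100 * g,
                    bgRaw = rep(0, n), bleachEnd = 11L)
  expect_equal(doubleNormalize(crv2)$F, rep(1, n), tolerance = 1e-12)
})

test_that("double normalization matches a hand-computed fixture", {
  # 2 pre-bleach frames; worked by hand:
  #   roi' = (90, 110, 30, 50), ref' = (200, 180, 190, 200), bg = 10
  #   mean_pre(roi') = 100, mean_pre(ref') = 190
  #   F(t) = (190/ref'(t)) * (roi'(t)/100)
  crv <- FRAPCurve(times = c(0, 1, 2, 3),
                   roiRaw = c(100, 120, 40, 60),
                   refRaw = c(210, 190, 200, 210),
                   bgRaw = rep(10, 4), bleachEnd = 3L)
  f <- doubleNormalize(crv)$F
  expect_equal(f[1], (190 / 200) * (90 / 100), tolerance = 1e-12)
  expect_equal(f[3], (190 / 190) * (30 / 100), tolerance = 1e-12)
  expect_equal(f[4], (190 / 200) * (50 / 100), tolerance = 1e-12)
})

test_that("nonpositive corrected reference is rejected", {
  crv <- FRAPCurve(times = 0:9, roiRaw = rep(50, 10), refRaw = rep(20, 10),
                   bgRaw = rep(10, 10), bleachEnd = 3L)
  crv@refRaw[5] <- 9.5
  expect_error(doubleNormalize(crv), "reference")
})

test_that("single-exponential fit recovers exact model parameters", {
  tt <- 0:80
  f0 <- 0.2; finf <- 0.8; tau <- 10
  Fn <- c(rep(1, 10), finf - (finf - f0) * exp(-(0:70) / tau))
  fit <- fitFrap(Fn, times = tt, bleachEnd = 11L)
  expect_true(fit@converged)
  expect_lt(abs(fit@tau - tau) / tau, 1e-6)
  expect_lt(abs(fit@mobileFraction - 0.75), 1e-6)
  expect_lt(abs(fit@immobileFraction - 0.25), 1e-6)
  expect_equal(fit@mobileFraction + fit@immobileFraction, 1)
  # residuals on exact model input are numerically zero
  pred <- fit@Finf - (fit@Finf - fit@F0) * exp(-(0:70) / fit@tau)
  expect_lt(max(abs(Fn[11:81] - pred)), 1e-9)
})

test_that("an immobile curve fits with zero mobile fraction", {
  Fn <- c(rep(1, 8), rep(0.25, 40))
  fit <- fitFrap(Fn, times = seq_along(Fn) - 1, bleachEnd = 9L)
  expect_true(fit@converged)
  expect_lt(abs(fit@mobileFraction), 1e-3)
})

test_that("round trip generate -> normalize -> fit recovers tau and immobile fraction", {
  for (p in list(c(8.9, 0.19), c(5.7, 0.13), c(15, 0.4))) {
    crv <- generateFrapCurve(tau = p[1], immobileFraction = p[2],
                             bleachDepth = 0.8, postDuration = 90)
    fit <- fitFrap(crv)
    expect_lt(abs(fit@tau - p[1]) / p[1], 1e-6)
    expect_lt(abs(fit@immobileFraction - p[2]) / max(p[2], 1e-6), 1e-6)
  }
})

test_that("noisy fits recover tau without bias", {
  taus <- vapply(1:100, function(s) {
    crv <- generateFrapCurve(tau = 10, immobileFraction = 0.25,
                             noiseSigma = 0.02 * 100, postDuration = 90,
                             seed = s)
    fitFrap(crv)@tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 10), 3 * sd(taus) / sqrt(length(taus)))
})

test_that("mobility fractions are invariant to a common channel gain", {
  crv <- generateFrapCurve(tau = 12, immobileFraction = 0.3, bgLevel = 0)
  crv2 <- FRAPCurve(times = crv@times, roiRaw = 3.7 * crv@roiRaw,
                    refRaw = 3.7 * crv@refRaw, bgRaw = crv@bgRaw,
                    bleachEnd = crv@bleachEnd)
  f1 <- fitFrap(crv); f2 <- fitFrap(crv2)
  expect_equal(f1@immobileFraction, f2@immobileFraction, tolerance = 1e-9)
})

test_that("no-bleach and short curves are rejected", {
  Fn <- rep(1, 30)
  expect_error(fitFrap(Fn, times = 0:29, bleachEnd = 11L), "no bleach")
  expect_error(fitFrap(c(1, 1, 0.5, 0.6), times = 0:3, bleachEnd = 3L),
               "post-bleach")
})

test_that("quality metrics report bleach depth and pool loss", {
  crv <- generateFrapCurve(tau = 10, immobileFraction = 0.2, bleachDepth = 0.8)
  qm <- frapQualityMetrics(crv)
  expect_equal(qm$bleach_depth, 0.8, tolerance = 1e-9)
  expect_equal(qm$gap_ratio, 1, tolerance = 1e-9)
  # reference loses 10% of the pool after the bleach
  n <- length(crv@times)
  ref <- crv@refRaw
  ref[crv@bleachEnd:n] <- crv@bgRaw[1] +
    0.9 * (ref[crv@bleachEnd:n] - crv@bgRaw[1])
  crv2 <- FRAPCurve(times = crv@times, roiRaw = crv@roiRaw, refRaw = ref,
                    bgRaw = crv@bgRaw, bleachEnd = crv@bleachEnd)
  expect_equal(frapQualityMetrics(crv2)$gap_ratio, 0.9, tolerance = 1e-9)
})

test_that("full-scale rescaling pins the first post-bleach sample to zero", {
  crv <- generateFrapCurve(tau = 10, immobileFraction = 0.25)
  nf <- doubleNormalize(crv)
  fs <- fullScaleNormalize(nf$F, crv@bleachEnd)
  expect_equal(fs[crv@bleachEnd], 0)
  expect_equal(mean(fs[seq_len(crv@bleachEnd - 1)]), 1, tolerance = 1e-9)
})
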
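test_that("flat and empty trains are classified nonresponsive", {
  prot <- quickProtocol(modality = "thermal")
  dur <- protocolDuration(prot)
  cfg <- quickConfig()
  pr <- NeuronProfile(baselineRate = 5, responseClass = "nonresponsive")
  tr <- simulateSpikeTrain(pr, prot, dur, seed = 21)
  r <- detectResponse(buildPsth(tr, prot, config = cfg), cfg)
  expect_false(r$responsive)
  expect_identical(r$responseSign, "none")
  r0 <- detectResponse(buildPsth(SpikeTrain("z", numeric(), dur), prot,
                                 config = cfg), cfg)
  expect_false(r0$responsive)
})

test_that("overwhelming evoked responses are detected as excited", {
  prot <- quickProtocol()
  dur <- protocolDuration(prot)
  cfg <- quickConfig()
  # gain 10x the baseline-band sd in Hz: sd(count) ~ sqrt(0.5)/0.1 ~ 7 Hz
  pr <- NeuronProfile(baselineRate = 5, evokedGain = 75,
                      responseClass = "excited")
  hits <- vapply(1:100, function(s) {
    tr <- simulateSpikeTrain(pr, prot, dur, seed = 300 + s)
    detectResponse(buildPsth(tr, prot, config = cfg), cfg)$responsive
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("after-discharge is absent without post-offset elevation", {
  prot <- quickProtocol()
  dur <- protocolDuration(prot)
  cfg <- quickConfig()
  pr <- NeuronProfile(baselineRate = 5, evokedGain = 75, adDuration = 0,
                      responseClass = "excited")
  tr <- simulateSpikeTrain(pr, prot, dur, seed = 8)
  ad <- detectAfterDischarge(buildPsth(tr, prot, config = cfg), cfg)
  expect_false(ad$adPresent)
  expect_equal(ad$adDuration, 0)
})

test_that("rectangular after-discharge durations are recovered to one bin", {
  prot <- quickProtocol()
  dur <- protocolDuration(prot)
  cfg <- quickConfig()
  pr <- NeuronProfile(baselineRate = 5, evokedGain = 75, adDuration = 1.2,
                      adRate = 80, responseClass = "excited")
  err <- vapply(1:100, function(s) {
    tr <- simulateSpikeTrain(pr, prot, dur, seed = 700 + s)
    detectAfterDischarge(buildPsth(tr, prot, config = cfg),
                         cfg)$adDuration - 1.2
  }, numeric(1))
  expect_gte(mean(abs(err) <= 0.1 + 1e-9), 0.95)
})

test_that("a PSTH too short for the scan window is rejected", {
  ev <- StimulusEvent(10, 13, modality = "thermal")
  tr <- SpikeTrain("u", c(1, 2), 40)
  cfg <- quickConfig()
  p <- buildPsth(tr, list(ev), window = c(5, 8), config = cfg)
  expect_error(detectAfterDischarge(p, cfg), "window ends")
})

test_that("paired suppression test matches the closed-form t oracle", {
  cfg <- quickConfig()
  # 5 trials; pre rates {10,11,9,10,10} Hz over the 5 s baseline and stim
  # rates {2,3,2,2,1} Hz over 3 s, realized as exact counts
  preRates <- c(10, 11, 9, 10, 10)
  stimRates <- c(2, 3, 2, 2, 1)
  onsets <- 10 + (0:4) * 25
  windows <- list(); counts <- numeric()
  for (i in 1:5) {
    windows <- c(windows, list(c(onsets[i] - 5, onsets[i]),
                               c(onsets[i], onsets[i] + 3)))
    counts <- c(counts, preRates[i] * 5, stimRates[i] * 3)
  }
  tr <- trainFromCounts(windows, counts, 150)
  evs <- lapply(onsets, function(o) StimulusEvent(o, o + 3,
                                                  modality = "thermal"))
  res <- detectSuppression(tr, evs, cfg)
  d <- preRates - stimRates
  tStat <- mean(d) / (sd(d) / sqrt(5))
  pOracle <- 2 * pt(-abs(tStat), df = 4)
  expect_equal(res$suppressionP, pOracle, tolerance = 1e-12)
  expect_true(res$suppressed)
})

test_that("suppression respects direction and degenerate variance", {
  cfg <- quickConfig()
  onsets <- 10 + (0:4) * 25
  evs <- lapply(onsets, function(o) StimulusEvent(o, o + 3,
                                                  modality = "thermal"))
  # identical pre and stim rates: zero mean difference, not suppressed
  windows <- list(); counts <- numeric()
  for (o in onsets) {
    windows <- c(windows, list(c(o - 5, o), c(o, o + 3)))
    counts <- c(counts, 5 * 5, 5 * 3)
  }
  same <- detectSuppression(trainFromCounts(windows, counts, 150), evs, cfg)
  expect_false(same$suppressed)
  # stim uniformly above pre: significant but wrong direction
  counts2 <- numeric()
  for (i in 1:5) counts2 <- c(counts2, 2 * 5, 20 * 3)
  up <- detectSuppression(trainFromCounts(windows, counts2, 150), evs, cfg)
  expect_false(up$suppressed)
  # exactly constant nonzero difference: p reported 0 with degeneracy flag
  counts3 <- numeric()
  for (i in 1:5) counts3 <- c(counts3, 10 * 5, 2 * 3)
  dg <- detectSuppression(trainFromCounts(windows, counts3, 150), evs, cfg)
  expect_true(dg$degenerateVariance)
  expect_equal(dg$suppressionP, 0)
  expect_true(dg$suppressed)
  expect_error(detectSuppression(trainFromCounts(windows[1:2],
                                                 counts3[1:2], 150),
                                 evs[1], cfg),
               "at least 3 trials")
})

test_that("rebound durations of suppressed neurons are recovered", {
  prot <- quickProtocol()
  dur <- protocolDuration(prot)
  cfg <- quickConfig()
  pr <- NeuronProfile(baselineRate = 5, responseClass = "suppressed",
                      suppressionFraction = 0.05, reboundDuration = 3,
                      reboundRate = 80)
  err <- vapply(1:100, function(s) {
    tr <- simulateSpikeTrain(pr, prot, dur, seed = 900 + s)
    detectRebound(buildPsth(tr, prot, config = cfg), cfg)$reboundDuration - 3
  }, numeric(1))
  expect_gte(mean(abs(err) <= 0.1 + 1e-9), 0.95)
  # no rebound segment -> no rebound detected
  pr0 <- NeuronProfile(baselineRate = 5, responseClass = "suppressed",
                       suppressionFraction = 0.05, reboundDuration = 0)
  tr0 <- simulateSpikeTrain(pr0, prot, dur, seed = 31)
  rb0 <- detectRebound(buildPsth(tr0, prot, config = cfg), cfg)
  expect_false(rb0$reboundPresent)
  expect_equal(rb0$reboundDuration, 0)
})

test_that("detectUnit assembles a coherent DetectionResult", {
  prot <- quickProtocol()
  dur <- protocolDuration(prot)
  cfg <- quickConfig()
  pr <- NeuronProfile(baselineRate = 5, evokedGain = 75, adDuration = 1,
                      adRate = 80, responseClass = "excited")
  tr <- simulateSpikeTrain(pr, prot, dur, seed = 45)
  d <- detectUnit(tr, prot, cfg)
  expect_s4_class(d, "DetectionResult")
  expect_true(d@responsive)
  expect_identical(d@responseSign, "excited")
  expect_true(d@adPresent)
  expect_false(d@reboundPresent)
  # identical inputs give identical results (determinism)
  d2 <- detectUnit(tr, prot, cfg)
  expect_equal(d2@adDuration, d@adDuration)
  expect_equal(d2@suppressionP, d@suppressionP)
  # suppressed neurons never contribute after-discharge durations
  prS <- NeuronProfile(baselineRate = 5, responseClass = "suppressed",
                       suppressionFraction = 0.05, reboundDuration = 2,
                       reboundRate = 80)
  for (s in 1:20) {
    trS <- simulateSpikeTrain(prS, prot, dur, seed = 1200 + s)
    dS <- detectUnit(trS, prot, cfg)
    if (identical(dS@responseSign, "suppressed")) {
      expect_equal(dS@adDuration, 0)
      expect_false(dS@adPresent)
    }
  }
})

test_that("sub-criterion runs are reported in diagnostics but scored 0", {
  prot <- quickProtocol()
  dur <- protocolDuration(prot)
  cfg <- quickConfig()
  # a 0.3 s after-discharge is below the 0.5 s criterion
  pr <- NeuronProfile(baselineRate = 5, evokedGain = 75, adDuration = 0.3,
                      adRate = 80, responseClass = "excited")
  hits <- 0L
  for (s in 1:20) {
    tr <- simulateSpikeTrain(pr, prot, dur, seed = 1500 + s)
    ad <- detectAfterDischarge(buildPsth(tr, prot, config = cfg), cfg)
    expect_false(ad$adPresent)
    expect_equal(ad$adDuration, 0)
    if (ad$rawRunDuration > 0) hits <- hits + 1L
  }
  expect_gt(hits, 10)  # the raw run is still visible diagnostically
})
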
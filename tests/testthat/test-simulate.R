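test_that("zero-rate and nonresponsive profiles give empty trains", {
  prot <- quickProtocol()
  dur <- protocolDuration(prot)
  pr <- NeuronProfile(baselineRate = 0, responseClass = "nonresponsive")
  tr <- simulateSpikeTrain(pr, prot, dur, seed = 1)
  expect_length(spikeTimes(tr), 0)
})

test_that("identical seeds and inputs reproduce identical trains", {
  prot <- quickProtocol()
  dur <- protocolDuration(prot)
  pr <- NeuronProfile(baselineRate = 4, evokedGain = 20,
                      responseClass = "excited")
  a <- simulateSpikeTrain(pr, prot, dur, seed = 77)
  b <- simulateSpikeTrain(pr, prot, dur, seed = 77)
  expect_identical(spikeTimes(a), spikeTimes(b))
  c <- simulateSpikeTrain(pr, prot, dur, seed = 78)
  expect_false(identical(spikeTimes(a), spikeTimes(c)))
})

test_that("homogeneous spike counts match the Poisson mean/variance oracle", {
  # 5 Hz for 100 s: count ~ Poisson(500); |N - 500| <= 3*sqrt(500) for
  # >= 99% of seeds (3-sigma bound, oracle = Poisson moments)
  pr <- NeuronProfile(baselineRate = 5, responseClass = "nonresponsive")
  ok <- vapply(1:1000, function(s) {
    n <- length(spikeTimes(simulateSpikeTrain(pr, list(), 100, seed = s)))
    abs(n - 500) <= 3 * sqrt(500)
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("in-stimulus counts match the rate-integral oracle", {
  # excited, gain 20 Hz over baseline 5 Hz, one 3 s event:
  # E[in-stimulus count] = 3 * 25
  ev <- StimulusEvent(10, 13, modality = "thermal")
  pr <- NeuronProfile(baselineRate = 5, evokedGain = 20,
                      responseClass = "excited")
  counts <- vapply(1:400, function(s) {
    st <- spikeTimes(simulateSpikeTrain(pr, list(ev), 30, seed = s))
    sum(st >= 10 & st < 13)
  }, numeric(1))
  expect_equal(mean(counts), 75, tolerance = 0.05)  # ~4 SEM
})

test_that("long-run empirical rate converges to the specified rate", {
  for (rate in c(0.5, 2, 8)) {
    pr <- NeuronProfile(baselineRate = rate,
                        responseClass = "nonresponsive")
    tr <- simulateSpikeTrain(pr, list(), 2000, seed = round(100 * rate))
    expect_equal(length(spikeTimes(tr)) / 2000, rate,
                 tolerance = 4 / sqrt(rate * 2000) + 1e-9)
  }
})

test_that("population spec fractions are honored in ground truth", {
  spec0 <- PopulationSpec(12, adIncidence = 0)
  gt <- simulatePopulation(spec0, seed = 2)@metadata$groundTruth
  expect_true(all(vapply(gt, `[[`, numeric(1), "ad_duration") == 0))

  silent <- PopulationSpec(10, silentFraction = 1)
  gt2 <- simulatePopulation(silent, seed = 3)@metadata$groundTruth
  expect_true(all(vapply(gt2, `[[`, numeric(1), "baseline_rate") == 0))
})

test_that("ground-truth AD incidence matches the binomial sampling oracle", {
  # n = 43 neurons at incidence 0.512 over 300 populations: the pooled
  # AD-positive fraction lies within 4 binomial SEs of 0.512
  spec <- cciLike(43)
  hits <- vapply(1:300, function(s) {
    gt <- simulatePopulation(spec, seed = s)@metadata$groundTruth
    sum(vapply(gt, `[[`, numeric(1), "ad_duration") > 0)
  }, numeric(1))
  phat <- sum(hits) / (300 * 43)
  se <- sqrt(0.512 * 0.488 / (300 * 43))
  expect_lt(abs(phat - 0.512), 4 * se)
  # ground-truth AD durations respect the >= 0.5 s floor of the mixture
  gt <- simulatePopulation(spec, seed = 5)@metadata$groundTruth
  ad <- vapply(gt, `[[`, numeric(1), "ad_duration")
  expect_true(all(ad == 0 | ad >= 0.5))
})

test_that("population events respect spacing and simulated sessions validate", {
  sess <- simulatePopulation(shamLike(3), seed = 4)
  ons <- sort(vapply(sessionEvents(sess), function(e) e@onset, numeric(1)))
  expect_true(all(diff(ons) >= 8))
  expect_true(validObject(sess))
})

test_that("force traces follow the closed-form trapezoid", {
  tr <- simulateForceTrace(10, 3, riseTime = 0.5, sampleRate = 200,
                           noiseSd = 0, seed = 1)
  expect_equal(forceIntegral(tr), 10 * (3 - 0.5), tolerance = 1e-9)
  expect_equal(max(tr$force), 10)
  z <- simulateForceTrace(0, 3, 0.5, 100, 0, 1)
  expect_true(all(z$force == 0))
  n1 <- simulateForceTrace(10, 3, 0.5, 100, noiseSd = 1, seed = 9)
  n2 <- simulateForceTrace(10, 3, 0.5, 100, noiseSd = 1, seed = 9)
  expect_identical(n1$force, n2$force)
  expect_true(all(n1$force >= 0))
  expect_error(simulateForceTrace(-1, 3, 0.5, 100), "non-negative")
  expect_error(simulateForceTrace(10, 3, riseTime = 2, 100), "riseTime")
})

test_that("up-down sequences follow the staircase rules", {
  lad <- defaultLadder("face")
  # near-step psychometric with threshold between rungs 4 and 6 g:
  # deterministic alternation around the threshold
  pr <- PsychometricProfile(5, slope = 1e6)
  rec <- simulateUpDownSequence(pr, lad, startIndex = 5, seed = 1)
  expect_true(all(rec$response == (rec$force > 5)))
  steps <- diff(rec$index)
  expect_true(all(steps == ifelse(rec$response[-nrow(rec)], -1, 1)))

  # threshold far below the ladder: all responses, pinned at the minimum
  lo <- simulateUpDownSequence(PsychometricProfile(0.001, 1e6), lad,
                               startIndex = 3, seed = 2)
  expect_true(all(lo$response))
  expect_equal(min(lo$index), 1)
  expect_error(simulateUpDownSequence(pr, lad, startIndex = 99, seed = 1),
               "out of range")
})

test_that("up-down estimates recover the latent threshold on repetition", {
  lad <- defaultLadder("face")
  pr <- PsychometricProfile(3, slope = 15)
  est <- vapply(1:2000, function(s) {
    rec <- simulateUpDownSequence(pr, lad, seed = s)
    suppressWarnings(
      updownThreshold(upDownRecord(lad, rec$index, rec$response)))
  }, numeric(1))
  expect_lt(abs(median(est) - 3) / 3, 0.15)
})
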
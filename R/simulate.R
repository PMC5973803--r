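#' Construct a NeuronProfile
#'
#' @param baselineRate,evokedGain,adDuration,adRate,responseClass,suppressionFraction,reboundDuration,reboundRate,adShape
#'   see [NeuronProfile-class].
#' @return a validated [NeuronProfile-class].
#' @export
NeuronProfile <- function(baselineRate = 1, evokedGain = 0, adDuration = 0,
                          adRate = 0, responseClass = "nonresponsive",
                          suppressionFraction = 0, reboundDuration = 0,
                          reboundRate = 0, adShape = "rectangular") {
  new("NeuronProfile", baselineRate = baselineRate, evokedGain = evokedGain,
      adDuration = adDuration, adRate = adRate, responseClass = responseClass,
      suppressionFraction = suppressionFraction,
      reboundDuration = reboundDuration, reboundRate = reboundRate,
      adShape = adShape)
}

#' Construct a PopulationSpec
#'
#' @param nNeurons,condition,adIncidence,adDurationDist,silentFraction,offCellFraction
#'   see [PopulationSpec-class].
#' @return a validated [PopulationSpec-class].
#' @export
PopulationSpec <- function(nNeurons, condition = "sham", adIncidence = 0,
                           adDurationDist = list(name = "uniform", min = 0.5,
                                                 max = 3),
                           silentFraction = 0, offCellFraction = 0) {
  new("PopulationSpec", nNeurons = as.integer(nNeurons),
      condition = condition, adIncidence = adIncidence,
      adDurationDist = adDurationDist, silentFraction = silentFraction,
      offCellFraction = offCellFraction)
}

#' Condition presets for population simulation
#'
#' `shamLike()` and `cciLike()` encode the group structure of the
#' sham-operated and nerve-injured (CCI-ION) recordings: after-discharge
#' incidences of 13.6% vs 51.2% among tactile-responsive neurons, and
#' silent fractions of 11% vs 25%.
#'
#' @param nNeurons population size (defaults: 22 sham-like, 43 injury-like,
#'   the tactile-responsive group sizes).
#' @return a [PopulationSpec-class].
#' @export
shamLike <- function(nNeurons = 22) {
  PopulationSpec(nNeurons, condition = "sham", adIncidence = 0.136,
                 silentFraction = 0.11, offCellFraction = 0)
}

#' @rdname shamLike
#' @export
cciLike <- function(nNeurons = 43) {
  PopulationSpec(nNeurons, condition = "cci_ion", adIncidence = 0.512,
                 silentFraction = 0.25, offCellFraction = 0)
}

#' Construct a PsychometricProfile
#'
#' @param threshold50 grams; @param slope dimensionless log10 slope.
#' @return a validated [PsychometricProfile-class].
#' @export
PsychometricProfile <- function(threshold50, slope = 10) {
  new("PsychometricProfile", threshold50 = threshold50, slope = slope)
}

## rate program for one profile: piecewise-constant segments over [0, dur].
## Returns data.frame(start, end, rate). Exponential AD mode is discretized
## into 50 ms steps (still piecewise-constant, so sampling stays exact).
rateProgram <- function(profile, events, duration) {
  segs <- data.frame(start = numeric(), end = numeric(), rate = numeric())
  addSeg <- function(s, e, r) {
    if (e > s && r >= 0)
      segs <<- rbind(segs, data.frame(start = s, end = e, rate = r))
    if (r < 0) stop2("negative rate arising from profile")
  }
  for (ev in events) {
    on <- ev@onset; off <- ev@offset
    if (on < 0 || off > duration)
      stop2("event outside [0, duration]")
    cls <- profile@responseClass
    stimRate <- switch(cls,
      excited = profile@baselineRate + profile@evokedGain,
      suppressed = profile@baselineRate * profile@suppressionFraction,
      nonresponsive = profile@baselineRate)
    addSeg(on, off, stimRate)
    if (identical(cls, "excited") && profile@adDuration > 0) {
      if (identical(profile@adShape, "rectangular")) {
        addSeg(off, min(off + profile@adDuration, duration), profile@adRate)
      } else {
        step <- 0.05
        tEnd <- min(off + 5 * profile@adDuration, duration)
        ts <- seq(off, tEnd, by = step)
        for (i in seq_len(length(ts) - 1L)) {
          mid <- (ts[i] + ts[i + 1L]) / 2 - off
          r <- profile@baselineRate +
            (profile@adRate - profile@baselineRate) *
            exp(-mid / profile@adDuration)
          addSeg(ts[i], ts[i + 1L], r)
        }
      }
    }
    if (identical(cls, "suppressed") && profile@reboundDuration > 0)
      addSeg(off, min(off + profile@reboundDuration, duration),
             profile@reboundRate)
  }
  if (nrow(segs)) {
    segs <- segs[order(segs$start), , drop = FALSE]
    if (any(segs$start[-1] < segs$end[-nrow(segs)] - 1e-12))
      stop2("overlapping stimulus/after-discharge segments; ",
            "increase inter-stimulus spacing")
  }
  ## fill gaps with baseline
  allSegs <- data.frame(start = numeric(), end = numeric(), rate = numeric())
  cursor <- 0
  for (i in seq_len(nrow(segs))) {
    if (segs$start[i] > cursor + 1e-12)
      allSegs <- rbind(allSegs, data.frame(start = cursor,
                                           end = segs$start[i],
                                           rate = profile@baselineRate))
    allSegs <- rbind(allSegs, segs[i, ])
    cursor <- max(cursor, segs$end[i])
  }
  if (cursor < duration - 1e-12)
    allSegs <- rbind(allSegs, data.frame(start = cursor, end = duration,
                                         rate = profile@baselineRate))
  allSegs
}

#' Simulate one spike train from a rate program
#'
#' Draws an inhomogeneous Poisson process with piecewise-constant rate:
#' baseline outside events, `baseline + evokedGain` (excited) or
#' `baseline * suppressionFraction` (suppressed) during events, and the
#' after-discharge or rebound rate for its ground-truth duration after each
#' offset. Sampling is exact for piecewise-constant rates: per segment the
#' spike count is Poisson(rate × length) and arrival times are sorted
#' uniforms.
#'
#' @param profile a [NeuronProfile-class].
#' @param events list of [StimulusEvent-class] within `[0, duration]`.
#' @param duration recording length in s.
#' @param seed integer; identical seed + inputs give identical trains.
#' @param unitId identifier for the resulting train.
#' @return a [SpikeTrain-class].
#' @examples
#' ev <- StimulusEvent(10, 13, forceTrace = data.frame(time = 0:3,
#'                                                     force = c(0, 10, 10, 0)))
#' pr <- NeuronProfile(baselineRate = 5, evokedGain = 20,
#'                     responseClass = "excited")
#' simulateSpikeTrain(pr, list(ev), duration = 30, seed = 1)
#' @export
simulateSpikeTrain <- function(profile, events, duration, seed,
                               unitId = "sim") {
  validObject(profile)
  segs <- rateProgram(profile, events, duration)
  spikes <- withSeed(seed, {
    out <- vector("list", nrow(segs))
    for (i in seq_len(nrow(segs))) {
      len <- segs$end[i] - segs$start[i]
      n <- rpois(1L, segs$rate[i] * len)
      if (n > 0L)
        out[[i]] <- segs$start[i] + sort(runif(n, 0, len))
    }
    unlist(out, use.names = FALSE)
  })
  if (is.null(spikes)) spikes <- numeric()
  SpikeTrain(unitId, sort(spikes), duration = duration)
}

## draw a ground-truth AD duration from the spec's named distribution
drawAdDuration <- function(dist) {
  switch(dist$name,
    uniform = runif(1L, dist$min, dist$max),
    exponential = 0.5 + stats::rexp(1L, 1 / dist$mean),
    fixed = dist$value,
    stop2("unknown adDurationDist: ", dist$name))
}

#' Default stimulus protocol for simulated sessions
#'
#' Five repetitions of 3 s mechanical stimuli with inter-stimulus spacing
#' of at least 8 s; spacing is widened so that each trial's aligned window
#' (5 s baseline + stimulus + post-offset scan) never overlaps the next, and
#' widened further when the population can carry long after-discharges —
#' mirroring the practice of waiting out the entire after-discharge before
#' the next stimulus.
#'
#' @param nTrials repetitions (default 5).
#' @param stimLength stimulus duration in s (default 3).
#' @param site,modality stimulus labels.
#' @param maxAdDuration longest ground-truth after-discharge to accommodate.
#' @param config an [AnalysisConfig-class] (for baseline/scan windows).
#' @param peakForce aesthesiometer peak force in grams for mechanical events.
#' @param seed integer seed for force-trace noise.
#' @return list of [StimulusEvent-class].
#' @export
defaultProtocol <- function(nTrials = 5, stimLength = 3, site = "face_ipsi",
                            modality = "mechanical", maxAdDuration = 3,
                            config = AnalysisConfig(), peakForce = 60,
                            seed = 1L) {
  spacing <- max(8, config@baselineWindow + stimLength +
                   config@reboundScanWindow + maxAdDuration + 1)
  onsets <- config@baselineWindow + 1 + (seq_len(nTrials) - 1L) * spacing
  lapply(seq_len(nTrials), function(i) {
    if (identical(modality, "mechanical")) {
      tr <- simulateForceTrace(peak = peakForce, duration = stimLength,
                               riseTime = 0.3, sampleRate = 100,
                               noiseSd = 0.5, seed = childSeed(seed, i))
      StimulusEvent(onsets[i], onsets[i] + stimLength, modality = modality,
                    site = site, forceTrace = tr)
    } else {
      StimulusEvent(onsets[i], onsets[i] + stimLength, modality = modality,
                    site = site,
                    laserParams = list(dutyOn = 0.03, dutyOff = 0.03,
                                       power = 2))
    }
  })
}

#' Simulate a population session
#'
#' Draws `nNeurons` i.i.d. from the population spec (silent/off-cell/
#' after-discharge mixture), simulates each unit against the shared stimulus
#' protocol, and stores every unit's ground-truth [NeuronProfile-class]
#' parameters in the session metadata (`metadata$groundTruth`) so detection
#' recovery can be asserted directly.
#'
#' @param spec a [PopulationSpec-class].
#' @param protocol list of [StimulusEvent-class]; default built by
#'   [defaultProtocol()].
#' @param seed integer master seed; per-unit child seeds are derived
#'   deterministically.
#' @param config an [AnalysisConfig-class] used to size the protocol.
#' @param baselineRateRange Hz range for non-silent baseline rates
#'   (log-uniform draw; default 0.3–5 Hz, matching median spontaneous rates
#'   near 1.6–1.9 Hz).
#' @param evokedGain,adRate,reboundRate Hz used for the respective segments.
#' @return a [Session-class] with `metadata$groundTruth` (one entry per
#'   unit) and `metadata$seed`.
#' @export
simulatePopulation <- function(spec, protocol = NULL, seed = 1L,
                               config = AnalysisConfig(),
                               baselineRateRange = c(0.3, 5),
                               evokedGain = 60, adRate = 60,
                               reboundRate = 60) {
  validObject(spec)
  maxAd <- if (identical(spec@adDurationDist$name, "uniform"))
    spec@adDurationDist$max else 3
  if (is.null(protocol))
    protocol <- defaultProtocol(maxAdDuration = maxAd, config = config,
                                seed = childSeed(seed, 999L))
  duration <- max(vapply(protocol, slot, numeric(1), "offset")) +
    config@reboundScanWindow + maxAd + 1
  profiles <- withSeed(childSeed(seed, 0L), {
    lapply(seq_len(spec@nNeurons), function(i) {
      silent <- runif(1) < spec@silentFraction
      base <- if (silent) 0 else
        exp(runif(1, log(baselineRateRange[1]), log(baselineRateRange[2])))
      off <- runif(1) < spec@offCellFraction
      if (off && !silent) {
        NeuronProfile(baselineRate = base, responseClass = "suppressed",
                      suppressionFraction = 0.1, reboundDuration = 1,
                      reboundRate = reboundRate)
      } else {
        hasAd <- runif(1) < spec@adIncidence
        adDur <- if (hasAd) drawAdDuration(spec@adDurationDist) else 0
        NeuronProfile(baselineRate = base, evokedGain = evokedGain,
                      adDuration = adDur, adRate = adRate,
                      responseClass = "excited")
      }
    })
  })
  units <- lapply(seq_along(profiles), function(i) {
    simulateSpikeTrain(profiles[[i]], protocol, duration,
                       seed = childSeed(seed, i),
                       unitId = sprintf("%s_u%03d", spec@condition, i))
  })
  gt <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    list(unit_id = units[[i]]@unitId, baseline_rate = p@baselineRate,
         evoked_gain = p@evokedGain, ad_duration = p@adDuration,
         ad_rate = p@adRate, response_class = p@responseClass,
         suppression_fraction = p@suppressionFraction,
         rebound_duration = p@reboundDuration,
         rebound_rate = p@reboundRate)
  })
  Session(sprintf("sim_%s_seed%d", spec@condition, as.integer(seed)),
          spec@condition, units = units, events = protocol,
          metadata = list(groundTruth = gt, seed = as.integer(seed)))
}

#' Simulate an aesthesiometer force trace
#'
#' Trapezoidal ramp–hold–ramp profile (rise, plateau at `peak`, symmetric
#' fall) plus clipped Gaussian noise; the trace is non-negative everywhere.
#'
#' @param peak plateau force in grams (>= 0).
#' @param duration total stimulus length in s.
#' @param riseTime ramp length in s; must be < duration/2.
#' @param sampleRate Hz.
#' @param noiseSd Gaussian noise SD in grams (0 gives the closed-form
#'   trapezoid, whose integral is `peak * (duration - riseTime)`).
#' @param seed integer.
#' @return data.frame with columns `time` (s) and `force` (g).
#' @examples
#' tr <- simulateForceTrace(10, 3, riseTime = 0.5, sampleRate = 100,
#'                          noiseSd = 0, seed = 1)
#' forceIntegral(tr)  # 25 g.s
#' @export
simulateForceTrace <- function(peak, duration, riseTime, sampleRate,
                               noiseSd = 0, seed = 1L) {
  if (peak < 0) stop2("peak force must be non-negative")
  if (riseTime >= duration / 2)
    stop2("riseTime must be < duration/2")
  tt <- seq(0, duration, by = 1 / sampleRate)
  f <- pmin(1, pmin(tt, duration - tt) / riseTime) * peak
  if (noiseSd > 0)
    f <- withSeed(seed, pmax(0, f + rnorm(length(f), 0, noiseSd)))
  data.frame(time = tt, force = f)
}

#' Simulate an up-down (staircase) response sequence
#'
#' Responses are Bernoulli draws from the logistic psychometric function
#' `plogis((log10(force) - log10(threshold50)) * slope)`. The staircase
#' steps down after a response and up after a non-response (clipped at the
#' ladder ends), and stops after four stimuli beyond the first response
#' change, or when pinned at a ladder end for three consecutive identical
#' outcomes.
#'
#' @param profile a [PsychometricProfile-class].
#' @param ladder strictly increasing filament forces in grams.
#' @param startIndex 1-based index of the first filament.
#' @param seed integer.
#' @param maxTrials hard cap on sequence length (default 20).
#' @return data.frame with columns `index`, `force`, `response` (logical).
#' @export
simulateUpDownSequence <- function(profile, ladder = defaultLadder("face"),
                                   startIndex = NULL, seed = 1L,
                                   maxTrials = 20L) {
  validObject(profile)
  if (is.unsorted(ladder, strictly = TRUE))
    stop2("ladder must be strictly increasing")
  if (is.null(startIndex)) startIndex <- ceiling(length(ladder) / 2)
  if (startIndex < 1L || startIndex > length(ladder))
    stop2("start index out of range")
  withSeed(seed, {
    idx <- startIndex
    ix <- integer(); resp <- logical()
    changed <- FALSE; afterChange <- 0L
    repeat {
      f <- ladder[idx]
      p <- plogis((log10(f) - log10(profile@threshold50)) * profile@slope)
      r <- runif(1) < p
      ix <- c(ix, idx); resp <- c(resp, r)
      n <- length(resp)
      if (n >= 2L && resp[n] != resp[n - 1L]) changed <- TRUE
      if (changed) afterChange <- afterChange + 1L
      pinned <- n >= 3L &&
        ((idx == 1L && all(resp[(n - 2L):n]) &&
            all(ix[(n - 2L):n] == 1L)) ||
         (idx == length(ladder) && !any(resp[(n - 2L):n]) &&
            all(ix[(n - 2L):n] == length(ladder))))
      if ((changed && afterChange > 4L) || pinned || n >= maxTrials) break
      idx <- if (r) max(1L, idx - 1L) else min(length(ladder), idx + 1L)
    }
    data.frame(index = ix, force = ladder[ix], response = resp)
  })
}
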
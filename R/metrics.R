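#' Spontaneous firing rate over quiet intervals
#'
#' Total spikes falling in the given quiet intervals divided by total quiet
#' time. Quiet intervals must exclude stimulus windows and their post-offset
#' scan windows; [quietIntervals()] builds that complement.
#'
#' @param train a [SpikeTrain-class].
#' @param intervals data.frame/matrix-like with columns `start`, `end` (s),
#'   non-overlapping.
#' @return rate in Hz.
#' @examples
#' tr <- SpikeTrain("u", seq(0.5, 179.5, by = 1), 180)
#' spontaneousRate(tr, data.frame(start = 0, end = 180))  # 1 Hz
#' @export
spontaneousRate <- function(train, intervals) {
  intervals <- as.data.frame(intervals)
  tot <- sum(intervals$end - intervals$start)
  if (tot <= 0) stop2("zero total quiet time")
  n <- sum(vapply(seq_len(nrow(intervals)), function(i) {
    sum(train@spikeTimes >= intervals$start[i] &
          train@spikeTimes < intervals$end[i])
  }, numeric(1)))
  n / tot
}

#' Quiet intervals of a session
#'
#' The complement, within `[0, duration]`, of all windows
#' `[onset - baselineWindow... onset, offset + scan]` is *not* excluded on
#' the baseline side: only `[onset, offset + reboundScanWindow + pad]` is
#' removed, since pre-stimulus time is by definition quiet.
#'
#' @param events list of [StimulusEvent-class].
#' @param duration recording length (s).
#' @param config an [AnalysisConfig-class].
#' @param pad extra guard after the scan window (s, default 0).
#' @return data.frame with columns `start`, `end`.
#' @export
quietIntervals <- function(events, duration, config = AnalysisConfig(),
                           pad = 0) {
  if (!length(events)) return(data.frame(start = 0, end = duration))
  ons <- vapply(events, slot, numeric(1), "onset")
  offs <- vapply(events, slot, numeric(1), "offset") +
    config@reboundScanWindow + pad
  o <- order(ons)
  ons <- ons[o]; offs <- pmin(offs[o], duration)
  out <- list(); cursor <- 0
  for (i in seq_along(ons)) {
    if (ons[i] > cursor)
      out[[length(out) + 1L]] <- data.frame(start = cursor, end = ons[i])
    cursor <- max(cursor, offs[i])
  }
  if (cursor < duration)
    out[[length(out) + 1L]] <- data.frame(start = cursor, end = duration)
  do.call(rbind, out)
}

#' Integral of an aesthesiometer force trace
#'
#' Trapezoidal integral of force (grams) over the trace's time support,
#' in gram-seconds. Handles irregular sampling.
#'
#' @param trace data.frame with columns `time` (s) and `force` (g), at least
#'   2 samples, forces non-negative.
#' @return numeric, g·s.
#' @export
forceIntegral <- function(trace) {
  if (nrow(trace) < 2L) stop2("force trace needs at least 2 samples")
  if (any(trace$force < 0)) stop2("force samples must be non-negative")
  trapz(trace$time, trace$force)
}

#' Force-normalized mechanical response magnitude
#'
#' The evoked firing rate normalized to the spontaneous rate, divided by
#' the stimulus force integral. `"subtract"` mode (default) uses
#' `(evoked - spontaneous) / integral`, which stays well defined for
#' spontaneously silent neurons; `"ratio"` mode uses
#' `(evoked / max(spontaneous, epsilon)) / integral` with the epsilon floor
#' taken from `config@epsilonRate` and recorded in the result.
#'
#' @param evokedRate Hz (mean rate over the stimulus window).
#' @param spontaneousRate Hz.
#' @param forceIntegral g·s, > 0.
#' @param mode `"subtract"` or `"ratio"`; default from `config`.
#' @param config an [AnalysisConfig-class].
#' @return named list: `magnitude`, `mode`, `epsilonUsed` (logical).
#' @examples
#' mechanicalMagnitude(20, 5, 30)$magnitude  # 0.5 Hz per g.s
#' @export
mechanicalMagnitude <- function(evokedRate, spontaneousRate, forceIntegral,
                                mode = NULL, config = AnalysisConfig()) {
  if (forceIntegral <= 0) stop2("force integral must be > 0")
  if (is.null(mode)) mode <- config@normalizationMode
  epsUsed <- FALSE
  mag <- if (identical(mode, "subtract")) {
    (evokedRate - spontaneousRate) / forceIntegral
  } else {
    denom <- spontaneousRate
    if (denom < config@epsilonRate) {
      denom <- config@epsilonRate
      epsUsed <- TRUE
      pb_log(sprintf("ratio mode: spontaneous rate floored at %.3g Hz",
                     config@epsilonRate))
    }
    (evokedRate / denom) / forceIntegral
  }
  list(magnitude = mag, mode = mode, epsilonUsed = epsUsed)
}

#' Thermal response magnitude
#'
#' Default is the rate ratio `(mean in-stimulus rate) / max(baselineMean,
#' epsilon)` — a near-unity value for weak responses; a `"subtract"` mode
#' returning the rate difference in Hz is also available.
#'
#' @param psth a [Psth-class] of thermal trials with its baseline band.
#' @param config an [AnalysisConfig-class].
#' @param mode `"ratio"` (default) or `"subtract"`.
#' @return named list: `magnitude`, `mode`, `epsilonUsed`.
#' @export
thermalMagnitude <- function(psth, config = AnalysisConfig(),
                             mode = "ratio") {
  lo <- psth@binEdges[-length(psth@binEdges)]
  stimBins <- which(lo >= -1e-9 & lo < psth@stimDuration - 1e-9)
  if (!length(stimBins)) stop2("PSTH does not cover the stimulus interval")
  evoked <- mean(meanRatePerBin(psth)[stimBins])
  epsUsed <- FALSE
  mag <- if (identical(mode, "subtract")) {
    evoked - psth@baselineMean
  } else {
    denom <- psth@baselineMean
    if (denom < config@epsilonRate) {
      denom <- config@epsilonRate
      epsUsed <- TRUE
    }
    evoked / denom
  }
  list(magnitude = mag, mode = mode, epsilonUsed = epsUsed)
}

#' Response magnitudes for every unit of a session
#'
#' One row per unit × site × modality: spontaneous rate (over the session's
#' quiet intervals), mean evoked rate, force integral (mechanical; mean over
#' trials), and the normalized magnitude.
#'
#' @param session a [Session-class].
#' @param config an [AnalysisConfig-class].
#' @return a data.frame.
#' @export
responseMagnitudes <- function(session, config = AnalysisConfig()) {
  validObject(session)
  keys <- vapply(session@events, function(e) paste(e@site, e@modality,
                                                   sep = "|"), character(1))
  groups <- split(session@events, keys)
  rows <- list()
  for (u in session@units) {
    qi <- quietIntervals(session@events, u@duration, config)
    spont <- spontaneousRate(u, qi)
    for (g in names(groups)) {
      evs <- groups[[g]]
      parts <- strsplit(g, "|", fixed = TRUE)[[1]]
      evoked <- mean(vapply(evs, function(e) {
        sum(u@spikeTimes >= e@onset & u@spikeTimes < e@offset) /
          (e@offset - e@onset)
      }, numeric(1)))
      if (identical(parts[2], "mechanical")) {
        fi <- mean(vapply(evs, function(e) forceIntegral(e@forceTrace),
                          numeric(1)))
        mm <- mechanicalMagnitude(evoked, spont, fi, config = config)
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = u@unitId, site = parts[1], modality = parts[2],
          spontaneous_rate = spont, evoked_rate = evoked,
          force_integral = fi, magnitude = mm$magnitude, mode = mm$mode,
          stringsAsFactors = FALSE)
      } else {
        psth <- buildPsth(u, evs, config = config)
        tm <- thermalMagnitude(psth, config)
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = u@unitId, site = parts[1], modality = parts[2],
          spontaneous_rate = spont, evoked_rate = evoked,
          force_integral = NA_real_, magnitude = tm$magnitude,
          mode = tm$mode, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
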
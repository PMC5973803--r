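## run-length scanner shared by after-discharge and rebound detection:
## length (in bins) of the supra-band run starting at the first post-offset
## bin, tolerating up to `gap` consecutive sub-band bins inside the run
## (default 0), stopping at the window end.
postOffsetRun <- function(psth, config, scanBins = NULL) {
  postBins <- which(psth@binEdges[-length(psth@binEdges)] >=
                      psth@stimDuration - 1e-9)
  if (!length(postBins)) return(0L)
  if (!is.null(scanBins)) postBins <- postBins[seq_len(min(scanBins,
                                                           length(postBins)))]
  supra <- meanRatePerBin(psth)[postBins] > psth@ciUpper + 1e-12
  run <- 0L; gaps <- 0L
  for (s in supra) {
    if (s) {
      run <- run + 1L + gaps
      gaps <- 0L
    } else {
      gaps <- gaps + 1L
      if (gaps > config@adGapTolerance) break
    }
  }
  run
}

#' Classify the stimulus response of a unit
#'
#' A unit is responsive with sign `"excited"` when at least one in-stimulus
#' bin's trial-averaged rate exceeds the upper edge of the baseline
#' confidence band. Suppression is decided separately by
#' [detectSuppression()]; this function alone returns `"none"` for anything
#' not excited.
#'
#' @param psth a [Psth-class] covering the stimulus interval.
#' @param config an [AnalysisConfig-class].
#' @return list with `responsive` (logical) and `responseSign`.
#' @export
detectResponse <- function(psth, config = AnalysisConfig()) {
  lo <- psth@binEdges[-length(psth@binEdges)]
  stimBins <- which(lo >= -1e-9 & lo < psth@stimDuration - 1e-9)
  if (!length(stimBins)) stop2("PSTH does not cover the stimulus interval")
  excited <- any(meanRatePerBin(psth)[stimBins] > psth@ciUpper + 1e-12)
  list(responsive = excited,
       responseSign = if (excited) "excited" else "none")
}

#' Detect and measure an after-discharge
#'
#' An after-discharge is a run of consecutive PSTH bins whose trial-averaged
#' rate exceeds the 99% baseline band, starting at the first bin after
#' stimulus offset and lasting at least `config@adMinDuration` (500 ms, i.e.
#' 5 bins at the default 100 ms bin width). Runs shorter than the criterion
#' yield `adDuration = 0` (the raw run length is returned separately for
#' diagnostics). Scanning continues until activity returns below the band
#' or the aligned window ends.
#'
#' @param psth a [Psth-class] extending at least `config@reboundScanWindow`
#'   past stimulus offset.
#' @param config an [AnalysisConfig-class].
#' @return list with `adPresent`, `adDuration` (s), and `rawRunDuration`
#'   (s, the run length regardless of the criterion).
#' @export
detectAfterDischarge <- function(psth, config = AnalysisConfig()) {
  postLen <- max(psth@binEdges) - psth@stimDuration
  if (postLen < config@reboundScanWindow - 1e-9)
    stop2(sprintf(
      "PSTH window ends %.2f s after offset; need >= %.2f s",
      postLen, config@reboundScanWindow))
  run <- postOffsetRun(psth, config)
  dur <- run * psth@binWidth
  present <- dur >= config@adMinDuration - 1e-9
  list(adPresent = present, adDuration = if (present) dur else 0,
       rawRunDuration = dur)
}

#' Test for stimulus-evoked suppression of firing
#'
#' Per trial, the firing rate in the 5 s before onset
#' (`config@baselineWindow`) is paired with the rate during the stimulus,
#' and a two-tailed paired t-test is applied. The unit is labelled
#' suppressed when `p < config@suppressionAlpha` *and* the mean stimulus
#' rate is below the mean pre-stimulus rate (the direction requirement keeps
#' excited cells out of this class).
#'
#' @param train a [SpikeTrain-class].
#' @param events list of [StimulusEvent-class]; at least 3 trials.
#' @param config an [AnalysisConfig-class].
#' @return list with `suppressed`, `suppressionP`, and
#'   `degenerateVariance` (TRUE when the trial differences have zero
#'   variance with a nonzero mean, in which case p is reported as 0).
#' @examples
#' # rates pre {10,11,9,10,10} vs stim {2,3,2,2,1} over 5 trials is a
#' # textbook suppression: t = mean(d)/(sd(d)/sqrt(5)) on df = 4
#' @export
detectSuppression <- function(train, events, config = AnalysisConfig()) {
  if (length(events) < 3L)
    stop2("paired t-test needs at least 3 trials")
  pre <- vapply(events, function(e) {
    sum(train@spikeTimes >= e@onset - config@baselineWindow &
          train@spikeTimes < e@onset) / config@baselineWindow
  }, numeric(1))
  stim <- vapply(events, function(e) {
    sum(train@spikeTimes >= e@onset & train@spikeTimes < e@offset) /
      (e@offset - e@onset)
  }, numeric(1))
  d <- pre - stim
  degenerate <- FALSE
  if (sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12) {
      p <- 1
    } else {
      p <- 0
      degenerate <- TRUE
    }
  } else {
    p <- t.test(pre, stim, paired = TRUE)$p.value
  }
  list(suppressed = (p < config@suppressionAlpha) && mean(stim) < mean(pre),
       suppressionP = p, degenerateVariance = degenerate)
}

#' Detect a post-inhibitory rebound burst
#'
#' For a suppressed unit, rebound is a run of consecutive supra-band PSTH
#' bins beginning at the first post-offset bin, within
#' `config@reboundScanWindow` after offset. Any nonzero run counts as
#' rebound (no minimum-duration criterion); runs shorter than one bin are
#' undetectable by construction.
#'
#' @param psth a [Psth-class].
#' @param config an [AnalysisConfig-class].
#' @return list with `reboundPresent` and `reboundDuration` (s).
#' @export
detectRebound <- function(psth, config = AnalysisConfig()) {
  scanBins <- round(config@reboundScanWindow / psth@binWidth)
  run <- postOffsetRun(psth, config, scanBins = scanBins)
  dur <- run * psth@binWidth
  list(reboundPresent = dur > 0, reboundDuration = dur)
}

#' Full detection for one unit against one event group
#'
#' Runs response classification, after-discharge measurement, the paired
#' suppression test, and (for suppressed units) rebound detection, and
#' assembles a [DetectionResult-class]. After-discharge and response are
#' treated independently; rebound is only populated for suppressed units.
#'
#' @param train a [SpikeTrain-class].
#' @param events list of [StimulusEvent-class] (one site × modality group).
#' @param config an [AnalysisConfig-class].
#' @return a [DetectionResult-class].
#' @export
detectUnit <- function(train, events, config = AnalysisConfig()) {
  psth <- buildPsth(train, events, config = config)
  resp <- detectResponse(psth, config)
  ad <- detectAfterDischarge(psth, config)
  sup <- detectSuppression(train, events, config)
  sign <- if (resp$responsive) "excited" else if (sup$suppressed)
    "suppressed" else "none"
  responsive <- resp$responsive || sup$suppressed
  rb <- list(reboundPresent = FALSE, reboundDuration = 0)
  adPresent <- ad$adPresent; adDuration <- ad$adDuration
  if (identical(sign, "suppressed")) {
    rb <- detectRebound(psth, config)
    ## a post-offset elevation of a suppressed cell is rebound, not AD
    adPresent <- FALSE; adDuration <- 0
  }
  new("DetectionResult", unitId = train@unitId, responsive = responsive,
      responseSign = sign, adPresent = adPresent, adDuration = adDuration,
      suppressionP = sup$suppressionP, reboundPresent = rb$reboundPresent,
      reboundDuration = rb$reboundDuration,
      diagnostics = list(adRawRun = ad$rawRunDuration,
                         degenerateVariance = sup$degenerateVariance,
                         baselineMean = psth@baselineMean,
                         ciUpper = psth@ciUpper))
}

#' Detect all units of a session
#'
#' Events are grouped by site × modality and each unit is scored against
#' each group; the result is one row per unit × group with all
#' [DetectionResult-class] fields.
#'
#' @param session a [Session-class].
#' @param config an [AnalysisConfig-class].
#' @param verbose log per-unit progress to stderr.
#' @return a data.frame.
#' @export
detectSession <- function(session, config = AnalysisConfig(),
                          verbose = FALSE) {
  validObject(session)
  keys <- vapply(session@events, function(e) paste(e@site, e@modality,
                                                   sep = "|"), character(1))
  groups <- split(session@events, keys)
  rows <- list()
  for (u in session@units) {
    if (verbose) pb_log("detect: unit ", u@unitId)
    for (g in names(groups)) {
      dr <- detectUnit(u, groups[[g]], config)
      parts <- strsplit(g, "|", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = dr@unitId, site = parts[1], modality = parts[2],
        responsive = dr@responsive, response_sign = dr@responseSign,
        ad_present = dr@adPresent, ad_duration = dr@adDuration,
        suppression_p = dr@suppressionP,
        rebound_present = dr@reboundPresent,
        rebound_duration = dr@reboundDuration,
        ad_raw_run = dr@diagnostics$adRawRun,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
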
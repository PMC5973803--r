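## Central S4 data objects. All time is in seconds from recording start;
## stimulus windows are half-open [onset, offset) so a spike on a boundary
## is never double-counted.

MODALITIES <- c("mechanical", "thermal")
SITES <- c("face_ipsi", "face_contra", "hindpaw_ipsi", "hindpaw_contra")
CONDITIONS <- c("sham", "cci_ion")
RESPONSE_CLASSES <- c("excited", "suppressed", "nonresponsive")

#' SpikeTrain: sorted spike timestamps for one unit
#'
#' One extracellular unit over one recording: spike times in seconds from
#' recording start, plus the total recorded duration. All rate statistics in
#' the package derive from this point process.
#'
#' @slot unitId character identifier.
#' @slot spikeTimes numeric, non-decreasing, all within `[0, duration]`.
#' @slot duration numeric, recording length in seconds (> 0).
#' @slot regionLabel free-text anatomical label (e.g. lateral/medial PB).
#' @export
setClass("SpikeTrain",
  representation(unitId = "character", spikeTimes = "numeric",
                 duration = "numeric", regionLabel = "character"),
  prototype(regionLabel = ""))

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (!is_scalar_chr(object@unitId) || !nzchar(object@unitId))
    msg <- c(msg, "unitId must be a non-empty string")
  if (!is_scalar_num(object@duration) || object@duration <= 0)
    msg <- c(msg, "duration must be a positive number")
  st <- object@spikeTimes
  if (length(st)) {
    if (anyNA(st)) msg <- c(msg, "spikeTimes contains NA")
    else {
      if (is.unsorted(st))
        msg <- c(msg, sprintf("spikeTimes of unit '%s' are not sorted",
                              object@unitId))
      if (min(st) < 0 || max(st) > object@duration)
        msg <- c(msg, sprintf(
          "spikeTimes of unit '%s' fall outside [0, duration]",
          object@unitId))
    }
  }
  if (length(msg)) msg else TRUE
})

#' StimulusEvent: one stimulus application
#'
#' A single mechanical or thermal stimulus: onset/offset (half-open window),
#' stimulation site, and for mechanical stimuli the sampled aesthesiometer
#' force trace in grams; thermal stimuli may carry laser duty-cycle
#' parameters (the protocol uses 30 ms on/off cycles at 2 W for 3 s).
#'
#' @slot onset,offset numeric seconds; `offset > onset`.
#' @slot modality `"mechanical"` or `"thermal"`.
#' @slot site one of `"face_ipsi"`, `"face_contra"`, `"hindpaw_ipsi"`,
#'   `"hindpaw_contra"`.
#' @slot forceTrace `data.frame` with columns `time` (s) and `force` (g),
#'   present iff modality is mechanical; forces non-negative.
#' @slot laserParams named list (`dutyOn`, `dutyOff` in s, `power` in W) or
#'   empty.
#' @export
setClass("StimulusEvent",
  representation(onset = "numeric", offset = "numeric", modality = "character",
                 site = "character", forceTrace = "data.frame",
                 laserParams = "list"),
  prototype(forceTrace = data.frame(time = numeric(), force = numeric()),
            laserParams = list()))

setValidity("StimulusEvent", function(object) {
  msg <- character()
  if (!is_scalar_num(object@onset) || object@onset < 0)
    msg <- c(msg, "onset must be a non-negative number")
  if (!is_scalar_num(object@offset) || object@offset <= object@onset)
    msg <- c(msg, "offset must exceed onset")
  if (!is_scalar_chr(object@modality) || !object@modality %in% MODALITIES)
    msg <- c(msg, sprintf("modality must be one of: %s",
                          paste(MODALITIES, collapse = ", ")))
  if (!is_scalar_chr(object@site) || !object@site %in% SITES)
    msg <- c(msg, sprintf("site must be one of: %s",
                          paste(SITES, collapse = ", ")))
  ft <- object@forceTrace
  hasTrace <- nrow(ft) > 0L
  if (hasTrace) {
    if (!all(c("time", "force") %in% names(ft)))
      msg <- c(msg, "forceTrace needs columns 'time' and 'force'")
    else if (any(ft$force < 0))
      msg <- c(msg, "force samples must be non-negative")
  }
  if (identical(object@modality, "mechanical") && !hasTrace)
    msg <- c(msg, "mechanical events require a force trace")
  if (identical(object@modality, "thermal") && hasTrace)
    msg <- c(msg, "thermal events must not carry a force trace")
  if (length(msg)) msg else TRUE
})

#' AnalysisConfig: shared analysis constants
#'
#' Holds the fixed criteria of the detection pipeline: the 99% confidence
#' level on baseline firing, the 500 ms minimum after-discharge duration,
#' the 5 s pre-stimulus baseline window used both for the confidence band
#' and the paired suppression test, and the PSTH bin width (100 ms default,
#' so the 500 ms criterion is exactly 5 bins).
#'
#' @slot binWidth PSTH bin width in s (default 0.1).
#' @slot baselineWindow s before onset used for baseline statistics
#'   (default 5).
#' @slot ciLevel two-sided confidence level for the baseline band
#'   (default 0.99).
#' @slot adMinDuration minimum after-discharge duration in s (default 0.5);
#'   snapped to an integer multiple of `binWidth` at construction, with a
#'   warning if snapping changed it.
#' @slot reboundScanWindow s after offset scanned for rebound (default 10).
#' @slot suppressionAlpha two-tailed level for the paired t-test
#'   (default 0.05).
#' @slot normalizationMode `"subtract"` or `"ratio"` for evoked-response
#'   normalization.
#' @slot ciMethod `"normal"` (mean ± z·sd over pooled baseline bin counts) or
#'   `"poisson_exact"` (0.5/99.5 percentiles of Poisson(mean count)).
#' @slot adGapTolerance integer, supra-band run may skip this many gap bins
#'   (default 0).
#' @slot epsilonRate floor in Hz for ratio-mode denominators (default 0.1,
#'   one spike per 10 s).
#' @slot rngSeed integer seed recorded for pipeline runs (NA if unset).
#' @export
setClass("AnalysisConfig",
  representation(binWidth = "numeric", baselineWindow = "numeric",
                 ciLevel = "numeric", adMinDuration = "numeric",
                 reboundScanWindow = "numeric", suppressionAlpha = "numeric",
                 normalizationMode = "character", ciMethod = "character",
                 adGapTolerance = "integer", epsilonRate = "numeric",
                 rngSeed = "integer"),
  prototype(binWidth = 0.1, baselineWindow = 5, ciLevel = 0.99,
            adMinDuration = 0.5, reboundScanWindow = 10,
            suppressionAlpha = 0.05, normalizationMode = "subtract",
            ciMethod = "normal", adGapTolerance = 0L, epsilonRate = 0.1,
            rngSeed = NA_integer_))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!is_scalar_num(object@binWidth) || object@binWidth <= 0)
    msg <- c(msg, "binWidth must be > 0")
  if (!is_scalar_num(object@adMinDuration) || object@adMinDuration <= 0)
    msg <- c(msg, "adMinDuration must be > 0")
  if (is_scalar_num(object@binWidth) && is_scalar_num(object@adMinDuration)) {
    if (object@binWidth > object@adMinDuration + 1e-9)
      msg <- c(msg, "binWidth must not exceed adMinDuration")
    k <- object@adMinDuration / object@binWidth
    if (abs(k - round(k)) > 1e-6)
      msg <- c(msg, "adMinDuration must be an integer multiple of binWidth")
  }
  if (!is_scalar_num(object@ciLevel) || object@ciLevel <= 0 ||
      object@ciLevel >= 1)
    msg <- c(msg, "ciLevel must be in (0, 1)")
  if (!is_scalar_num(object@baselineWindow) || object@baselineWindow <= 0)
    msg <- c(msg, "baselineWindow must be > 0")
  if (!is_scalar_num(object@reboundScanWindow) || object@reboundScanWindow <= 0)
    msg <- c(msg, "reboundScanWindow must be > 0")
  if (!is_scalar_num(object@suppressionAlpha) || object@suppressionAlpha <= 0 ||
      object@suppressionAlpha >= 1)
    msg <- c(msg, "suppressionAlpha must be in (0, 1)")
  if (!object@normalizationMode %in% c("subtract", "ratio"))
    msg <- c(msg, "normalizationMode must be 'subtract' or 'ratio'")
  if (!object@ciMethod %in% c("normal", "poisson_exact"))
    msg <- c(msg, "ciMethod must be 'normal' or 'poisson_exact'")
  if (object@adGapTolerance < 0L)
    msg <- c(msg, "adGapTolerance must be >= 0")
  if (!is_scalar_num(object@epsilonRate) || object@epsilonRate <= 0)
    msg <- c(msg, "epsilonRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Session: one animal's recording session
#'
#' Units (sorted spike trains), stimulus events, the animal's surgical
#' condition, and free-form metadata (the simulator stores each unit's
#' ground-truth generating profile there).
#'
#' @slot animalId character.
#' @slot condition `"sham"` or `"cci_ion"`.
#' @slot units list of [SpikeTrain-class] objects.
#' @slot events list of [StimulusEvent-class] objects, spaced >= 8 s apart.
#' @slot metadata free-form named list.
#' @export
setClass("Session",
  representation(animalId = "character", condition = "character",
                 units = "list", events = "list", metadata = "list"),
  prototype(metadata = list()))

setValidity("Session", function(object) {
  msg <- character()
  if (!is_scalar_chr(object@animalId) || !nzchar(object@animalId))
    msg <- c(msg, "animalId must be a non-empty string")
  if (!is_scalar_chr(object@condition) || !object@condition %in% CONDITIONS)
    msg <- c(msg, sprintf("condition must be one of: %s",
                          paste(CONDITIONS, collapse = ", ")))
  if (!all(vapply(object@units, is, logical(1), class2 = "SpikeTrain")))
    msg <- c(msg, "units must all be SpikeTrain objects")
  if (!all(vapply(object@events, is, logical(1), class2 = "StimulusEvent")))
    msg <- c(msg, "events must all be StimulusEvent objects")
  else if (length(object@events) && length(object@units)) {
    offs <- vapply(object@events, slot, numeric(1), name = "offset")
    durs <- vapply(object@units, slot, numeric(1), name = "duration")
    if (max(offs) > min(durs))
      msg <- c(msg, "every event must lie within every unit's duration")
    ons <- sort(vapply(object@events, slot, numeric(1), name = "onset"))
    if (length(ons) > 1L && any(diff(ons) < 8 - 1e-9))
      msg <- c(msg, "inter-stimulus spacing must be >= 8 s")
  }
  if (length(msg)) msg else TRUE
})

#' NeuronProfile: ground-truth generator parameters for one simulated unit
#'
#' Piecewise-constant firing-rate program for the inhomogeneous Poisson
#' simulator: baseline rate, an additive evoked gain during stimuli (excited
#' class) or a multiplicative retained fraction (suppressed class), and
#' post-offset after-discharge or rebound segments.
#'
#' @slot baselineRate Hz, >= 0 (0 encodes a spontaneously silent neuron).
#' @slot evokedGain additive Hz during the stimulus for the excited class.
#' @slot adDuration ground-truth after-discharge length in s (rate returns to
#'   baseline afterwards); 0 for nonresponsive neurons.
#' @slot adRate Hz during the after-discharge.
#' @slot responseClass `"excited"`, `"suppressed"` or `"nonresponsive"`.
#' @slot suppressionFraction fraction of baseline retained during stimuli for
#'   the suppressed class, in `[0, 1)`.
#' @slot reboundDuration,reboundRate post-offset rebound segment (suppressed
#'   class).
#' @slot adShape `"rectangular"` (constant adRate for adDuration) or
#'   `"exponential"` (rate decays exponentially toward baseline with time
#'   constant `adDuration`).
#' @export
setClass("NeuronProfile",
  representation(baselineRate = "numeric", evokedGain = "numeric",
                 adDuration = "numeric", adRate = "numeric",
                 responseClass = "character",
                 suppressionFraction = "numeric",
                 reboundDuration = "numeric", reboundRate = "numeric",
                 adShape = "character"),
  prototype(baselineRate = 1, evokedGain = 0, adDuration = 0, adRate = 0,
            responseClass = "nonresponsive", suppressionFraction = 0,
            reboundDuration = 0, reboundRate = 0, adShape = "rectangular"))

setValidity("NeuronProfile", function(object) {
  msg <- character()
  if (!is_scalar_num(object@baselineRate) || object@baselineRate < 0)
    msg <- c(msg, "baselineRate must be >= 0")
  if (!object@responseClass %in% RESPONSE_CLASSES)
    msg <- c(msg, sprintf("responseClass must be one of: %s",
                          paste(RESPONSE_CLASSES, collapse = ", ")))
  if (identical(object@responseClass, "suppressed") &&
      (object@suppressionFraction < 0 || object@suppressionFraction >= 1))
    msg <- c(msg, "suppressionFraction must be in [0, 1) for suppressed class")
  if (identical(object@responseClass, "nonresponsive") &&
      object@adDuration != 0)
    msg <- c(msg, "adDuration must be 0 for nonresponsive class")
  if (object@adDuration < 0 || object@reboundDuration < 0)
    msg <- c(msg, "durations must be >= 0")
  if (object@adRate < 0 || object@reboundRate < 0 ||
      object@baselineRate + object@evokedGain < 0)
    msg <- c(msg, "all firing rates must be >= 0")
  if (!object@adShape %in% c("rectangular", "exponential"))
    msg <- c(msg, "adShape must be 'rectangular' or 'exponential'")
  if (length(msg)) msg else TRUE
})

#' PopulationSpec: distributional description of a simulated population
#'
#' @slot nNeurons integer >= 1.
#' @slot condition `"sham"` or `"cci_ion"`.
#' @slot adIncidence probability a tactile-responsive neuron carries an
#'   after-discharge (ground truth).
#' @slot adDurationDist named list, e.g. `list(name = "uniform", min = .5,
#'   max = 3)` or `list(name = "exponential", mean = 1.5)`, for AD-positive
#'   neurons.
#' @slot silentFraction probability a neuron has zero baseline rate.
#' @slot offCellFraction probability a neuron is of the suppressed class.
#' @export
setClass("PopulationSpec",
  representation(nNeurons = "integer", condition = "character",
                 adIncidence = "numeric", adDurationDist = "list",
                 silentFraction = "numeric", offCellFraction = "numeric"),
  prototype(nNeurons = 1L, condition = "sham", adIncidence = 0,
            adDurationDist = list(name = "uniform", min = 0.5, max = 3),
            silentFraction = 0, offCellFraction = 0))

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (object@nNeurons < 1L) msg <- c(msg, "nNeurons must be >= 1")
  if (!object@condition %in% CONDITIONS)
    msg <- c(msg, "condition must be 'sham' or 'cci_ion'")
  for (p in c("adIncidence", "silentFraction", "offCellFraction")) {
    v <- slot(object, p)
    if (!is_scalar_num(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a probability in [0, 1]", p))
  }
  if (is.null(object@adDurationDist$name))
    msg <- c(msg, "adDurationDist must carry a 'name'")
  if (length(msg)) msg else TRUE
})

#' PsychometricProfile: latent psychometric function behind up-down testing
#'
#' Response probability at force f (grams) is
#' `plogis((log10(f) - log10(threshold50)) * slope)`.
#'
#' @slot threshold50 grams, > 0 (the 50% withdrawal threshold).
#' @slot slope dimensionless logistic slope on the log10-force axis, > 0.
#' @export
setClass("PsychometricProfile",
  representation(threshold50 = "numeric", slope = "numeric"),
  prototype(threshold50 = 5, slope = 10))

setValidity("PsychometricProfile", function(object) {
  msg <- character()
  if (!is_scalar_num(object@threshold50) || object@threshold50 <= 0)
    msg <- c(msg, "threshold50 must be > 0")
  if (!is_scalar_num(object@slope) || object@slope <= 0)
    msg <- c(msg, "slope must be > 0")
  if (length(msg)) msg else TRUE
})

#' Psth: trial-aligned binned spike counts with baseline statistics
#'
#' Counts are per trial and per bin (half-open bins, aligned to stimulus
#' onset at time 0). Baseline statistics are computed over the pooled
#' per-trial counts of all baseline bins, in Hz, and the confidence band
#' (default 99%) is what all detection criteria compare against.
#'
#' @slot binEdges numeric of length nBins + 1, seconds relative to onset.
#' @slot counts integer matrix, nTrials x nBins.
#' @slot nTrials integer.
#' @slot binWidth numeric s.
#' @slot stimDuration numeric s (common to the aligned events).
#' @slot baselineMean,baselineSd,ciLower,ciUpper numeric Hz; `ciLower` is
#'   floored at 0.
#' @slot ciLevel numeric, the two-sided level used.
#' @slot ciMethod `"normal"` or `"poisson_exact"`.
#' @export
setClass("Psth",
  representation(binEdges = "numeric", counts = "matrix", nTrials = "integer",
                 binWidth = "numeric", stimDuration = "numeric",
                 baselineMean = "numeric", baselineSd = "numeric",
                 ciLower = "numeric", ciUpper = "numeric",
                 ciLevel = "numeric", ciMethod = "character"))

setValidity("Psth", function(object) {
  msg <- character()
  if (length(object@binEdges) != ncol(object@counts) + 1L)
    msg <- c(msg, "binEdges must have ncol(counts) + 1 entries")
  if (nrow(object@counts) != object@nTrials)
    msg <- c(msg, "counts must have one row per trial")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(object@ciLower) && length(object@ciUpper)) {
    if (object@ciLower > object@baselineMean + 1e-9 ||
        object@baselineMean > object@ciUpper + 1e-9)
      msg <- c(msg, "need ciLower <= baselineMean <= ciUpper")
    if (object@ciLower < 0) msg <- c(msg, "ciLower must be floored at 0")
  }
  if (length(msg)) msg else TRUE
})

#' DetectionResult: per-unit response classification
#'
#' After-discharge presence requires a supra-band run of at least the
#' configured minimum duration (500 ms) starting at the first post-offset
#' bin; shorter runs are reported as 0 in `adDuration` (the raw run length
#' is kept in `diagnostics$adRawRun`). Rebound fields are populated only for
#' suppressed units.
#'
#' @slot unitId character.
#' @slot responsive logical.
#' @slot responseSign `"excited"`, `"suppressed"` or `"none"`.
#' @slot adPresent logical; `adDuration` s (0 when absent).
#' @slot suppressionP paired t-test p-value (NA when not computed).
#' @slot reboundPresent logical; `reboundDuration` s.
#' @slot diagnostics free-form list (raw run lengths, degenerate-variance
#'   flags).
#' @export
setClass("DetectionResult",
  representation(unitId = "character", responsive = "logical",
                 responseSign = "character", adPresent = "logical",
                 adDuration = "numeric", suppressionP = "numeric",
                 reboundPresent = "logical", reboundDuration = "numeric",
                 diagnostics = "list"),
  prototype(suppressionP = NA_real_, reboundPresent = FALSE,
            reboundDuration = 0, diagnostics = list()))

setValidity("DetectionResult", function(object) {
  msg <- character()
  if (!object@responseSign %in% c("excited", "suppressed", "none"))
    msg <- c(msg, "responseSign must be 'excited', 'suppressed' or 'none'")
  if (!object@adPresent && object@adDuration != 0)
    msg <- c(msg, "adDuration must be 0 when adPresent is FALSE")
  if (object@adDuration < 0 || object@reboundDuration < 0)
    msg <- c(msg, "durations must be >= 0")
  if (object@reboundPresent && !identical(object@responseSign, "suppressed"))
    msg <- c(msg, "rebound fields are only populated for suppressed units")
  if (length(msg)) msg else TRUE
})

#' GroupComparison: one between-group test with summaries
#'
#' @slot testName character (e.g. `"mann_whitney_u"`).
#' @slot statistic numeric test statistic (U, chi-square, ...).
#' @slot pValue two-tailed p-value in `[0, 1]`.
#' @slot effectSize Cohen's d where applicable, else NA.
#' @slot groupSummaries data.frame with columns `group`, `n`, `median`,
#'   `ciLow`, `ciHigh`, `ciMethod`.
#' @export
setClass("GroupComparison",
  representation(testName = "character", statistic = "numeric",
                 pValue = "numeric", effectSize = "numeric",
                 groupSummaries = "data.frame"),
  prototype(effectSize = NA_real_,
            groupSummaries = data.frame(group = character(), n = integer(),
                                        median = numeric(), ciLow = numeric(),
                                        ciHigh = numeric(),
                                        ciMethod = character())))

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must be in [0, 1]")
  gs <- object@groupSummaries
  if (nrow(gs)) {
    if (any(gs$n < 1)) msg <- c(msg, "each group must have n >= 1")
    ok <- is.na(gs$ciLow) | is.na(gs$ciHigh) |
      (gs$ciLow <= gs$median + 1e-12 & gs$median <= gs$ciHigh + 1e-12)
    if (!all(ok)) msg <- c(msg, "need ciLow <= median <= ciHigh")
  }
  if (length(msg)) msg else TRUE
})
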
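setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes over %.1f s (%.3f Hz)%s\n",
              object@unitId, length(object@spikeTimes), object@duration,
              length(object@spikeTimes) / object@duration,
              if (nzchar(object@regionLabel))
                sprintf(" [%s]", object@regionLabel) else ""))
})

setMethod("show", "StimulusEvent", function(object) {
  cat(sprintf("StimulusEvent: %s at %s, [%.2f, %.2f) s%s\n",
              object@modality, object@site, object@onset, object@offset,
              if (nrow(object@forceTrace))
                sprintf(", %d force samples", nrow(object@forceTrace))
              else ""))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat(sprintf(paste0(
    "AnalysisConfig: bin %.3g s | baseline %.3g s | CI %.2f (%s)\n",
    "  AD >= %.3g s | rebound scan %.3g s | suppression alpha %.3g\n",
    "  normalization '%s'\n"),
    object@binWidth, object@baselineWindow, object@ciLevel,
    object@ciMethod, object@adMinDuration, object@reboundScanWindow,
    object@suppressionAlpha, object@normalizationMode))
})

setMethod("show", "Session", function(object) {
  cat(sprintf("Session '%s' (%s): %d units, %d events\n",
              object@animalId, object@condition, length(object@units),
              length(object@events)))
})

setMethod("show", "Psth", function(object) {
  cat(sprintf(paste0(
    "Psth: %d trials x %d bins (%.3g s), window [%.1f, %.1f] s\n",
    "  baseline %.3f Hz (sd %.3f), %.0f%% band [%.3f, %.3f] Hz (%s)\n"),
    object@nTrials, ncol(object@counts), object@binWidth,
    min(object@binEdges), max(object@binEdges), object@baselineMean,
    object@baselineSd, 100 * object@ciLevel, object@ciLower,
    object@ciUpper, object@ciMethod))
})

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf(paste0(
    "DetectionResult '%s': %s%s | AD %s (%.2f s) | suppression p = %s",
    " | rebound %s (%.2f s)\n"),
    object@unitId, if (object@responsive) "responsive " else
      "nonresponsive ", object@responseSign,
    if (object@adPresent) "present" else "absent", object@adDuration,
    format.pval(object@suppressionP, digits = 3),
    if (object@reboundPresent) "present" else "absent",
    object@reboundDuration))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison [%s]: statistic = %.4g, p = %s%s\n",
              object@testName, object@statistic,
              format.pval(object@pValue, digits = 3),
              if (!is.na(object@effectSize))
                sprintf(", d = %.3g", object@effectSize) else ""))
  gs <- object@groupSummaries
  for (i in seq_len(nrow(gs)))
    cat(sprintf("  %s: n = %d, median = %.4g [%.4g, %.4g] (%s)\n",
                gs$group[i], gs$n[i], gs$median[i], gs$ciLow[i],
                gs$ciHigh[i], gs$ciMethod[i]))
})

setMethod("show", "NeuronProfile", function(object) {
  cat(sprintf(paste0(
    "NeuronProfile (%s): baseline %.3g Hz, gain %.3g Hz, AD %.3g s @",
    " %.3g Hz (%s)\n"),
    object@responseClass, object@baselineRate, object@evokedGain,
    object@adDuration, object@adRate, object@adShape))
})

setMethod("show", "PopulationSpec", function(object) {
  cat(sprintf(paste0(
    "PopulationSpec (%s): n = %d, AD incidence %.3f, silent %.2f,",
    " OFF %.2f\n"),
    object@condition, object@nNeurons, object@adIncidence,
    object@silentFraction, object@offCellFraction))
})

setMethod("show", "PsychometricProfile", function(object) {
  cat(sprintf("PsychometricProfile: threshold50 = %.3g g, slope = %.3g\n",
              object@threshold50, object@slope))
})
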
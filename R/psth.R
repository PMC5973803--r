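#' Build a peristimulus time histogram
#'
#' Aligns the spike train to each event onset and bins spikes into uniform
#' half-open bins of `config@binWidth` over `[-pre, post)` seconds around
#' onset (a spike exactly on a bin edge falls in the right-hand bin). The
#' baseline confidence band is computed over the `pre` window (see
#' [baselineBand()]) and stored on the object.
#'
#' @param train a [SpikeTrain-class].
#' @param events list of [StimulusEvent-class] to align to; all must share
#'   the same stimulus duration.
#' @param window numeric `c(pre, post)` in seconds (both positive); defaults
#'   to `c(config@baselineWindow, stimulus length + config@reboundScanWindow)`.
#' @param config an [AnalysisConfig-class].
#' @return a [Psth-class]. The sum of all counts equals the number of spikes
#'   falling in the aligned windows.
#' @examples
#' ev <- StimulusEvent(10, 13, modality = "thermal")
#' tr <- SpikeTrain("u1", c(9.0, 10.05, 10.15, 10.15, 10.95), duration = 40)
#' p <- buildPsth(tr, list(ev), config = AnalysisConfig())
#' sum(psthCounts(p))
#' @export
buildPsth <- function(train, events, window = NULL,
                      config = AnalysisConfig()) {
  validObject(train); validObject(config)
  if (!length(events)) stop2("no events to align to")
  stimLens <- vapply(events, function(e) e@offset - e@onset, numeric(1))
  if (diff(range(stimLens)) > 1e-9)
    stop2("events must share a common stimulus duration for PSTH alignment")
  stimLen <- stimLens[1]
  if (is.null(window))
    window <- c(config@baselineWindow, stimLen + config@reboundScanWindow)
  pre <- window[1]; post <- window[2]
  if (pre <= 0 || post <= 0) stop2("window components must be positive")
  onsets <- vapply(events, slot, numeric(1), "onset")
  ## aligned windows must lie inside the recording and not overlap
  if (any(onsets - pre < -1e-9) ||
      any(onsets + post > train@duration + 1e-9))
    stop2("aligned window exceeds the recording for unit '", train@unitId,
          "'")
  o <- order(onsets)
  if (length(onsets) > 1L) {
    starts <- onsets[o] - pre; ends <- onsets[o] + post
    bad <- which(starts[-1] < ends[-length(ends)] - 1e-9)
    if (length(bad))
      stop2(sprintf(
        "aligned windows overlap for events %d and %d (after expansion)",
        o[bad[1]], o[bad[1] + 1L]))
  }
  nBins <- round((pre + post) / config@binWidth)
  if (abs(nBins * config@binWidth - (pre + post)) > 1e-6)
    stop2("window length must be an integer multiple of binWidth")
  edges <- -pre + config@binWidth * (0:nBins)
  counts <- matrix(0L, nrow = length(events), ncol = nBins)
  for (t in seq_along(events)) {
    rel <- train@spikeTimes - onsets[t]
    rel <- rel[rel >= -pre - 1e-12 & rel < post - 1e-12]
    if (length(rel)) {
      ## small forward tolerance keeps an edge spike in its right-hand bin
      ## despite floating division
      b <- floor((rel + pre) / config@binWidth + 1e-9) + 1L
      b <- b[b >= 1L & b <= nBins]
      tb <- tabulate(b, nbins = nBins)
      counts[t, ] <- as.integer(tb)
    }
  }
  psth <- new("Psth", binEdges = edges, counts = counts,
              nTrials = length(events), binWidth = config@binWidth,
              stimDuration = stimLen, baselineMean = 0, baselineSd = 0,
              ciLower = 0, ciUpper = 0, ciLevel = config@ciLevel,
              ciMethod = config@ciMethod)
  bb <- baselineBand(psth, config)
  psth@baselineMean <- bb[["baselineMean"]]
  psth@baselineSd <- bb[["baselineSd"]]
  psth@ciLower <- bb[["ciLower"]]
  psth@ciUpper <- bb[["ciUpper"]]
  validObject(psth)
  psth
}

#' Baseline statistics and confidence band of a PSTH
#'
#' The baseline window is the pre-onset part of the aligned window (all bins
#' ending at or before time 0). Mean and SD are computed over the pooled
#' per-trial, per-bin counts of all baseline bins, converted to Hz. The
#' band is `mean ± z((1 + level)/2) · sd` with the lower edge floored at 0
#' (`"normal"` method), or the 0.5th/99.5th Poisson percentiles of
#' `Poisson(baselineMean · binWidth)` converted to Hz (`"poisson_exact"`).
#'
#' @param psth a [Psth-class].
#' @param config an [AnalysisConfig-class].
#' @return named numeric: `baselineMean`, `baselineSd`, `ciLower`,
#'   `ciUpper` (all Hz).
#' @export
baselineBand <- function(psth, config = AnalysisConfig()) {
  baseBins <- which(psth@binEdges[-1] <= 1e-12)
  if (!length(baseBins)) stop2("PSTH has no baseline bins before onset")
  pooled <- as.vector(psth@counts[, baseBins, drop = FALSE])
  if (length(pooled) < 10L)
    warning("fewer than 10 pooled baseline bins; band is unreliable")
  m <- mean(pooled) / psth@binWidth
  s <- sd(pooled) / psth@binWidth
  if (is.na(s)) s <- 0
  alpha <- (1 - config@ciLevel) / 2
  if (identical(config@ciMethod, "poisson_exact")) {
    lam <- m * psth@binWidth
    lo <- qpois(alpha, lam) / psth@binWidth
    hi <- qpois(1 - alpha, lam) / psth@binWidth
  } else {
    z <- qnorm(1 - alpha)
    lo <- m - z * s
    hi <- m + z * s
  }
  c(baselineMean = m, baselineSd = s, ciLower = max(0, lo), ciUpper = hi)
}

#' Serialize a PSTH to a plain table
#'
#' One row per bin: bin start/end (s relative to onset), per-trial counts,
#' and the trial-averaged rate in Hz — the layout used for PSTH plotting.
#'
#' @param psth a [Psth-class].
#' @return a data.frame.
#' @export
psthTable <- function(psth) {
  nBins <- ncol(psth@counts)
  tab <- data.frame(bin_start = psth@binEdges[-(nBins + 1L)],
                    bin_end = psth@binEdges[-1])
  for (t in seq_len(psth@nTrials))
    tab[[sprintf("trial_%d", t)]] <- psth@counts[t, ]
  tab$mean_rate_hz <- meanRatePerBin(psth)
  tab
}
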
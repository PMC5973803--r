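## shared fixtures: a small protocol and deterministic trains built in code

quickConfig <- function(...) AnalysisConfig(...)

quickProtocol <- function(nTrials = 5, stimLength = 3, maxAd = 3,
                          modality = "mechanical") {
  defaultProtocol(nTrials = nTrials, stimLength = stimLength,
                  maxAdDuration = maxAd, modality = modality, seed = 11L)
}

protocolDuration <- function(protocol, config = AnalysisConfig(),
                             maxAd = 3) {
  max(vapply(protocol, function(e) e@offset, numeric(1))) +
    config@reboundScanWindow + maxAd + 1
}

## a spike train realizing exact per-window counts: spikes uniformly spread
## (deterministically) inside each requested window
trainFromCounts <- function(windows, counts, duration, unitId = "fix") {
  spikes <- unlist(lapply(seq_along(counts), function(i) {
    n <- counts[i]
    if (n == 0) return(numeric())
    a <- windows[[i]][1]; b <- windows[[i]][2]
    a + (seq_len(n) - 0.5) / n * (b - a)
  }))
  SpikeTrain(unitId, sort(spikes), duration)
}
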
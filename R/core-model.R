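#' Construct a SpikeTrain
#'
#' @param unitId unit identifier.
#' @param spikeTimes numeric vector of spike times in seconds from recording
#'   start, non-decreasing, within `[0, duration]`.
#' @param duration recording duration in seconds.
#' @param regionLabel optional anatomical label.
#' @return a validated [SpikeTrain-class].
#' @examples
#' SpikeTrain("u1", c(0.5, 1.2, 2.9), duration = 180)
#' @export
SpikeTrain <- function(unitId, spikeTimes = numeric(), duration,
                       regionLabel = "") {
  new("SpikeTrain", unitId = as.character(unitId),
      spikeTimes = as.numeric(spikeTimes), duration = as.numeric(duration),
      regionLabel = as.character(regionLabel))
}

#' Construct a StimulusEvent
#'
#' @param onset,offset window in seconds (half-open `[onset, offset)`).
#' @param modality `"mechanical"` or `"thermal"`.
#' @param site stimulation site label.
#' @param forceTrace data.frame with `time` (s) and `force` (g); required for
#'   mechanical events.
#' @param laserParams optional named list (`dutyOn`, `dutyOff`, `power`).
#' @return a validated [StimulusEvent-class].
#' @export
StimulusEvent <- function(onset, offset = onset + 3, modality = "mechanical",
                          site = "face_ipsi", forceTrace = NULL,
                          laserParams = list()) {
  if (is.null(forceTrace))
    forceTrace <- data.frame(time = numeric(), force = numeric())
  new("StimulusEvent", onset = as.numeric(onset), offset = as.numeric(offset),
      modality = modality, site = site, forceTrace = forceTrace,
      laserParams = laserParams)
}

#' Construct an AnalysisConfig
#'
#' `adMinDuration` is snapped to the nearest integer multiple of `binWidth`
#' so the after-discharge criterion is expressible in whole bins; a warning
#' is emitted if snapping changed the requested value.
#'
#' @param binWidth,baselineWindow,ciLevel,adMinDuration,reboundScanWindow,suppressionAlpha,normalizationMode,ciMethod,adGapTolerance,epsilonRate,rngSeed
#'   see [AnalysisConfig-class].
#' @return a validated [AnalysisConfig-class].
#' @examples
#' cfg <- AnalysisConfig()                # the default criteria
#' cfg2 <- AnalysisConfig(binWidth = 0.05, ciMethod = "poisson_exact")
#' @export
AnalysisConfig <- function(binWidth = 0.1, baselineWindow = 5,
                           ciLevel = 0.99, adMinDuration = 0.5,
                           reboundScanWindow = 10, suppressionAlpha = 0.05,
                           normalizationMode = "subtract",
                           ciMethod = "normal", adGapTolerance = 0L,
                           epsilonRate = 0.1, rngSeed = NA_integer_) {
  snapped <- round(adMinDuration / binWidth) * binWidth
  if (abs(snapped - adMinDuration) > 1e-9) {
    warning(sprintf(
      "adMinDuration %.4g s snapped to %.4g s (nearest multiple of binWidth)",
      adMinDuration, snapped))
    adMinDuration <- snapped
  }
  new("AnalysisConfig", binWidth = binWidth, baselineWindow = baselineWindow,
      ciLevel = ciLevel, adMinDuration = adMinDuration,
      reboundScanWindow = reboundScanWindow,
      suppressionAlpha = suppressionAlpha,
      normalizationMode = normalizationMode, ciMethod = ciMethod,
      adGapTolerance = as.integer(adGapTolerance), epsilonRate = epsilonRate,
      rngSeed = as.integer(rngSeed))
}

#' Read an AnalysisConfig from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file with keys named as the [AnalysisConfig()] arguments.
#' @return an [AnalysisConfig-class].
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(AnalysisConfig))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop2("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(AnalysisConfig, vals)
}

#' Construct a Session
#'
#' @param animalId animal identifier.
#' @param condition `"sham"` or `"cci_ion"`.
#' @param units list of [SpikeTrain-class].
#' @param events list of [StimulusEvent-class].
#' @param metadata free-form named list.
#' @return a validated [Session-class].
#' @export
Session <- function(animalId, condition, units = list(), events = list(),
                    metadata = list()) {
  new("Session", animalId = as.character(animalId), condition = condition,
      units = units, events = events, metadata = metadata)
}

## ---- session manifest I/O -------------------------------------------------
## Dialect: per-unit spike times one per line (plain text, full precision),
## events as a TSV with named columns, manifest as YAML. Force traces are
## stored inline in the event table as "t:f;t:f;..." pairs so one table
## carries the whole protocol.

serializeForceTrace <- function(ft) {
  if (nrow(ft) == 0L) return("")
  paste(sprintf("%.17g:%.17g", ft$time, ft$force), collapse = ";")
}

deserializeForceTrace <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(time = numeric(), force = numeric()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(time = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
             force = vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
}

#' Write a Session to disk
#'
#' Writes one spike-time file per unit (one timestamp per line, full
#' precision), a tab-separated event table, and a YAML manifest tying them
#' together. The output is read back by [readSession()].
#'
#' @param session a [Session-class].
#' @param outDir directory to create/write into.
#' @return the manifest path, invisibly usable by [readSession()].
#' @export
writeSession <- function(session, outDir) {
  validObject(session)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop2("cannot create directory: ", outDir)
  unitEntries <- lapply(session@units, function(u) {
    fn <- sprintf("unit_%s.txt", u@unitId)
    writeLines(sprintf("%.17g", u@spikeTimes), file.path(outDir, fn))
    list(unit_id = u@unitId, file = fn, duration = u@duration,
         region_label = u@regionLabel)
  })
  evTab <- data.frame(
    onset = vapply(session@events, slot, numeric(1), "onset"),
    offset = vapply(session@events, slot, numeric(1), "offset"),
    modality = vapply(session@events, slot, character(1), "modality"),
    site = vapply(session@events, slot, character(1), "site"),
    force_trace = vapply(session@events, function(e)
      serializeForceTrace(e@forceTrace), character(1)),
    laser_duty_on = vapply(session@events, function(e)
      if (length(e@laserParams)) e@laserParams$dutyOn else NA_real_,
      numeric(1)),
    laser_duty_off = vapply(session@events, function(e)
      if (length(e@laserParams)) e@laserParams$dutyOff else NA_real_,
      numeric(1)),
    laser_power = vapply(session@events, function(e)
      if (length(e@laserParams)) e@laserParams$power else NA_real_,
      numeric(1)),
    stringsAsFactors = FALSE)
  evFile <- "events.tsv"
  ## full-precision numeric serialization
  evOut <- evTab
  for (cc in c("onset", "offset", "laser_duty_on", "laser_duty_off",
               "laser_power"))
    evOut[[cc]] <- sprintf("%.17g", evTab[[cc]])
  write.table(evOut, file.path(outDir, evFile), sep = "\t", row.names = FALSE,
              quote = FALSE)
  manifest <- list(
    animal_id = session@animalId,
    condition = session@condition,
    events_file = evFile,
    units = unitEntries,
    metadata = session@metadata)
  manifestPath <- file.path(outDir, "session.yaml")
  yaml::write_yaml(manifest, manifestPath, precision = 17)
  manifestPath
}

#' Read a Session from a manifest
#'
#' @param manifestPath path to a `session.yaml` written by [writeSession()]
#'   (or hand-authored in the same dialect).
#' @return a fully validated [Session-class]; invariant violations in the
#'   referenced files raise validation errors naming the offending unit.
#' @export
readSession <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop2("manifest not found: ", manifestPath)
  man <- yaml::read_yaml(manifestPath)
  base <- dirname(manifestPath)
  for (key in c("animal_id", "condition", "events_file"))
    if (is.null(man[[key]])) stop2("manifest missing key: ", key)
  if (!man$condition %in% CONDITIONS)
    stop2("unknown condition label: '", man$condition, "'")
  units <- lapply(man$units, function(u) {
    f <- file.path(base, u$file)
    if (!file.exists(f)) stop2("spike-time file not found: ", f)
    lines <- readLines(f)
    lines <- lines[nzchar(trimws(lines))]
    st <- as.numeric(lines)
    if (anyNA(st)) stop2("non-numeric spike time in ", f)
    SpikeTrain(u$unit_id, st, duration = u$duration,
               regionLabel = if (is.null(u$region_label)) "" else
                 u$region_label)
  })
  evFile <- file.path(base, man$events_file)
  if (!file.exists(evFile)) stop2("event table not found: ", evFile)
  evTab <- read.table(evFile, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = c(onset = "numeric", offset = "numeric",
                                     modality = "character",
                                     site = "character",
                                     force_trace = "character"))
  events <- lapply(seq_len(nrow(evTab)), function(i) {
    lp <- list()
    if (!is.na(evTab$laser_power[i]))
      lp <- list(dutyOn = evTab$laser_duty_on[i],
                 dutyOff = evTab$laser_duty_off[i],
                 power = evTab$laser_power[i])
    StimulusEvent(onset = evTab$onset[i], offset = evTab$offset[i],
                  modality = evTab$modality[i], site = evTab$site[i],
                  forceTrace = deserializeForceTrace(evTab$force_trace[i]),
                  laserParams = lp)
  })
  meta <- if (is.null(man$metadata)) list() else man$metadata
  sess <- Session(man$animal_id, man$condition, units = units,
                  events = events, metadata = meta)
  pb_log(sprintf("read session '%s' (%s): %d units, %d events",
                 sess@animalId, sess@condition, length(units),
                 length(events)))
  sess
}
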
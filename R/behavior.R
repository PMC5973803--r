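#' Default von Frey filament ladders
#'
#' Approximately log-spaced filament sets covering 0.4–26 g for the face
#' and 2–60 g for the hind paw. The exact set in use is an input; these are
#' conventional defaults.
#'
#' @param site `"face"` or `"hindpaw"`.
#' @return numeric vector of forces in grams, strictly increasing.
#' @export
defaultLadder <- function(site = c("face", "hindpaw")) {
  site <- match.arg(site)
  switch(site,
         face = c(0.4, 0.6, 1, 2, 4, 6, 8, 15, 26),
         hindpaw = c(2, 4, 6, 8, 15, 26, 40, 60))
}

#' Assemble an up-down testing record
#'
#' @param ladder strictly increasing filament forces (g).
#' @param indices 1-based filament index per stimulus.
#' @param responses logical withdrawal response per stimulus.
#' @param side,site optional labels.
#' @return a list of class `UpDownRecord`. Sequences outside 6–20 stimuli
#'   trigger a warning (10–12 is typical), not an error.
#' @export
upDownRecord <- function(ladder, indices, responses, side = "ipsi",
                         site = "face") {
  if (is.unsorted(ladder, strictly = TRUE))
    stop2("ladder must be strictly increasing")
  if (length(indices) != length(responses))
    stop2("indices and responses must have equal length")
  if (!length(indices)) stop2("empty up-down sequence")
  if (any(indices < 1L | indices > length(ladder)))
    stop2("filament index outside the ladder")
  if (length(indices) < 6L || length(indices) > 20L)
    warning(sprintf("up-down sequence of length %d (expected ~10-12)",
                    length(indices)))
  structure(list(ladder = ladder, indices = as.integer(indices),
                 responses = as.logical(responses), side = side,
                 site = site),
            class = "UpDownRecord")
}

## Staircase coefficient for a terminal response pattern.
##
## The pattern is the O/X string (O = no response/step up, X = response/
## step down) starting at the trial before the first response change. The
## coefficient k is obtained by maximum likelihood under the model the
## small-sample staircase tables were computed for: a normal tolerance
## distribution on the (log) stimulus axis with SD equal to the step size.
## With stimulus levels expressed in step units (x1 = 0, down after X, up
## after O), k = muHat - xFinal, so the estimate is Xf + k*delta on the
## log10-force scale. The two-trial patterns give k = -0.5 ("OX") and
## +0.5 ("XO"): the midpoint rule.
computeUpdownK <- function(pattern) {
  resp <- strsplit(pattern, "")[[1]]
  if (!all(resp %in% c("O", "X"))) stop2("pattern must use only O and X")
  n <- length(resp)
  if (n < 2L) stop2("pattern needs at least 2 trials")
  x <- numeric(n); x[1] <- 0
  for (i in seq_len(n - 1L))
    x[i + 1L] <- x[i] + if (resp[i] == "X") -1 else 1
  isX <- resp == "X"
  negLogLik <- function(mu) {
    p <- pnorm(x - mu)   # response probability at level x, sigma = 1
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(log(ifelse(isX, p, 1 - p)))
  }
  opt <- optimize(negLogLik, interval = c(min(x) - 6, max(x) + 6),
                  tol = 1e-9)
  opt$minimum - x[n]
}

## cached k table, loaded from the shipped plain-text table when available
.kTableEnv <- new.env(parent = emptyenv())

updownKTable <- function() {
  if (is.null(.kTableEnv$tab)) {
    f <- system.file("extdata", "updown_k_table.tsv", package = "pbspike")
    if (nzchar(f) && file.exists(f)) {
      tab <- read.table(f, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE, comment.char = "#")
      .kTableEnv$tab <- stats::setNames(tab$k, tab$pattern)
    } else {
      .kTableEnv$tab <- numeric()
    }
  }
  .kTableEnv$tab
}

dixonK <- function(pattern) {
  tab <- updownKTable()
  if (pattern %in% names(tab)) return(unname(tab[[pattern]]))
  computeUpdownK(pattern)
}

#' Up-down 50% withdrawal threshold
#'
#' Implements the standard small-sample staircase (up-down) estimator on a
#' log-spaced filament ladder: `threshold = 10^(Xf + k * delta)` grams,
#' where `Xf` is log10 of the final filament force, `delta` the mean log10
#' step of the ladder, and `k` the tabulated staircase coefficient for the
#' terminal response pattern (the responses from the trial before the first
#' change onward, at most the last 6). Sequences with responses at every
#' trial return the ladder minimum; sequences with no response anywhere
#' return the ladder maximum (pinned convention).
#'
#' @param record an `UpDownRecord` from [upDownRecord()], or a data.frame
#'   with columns `index` and `response` plus a `ladder` argument.
#' @param ladder required when `record` is a data.frame.
#' @return threshold in grams.
#' @examples
#' lad <- defaultLadder("face")
#' rec <- upDownRecord(lad, c(5, 4, 5, 4, 5, 4),
#'                     c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
#' updownThreshold(rec)
#' @export
updownThreshold <- function(record, ladder = NULL) {
  if (is.data.frame(record)) {
    if (is.null(ladder)) stop2("ladder required with a data.frame record")
    record <- suppressWarnings(
      upDownRecord(ladder, record$index, record$response))
  }
  if (!inherits(record, "UpDownRecord")) stop2("not an UpDownRecord")
  r <- record$responses
  if (!length(r)) stop2("empty up-down sequence")
  if (all(r)) return(min(record$ladder))
  if (!any(r)) return(max(record$ladder))
  chg <- which(diff(r) != 0)[1]      # r[chg] != r[chg + 1]
  keep <- seq.int(chg, length(r))
  if (length(keep) > 6L) keep <- keep[(length(keep) - 5L):length(keep)]
  pattern <- paste(ifelse(r[keep], "X", "O"), collapse = "")
  delta <- mean(diff(log10(record$ladder)))
  xf <- log10(record$ladder[record$indices[length(r)]])
  10^(xf + dixonK(pattern) * delta)
}

#' Mean grimace-scale score
#'
#' Arithmetic mean over all non-missing image × action-unit scores. Scores
#' are 0, 1 or 2 over the four facial action units (orbital tightening,
#' nose-cheek bulge, whisker tightening, ear position), typically across 10
#' images per animal.
#'
#' @param scores numeric matrix or data.frame (images × 4 action units);
#'   NA marks a unit that could not be scored.
#' @return mean score in `[0, 2]`.
#' @export
grimaceMean <- function(scores) {
  m <- as.matrix(scores)
  if (ncol(m) != 4L)
    stop2("grimace records need exactly 4 action-unit columns")
  vals <- m[!is.na(m)]
  if (!length(vals)) stop2("all action-unit scores are missing")
  if (!all(vals %in% c(0, 1, 2)))
    stop2("grimace scores must be 0, 1 or 2")
  mean(vals)
}

#' Mean Hargreaves withdrawal latency
#'
#' @param latencies positive withdrawal latencies in seconds (5 trials
#'   expected; any positive number of trials is accepted).
#' @return arithmetic mean latency in s.
#' @export
hargreavesLatency <- function(latencies) {
  if (!length(latencies)) stop2("need at least one latency")
  if (any(latencies <= 0)) stop2("latencies must be positive")
  if (length(latencies) != 5L)
    warning(sprintf("%d latencies provided (5 expected)",
                    length(latencies)))
  mean(latencies)
}
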
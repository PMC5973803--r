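#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rpois runif rbinom rnorm qnorm qpois t.test wilcox.test
#'   binom.test chisq.test median sd qbinom pbinom dbinom plogis quantile
#'   optimize complete.cases
#' @importFrom utils read.table write.table packageVersion
NULL

## internal logging: progress/warnings to stderr, controlled by option
pb_log <- function(..., verbose = getOption("pbspike.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}

## scalar checks used throughout validity methods and constructors
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stop2 <- function(...) stop(..., call. = FALSE)

## deterministic child-seed derivation: one user seed fans out to stages/units
## without collisions; kept below 2^31 - 1 so it is a valid R integer seed.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(index)) %%
               2147483647)
}

## run code with a locally-set RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## trapezoidal rule on possibly irregular samples
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop2("need at least 2 samples for trapezoidal integration")
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
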
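#' Mann-Whitney U test with group summaries
#'
#' The U statistic is the smaller of the two groups' U values, computed
#' from midranks (so ties are handled). The two-tailed p-value is exact (by
#' enumeration of rank assignments) when `nA + nB <= 20` and the data are
#' tie-free, otherwise a normal approximation with tie and continuity
#' correction is used. Group summaries are medians with distribution-free
#' 95% CIs; Cohen's d is attached when both groups have n >= 2 and a
#' nonzero pooled SD.
#'
#' @param groupA,groupB numeric vectors (non-empty).
#' @param labels length-2 character, names for the two groups.
#' @param ciLevel level for the median CIs (default 0.95).
#' @return a [GroupComparison-class].
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5))   # complete separation: U = 0
#' @export
mannWhitneyU <- function(groupA, groupB, labels = c("A", "B"),
                         ciLevel = 0.95) {
  if (!length(groupA) || !length(groupB)) stop2("both groups must be non-empty")
  nA <- length(groupA); nB <- length(groupB)
  rk <- rank(c(groupA, groupB))           # midranks
  rA <- sum(rk[seq_len(nA)])
  uA <- rA - nA * (nA + 1) / 2            # U for group A
  uB <- nA * nB - uA
  u <- min(uA, uB)
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  exact <- (nA + nB <= 20) && !ties
  p <- suppressWarnings(
    wilcox.test(groupA, groupB, exact = exact, correct = TRUE)$p.value)
  d <- if (nA >= 2 && nB >= 2 && sd(groupA) + sd(groupB) > 0) {
    tryCatch(cohensD(groupA, groupB), error = function(e) NA_real_)
  } else NA_real_
  gs <- rbind(groupSummaryRow(labels[1], groupA, ciLevel),
              groupSummaryRow(labels[2], groupB, ciLevel))
  new("GroupComparison", testName = "mann_whitney_u", statistic = u,
      pValue = min(1, p), effectSize = d, groupSummaries = gs)
}

groupSummaryRow <- function(label, values, ciLevel = 0.95) {
  ci <- suppressWarnings(medianCI(values, level = ciLevel))
  data.frame(group = label, n = length(values), median = ci$median,
             ciLow = ci$ciLow, ciHigh = ci$ciHigh, ciMethod = ci$method,
             stringsAsFactors = FALSE)
}

#' Median with a 95% confidence interval
#'
#' Default method is distribution-free order statistics: the CI endpoints
#' are the j-th smallest and j-th largest observations with j chosen as the
#' largest rank whose binomial tail `P(Bin(n, 1/2) < j) <= (1-level)/2`, so
#' achieved coverage is at least the nominal level. A seeded
#' bootstrap-percentile alternative is available. With n < 6 no
#' order-statistic 95% CI exists; the full data range is returned with a
#' coverage warning.
#'
#' @param values numeric, n >= 1.
#' @param level confidence level (default 0.95).
#' @param method `"order"` or `"bootstrap"`.
#' @param nBoot bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return list: `median`, `ciLow`, `ciHigh`, `method`, `coverage`
#'   (achieved coverage for the order method, NA otherwise).
#' @export
medianCI <- function(values, level = 0.95, method = c("order", "bootstrap"),
                     nBoot = 2000L, seed = 1L) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 1L) stop2("need at least one value")
  med <- median(values)
  if (identical(method, "bootstrap")) {
    bs <- withSeed(seed, {
      vapply(seq_len(nBoot), function(i)
        median(sample(values, n, replace = TRUE)), numeric(1))
    })
    qs <- quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    return(list(median = med, ciLow = qs[1], ciHigh = qs[2],
                method = "bootstrap", coverage = NA_real_))
  }
  s <- sort(values)
  alpha <- (1 - level) / 2
  j <- qbinom(alpha, n, 0.5)      # largest j with P(X < j) <= alpha
  if (pbinom(j - 1, n, 0.5) > alpha) j <- j - 1L   # guard qbinom convention
  if (n < 6L || j < 1L) {
    warning(sprintf(
      "order-statistic %.0f%% CI undefined at n = %d; returning data range",
      100 * level, n))
    return(list(median = med, ciLow = s[1], ciHigh = s[n],
                method = "range", coverage = 1 - 2 * pbinom(-1, n, 0.5)))
  }
  list(median = med, ciLow = s[j], ciHigh = s[n + 1L - j],
       method = "order", coverage = 1 - 2 * pbinom(j - 1, n, 0.5))
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' `|mean(a) - mean(b)|` divided by the pooled SD with n-1 weights.
#'
#' @param groupA,groupB numeric, n >= 2 each.
#' @return non-negative effect size.
#' @export
cohensD <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2 || nB < 2) stop2("Cohen's d needs n >= 2 per group")
  sp2 <- ((nA - 1) * stats::var(groupA) + (nB - 1) * stats::var(groupB)) /
    (nA + nB - 2)
  if (sp2 <= 0) stop2("zero pooled SD: Cohen's d undefined")
  abs(mean(groupA) - mean(groupB)) / sqrt(sp2)
}

#' Exact two-tailed binomial test p-value
#'
#' Minimum-likelihood two-siding (the common exact convention): the p-value
#' is the sum of probabilities of all outcomes no more likely than the
#' observed one under `Bin(n, p0)`, capped at 1. A `"doubling"` method
#' (twice the smaller one-sided tail) is also available.
#'
#' @param successes observed count, `0 <= successes <= n`.
#' @param n number of trials.
#' @param p0 null success probability in (0, 1).
#' @param method `"minlike"` (default) or `"doubling"`.
#' @return two-tailed p-value.
#' @examples
#' binomialTwoTailed(9, 10, 0.5)   # 22/1024 = 0.021484375
#' @export
binomialTwoTailed <- function(successes, n, p0 = 0.5,
                              method = c("minlike", "doubling")) {
  method <- match.arg(method)
  if (n < 1 || successes < 0 || successes > n)
    stop2("need 0 <= successes <= n with n >= 1")
  if (p0 <= 0 || p0 >= 1) stop2("p0 must be in (0, 1)")
  if (identical(method, "minlike"))
    return(binom.test(successes, n, p0)$p.value)
  lower <- pbinom(successes, n, p0)
  upper <- pbinom(successes - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Yates continuity correction defaults to ON (the tables here have small
#' cells); a warning is emitted when any expected cell is below 5.
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @param yates apply the continuity correction (default TRUE).
#' @return a [GroupComparison-class] (statistic = chi-square, df = 1).
#' @export
chiSquare2x2 <- function(tab, yates = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop2("table must be 2x2")
  if (any(tab < 0)) stop2("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop2("zero margin: chi-square undefined")
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd < 5))
    warning("expected cell count below 5; chi-square approximation is weak")
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  gs <- data.frame(group = c("row1", "row2"), n = rowSums(tab),
                   median = tab[, 1] / rowSums(tab),
                   ciLow = NA_real_, ciHigh = NA_real_,
                   ciMethod = "proportion", stringsAsFactors = FALSE)
  new("GroupComparison", testName = if (yates) "chi_square_yates" else
        "chi_square", statistic = unname(ct$statistic),
      pValue = unname(ct$p.value), effectSize = NA_real_,
      groupSummaries = gs)
}

#' After-discharge incidence contrast between two populations
#'
#' Mirrors the incidence comparison of the recordings: the larger (test)
#' group's after-discharge count is tested against a reference proportion
#' with the exact two-tailed binomial test. The reference may be given as a
#' proportion (e.g. the printed sham incidence 0.136) or as the reference
#' group's own counts, in which case its empirical proportion is used with
#' a Haldane-style `0.5/n` guard when the reference count is 0.
#'
#' @param testCount,testN after-discharge-positive count and group size of
#'   the test (injury-side) population.
#' @param reference either a single proportion in (0, 1), or `c(count, n)`
#'   for the reference population.
#' @return list: `pValue`, `p0`, `testIncidence`.
#' @export
compareAdIncidence <- function(testCount, testN, reference) {
  if (length(reference) == 1L) {
    p0 <- reference
  } else {
    k <- reference[1]; nRef <- reference[2]
    p0 <- if (k <= 0) 0.5 / nRef else if (k >= nRef)
      1 - 0.5 / nRef else k / nRef
  }
  list(pValue = binomialTwoTailed(testCount, testN, p0), p0 = p0,
       testIncidence = testCount / testN)
}
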
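## full-permutation oracle for the exact two-tailed Mann-Whitney p-value:
## enumerate all C(nA+nB, nA) label assignments of the pooled data
mwuEnumOracle <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a); n <- length(pooled)
  uOf <- function(idx) {
    rk <- rank(pooled)
    rA <- sum(rk[idx])
    uA <- rA - nA * (nA + 1) / 2
    min(uA, nA * (n - nA) - uA)
  }
  obs <- uOf(seq_len(nA))
  combs <- utils::combn(n, nA)
  us <- apply(combs, 2, uOf)
  mean(us <= obs + 1e-9)
}

test_that("complete separation gives U = 0 and identical groups U = n^2/2", {
  sep <- mannWhitneyU(c(1, 2, 3), c(4, 5))
  expect_equal(sep@statistic, 0)
  same <- mannWhitneyU(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same@statistic, 16 / 2)
  expect_gt(same@pValue, 0.9)
  expect_error(mannWhitneyU(numeric(), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p matches full enumeration for small groups", {
  set.seed(42)
  for (nA in 2:4) for (nB in 2:(min(6, 10 - nA))) {
    a <- rnorm(nA); b <- rnorm(nB, 1)
    got <- mannWhitneyU(a, b)@pValue
    expect_equal(got, mwuEnumOracle(a, b), tolerance = 1e-12,
                 label = sprintf("nA=%d nB=%d", nA, nB))
  }
  # the spec'd worked case: a = {1,2,3}, b = {4,5}
  expect_equal(mannWhitneyU(c(1, 2, 3), c(4, 5))@pValue,
               mwuEnumOracle(c(1, 2, 3), c(4, 5)), tolerance = 1e-12)
})

test_that("tests are symmetric under group label swap", {
  set.seed(7)
  a <- rnorm(8); b <- rnorm(5, 0.5)
  expect_equal(mannWhitneyU(a, b)@pValue, mannWhitneyU(b, a)@pValue)
  expect_equal(mannWhitneyU(a, b)@statistic, mannWhitneyU(b, a)@statistic)
  expect_equal(cohensD(a, b), cohensD(b, a))
})

test_that("median CIs use order statistics with guaranteed coverage", {
  expect_warning(one <- medianCI(5), "n = 1")
  expect_equal(one$median, 5)
  expect_equal(c(one$ciLow, one$ciHigh), c(5, 5))
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9)
  ci <- medianCI(x)
  expect_identical(ci$method, "order")
  expect_gte(ci$coverage, 0.95)
  expect_lte(ci$ciLow, ci$median)
  expect_gte(ci$ciHigh, ci$median)
  # order-statistic endpoints are data points
  expect_true(all(c(ci$ciLow, ci$ciHigh) %in% x))
  # monotone-transform equivariance
  ci2 <- medianCI(exp(x))
  expect_equal(ci2$ciLow, exp(ci$ciLow))
  expect_equal(ci2$ciHigh, exp(ci$ciHigh))
  # bootstrap variant is seeded and reproducible
  b1 <- medianCI(x, method = "bootstrap", seed = 4)
  b2 <- medianCI(x, method = "bootstrap", seed = 4)
  expect_equal(b1$ciLow, b2$ciLow)
})

test_that("Cohen's d matches the closed-form oracle", {
  expect_equal(cohensD(c(1, 2, 3), c(4, 5, 6)), 3)  # pooled SD = 1
  expect_equal(cohensD(c(0, 2), c(0, 2)), 0)
  expect_error(cohensD(c(0, 0), c(2, 2)), "zero pooled SD")
  expect_error(cohensD(1, c(2, 3)), "n >= 2")
})

test_that("binomial two-tailed p equals direct minimum-likelihood summation", {
  sumOracle <- function(k, n, p0) {
    d <- dbinom(0:n, n, p0)
    min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
  }
  expect_equal(binomialTwoTailed(9, 10, 0.5), 0.021484375,
               tolerance = 1e-12)
  for (p0 in c(0.1, 0.136, 0.5)) {
    for (k in c(0, 1, 7, 25, 50)) {
      expect_equal(binomialTwoTailed(k, 50, p0), sumOracle(k, 50, p0),
                   tolerance = 1e-12,
                   label = sprintf("k=%d p0=%.3f", k, p0))
    }
  }
  # a null-consistent observation is not significant
  expect_gt(binomialTwoTailed(25, 50, 0.5), 0.9)
  # the AD-incidence contrast of 22/43 against 3/22 is overwhelming
  expect_lt(binomialTwoTailed(22, 43, 3 / 22), 1e-4)
  # doubling variant stays a valid p-value
  expect_lte(binomialTwoTailed(9, 10, 0.5, method = "doubling"), 1)
  expect_error(binomialTwoTailed(11, 10, 0.5), "successes")
  expect_error(binomialTwoTailed(5, 10, 0), "p0")
})

test_that("2x2 chi-square matches the closed-form oracle", {
  chisqOracle <- function(tab, yates) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    d <- abs(tab - e)
    if (yates) d <- pmax(0, d - 0.5)
    x2 <- sum(d^2 / e)
    c(stat = x2, p = pchisq(x2, df = 1, lower.tail = FALSE))
  }
  offTab <- matrix(c(3, 19, 11, 32), 2, 2, byrow = TRUE)
  for (yates in c(TRUE, FALSE)) {
    got <- suppressWarnings(chiSquare2x2(offTab, yates = yates))
    want <- chisqOracle(offTab, yates)
    expect_equal(got@statistic, unname(want["stat"]), tolerance = 1e-12)
    expect_equal(got@pValue, unname(want["p"]), tolerance = 1e-12)
  }
  # independence: a table proportional to its margins
  ind <- suppressWarnings(chiSquare2x2(matrix(c(10, 20, 5, 10), 2, 2,
                                              byrow = TRUE), yates = FALSE))
  expect_equal(ind@statistic, 0, tolerance = 1e-12)
  expect_equal(ind@pValue, 1)
  # doubling all cells doubles the uncorrected statistic
  t1 <- suppressWarnings(chiSquare2x2(offTab, yates = FALSE))@statistic
  t2 <- suppressWarnings(chiSquare2x2(2 * offTab, yates = FALSE))@statistic
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2, 2)), "zero margin")
})

test_that("all reported p-values are valid probabilities", {
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    p <- mannWhitneyU(a, b)@pValue
    expect_gte(p, 0); expect_lte(p, 1)
  }
  for (i in 1:20) {
    n <- sample(2:40, 1); k <- sample(0:n, 1)
    p <- binomialTwoTailed(k, n, runif(1, 0.05, 0.95))
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("incidence contrast guards a zero reference count", {
  r <- compareAdIncidence(22, 43, c(0, 22))
  expect_equal(r$p0, 0.5 / 22)
  expect_lt(r$pValue, 1e-4)
  r2 <- compareAdIncidence(22, 43, 0.136)
  expect_equal(r2$p0, 0.136)
  expect_equal(r2$testIncidence, 22 / 43)
})
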
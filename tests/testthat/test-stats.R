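test_that("Fisher exact two-tailed p matches an enumeration oracle on hand cases", {
  ## perfectly balanced table is uninformative
  expect_identical(fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  ## identical rows -> p = 1 regardless of size
  expect_equal(fisherExact2x2(matrix(c(7, 7, 181, 181), 2))$p, 1, tolerance = 1e-10)
  ## maximally unbalanced 10/10: only the two extreme tables fall in the tail
  r <- fisherExact2x2(matrix(c(0, 10, 10, 0), 2))
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r$p, fisherEnumOracle(0, 10, 10, 0), tolerance = 1e-12)
  expect_identical(r$oddsRatio, 0)
  ## one-tailed is never larger than two-tailed
  expect_lte(r$pOneTailed, r$p)
  expect_error(fisherExact2x2(matrix(c(1, 2, 3), 1)), "2x2")
  expect_error(fisherExact2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Fisher exact agrees with the installed implementation on random tables", {
  set.seed(501)
  for (i in 1:300) {
    m <- matrix(rpois(4, sample(c(2, 8, 40), 1)), 2)
    if (sum(m) == 0) next
    ours <- fisherExact2x2(m)
    ref <- stats::fisher.test(m)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-10)
    expect_true(ours$p > 0 && ours$p <= 1)
    expect_lte(ours$pOneTailed, ours$p + 1e-12)
  }
})

test_that("chi-squared on a 2x2 matches the closed form n(ad-bc)^2/(margins)", {
  m <- matrix(c(20, 10, 10, 20), 2)
  r <- chi2Test(m)
  closed <- sum(m) * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    (rowSums(m)[1] * rowSums(m)[2] * colSums(m)[1] * colSums(m)[2])
  expect_equal(r$statistic, unname(closed), tolerance = 1e-12)
  expect_equal(r$statistic, 100 / 15, tolerance = 1e-12)
  expect_identical(r$df, 1L)
  expect_equal(r$p, pchisq(r$statistic, 1, lower.tail = FALSE))
  ## cross-check against the installed implementation (no correction)
  set.seed(502)
  for (i in 1:100) {
    m <- matrix(rpois(4, 30) + 1, 2)
    expect_equal(chi2Test(m, poolExpectedBelow = 0)$statistic,
                 unname(stats::chisq.test(m, correct = FALSE)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("small expected counts are pooled, reducing the degrees of freedom", {
  ## 2 x 5 with two nearly-empty high bins
  m <- rbind(c(30, 20, 10, 1, 0), c(28, 22, 9, 0, 1))
  r <- chi2Test(m, poolExpectedBelow = 1, ordered = TRUE)
  expect_lt(ncol(r$table), 5L)
  expect_identical(r$df, (2L - 1L) * (ncol(r$table) - 1L))
  ## pooling preserves the total count
  expect_identical(sum(r$table), sum(m))
  ## ordered pooling merges into the adjacent bin, keeping the bin order
  expect_identical(nrow(r$table), 2L)
  ## zero-margin columns are dropped with a warning
  expect_warning(chi2Test(rbind(c(5, 0, 5), c(6, 0, 7)), poolExpectedBelow = 0),
                 "zero-margin")
  expect_error(suppressWarnings(chi2Test(rbind(c(0, 0), c(0, 0)))), "degenerate")
})

test_that("goodness-of-fit is zero for a perfect fit and detects skew", {
  r <- chi2GoF(c(25, 25, 25, 25))
  expect_identical(r$statistic, 0)
  expect_identical(r$df, 3L)
  expect_identical(r$p, 1)
  expect_lt(chi2GoF(c(80, 10, 5, 5))$p, 1e-6)
  ## explicit expected proportions
  r2 <- chi2GoF(c(30, 60, 10), expectedProbs = c(0.3, 0.6, 0.1))
  expect_identical(r2$statistic, 0)
  ## pooling in GoF also reduces df
  r3 <- chi2GoF(c(50, 48, 1, 1), expectedProbs = c(0.48, 0.48, 0.02, 0.02),
                poolExpectedBelow = 5)
  expect_lt(r3$df, 3L)
  expect_error(chi2GoF(c(0, 0, 0)), "empty")
})

test_that("ratio propagation follows quadrature and is scale-invariant", {
  r <- ratioWithPropagatedSD(ratioSD(2, 0.2), ratioSD(1, 0.1))
  expect_equal(r$value, 2)
  expect_equal(r$sd, 2 * sqrt(0.01 + 0.01), tolerance = 1e-12)
  ## zero numerator rule
  r0 <- ratioWithPropagatedSD(ratioSD(0, 0.3), ratioSD(2, 0.5))
  expect_identical(r0$value, 0)
  expect_identical(r0$sd, 0.15)
  expect_error(ratioWithPropagatedSD(ratioSD(1, 0.1), ratioSD(0, 0.1)),
               "zero denominator")
  ## scaling numerator and denominator together leaves value and relative sd
  set.seed(503)
  for (i in 1:50) {
    v1 <- runif(1, 0.5, 5); s1 <- runif(1, 0, 0.5)
    v2 <- runif(1, 0.5, 5); s2 <- runif(1, 0, 0.5)
    k <- runif(1, 0.1, 10)
    a <- ratioWithPropagatedSD(ratioSD(v1, s1), ratioSD(v2, s2))
    b <- ratioWithPropagatedSD(ratioSD(k * v1, k * s1), ratioSD(v2, s2))
    expect_equal(b$value, k * a$value, tolerance = 1e-12)
    expect_equal(b$sd, k * a$sd, tolerance = 1e-12)
  }
})

test_that("overlap summaries exclude insertions and bin the histogram as 0..14, >=15", {
  b <- data.frame(kind = c("blunt", "microhomology", "microhomology",
                           "insertion", "microhomology"),
                  overlapLen = c(0L, 3L, 5L, 0L, 21L))
  s <- meanOverlap(b)
  expect_identical(s$nJunctions, 5L)
  expect_identical(s$nWithInsertion, 1L)
  expect_equal(s$meanOverlap, mean(c(0, 3, 5, 21)))
  expect_identical(length(s$histogram), 16L)
  expect_identical(names(s$histogram)[16], ">=15")
  expect_identical(unname(s$histogram[c("0", "3", "5", ">=15")]), rep(1L, 4))
  expect_identical(sum(s$histogram), 4L)
  ## every boundary an insertion: mean undefined but flagged, not an error
  sAll <- meanOverlap(data.frame(kind = "insertion", overlapLen = 0L))
  expect_true(sAll$allInsertions)
  expect_true(is.na(sAll$meanOverlap))
  expect_error(meanOverlap(b[0, ]), "no boundaries")
})

test_that("overlap distribution comparison reports mean shift and a pooled chi-squared", {
  set.seed(504)
  mk <- function(ols) meanOverlap(data.frame(kind = ifelse(ols > 0, "microhomology",
                                                           "blunt"),
                                             overlapLen = ols))
  a <- mk(rbinom(200, 20, 0.1))
  ## bins empty in both groups are dropped (warned about) before testing
  cmpSelf <- suppressWarnings(compareOverlapDistributions(a, a))
  expect_identical(cmpSelf$meanDifference, 0)
  expect_identical(cmpSelf$chisq$statistic, 0)
  expect_identical(cmpSelf$chisq$p, 1)
  ## a heavier microhomology tail shifts the mean up and is detectable
  b <- mk(rbinom(200, 20, 0.35))
  cmp <- suppressWarnings(compareOverlapDistributions(a, b))
  expect_gt(cmp$meanDifference, 0)
  expect_lt(cmp$chisq$p, 1e-6)
  expect_error(compareOverlapDistributions(a, meanOverlap(
    data.frame(kind = "blunt", overlapLen = 0L), mhBinMax = 10L)),
    "incompatible")
})
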
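mkSeries <- function(asym, rater, ids = seq_along(asym)) {
  raterSeries(data.frame(id = ids, level = "L4/5",
                         thetaLeft = 40 + asym, thetaRight = 40), rater)
}

test_that("bland-altman on identical and constant-offset series", {
  a <- mkSeries(c(1, -2, 3, 0.5, -4), "A")
  res <- blandAltman(a, a)
  expect_equal(res@bias, 0); expect_equal(res@loaLow, 0); expect_equal(res@loaHigh, 0)

  b <- mkSeries(c(1, -2, 3, 0.5, -4) + 3, "B")
  res2 <- blandAltman(a, b)
  expect_equal(res2@bias, -3)
  expect_equal(res2@loaLow, -3); expect_equal(res2@loaHigh, -3)
  expect_equal(res2@direction, "A - B")

  # antisymmetry: swapping the raters negates bias and swaps/negates the LoA
  res3 <- blandAltman(b, a)
  expect_equal(res3@bias, -res2@bias)
  expect_equal(res3@loaLow, -res2@loaHigh)
  expect_equal(res3@loaHigh, -res2@loaLow)

  expect_error(blandAltman(mkSeries(1, "A"), mkSeries(1, "B")),
               class = "InsufficientOverlapError")
})

test_that("bland-altman recovers seeded Laplace bias and limits", {
  set.seed(1)
  diffs <- rlaplace(2000, 1, 2)
  a <- mkSeries(diffs, "A"); b <- mkSeries(rep(0, 2000), "B")
  res <- blandAltman(a, b, reference = 10)
  expect_lt(abs(res@bias - 1), 0.15)
  expect_lt(abs(res@loaLow - (1 + 2 * log(0.05))), 0.3)
  expect_lt(abs(res@loaHigh - (1 - 2 * log(0.05))), 0.3)
  expect_equal(res@n, 2000L)
  expect_equal(res@means, (diffs + 0) / 2)
  # fraction of slices under the 10-degree reference, per rater
  expect_equal(unname(res@fracWithinRef["A"]), mean(abs(diffs) < 10))
  expect_equal(unname(res@fracWithinRef["B"]), 1)
})

test_that("bland-altman analyses only the common (id, level) pairs", {
  a <- mkSeries(c(1, 2, 3, 4), "A", ids = c("w", "x", "y", "z"))
  b <- mkSeries(c(9, 2.5, 3.5), "B", ids = c("x", "y", "q"))
  res <- blandAltman(a, b)
  expect_equal(res@n, 2L)  # x and y only
  expect_equal(sort(res@diffs), sort(c(2 - 9, 3 - 2.5)))
})

test_that("r-squared matches hand-computed Pearson and is affine invariant", {
  a <- mkSeries(c(1, 2, 3, 4), "A")
  b <- mkSeries(c(1, 2, 3, 100), "B")
  # independent hand computation of Pearson r on (1,2,3,4) vs (1,2,3,100)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 100)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rSquared(a, b), r^2, tolerance = 1e-12)
  expect_equal(rSquared(a, b), 0.6162665, tolerance = 1e-6)

  expect_equal(rSquared(a, a), 1)
  aff <- mkSeries(2 * c(1, 2, 3, 4) + 5, "C")
  expect_equal(rSquared(a, aff), 1)
  expect_equal(rSquared(a, b), rSquared(b, a))
  expect_error(rSquared(a, mkSeries(rep(2, 4), "Z")), class = "ZeroVarianceError")
  expect_error(rSquared(mkSeries(1:2, "A"), mkSeries(1:2, "B")),
               class = "InsufficientOverlapError")
})

test_that("normality gate separates normal from heavy-tailed samples", {
  set.seed(5)
  xn <- rnorm(5000)
  resN <- normalityTests(xn)
  expect_false(resN$nonparametricRequired)

  set.seed(5)
  xl <- rlaplace(5000, 0, 1)
  resL <- normalityTests(xl)
  expect_true(resL$nonparametricRequired)
  expect_lt(resL$shapiro$p, 0.05)

  expect_error(normalityTests(rnorm(5)), class = "ArgumentError")
})

test_that("rater dice matrix compares annotation sets per ROI", {
  rec1 <- testPhantom(imageSize = 128L)
  rec2 <- testPhantom(thetaLeft = 44, thetaRight = 41, imageSize = 128L)
  self <- list(s1 = rec1@mask, s2 = rec2@mask)
  # a second rater who dilates the facet joints by one pixel
  dilFJ <- function(mask) {
    lab <- maskLabels(mask)
    lab[facetropism:::.dilate8(lab == 2L) & lab == 0L] <- 2L
    labelMask(lab, pixelSpacing(mask))
  }
  other <- lapply(self, dilFJ)
  tab <- raterDiceMatrix(list(A = self, B = self))
  expect_equal(tab$dice, rep(1, 3))

  tab2 <- raterDiceMatrix(list(A = self, B = other))
  fj <- tab2$dice[tab2$class == "FJ"]
  vb <- tab2$dice[tab2$class == "VB"]
  expect_lt(fj, vb)  # smaller structures are more overlap-sensitive
  expect_equal(vb, 1)

  expect_error(raterDiceMatrix(list(A = self, B = self["s1"])),
               class = "KeyMismatchError")
})
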
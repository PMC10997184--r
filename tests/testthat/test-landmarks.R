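test_that("landmarks on an ideal phantom match analytic truth within one pixel diagonal", {
  for (n in c(256L, 512L)) {
    rec <- testPhantom(thetaLeft = 47, thetaRight = 38, imageSize = n)
    lm <- extractLandmarks(rec@mask)
    truth <- landmarkCoords(rec@truthLandmarks)
    est <- landmarkCoords(lm)
    tol <- sqrt(2) * pixelSpacing(rec@mask)[1]
    for (nm in rownames(truth)) {
      expect_lt(sqrt(sum((est[nm, ] - truth[nm, ])^2)), tol)
    }
  }
})

test_that("missing ROIs are reported by class", {
  rec <- testPhantom(imageSize = 128L)
  lab <- maskLabels(rec@mask)
  for (cls in c(VB = 1L, FJ = 2L, PA = 3L)) {
    broken <- lab
    broken[broken == cls] <- 0L
    err <- tryCatch(extractLandmarks(labelMask(broken, 1.4)), error = identity)
    expect_s3_class(err, "MissingROIError")
    expect_equal(err$roi, names(which(c(VB = 1L, FJ = 2L, PA = 3L) == cls)))
  }
})

test_that("left-right mirroring swaps the facet landmark pairs", {
  rec <- testPhantom(thetaLeft = 50, thetaRight = 35, imageSize = 256L)
  lab <- maskLabels(rec@mask)
  s <- pixelSpacing(rec@mask)
  flip <- labelMask(lab[, ncol(lab):1], s)
  lm <- extractLandmarks(rec@mask)
  lmF <- extractLandmarks(flip)
  w <- (ncol(lab) - 1) * s[2]
  mirror <- function(p) c(p[1], w - p[2])
  for (pair in list(c("AFL", "AFR"), c("PFL", "PFR"))) {
    expect_equal(slot(lmF, pair[1]), mirror(slot(lm, pair[2])), tolerance = 1e-9)
    expect_equal(slot(lmF, pair[2]), mirror(slot(lm, pair[1])), tolerance = 1e-9)
  }
})

test_that("two facet components on the same side raise LateralityError", {
  # hand-built mask: VB blob, PA posterior, both FJ blobs on the left
  m <- matrix(0L, 40, 40)
  m[6:10, 18:24] <- 1L           # VB
  m[30:34, 18:24] <- 3L          # PA
  m[14:16, 30:32] <- 2L          # FJ 1, left of midline
  m[20:22, 33:35] <- 2L          # FJ 2, also left
  expect_error(extractLandmarks(labelMask(m, 1)), class = "LateralityError")
})

test_that("a single FJ component is rejected", {
  rec <- testPhantom(imageSize = 128L)
  lab <- maskLabels(rec@mask)
  cc <- facetropism:::connectedComponents(lab == 2L)
  lab[cc == 2L] <- 0L
  expect_error(extractLandmarks(labelMask(lab, 1.4)), class = "MissingROIError")
})

test_that("landmarks are translation invariant and spacing equivariant", {
  rec <- testPhantom(imageSize = 192L)
  lab <- maskLabels(rec@mask)
  s <- pixelSpacing(rec@mask)
  lm <- landmarkCoords(extractLandmarks(rec@mask))

  dr <- 4L; dc <- 7L
  shifted <- matrix(0L, nrow(lab), ncol(lab))
  shifted[(1 + dr):nrow(lab), (1 + dc):ncol(lab)] <-
    lab[1:(nrow(lab) - dr), 1:(ncol(lab) - dc)]
  lmS <- landmarkCoords(extractLandmarks(labelMask(shifted, s)))
  expect_equal(lmS, lm + rep(c(dr * s[1], dc * s[2]), each = 6),
               tolerance = 1e-9)

  lm2 <- landmarkCoords(extractLandmarks(labelMask(lab, 2 * s)))
  expect_equal(lm2, 2 * lm, tolerance = 1e-9)
})

test_that("laterality postcondition holds on random cohort phantoms", {
  specs <- sampleCohortSpecs(6, "L4/5", "male", seed = 13, imageSize = 128L)
  for (sp in specs) {
    lm <- extractLandmarks(generatePhantom(sp)@mask)
    v <- lm@SP - lm@VBC
    nvec <- c(-v[2], v[1]) / sqrt(sum(v^2))
    lat <- function(p) sum((p - lm@VBC) * nvec)
    expect_gt(lat(lm@AFL), 0); expect_gt(lat(lm@PFL), 0)
    expect_lt(lat(lm@AFR), 0); expect_lt(lat(lm@PFR), 0)
  }
})
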
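mk <- function(m, s = 0.35) labelMask(m, s)

test_that("overlap metrics on trivial configurations", {
  a <- matrix(0L, 8, 8); a[2:4, 2:4] <- 1L
  expect_equal(diceIoU(mk(a), mk(a), 1L), c(dice = 1, iou = 1))

  b <- matrix(0L, 8, 8); b[6:8, 6:8] <- 1L
  expect_equal(diceIoU(mk(a), mk(b), 1L), c(dice = 0, iou = 0))

  # 2x2 block vs the same block shifted one column: dice 0.5, iou 1/3
  p <- matrix(0L, 6, 6); p[3:4, 3:4] <- 1L
  r <- matrix(0L, 6, 6); r[3:4, 4:5] <- 1L
  expect_equal(diceIoU(mk(p), mk(r), 1L), c(dice = 0.5, iou = 1 / 3))

  expect_warning(z <- diceIoU(mk(p), mk(r), 3L), class = "EmptyClassWarning")
  expect_equal(z, c(dice = 1, iou = 1))
  r2 <- r; r2[3, 3] <- 3L
  expect_equal(diceIoU(mk(p), mk(r2), 3L), c(dice = 0, iou = 0))

  expect_error(diceIoU(mk(p), mk(matrix(0L, 5, 5)), 1L), class = "ShapeError")
})

test_that("surface distances on trivial configurations", {
  a <- matrix(0L, 10, 10); a[3:6, 3:6] <- 2L
  sd0 <- surfaceDistances(mk(a), mk(a), 2L)
  expect_equal(sd0, c(asd = 0, hd95 = 0))

  # two single pixels 5 pixels apart at 0.35 mm -> both distances 1.75 mm
  p <- matrix(0L, 10, 10); p[4, 2] <- 1L
  r <- matrix(0L, 10, 10); r[4, 7] <- 1L
  expect_equal(surfaceDistances(mk(p), mk(r), 1L),
               c(asd = 1.75, hd95 = 1.75))

  err <- tryCatch(surfaceDistances(mk(p), mk(r), 3L), error = identity)
  expect_s3_class(err, "EmptySurfaceError")
})

test_that("metrics equal the brute-force oracle on random small masks", {
  set.seed(7)
  for (k in 1:30) {
    pair <- randomMaskPair(dim = sample(12:32, 1))
    for (cl in 1:3) {
      got <- diceIoU(pair$pred, pair$ref, cl)
      want <- suppressWarnings(bfDiceIoU(maskLabels(pair$pred),
                                         maskLabels(pair$ref), cl))
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
      # Dice-IoU identity D = 2J/(1+J)
      expect_equal(got[["dice"]], 2 * got[["iou"]] / (1 + got[["iou"]]),
                   tolerance = 1e-12)
      if (any(maskLabels(pair$pred) == cl) && any(maskLabels(pair$ref) == cl)) {
        gotS <- surfaceDistances(pair$pred, pair$ref, cl)
        wantS <- bfSurfaceDistances(maskLabels(pair$pred), maskLabels(pair$ref),
                                    cl, pixelSpacing(pair$pred))
        expect_equal(unname(gotS), unname(wantS), tolerance = 1e-9)
        # symmetry of the pooled/averaged definitions
        rev <- surfaceDistances(pair$ref, pair$pred, cl)
        expect_equal(unname(rev), unname(gotS), tolerance = 1e-12)
      }
    }
  }
})

test_that("pair and set evaluation aggregate correctly", {
  rec <- testPhantom(imageSize = 128L)
  res <- evaluatePair(rec@mask, rec@mask)
  expect_equal(res@perClass$dice, rep(1, 3))
  expect_equal(res@macro[["asd"]], 0)

  expect_warning(tab <- evaluateSet(list(list(pred = rec@mask, ref = rec@mask))),
                 class = "DegenerateSetWarning")
  expect_equal(tab$se, rep(0, nrow(tab)))
  expect_equal(tab$mean[tab$class == "macro" & tab$metric == "dice"], 1)

  # dilated prediction: macro dice matches direct recomputation
  lab <- maskLabels(rec@mask)
  dil <- lab
  for (cl in 1:3) dil[facetropism:::.dilate8(lab == cl) & lab == 0L] <- cl
  pred <- labelMask(dil, pixelSpacing(rec@mask))
  res2 <- evaluatePair(pred, rec@mask)
  direct <- mean(vapply(1:3, function(cl)
    bfDiceIoU(dil, lab, cl)[["dice"]], 0))
  expect_equal(res2@macro[["dice"]], direct, tolerance = 1e-12)
  expect_true(res2@macro[["dice"]] < 1)
})
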
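test_that("generalized dice loss on exact, disjoint, and hand-computed cases", {
  ref <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
  oneHot <- cbind(as.numeric(ref == 0L), as.numeric(ref == 1L))
  expect_equal(generalizedDiceLoss(oneHot, as.vector(ref)), 0, tolerance = 1e-12)

  swapped <- oneHot[, 2:1]
  expect_equal(generalizedDiceLoss(swapped, as.vector(ref)), 1, tolerance = 1e-9)

  # 2x2, two classes, ref = [A,A;A,B], prob 0.8 on the correct class:
  # w_A = 1/9, w_B = 1; hand double-loop oracle gives 0.29411765
  pred <- rbind(c(.8, .2), c(.8, .2), c(.8, .2), c(.2, .8))
  refOH <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1))
  expect_equal(generalizedDiceLoss(pred, refOH), bfGDL(pred, refOH),
               tolerance = 1e-12)
  expect_equal(generalizedDiceLoss(pred, refOH), 5 / 17, tolerance = 1e-9)

  expect_error(generalizedDiceLoss(pred[, 1, drop = FALSE], refOH),
               class = "ShapeError")
  expect_error(generalizedDiceLoss(pred * 2, refOH), class = "ArgumentError")
})

test_that("generalized dice loss equals the double-loop oracle on random tensors", {
  set.seed(11)
  for (k in 1:20) {
    lab <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    P <- randomProbs(64, 4)
    R <- facetropism:::.asOneHot(as.vector(lab), 4L)
    expect_equal(generalizedDiceLoss(P, lab), bfGDL(P, R), tolerance = 1e-9)
    # strictly positive for any non-one-hot prediction
    expect_gt(generalizedDiceLoss(P, lab), 0)
  }
})

test_that("fold assignment is a participant-level partition", {
  fa <- splitFolds(sprintf("p%02d", 1:10), 5, seed = 3)
  expect_equal(as.integer(sort(table(fa$fold))), rep(2L, 5))
  expect_setequal(fa$participant, sprintf("p%02d", 1:10))

  # slices of one participant inherit a single fold (lookup by participant)
  slices <- rep(sprintf("p%02d", 1:10), each = 3)
  folds <- fa$fold[match(slices, fa$participant)]
  expect_true(all(tapply(folds, slices, function(f) length(unique(f))) == 1))

  expect_identical(splitFolds(letters[1:7], 3, seed = 9),
                   splitFolds(letters[1:7], 3, seed = 9))
  expect_error(splitFolds(letters[1:3], 5), class = "ArgumentError")
})

test_that("augmentations transform image and mask consistently", {
  rec <- testPhantom(imageSize = 128L)
  img <- facetropism:::.phantomImage(maskLabels(rec@mask), rec@spec)
  flipOnly <- list(list(name = "horizontal_flip", prob = 1))
  set.seed(1)
  out <- applyAugmentations(img, maskLabels(rec@mask), flipOnly)
  expect_identical(out$image, img[, ncol(img):1])
  expect_identical(out$mask, maskLabels(rec@mask)[, ncol(img):1])

  # intensity-only transforms never touch the mask
  intens <- Filter(function(a) a$name != "horizontal_flip", defaultAugmentations())
  intens <- lapply(intens, function(a) { a$prob <- 1; a })
  set.seed(2)
  out2 <- applyAugmentations(img, maskLabels(rec@mask), intens)
  expect_identical(out2$mask, maskLabels(rec@mask))
  expect_false(identical(out2$image, img))
})

test_that("invalid training configurations are rejected", {
  expect_error(trainConfig("desk", earlyStopPatience = 15L, maxEpochs = 15L),
               "strictly less")
  expect_error(trainConfig("desk", folds = 1L), "folds")
  expect_error(trainConfig("desk", learningRate = 0), "positive")
})

test_that("the desk-scale trainer learns phantom segmentation", {
  specs <- sampleCohortSpecs(14, "L4/5", "female", seed = 21, imageSize = 128L)
  recs <- lapply(seq_along(specs), function(i) {
    r <- generatePhantom(specs[[i]], image = TRUE)
    list(participant = sprintf("p%02d", i), image = r@image, mask = r@mask)
  })
  cfg <- trainConfig("desk", maxEpochs = 15L, earlyStopPatience = 6L, seed = 4L)
  res <- trainAndSelect(recs, cfg)
  expect_equal(nrow(res$perFold), 2)
  expect_gt(res$metrics$mean[res$metrics$metric == "iou"], 0.5)
  # prediction produces a valid mask of the right shape
  pm <- predictMask(res$models[[1]], recs[[1]]$image,
                    pixelSpacing(recs[[1]]$mask))
  expect_s4_class(pm, "LabelMask")
  expect_identical(dim(maskLabels(pm)), dim(maskLabels(recs[[1]]$mask)))
  # soft predictions are per-pixel distributions
  P <- predictProb(res$models[[1]], recs[[1]]$image)
  expect_equal(dim(P), c(128, 128, 4))
  expect_lt(max(abs(apply(P, c(1, 2), sum) - 1)), 1e-6)
})
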
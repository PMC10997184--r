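# Overlap and surface-distance metrics for predicted vs. reference masks.

.checkPair <- function(pred, ref) {
  stopifnot(is(pred, "LabelMask"), is(ref, "LabelMask"))
  if (!identical(dim(pred@labels), dim(ref@labels)))
    stopCondition("ShapeError", sprintf(
      "mask shapes differ: %s vs %s",
      paste(dim(pred@labels), collapse = "x"),
      paste(dim(ref@labels), collapse = "x")))
  if (!isTRUE(all.equal(pred@pixelSpacing, ref@pixelSpacing)))
    stopCondition("ShapeError", "mask pixel spacings differ")
}

#' Dice and IoU for one class
#'
#' \code{dice = 2|P&R| / (|P|+|R|)}, \code{iou = |P&R| / |P|R|union}. When the
#' class is empty in both masks the metrics are defined as 1 (with a warning);
#' when it is empty in exactly one, both are 0.
#'
#' @param pred,ref \linkS4class{LabelMask}s of identical shape and spacing.
#' @param classId integer class label (1 = VB, 2 = FJ, 3 = PA).
#' @return named numeric \code{c(dice, iou)}.
#' @export
diceIoU <- function(pred, ref, classId) {
  .checkPair(pred, ref)
  p <- pred@labels == classId
  r <- ref@labels == classId
  np <- sum(p); nr <- sum(r)
  if (np == 0 && nr == 0) {
    warnCondition("EmptyClassWarning", sprintf(
      "class %d empty in both masks; dice/iou defined as 1", classId))
    return(c(dice = 1, iou = 1))
  }
  if (np == 0 || nr == 0) return(c(dice = 0, iou = 0))
  ni <- sum(p & r)
  c(dice = 2 * ni / (np + nr), iou = ni / (np + nr - ni))
}

# Class surface: pixels of the class with at least one 4-neighbour outside
# the class; the image border counts as outside.
surfacePixels <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- bw
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
              pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  bw & !interior
}

# Directed nearest distances (mm) from each point of A to the set B.
# Points are k x 2 matrices of mm coordinates; chunked so memory stays modest.
.directedDistances <- function(A, B, chunk = 2048L) {
  nb <- nrow(B)
  out <- numeric(nrow(A))
  b1 <- B[, 1]; b2 <- B[, 2]
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    d2 <- outer(A[s:e, 1], b1, "-")^2 + outer(A[s:e, 2], b2, "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Surface distances (ASD, HD95) for one class
#'
#' Surfaces are the class pixels with a 4-neighbour outside the class (image
#' border counts as outside); distances are Euclidean between pixel centres in
#' mm. ASD is the mean of the two directed average surface distances; HD95 the
#' 95th percentile (linear interpolation) of the pooled multiset of both
#' directed distance sets.
#'
#' @inheritParams diceIoU
#' @return named numeric \code{c(asd, hd95)} in mm.
#' @export
surfaceDistances <- function(pred, ref, classId) {
  .checkPair(pred, ref)
  sp <- pred@pixelSpacing
  toMM <- function(bw) {
    idx <- which(surfacePixels(bw), arr.ind = TRUE)
    cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2])
  }
  P <- toMM(pred@labels == classId)
  R <- toMM(ref@labels == classId)
  if (nrow(P) == 0)
    stopCondition("EmptySurfaceError",
                  sprintf("class %d has no surface in the predicted mask", classId),
                  which = "pred")
  if (nrow(R) == 0)
    stopCondition("EmptySurfaceError",
                  sprintf("class %d has no surface in the reference mask", classId),
                  which = "ref")
  dPR <- .directedDistances(P, R)
  dRP <- .directedDistances(R, P)
  c(asd = (mean(dPR) + mean(dRP)) / 2,
    hd95 = unname(quantile(c(dPR, dRP), 0.95, type = 7)))
}

#' Evaluate one predicted-vs-reference mask pair
#'
#' Applies \code{\link{diceIoU}} and \code{\link{surfaceDistances}} to the
#' three foreground classes and macro-averages them.
#'
#' @inheritParams diceIoU
#' @return A \linkS4class{SegEvalResult}.
#' @export
evaluatePair <- function(pred, ref) {
  .checkPair(pred, ref)
  rows <- lapply(names(.classIds), function(cls) {
    id <- .classIds[[cls]]
    di <- diceIoU(pred, ref, id)
    sd2 <- surfaceDistances(pred, ref, id)
    data.frame(class = cls, dice = di[["dice"]], iou = di[["iou"]],
               asd = sd2[["asd"]], hd95 = sd2[["hd95"]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  macro <- colMeans(tab[, c("dice", "iou", "asd", "hd95")])
  new("SegEvalResult", perClass = tab, macro = macro)
}

#' Evaluate a set of mask pairs
#'
#' @param pairs list of \code{list(pred = , ref = )} mask pairs.
#' @return data.frame with mean and SE (over pairs) per class and metric,
#'   including the macro rows.
#' @export
evaluateSet <- function(pairs) {
  if (!length(pairs)) stopCondition("ArgumentError", "no pairs to evaluate")
  res <- lapply(pairs, function(p) evaluatePair(p$pred, p$ref))
  if (length(pairs) == 1)
    warnCondition("DegenerateSetWarning", "single pair; SE reported as 0")
  seOf <- function(x) if (length(x) < 2) 0 else sd(x) / sqrt(length(x))
  classes <- c(names(.classIds), "macro")
  metrics <- c("dice", "iou", "asd", "hd95")
  out <- expand.grid(class = classes, metric = metrics,
                     stringsAsFactors = FALSE)
  vals <- mapply(function(cls, met) {
    v <- vapply(res, function(r)
      if (cls == "macro") r@macro[[met]]
      else r@perClass[r@perClass$class == cls, met], 0)
    c(mean(v), seOf(v))
  }, out$class, out$metric)
  out$mean <- vals[1, ]
  out$se <- vals[2, ]
  out[order(match(out$class, classes), match(out$metric, metrics)), ]
}
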
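#' @rdname LabelMask-class
#' @param object,x an object.
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname LabelMask-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname FacetAngles-class
#' @export
setGeneric("thetaLeft", function(x) standardGeneric("thetaLeft"))

#' @rdname FacetAngles-class
#' @export
setGeneric("thetaRight", function(x) standardGeneric("thetaRight"))

#' @rdname FacetAngles-class
#' @export
setGeneric("asymmetry", function(x) standardGeneric("asymmetry"))

#' @rdname LandmarkSet-class
#' @export
setGeneric("landmarkCoords", function(x) standardGeneric("landmarkCoords"))

#' @export
#' @rdname LabelMask-class
setMethod("maskLabels", "LabelMask", function(x) x@labels)

#' @export
#' @rdname LabelMask-class
setMethod("pixelSpacing", "LabelMask", function(x) x@pixelSpacing)

#' @export
#' @rdname FacetAngles-class
setMethod("thetaLeft", "FacetAngles", function(x) x@thetaLeft)

#' @export
#' @rdname FacetAngles-class
setMethod("thetaRight", "FacetAngles", function(x) x@thetaRight)

#' @export
#' @rdname FacetAngles-class
setMethod("asymmetry", "FacetAngles", function(x) x@asymmetry)

#' @export
#' @rdname LandmarkSet-class
setMethod("landmarkCoords", "LandmarkSet", function(x) {
  m <- rbind(AFR = x@AFR, PFR = x@PFR, AFL = x@AFL,
             PFL = x@PFL, VBC = x@VBC, SP = x@SP)
  colnames(m) <- c("ap_mm", "rl_mm")
  m
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels, levels = 0:3))
  cat(sprintf("LabelMask %dx%d px, spacing (%.4g, %.4g) mm [%s]\n",
              d[1], d[2], object@pixelSpacing[1], object@pixelSpacing[2],
              object@orientation))
  cat(sprintf("  pixels: bg=%d VB=%d FJ=%d PA=%d\n",
              tab[1], tab[2], tab[3], tab[4]))
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet (ap, rl) mm\n")
  print(round(landmarkCoords(object), 3))
})

setMethod("show", "FacetAngles", function(object) {
  cat(sprintf("FacetAngles: thetaL = %.2f deg, thetaR = %.2f deg, asymmetry = %+.2f deg\n",
              object@thetaLeft, object@thetaRight, object@asymmetry))
})

setMethod("show", "TropismCall", function(object) {
  cat(sprintf("TropismCall: |asymmetry| > %g deg -> %s%s\n", object@threshold,
              object@isTropism,
              if (!is.na(object@grade)) sprintf(" (grade: %s)", object@grade) else ""))
})

setMethod("show", "PhantomRecord", function(object) {
  cat(sprintf("PhantomRecord %d px @ %.3g mm, truth thetaL/thetaR = %.2f/%.2f deg%s\n",
              object@spec@imageSize, object@spec@pixelSpacing,
              object@truthAngles@thetaLeft, object@truthAngles@thetaRight,
              if (is.null(object@image)) "" else " (+image)"))
})

setMethod("show", "SegEvalResult", function(object) {
  cat("SegEvalResult (per class + macro):\n")
  print(cbind(object@perClass[, 1, drop = FALSE],
              round(object@perClass[, -1], 4)))
  cat("macro:", paste(sprintf("%s=%.4f", names(object@macro), object@macro),
                      collapse = " "), "\n")
})

setMethod("show", "RaterSeries", function(object) {
  cat(sprintf("RaterSeries '%s': %d slices\n", object@raterId,
              nrow(object@angles)))
})

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf("Bland-Altman (%s), n = %d\n", object@direction, object@n))
  cat(sprintf("  median bias %.3f deg, LoA [%.3f, %.3f] (2.5/97.5 pctl)\n",
              object@bias, object@loaLow, object@loaHigh))
  cat(sprintf("  frac |asymmetry| < %g deg: %s\n", object@reference,
              paste(sprintf("%s=%.3f", names(object@fracWithinRef),
                            object@fracWithinRef), collapse = " ")))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %s, %d folds, <=%d epochs (patience %d), lr %g, wd %g, batch %d, seed %d\n",
    object@architecture, object@folds, object@maxEpochs,
    object@earlyStopPatience, object@learningRate, object@weightDecay,
    object@batchSize, object@seed))
  cat("  augmentations:", paste(vapply(object@augmentations, `[[`, "", "name"),
                                collapse = ", "), "\n")
})
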
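setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Four-class axial label mask
#'
#' The common currency of the pipeline: a 2-D integer label map of one axial
#' lumbar slice with its pixel spacing. Labels are 0 = background,
#' 1 = vertebral body (VB), 2 = facet joints (FJ, both sides share the label;
#' laterality is derived geometrically downstream), 3 = posterior arch (PA).
#'
#' The orientation convention is radiological axial display and is pinned
#' throughout the package: row 1 is anterior and rows increase posteriorly;
#' columns increase toward the patient's left. Physical coordinates are
#' \code{(ap, rl)} millimetres obtained from 0-based pixel indices times
#' \code{pixelSpacing} (row, col).
#'
#' @slot labels integer matrix with values in \{0,1,2,3\}.
#' @slot pixelSpacing numeric length-2, mm per pixel (row, col), positive.
#' @slot orientation character, currently always \code{"radiological"}.
#' @export
setClass("LabelMask",
  representation(labels = "matrix", pixelSpacing = "numeric",
                 orientation = "character"),
  validity = function(object) {
    v <- object@labels
    if (!is.numeric(v)) return("labels must be a numeric/integer matrix")
    bad <- setdiff(unique(as.vector(v)), 0:3)
    if (length(bad))
      return(sprintf("labels outside {0,1,2,3}: %s",
                     paste(sort(bad), collapse = ", ")))
    if (length(object@pixelSpacing) != 2L || any(!is.finite(object@pixelSpacing)) ||
        any(object@pixelSpacing <= 0))
      return("pixelSpacing must be two strictly positive numbers (row, col) in mm")
    if (!identical(object@orientation, "radiological"))
      return("orientation must be 'radiological'")
    TRUE
  })

#' Construct a LabelMask
#'
#' @param labels integer matrix, values in 0:3.
#' @param pixelSpacing mm per pixel; scalar (isotropic) or length-2 (row, col).
#' @return A \linkS4class{LabelMask}.
#' @export
labelMask <- function(labels, pixelSpacing) {
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  m <- matrix(as.integer(labels), nrow = nrow(labels), ncol = ncol(labels))
  bad <- setdiff(unique(as.vector(m)), 0:3)
  if (length(bad))
    stopCondition("LabelError", sprintf(
      "label values outside {0,1,2,3}: %s", paste(sort(bad), collapse = ", ")))
  new("LabelMask", labels = m, pixelSpacing = as.numeric(pixelSpacing),
      orientation = "radiological")
}

# Class ids and names used throughout.
.classIds <- c(VB = 1L, FJ = 2L, PA = 3L)

#' The six anatomical landmarks of one axial slice
#'
#' Points are \code{(ap, rl)} in mm: \code{ap} anteroposterior (increasing
#' posterior), \code{rl} right-left (increasing toward patient left). AFR/PFR
#' are the anterior/posterior endpoints of the right facet joint, AFL/PFL of
#' the left; VBC is the vertebral body centre of mass; SP the spinous process
#' (most posterior point of the posterior arch).
#'
#' Validity enforces the laterality contract: AFL/PFL lie on the patient-left
#' side of the VBC->SP midline, AFR/PFR on the patient-right side.
#' @export
setClass("LandmarkSet",
  representation(AFR = "numeric", PFR = "numeric", AFL = "numeric",
                 PFL = "numeric", VBC = "numeric", SP = "numeric"),
  validity = function(object) {
    pts <- list(AFR = object@AFR, PFR = object@PFR, AFL = object@AFL,
                PFL = object@PFL, VBC = object@VBC, SP = object@SP)
    for (nm in names(pts)) {
      if (length(pts[[nm]]) != 2L || any(!is.finite(pts[[nm]])))
        return(sprintf("%s must be a finite (ap, rl) pair", nm))
    }
    v <- object@SP - object@VBC
    if (sqrt(sum(v^2)) > 0) {
      n <- c(-v[2], v[1]) / sqrt(sum(v^2))  # +ve toward patient left
      lat <- function(p) sum((p - object@VBC) * n)
      if (lat(object@AFL) <= 0 || lat(object@PFL) <= 0)
        return("AFL/PFL must lie on the patient-left side of the VBC->SP line")
      if (lat(object@AFR) >= 0 || lat(object@PFR) >= 0)
        return("AFR/PFR must lie on the patient-right side of the VBC->SP line")
    }
    TRUE
  })

#' Construct a LandmarkSet
#' @param AFR,PFR,AFL,PFL,VBC,SP numeric length-2 \code{(ap, rl)} points in mm.
#' @return A \linkS4class{LandmarkSet}.
#' @export
landmarkSet <- function(AFR, PFR, AFL, PFL, VBC, SP) {
  as2 <- function(p) as.numeric(p)[1:2]
  new("LandmarkSet", AFR = as2(AFR), PFR = as2(PFR), AFL = as2(AFL),
      PFL = as2(PFL), VBC = as2(VBC), SP = as2(SP))
}

#' Facet joint angles of one slice
#'
#' Left/right facet joint angles (degrees, acute, in [0, 90]) against the
#' VBC->SP midline, and their signed asymmetry \code{thetaLeft - thetaRight}.
#' @export
setClass("FacetAngles",
  representation(thetaLeft = "numeric", thetaRight = "numeric",
                 asymmetry = "numeric"),
  validity = function(object) {
    for (nm in c("thetaLeft", "thetaRight", "asymmetry")) {
      v <- slot(object, nm)
      if (length(v) != 1L || !is.finite(v)) return(sprintf("%s must be scalar", nm))
    }
    if (object@thetaLeft < 0 || object@thetaLeft > 90 ||
        object@thetaRight < 0 || object@thetaRight > 90)
      return("theta angles must lie in [0, 90] degrees")
    if (object@asymmetry != object@thetaLeft - object@thetaRight)
      return("asymmetry must equal thetaLeft - thetaRight exactly")
    TRUE
  })

#' Construct FacetAngles
#' @param thetaLeft,thetaRight angles in degrees, each in [0, 90].
#' @return A \linkS4class{FacetAngles}; asymmetry is derived.
#' @export
facetAngles <- function(thetaLeft, thetaRight) {
  new("FacetAngles", thetaLeft = as.numeric(thetaLeft),
      thetaRight = as.numeric(thetaRight),
      asymmetry = as.numeric(thetaLeft) - as.numeric(thetaRight))
}

#' Facet tropism call
#'
#' @slot threshold degrees, the asymmetry threshold applied.
#' @slot isTropism TRUE iff |asymmetry| strictly exceeds the threshold.
#' @slot grade graded severity under a named scheme, or NA.
#' @export
setClass("TropismCall",
  representation(threshold = "numeric", isTropism = "logical",
                 grade = "character"))

#' Synthetic phantom specification
#'
#' Parametrises one synthetic axial lumbar slice. All geometric dimensions are
#' in mm; the rendered field of view is \code{imageSize * pixelSpacing} mm
#' square. \code{thetaLeft}/\code{thetaRight} are the ground-truth facet
#' angles. See \code{\link{phantomSpec}} for defaults.
#' @export
setClass("PhantomSpec",
  representation(imageSize = "integer", pixelSpacing = "numeric",
                 thetaLeft = "numeric", thetaRight = "numeric",
                 vbSemiAxes = "numeric", facetLength = "numeric",
                 facetWidth = "numeric", paThickness = "numeric",
                 spLength = "numeric", noiseSd = "numeric",
                 blurSigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@imageSize < 32L) return("imageSize must be >= 32 pixels")
    if (object@pixelSpacing <= 0) return("pixelSpacing must be positive")
    for (nm in c("thetaLeft", "thetaRight")) {
      th <- slot(object, nm)
      if (length(th) != 1L || !is.finite(th) || th <= 0 || th >= 90)
        return(sprintf("%s must lie strictly inside (0, 90) degrees", nm))
    }
    if (length(object@vbSemiAxes) != 2L || any(object@vbSemiAxes <= 0))
      return("vbSemiAxes must be two positive mm values (ap, rl)")
    for (nm in c("facetLength", "facetWidth", "paThickness", "spLength"))
      if (slot(object, nm) <= 0) return(sprintf("%s must be positive", nm))
    if (object@noiseSd < 0 || object@blurSigma < 0)
      return("noiseSd and blurSigma must be non-negative")
    TRUE
  })

#' Phantom record: mask + ground truth
#'
#' @slot mask the rasterised \linkS4class{LabelMask}.
#' @slot image optional grayscale matrix in [0, 1] (NULL when not synthesised).
#' @slot truthAngles the analytic \linkS4class{FacetAngles}.
#' @slot truthLandmarks analytic continuous-coordinate \linkS4class{LandmarkSet}
#'   (mm, pre-rasterization).
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @export
setClass("PhantomRecord",
  representation(mask = "LabelMask", image = "matrixOrNULL",
                 truthAngles = "FacetAngles", truthLandmarks = "LandmarkSet",
                 spec = "PhantomSpec"))

#' Per-pair segmentation evaluation result
#'
#' Per-class Dice, IoU (unitless) and ASD, HD95 (mm) for one predicted vs.
#' reference mask pair, plus macro-averages over the three foreground classes.
#' @export
setClass("SegEvalResult",
  representation(perClass = "data.frame", macro = "numeric"))

#' A rater's angle series over slices
#'
#' One row per (id, level): thetaLeft, thetaRight, asymmetry in degrees.
#' @export
setClass("RaterSeries",
  representation(raterId = "character", angles = "data.frame"),
  validity = function(object) {
    need <- c("id", "level", "thetaLeft", "thetaRight", "asymmetry")
    miss <- setdiff(need, names(object@angles))
    if (length(miss)) return(sprintf("angles missing column(s): %s",
                                     paste(miss, collapse = ", ")))
    key <- paste(object@angles$id, object@angles$level, sep = "\r")
    if (anyDuplicated(key))
      return(sprintf("duplicate (id, level) pair(s): %s",
                     paste(unique(sub("\r", ":", key[duplicated(key)])), collapse = ", ")))
    TRUE
  })

#' Nonparametric Bland-Altman result
#'
#' Median bias with 2.5th/97.5th percentile limits of agreement of the
#' pairwise differences (first series minus second), the paired means/diffs
#' for plotting, and the per-rater fraction of slices with |asymmetry| below
#' the clinical reference value.
#' @export
setClass("BlandAltmanResult",
  representation(n = "integer", bias = "numeric", loaLow = "numeric",
                 loaHigh = "numeric", means = "numeric", diffs = "numeric",
                 fracWithinRef = "numeric", reference = "numeric",
                 direction = "character"))

#' Segmentation training configuration
#'
#' Mirrors the training protocol: Generalized Dice Loss, participant-level
#' k-fold cross-validation, Adam, early stopping on validation IoU, and the
#' named augmentations. \code{architecture} is a string resolved by the
#' trainer ("linear" or "mlp<H>", e.g. "mlp16").
#' @export
setClass("TrainConfig",
  representation(nClasses = "integer", inputSize = "integer",
                 batchSize = "integer", maxEpochs = "integer",
                 earlyStopPatience = "integer", learningRate = "numeric",
                 weightDecay = "numeric", folds = "integer", seed = "integer",
                 augmentations = "list", architecture = "character"),
  validity = function(object) {
    if (object@nClasses != 4L) return("nClasses must be 4")
    if (object@folds < 2L) return("folds must be >= 2")
    if (object@earlyStopPatience >= object@maxEpochs)
      return("earlyStopPatience must be strictly less than maxEpochs")
    if (object@learningRate <= 0) return("learningRate must be positive")
    if (object@weightDecay < 0) return("weightDecay must be non-negative")
    TRUE
  })
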
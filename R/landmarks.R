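# Landmark extraction from a four-class label mask: the postprocessing stage
# between segmentation and angle measurement.

# (ap, rl) mm coordinates of the pixels set in a logical matrix.
.pixelCoords <- function(bw, spacing) {
  idx <- which(bw, arr.ind = TRUE)
  cbind(ap = (idx[, 1] - 1) * spacing[1], rl = (idx[, 2] - 1) * spacing[2],
        col = idx[, 2])  # col kept for deterministic tie-breaking
}

#' Extract the six anatomical landmarks from a label mask
#'
#' Implements the deterministic landmark rules:
#' \itemize{
#'   \item VBC: centre of mass of the largest VB connected component (mm).
#'   \item SP: the PA pixel with the maximal posterior (row) coordinate; ties
#'     broken by column closest to VBC's column, then by lower column index.
#'   \item Facet endpoints: of the FJ components keep the two largest
#'     (4-connectivity); assign left/right by the sign of the lateral offset
#'     of each component centroid from the VBC->SP midline; within each
#'     component the anterior endpoint minimises and the posterior endpoint
#'     maximises the projection onto the VBC->SP axis, ties broken by greater
#'     absolute lateral offset, then lower column index.
#' }
#'
#' @param mask a \linkS4class{LabelMask}.
#' @return A \linkS4class{LandmarkSet} in mm.
#' @export
extractLandmarks <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  lab <- mask@labels
  sp <- mask@pixelSpacing
  for (cls in c("VB", "PA", "FJ"))
    if (!any(lab == .classIds[[cls]]))
      stopCondition("MissingROIError", sprintf("mask contains no %s pixels", cls),
                    roi = cls)

  ccVB <- connectedComponents(lab == 1L)
  vbPix <- .pixelCoords(ccVB == 1L, sp)  # component 1 = largest
  vbc <- c(mean(vbPix[, "ap"]), mean(vbPix[, "rl"]))

  ccPA <- connectedComponents(lab == 3L)
  paPix <- .pixelCoords(ccPA == 1L, sp)
  post <- paPix[paPix[, "ap"] == max(paPix[, "ap"]), , drop = FALSE]
  ord <- order(abs(post[, "rl"] - vbc[2]), post[, "col"])
  spPt <- post[ord[1], c("ap", "rl")]

  if (all(spPt == vbc))
    stopCondition("DegenerateAxisError", "VBC and SP coincide; midline undefined")
  m <- (spPt - vbc) / sqrt(sum((spPt - vbc)^2))
  nvec <- c(-m[2], m[1])  # positive toward patient left

  ccFJ <- connectedComponents(lab == 2L)
  k <- max(ccFJ)
  if (k < 2L)
    stopCondition("MissingROIError", sprintf(
      "FJ class forms %d connected component(s); two facet joints required", k),
      roi = "FJ")
  comps <- lapply(1:2, function(i) .pixelCoords(ccFJ == i, sp))
  latC <- vapply(comps, function(p)
    sum((c(mean(p[, "ap"]), mean(p[, "rl"])) - vbc) * nvec), 0)
  if (all(latC > 0) || all(latC < 0) || any(latC == 0))
    stopCondition("LateralityError", sprintf(
      "retained FJ components lie on the same side of the midline (lateral offsets %.2f, %.2f mm)",
      latC[1], latC[2]))
  left <- comps[[which(latC > 0)]]
  right <- comps[[which(latC < 0)]]

  endpoints <- function(p) {
    proj <- (p[, "ap"] - vbc[1]) * m[1] + (p[, "rl"] - vbc[2]) * m[2]
    lat <- (p[, "ap"] - vbc[1]) * nvec[1] + (p[, "rl"] - vbc[2]) * nvec[2]
    pick <- function(target) {
      cand <- which(proj == target)
      cand <- cand[order(-abs(lat[cand]), p[cand, "col"])]
      p[cand[1], c("ap", "rl")]
    }
    list(AF = pick(min(proj)), PF = pick(max(proj)))
  }
  eL <- endpoints(left)
  eR <- endpoints(right)
  landmarkSet(AFR = eR$AF, PFR = eR$PF, AFL = eL$AF, PFL = eL$PF,
              VBC = vbc, SP = spPt)
}
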
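# Synthetic axial lumbar-slice phantoms with analytic ground truth.
#
# The phantom renders the minimal anatomy the landmark algorithm relies on:
# an elliptical vertebral body (VB) anteriorly on the midline, a posterior
# arch (PA) as a ring segment around the spinal canal with a spinous-process
# strip protruding posteriorly, and two facet-joint (FJ) strips placed
# posterolaterally at the specified angles to the VBC->SP axis. FJ strips
# taper to sharp tips at their endpoints so that the extreme-projection
# landmark rule recovers the analytic endpoints to within rasterization
# error. All geometry is in mm; ground truth is stored in continuous
# coordinates before rasterization.

#' Construct a phantom specification
#'
#' Defaults emulate the axial acquisition the pipeline targets: 512x512
#' pixels at 0.35 mm spacing (a ~180 mm field of view). When
#' \code{pixelSpacing} is omitted it is scaled so the physical field stays
#' constant (e.g. \code{imageSize = 128} gives 1.4 mm/px), which keeps the
#' mm-scale anatomy valid at any raster resolution.
#'
#' @param imageSize pixels per side (square image).
#' @param pixelSpacing mm per pixel; default \code{0.35 * 512 / imageSize}.
#' @param thetaLeft,thetaRight ground-truth facet angles in degrees,
#'   strictly inside (0, 90); the sampler draws from [5, 85].
#' @param vbSemiAxes vertebral-body ellipse semi-axes (ap, rl) in mm.
#' @param facetLength,facetWidth facet strip dimensions in mm.
#' @param paThickness posterior-arch ring thickness in mm.
#' @param spLength spinous-process protrusion length in mm.
#' @param noiseSd additive Gaussian noise SD (intensity units) for the
#'   synthesised grayscale image.
#' @param blurSigma Gaussian blur sigma in mm for the synthesised image.
#' @param seed integer RNG seed (image noise; masks are deterministic).
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(imageSize = 512L,
                        pixelSpacing = 0.35 * 512 / imageSize,
                        thetaLeft = 45, thetaRight = 40,
                        vbSemiAxes = c(16, 22),
                        facetLength = 20, facetWidth = 3,
                        paThickness = 5, spLength = 12,
                        noiseSd = 0.03, blurSigma = 0.5,
                        seed = 1L) {
  new("PhantomSpec", imageSize = as.integer(imageSize),
      pixelSpacing = as.numeric(pixelSpacing),
      thetaLeft = as.numeric(thetaLeft), thetaRight = as.numeric(thetaRight),
      vbSemiAxes = as.numeric(vbSemiAxes),
      facetLength = as.numeric(facetLength), facetWidth = as.numeric(facetWidth),
      paThickness = as.numeric(paThickness), spLength = as.numeric(spLength),
      noiseSd = as.numeric(noiseSd), blurSigma = as.numeric(blurSigma),
      seed = as.integer(seed))
}

# Fixed layout constants (mm); chosen once so that all regions are pairwise
# clear of each other across the supported angle range.
.phantomLayout <- list(
  vbcApFrac = 0.35,     # VBC anteroposterior position as fraction of field
  canalGap = 14,        # VB posterior pole -> canal centre
  canalRadius = 9,      # PA ring inner radius
  ringHalfAngleDeg = 135,  # ring angular extent about the posterior direction
  spHalfWidth = 3,      # spinous-process strip half width
  facetLatOffset = 26,  # facet centre lateral distance from midline
  facetApOffset = 2     # facet centre posterior offset from canal centre
)

# All analytic geometry for a spec: centres, endpoints, truth landmarks.
.phantomGeometry <- function(spec) {
  L <- .phantomLayout
  s <- spec@pixelSpacing
  field <- (spec@imageSize - 1) * s        # extent of pixel-centre grid, mm
  # lateral midline pinned to a pixel-column centre: keeps the spinous
  # process tie-break on the midline and the VBC->SP axis exactly vertical
  mid <- s * floor((spec@imageSize - 1) / 2)
  vbc <- c(L$vbcApFrac * field, mid)
  canal <- c(vbc[1] + spec@vbSemiAxes[1] + L$canalGap, mid)
  rIn <- L$canalRadius
  rOut <- rIn + spec@paThickness
  spTip <- c(canal[1] + rOut + spec@spLength, mid)
  mkFacet <- function(theta, side) {  # side +1 = patient left, -1 = right
    th <- theta * pi / 180
    d <- c(cos(th), side * sin(th))          # anterior -> posterior direction
    ctr <- c(canal[1] + L$facetApOffset, mid + side * L$facetLatOffset)
    list(center = ctr, dir = d,
         AF = ctr - spec@facetLength / 2 * d,
         PF = ctr + spec@facetLength / 2 * d,
         halfWidth = spec@facetWidth / 2)
  }
  fL <- mkFacet(spec@thetaLeft, +1)
  fR <- mkFacet(spec@thetaRight, -1)
  list(field = field, mid = mid, vbc = vbc, canal = canal,
       rIn = rIn, rOut = rOut, spTip = spTip, facetLeft = fL, facetRight = fR,
       landmarks = landmarkSet(AFR = fR$AF, PFR = fR$PF, AFL = fL$AF,
                               PFL = fL$PF, VBC = vbc, SP = spTip))
}

.dilate8 <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  out <- bw
  out[-1, ] <- out[-1, ] | bw[-h, ]
  out[-h, ] <- out[-h, ] | bw[-1, ]
  tmp <- out
  out[, -1] <- out[, -1] | tmp[, -w]
  out[, -w] <- out[, -w] | tmp[, -1]
  out
}

# Supercover of a segment: pixels whose cell the segment passes through
# (separating-axis test on the segment's axes; slightly conservative on the
# cell axes). Supercovers of connected sets are 4-connected.
.scSegment <- function(AP, RL, A, B, s) {
  v <- B - A
  len <- sqrt(sum(v^2))
  if (len < 1e-9)
    return(abs(AP - A[1]) <= s / 2 & abs(RL - A[2]) <= s / 2)
  d <- v / len; nv <- c(-d[2], d[1])
  qa <- AP - A[1]; qb <- RL - A[2]
  sp <- qa * d[1] + qb * d[2]
  tp <- qa * nv[1] + qb * nv[2]
  band <- (s / 2) * (abs(nv[1]) + abs(nv[2]))
  bandS <- (s / 2) * (abs(d[1]) + abs(d[2]))
  sp >= -bandS & sp <= len + bandS & abs(tp) <= band
}

# Facet strip rasterization. The body is a constant-width core kept clear of
# the tip rows; the tips are approached through a supercover polyline whose
# last leg is parallel to the VBC->SP axis, so the extreme-projection pixel
# sits in the single column containing the endpoint -- this bounds the
# landmark quantization error at half a pixel laterally, which is what keeps
# angle recovery within the rasterization tolerance.
.rasterizeFacet <- function(AP, RL, f, s) {
  AF <- f$AF; PF <- f$PF
  bend <- 2 * s
  margin <- f$halfWidth * tan(60 * pi / 180) + 2 * s
  qa <- AP - f$center[1]; qb <- RL - f$center[2]
  sproj <- qa * f$dir[1] + qb * f$dir[2]
  tproj <- -qa * f$dir[2] + qb * f$dir[1]
  halfLen <- sqrt(sum((PF - AF)^2)) / 2
  if (margin >= halfLen)
    stopCondition("GeometryError", sprintf(
      "facet width %.3g mm too large for facet length %.3g mm at %.3g mm spacing",
      2 * f$halfWidth, 2 * halfLen, s))
  core <- abs(sproj) <= halfLen - margin & abs(tproj) <= f$halfWidth
  if (PF[1] - AF[1] > 2 * bend + s) {
    A2 <- c(AF[1] + bend, AF[2])
    P2 <- c(PF[1] - bend, PF[2])
    .scSegment(AP, RL, AF, A2, s) | .scSegment(AP, RL, A2, P2, s) |
      .scSegment(AP, RL, P2, PF, s) | core
  } else {
    # near-horizontal facet: vertical tip whiskers would overlap; fall back
    # to the plain segment supercover (accuracy degrades above ~80 degrees)
    .scSegment(AP, RL, AF, PF, s) | core
  }
}

#' Generate a synthetic axial-slice phantom
#'
#' Rasterises the spec's analytic geometry into a four-class
#' \linkS4class{LabelMask} and (optionally) a grayscale image with per-class
#' intensities, Gaussian blur and additive Gaussian noise. The generator
#' verifies its own topological contract -- VB, PA and the two FJ strips must
#' rasterize non-empty, pairwise disjoint and non-touching, with one
#' connected component each -- and raises a \code{GeometryError} otherwise.
#' Identical spec + seed gives bit-identical output.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param image logical; also synthesise the grayscale image?
#' @return A \linkS4class{PhantomRecord}.
#' @export
generatePhantom <- function(spec, image = FALSE) {
  stopifnot(is(spec, "PhantomSpec"))
  g <- .phantomGeometry(spec)
  n <- spec@imageSize
  s <- spec@pixelSpacing
  ap <- (seq_len(n) - 1) * s
  rl <- (seq_len(n) - 1) * s
  AP <- matrix(ap, n, n)               # varies along rows
  RL <- matrix(rl, n, n, byrow = TRUE) # varies along cols
  vb <- ((AP - g$vbc[1]) / spec@vbSemiAxes[1])^2 +
        ((RL - g$vbc[2]) / spec@vbSemiAxes[2])^2 <= 1
  dxa <- AP - g$canal[1]; dxb <- RL - g$canal[2]
  r <- sqrt(dxa^2 + dxb^2)
  ring <- r >= g$rIn & r <= g$rOut &
          dxa >= r * cos(.phantomLayout$ringHalfAngleDeg * pi / 180)
  sp <- AP >= g$canal[1] + g$rIn & AP <= g$spTip[1] &
        abs(RL - g$mid) <= .phantomLayout$spHalfWidth
  pa <- ring | sp
  fjl <- .rasterizeFacet(AP, RL, g$facetLeft, s)
  fjr <- .rasterizeFacet(AP, RL, g$facetRight, s)

  regions <- list(VB = vb, PA = pa, `FJ-left` = fjl, `FJ-right` = fjr)
  for (nm in names(regions))
    if (!any(regions[[nm]]))
      stopCondition("GeometryError", sprintf(
        "region %s rasterizes to zero pixels (geometry too small for %d px @ %g mm)",
        nm, n, s))
  for (i in seq_along(regions)) for (j in seq_along(regions)) {
    if (i >= j) next
    if (any(.dilate8(regions[[i]]) & regions[[j]]))
      stopCondition("GeometryError", sprintf(
        "regions %s and %s overlap or touch", names(regions)[i], names(regions)[j]))
  }
  for (nm in names(regions)) {
    k <- max(connectedComponents(regions[[nm]]))
    if (k != 1L)
      stopCondition("GeometryError", sprintf(
        "region %s rasterizes to %d connected components (expected 1)", nm, k))
  }

  lab <- matrix(0L, n, n)
  lab[vb] <- 1L; lab[fjl | fjr] <- 2L; lab[pa] <- 3L
  mask <- labelMask(lab, s)
  img <- NULL
  if (image) img <- .phantomImage(lab, spec)
  new("PhantomRecord", mask = mask, image = img,
      truthAngles = facetAngles(spec@thetaLeft, spec@thetaRight),
      truthLandmarks = g$landmarks, spec = spec)
}

.classIntensity <- c(0.2, 0.7, 0.5, 0.9)  # bg, VB, FJ, PA

.blurGaussian <- function(m, sigmaPx) {
  if (all(sigmaPx <= 0)) return(m)
  conv1 <- function(x, sigma, along) {
    if (sigma <= 0) return(x)
    rad <- max(1L, ceiling(3 * sigma))
    k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2)); k <- k / sum(k)
    out <- 0
    idx <- seq_len(if (along == 1) nrow(x) else ncol(x))
    for (o in seq(-rad, rad)) {
      sidx <- pmin(pmax(idx + o, 1L), length(idx))  # replicate edges
      out <- out + k[o + rad + 1] *
        (if (along == 1) x[sidx, , drop = FALSE] else x[, sidx, drop = FALSE])
    }
    out
  }
  conv1(conv1(m, sigmaPx[1], 1L), sigmaPx[2], 2L)
}

.phantomImage <- function(lab, spec) {
  img <- matrix(.classIntensity[lab + 1L], nrow(lab), ncol(lab))
  img <- .blurGaussian(img, rep(spec@blurSigma / spec@pixelSpacing, 2))
  if (spec@noiseSd > 0)
    img <- img + withSeed(spec@seed,
                          matrix(rnorm(length(img), 0, spec@noiseSd),
                                 nrow(img), ncol(img)))
  img
}

#' Reference cohort angle statistics
#'
#' Population means and standard errors of the right/left facet angles per
#' spinal level and sex, with the subgroup sizes they were computed from.
#' These are the sampling targets for \code{\link{sampleCohortSpecs}}:
#' per-subject SD is recovered as \code{SE * sqrt(nTable)}.
#'
#' @return data.frame with columns sex, level, meanRight, seRight, meanLeft,
#'   seLeft, nTable.
#' @export
cohortReference <- function() {
  data.frame(
    sex = rep(c("female", "male"), each = 3),
    level = rep(c("L3/4", "L4/5", "L5/S1"), 2),
    meanRight = c(36.15, 44.28, 48.00, 36.42, 44.49, 47.56),
    seRight   = c(0.35, 0.41, 0.41, 0.39, 0.45, 0.46),
    meanLeft  = c(38.03, 46.76, 48.11, 38.03, 47.68, 47.41),
    seLeft    = c(0.34, 0.39, 0.42, 0.38, 0.46, 0.47),
    nTable    = c(678, 678, 678, 599, 599, 599),
    stringsAsFactors = FALSE)
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

#' Sample cohort-like phantom specifications
#'
#' Draws ground-truth left/right facet angles from truncated normal
#' distributions (support [5, 85] degrees) whose means match the reference
#' cohort subgroup means and whose SDs equal \code{SE * sqrt(nTable)} (see
#' \code{\link{cohortReference}}), then wraps them in phantom specs.
#'
#' @param n number of specs to draw.
#' @param level spinal level ("L3/4", "L4/5", "L5/S1"; common aliases accepted).
#' @param sex subgroup label ("female"/"male").
#' @param seed integer seed; the draw is reproducible and does not disturb the
#'   caller's RNG.
#' @param ... further arguments to \code{\link{phantomSpec}} (e.g.
#'   \code{imageSize}).
#' @return list of \linkS4class{PhantomSpec}.
#' @export
sampleCohortSpecs <- function(n, level, sex, seed = 1L, ...) {
  if (n < 1) stopCondition("ArgumentError", "n must be >= 1")
  level <- normalizeLevel(level)
  sex <- normalizeSex(sex)
  ref <- cohortReference()
  row <- ref[ref$sex == sex & ref$level == level, ]
  withSeed(seed, {
    thL <- .rtruncnorm(n, row$meanLeft, row$seLeft * sqrt(row$nTable), 5, 85)
    thR <- .rtruncnorm(n, row$meanRight, row$seRight * sqrt(row$nTable), 5, 85)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i)
      phantomSpec(thetaLeft = thL[i], thetaRight = thR[i], seed = seeds[i], ...))
  })
}
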
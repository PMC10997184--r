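# Facet joint angles, tropism calls, and cohort-level summaries.

.angleBetween <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stopCondition("DegenerateAxisError", "zero-length direction vector")
  # acute-angle convention: facet lines are undirected, so take |cos|
  acos(min(1, abs(sum(u * v)) / (nu * nv))) * 180 / pi
}

#' Compute facet joint angles from landmarks
#'
#' For each side the facet line runs from the anterior to the posterior facet
#' endpoint; its angle against the midline (VBC -> SP) is
#' \code{acos(|u.v| / (|u||v|))} in degrees -- the acute angle in [0, 90],
#' invariant to reversing either line's direction. Asymmetry is the signed
#' difference \code{thetaLeft - thetaRight}.
#'
#' @param lm a \linkS4class{LandmarkSet}.
#' @return A \linkS4class{FacetAngles}.
#' @export
computeAngles <- function(lm) {
  stopifnot(is(lm, "LandmarkSet"))
  v <- lm@SP - lm@VBC
  facetAngles(thetaLeft = .angleBetween(lm@PFL - lm@AFL, v),
              thetaRight = .angleBetween(lm@PFR - lm@AFR, v))
}

#' Facet tropism threshold and grading registry
#'
#' Literature thresholds and graded schemes for facet tropism. Binary
#' thresholds are |asymmetry| cutoffs (strict \code{>}); the graded scheme
#' bands use exclusive lower and inclusive upper bounds.
#'
#' @return list with \code{thresholds} (named degrees) and \code{schemes}
#'   (named lists of band upper bounds).
#' @export
tropismSchemes <- function() {
  list(
    thresholds = c(zhou2017 = 5, kalichman2009 = 7, samartzis2015 = 7,
                   ko2018 = 7, samartzis2016 = 8, chadha2012 = 10,
                   bao2014 = 10, schleich2015 = 10, wang2016 = 10,
                   gao2016 = 10),
    schemes = list(
      # |asymmetry| in (5,7] mild, (7,15] moderate, >15 severe
      mohanty2017 = c(none = 5, mild = 7, moderate = 15, severe = Inf)
    ))
}

#' Classify facet tropism
#'
#' @param angles a \linkS4class{FacetAngles}.
#' @param threshold degrees; tropism iff |asymmetry| strictly exceeds it.
#' @param scheme optional grading scheme name (see
#'   \code{\link{tropismSchemes}}) or a named numeric vector of band upper
#'   bounds (exclusive lower, inclusive upper).
#' @return A \linkS4class{TropismCall}.
#' @export
classifyTropism <- function(angles, threshold = 7, scheme = NULL) {
  stopifnot(is(angles, "FacetAngles"))
  .scalarNum(threshold, "threshold", min = 0, strict = TRUE)
  a <- abs(angles@asymmetry)
  grade <- NA_character_
  if (!is.null(scheme)) {
    bands <- if (is.character(scheme)) {
      sc <- tropismSchemes()$schemes[[scheme]]
      if (is.null(sc))
        stopCondition("ArgumentError", sprintf("unknown grading scheme '%s'", scheme))
      sc
    } else scheme
    grade <- names(bands)[which(a <= bands)[1]]
  }
  new("TropismCall", threshold = threshold, isTropism = a > threshold,
      grade = grade)
}

# Report rounding: half-even (base R round) to 2 decimals; stored values stay
# unrounded, this is only for printed tables.
reportRound <- function(x) round(x, 2)

#' Summarise facet angles over a cohort
#'
#' Per (level, sex) cell: mean and SE (sample SD / sqrt(n)) of the right and
#' left angles, the pooled per-subject average (thetaL + thetaR)/2, and the
#' asymmetry magnitude |thetaL - thetaR|; facet-tropism prevalence (count and
#' percentage) at each threshold; plus the full signed-asymmetry distribution
#' with the fractions inside +/-10 and +/-20 degrees.
#'
#' @param records data.frame with columns id, level, sex, thetaLeft,
#'   thetaRight (degrees); or a list of such rows.
#' @param thresholds numeric vector of |asymmetry| thresholds (degrees).
#' @return list with \code{cells}, \code{prevalence}, \code{distribution}.
#' @export
summarizeCohort <- function(records, thresholds = c(7, 10)) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("id", "level", "sex", "thetaLeft", "thetaRight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopCondition("SchemaError", sprintf("records missing column(s): %s",
                                         paste(miss, collapse = ", ")))
  if (nrow(df) == 0)
    stopCondition("EmptyCellError", "no records to summarise")
  df$level <- normalizeLevel(df$level)
  df$sex <- normalizeSex(df$sex)
  df$asym <- df$thetaLeft - df$thetaRight

  seOf <- function(x) if (length(x) < 2) 0 else sd(x) / sqrt(length(x))
  cellList <- split(df, list(df$sex, df$level), drop = TRUE, sep = "\r")
  warned <- FALSE
  cells <- do.call(rbind, lapply(cellList, function(d) {
    if (nrow(d) == 1 && !warned) {
      warned <<- TRUE
      warnCondition("DegenerateCellWarning", sprintf(
        "cell (%s, %s) has a single record; SE reported as 0", d$sex[1], d$level[1]))
    }
    avg <- (d$thetaLeft + d$thetaRight) / 2
    data.frame(sex = d$sex[1], level = d$level[1], n = nrow(d),
               meanRight = mean(d$thetaRight), seRight = seOf(d$thetaRight),
               meanLeft = mean(d$thetaLeft), seLeft = seOf(d$thetaLeft),
               meanAverage = mean(avg), seAverage = seOf(avg),
               meanAbsAsymmetry = mean(abs(d$asym)),
               seAbsAsymmetry = seOf(abs(d$asym)),
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  cells <- cells[order(cells$sex, cells$level), ]

  prev <- do.call(rbind, lapply(cellList, function(d) {
    do.call(rbind, lapply(thresholds, function(th) {
      cnt <- sum(abs(d$asym) > th)
      data.frame(sex = d$sex[1], level = d$level[1], threshold = th,
                 n = nrow(d), count = cnt, percent = 100 * cnt / nrow(d),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(prev) <- NULL
  prev <- prev[order(prev$sex, prev$level, prev$threshold), ]

  list(cells = cells, prevalence = prev,
       distribution = list(
         asymmetry = df$asym,
         fracWithin10 = mean(abs(df$asym) < 10),
         fracWithin20 = mean(abs(df$asym) < 20)))
}

#' Histogram of signed asymmetry for reporting
#'
#' @param asymmetry numeric vector of signed asymmetries (degrees).
#' @param binWidth bin width in degrees.
#' @return data.frame with bin edges and counts.
#' @export
asymmetryHistogram <- function(asymmetry, binWidth = 2) {
  lo <- floor(min(asymmetry) / binWidth) * binWidth
  hi <- ceiling(max(asymmetry) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  edges <- seq(lo, hi, by = binWidth)
  counts <- as.integer(table(cut(asymmetry, breaks = edges, include.lowest = TRUE,
                                 right = FALSE)))
  data.frame(binLow = head(edges, -1), binHigh = edges[-1], count = counts)
}
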
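# Rater-agreement analytics: nonparametric Bland-Altman, r-squared,
# normality gates, and per-ROI rater Dice matrices.

#' Construct a rater series
#'
#' @param angles data.frame with columns id, level, thetaLeft, thetaRight
#'   (asymmetry is derived if absent).
#' @param raterId label for the rater.
#' @return A \linkS4class{RaterSeries}.
#' @export
raterSeries <- function(angles, raterId) {
  df <- as.data.frame(angles, stringsAsFactors = FALSE)
  if (is.null(df$asymmetry)) df$asymmetry <- df$thetaLeft - df$thetaRight
  df$id <- as.character(df$id)
  df$level <- normalizeLevel(df$level)
  new("RaterSeries", raterId = as.character(raterId), angles = df)
}

.commonPairs <- function(a, b) {
  ka <- paste(a@angles$id, a@angles$level, sep = "\r")
  kb <- paste(b@angles$id, b@angles$level, sep = "\r")
  common <- intersect(ka, kb)
  list(a = a@angles[match(common, ka), , drop = FALSE],
       b = b@angles[match(common, kb), , drop = FALSE])
}

#' Nonparametric Bland-Altman agreement on facet asymmetry
#'
#' Differences are \code{asymmetry(a) - asymmetry(b)} over the common
#' (id, level) pairs. The bias is the median difference; the limits of
#' agreement are the 2.5th and 97.5th percentiles (linear interpolation) --
#' the nonparametric variant appropriate when differences fail normality.
#' \code{fracWithinRef} reports, per rater, the fraction of common slices
#' whose |asymmetry| is strictly below the clinical reference value.
#'
#' @param a,b \linkS4class{RaterSeries}.
#' @param reference reference asymmetry in degrees (clinical threshold).
#' @return A \linkS4class{BlandAltmanResult}.
#' @export
blandAltman <- function(a, b, reference = 10) {
  stopifnot(is(a, "RaterSeries"), is(b, "RaterSeries"))
  cp <- .commonPairs(a, b)
  n <- nrow(cp$a)
  if (n < 2)
    stopCondition("InsufficientOverlapError", sprintf(
      "only %d common (id, level) pair(s) between raters %s and %s",
      n, a@raterId, b@raterId))
  diffs <- cp$a$asymmetry - cp$b$asymmetry
  loa <- quantile(diffs, c(0.025, 0.975), type = 7, names = FALSE)
  frac <- c(mean(abs(cp$a$asymmetry) < reference),
            mean(abs(cp$b$asymmetry) < reference))
  names(frac) <- c(a@raterId, b@raterId)
  new("BlandAltmanResult", n = as.integer(n), bias = median(diffs),
      loaLow = loa[1], loaHigh = loa[2],
      means = (cp$a$asymmetry + cp$b$asymmetry) / 2, diffs = diffs,
      fracWithinRef = frac, reference = as.numeric(reference),
      direction = sprintf("%s - %s", a@raterId, b@raterId))
}

#' Coefficient of determination between two raters
#'
#' Squared Pearson correlation of the chosen measure over common pairs
#' (equal to OLS R-squared in simple linear regression).
#'
#' @param a,b \linkS4class{RaterSeries}.
#' @param measure one of "asymmetry", "thetaLeft", "thetaRight".
#' @return r-squared, unitless in [0, 1].
#' @export
rSquared <- function(a, b, measure = c("asymmetry", "thetaLeft", "thetaRight")) {
  measure <- match.arg(measure)
  cp <- .commonPairs(a, b)
  if (nrow(cp$a) < 3)
    stopCondition("InsufficientOverlapError",
                  "r-squared needs at least 3 common pairs")
  x <- cp$a[[measure]]; y <- cp$b[[measure]]
  if (sd(x) == 0 || sd(y) == 0)
    stopCondition("ZeroVarianceError", "zero variance in one of the series")
  cor(x, y)^2
}

#' Normality gate for agreement analyses
#'
#' Shapiro-Wilk and Kolmogorov-Smirnov (against a normal with the sample mean
#' and SD) tests, plus a flag saying whether the nonparametric analysis path
#' is required at alpha = 0.05 (either test rejecting). For n > 5000 the
#' Shapiro-Wilk statistic is computed on 5000 evenly spaced order statistics
#' (the test's implementation limit).
#'
#' @param x numeric vector (degrees), n >= 8.
#' @param alpha significance level for the flag.
#' @return list with shapiro (statistic, p), ks (statistic, p), and
#'   \code{nonparametricRequired}.
#' @export
normalityTests <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 8)
    stopCondition("ArgumentError", sprintf("need n >= 8 observations, got %d", n))
  xs <- if (n > 5000) sort(x)[round(seq(1, n, length.out = 5000))] else x
  sw <- shapiro.test(xs)
  ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  list(shapiro = list(statistic = unname(sw$statistic), p = sw$p.value),
       ks = list(statistic = unname(ks$statistic), p = ks$p.value),
       nonparametricRequired = (sw$p.value < alpha) || (ks$p.value < alpha))
}

#' Per-ROI Dice between annotation sets
#'
#' For every ordered pair of raters (including a rater against a
#' re-annotation of itself for intrarater reliability), the mean per-class
#' Dice over the common slices.
#'
#' @param annotationSets named list (rater -> named list of
#'   \linkS4class{LabelMask}s keyed by slice id). All sets must cover the
#'   same slice keys.
#' @return data.frame raterA, raterB, class, dice (mean over slices).
#' @export
raterDiceMatrix <- function(annotationSets) {
  raters <- names(annotationSets)
  if (length(raters) < 2)
    stopCondition("ArgumentError", "need at least two annotation sets")
  keys <- lapply(annotationSets, names)
  all <- Reduce(union, keys)
  for (r in raters) {
    missing <- setdiff(all, keys[[r]])
    if (length(missing))
      stopCondition("KeyMismatchError", sprintf(
        "rater %s is missing slice(s): %s", r, paste(missing, collapse = ", ")))
  }
  out <- list()
  for (i in seq_along(raters)) for (j in seq_along(raters)) {
    if (i >= j) next
    d <- vapply(names(.classIds), function(cls) {
      mean(vapply(all, function(k)
        diceIoU(annotationSets[[i]][[k]], annotationSets[[j]][[k]],
                .classIds[[cls]])[["dice"]], 0))
    }, 0)
    out[[length(out) + 1L]] <- data.frame(
      raterA = raters[i], raterB = raters[j], class = names(.classIds),
      dice = unname(d), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
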
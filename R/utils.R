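#' @import methods
#' @importFrom stats quantile median sd cor rnorm runif shapiro.test ks.test setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Structured error conditions. Every package error inherits "facetError" so
# callers can catch broadly; the leading class names the contract violated
# (GeometryError, LabelError, FormatError, MissingROIError, LateralityError,
# DegenerateAxisError, EmptySurfaceError, ...).
stopCondition <- function(class, message, ...) {
  stop(structure(
    class = c(class, "facetError", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

warnCondition <- function(class, message, ...) {
  warning(structure(
    class = c(class, "facetWarning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# restored afterwards so library code never perturbs user-level randomness.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Canonical spinal level labels with common aliases.
.levelCanonical <- c("L3/4", "L4/5", "L5/S1")

normalizeLevel <- function(level) {
  lv <- toupper(gsub("[ _-]", "", as.character(level)))
  lv <- gsub("L3L4|L34|L3/4", "L3/4", lv)
  lv <- gsub("L4L5|L45|L4/5", "L4/5", lv)
  lv <- gsub("L5S1|L5/S1", "L5/S1", lv)
  bad <- !(lv %in% .levelCanonical)
  if (any(bad))
    stopCondition("LevelError", sprintf(
      "unknown spinal level(s): %s (expected one of %s)",
      paste(unique(level[bad]), collapse = ", "),
      paste(.levelCanonical, collapse = ", ")))
  lv
}

normalizeSex <- function(sex) {
  sx <- tolower(as.character(sex))
  sx[sx %in% c("f", "female")] <- "female"
  sx[sx %in% c("m", "male")] <- "male"
  bad <- !(sx %in% c("female", "male"))
  if (any(bad))
    stopCondition("SexError", sprintf(
      "unknown sex label(s): %s (expected female/male)",
      paste(unique(sex[bad]), collapse = ", ")))
  sx
}

.scalarNum <- function(x, name, min = -Inf, max = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopCondition("ArgumentError", sprintf("%s must be a finite numeric scalar", name))
  ok <- if (strict) (x > min && x < max) else (x >= min && x <= max)
  if (!ok)
    stopCondition("ArgumentError", sprintf(
      "%s = %g outside %s%g, %g%s", name, x,
      if (strict) "(" else "[", min, max, if (strict) ")" else "]"))
  invisible(x)
}
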
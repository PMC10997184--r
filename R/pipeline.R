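# End-to-end orchestration: phantom generation or mask ingestion ->
# landmarks -> angles -> cohort summary, with a run manifest and explicit
# per-slice failure accounting. Slice selection per level stays an input
# (the metadata table): the framework is deliberately semiautomatic.

#' Run the measurement pipeline
#'
#' Two entry modes: \code{phantom} (generate n phantoms per the cohort
#' sampler and measure them) or \code{metadata} (read masks listed in a
#' slice-metadata CSV). Stages run in order landmarks -> angles -> cohort;
#' per-slice failures are logged to \code{exclusions.csv} with reasons and
#' excluded, never silently dropped; if more than half the slices of a stage
#' fail the run aborts. Outputs (CSV tables plus \code{manifest.json}) are
#' deterministic under the seed.
#'
#' @param outDir output directory (created if needed).
#' @param phantom NULL, or list(n, level, sex, imageSize, image) describing a
#'   phantom cohort to generate.
#' @param metadata NULL, or path to a slice-metadata CSV
#'   (see \code{\link{loadMetadata}}).
#' @param pixelSpacing spacing for PNG masks read via metadata.
#' @param thresholds facet-tropism thresholds in degrees.
#' @param seed integer seed for phantom sampling.
#' @param resume if TRUE, stages whose output files already exist are skipped.
#' @return the manifest (list), invisibly; written as \code{manifest.json}.
#' @export
runPipeline <- function(outDir, phantom = NULL, metadata = NULL,
                        pixelSpacing = NULL, thresholds = c(7, 10),
                        seed = 1L, resume = FALSE) {
  if (is.null(phantom) == is.null(metadata))
    stopCondition("ConfigError", "exactly one of phantom/metadata must be given")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "facetropism",
                   version = as.character(utils::packageVersion("facetropism")),
                   seed = as.integer(seed), stages = list())
  exclusions <- data.frame(id = character(), level = character(),
                           stage = character(), reason = character(),
                           stringsAsFactors = FALSE)

  # ---- stage: inputs (generate or ingest masks) ----
  slices <- list()  # per slice: id, level, sex, mask, truth (optional)
  if (!is.null(phantom)) {
    ph <- utils::modifyList(list(n = 10L, level = "L4/5", sex = "female",
                                 imageSize = 128L, image = FALSE), phantom)
    specs <- sampleCohortSpecs(ph$n, ph$level, ph$sex, seed = seed,
                               imageSize = ph$imageSize)
    maskDir <- file.path(outDir, "masks")
    dir.create(maskDir, showWarnings = FALSE)
    truth <- data.frame()
    for (i in seq_along(specs)) {
      rec <- generatePhantom(specs[[i]], image = isTRUE(ph$image))
      id <- sprintf("phantom_%04d", i)
      writeMask(rec@mask, file.path(maskDir, sprintf("mask_%04d.png", i)))
      if (!is.null(rec@image))
        writeImage(rec@image, file.path(maskDir, sprintf("img_%04d.png", i)))
      lm <- landmarkCoords(rec@truthLandmarks)
      truth <- rbind(truth, data.frame(
        id = id, level = normalizeLevel(ph$level),
        theta_left_deg = rec@truthAngles@thetaLeft,
        theta_right_deg = rec@truthAngles@thetaRight,
        asymmetry_deg = rec@truthAngles@asymmetry,
        t(setNames(as.vector(t(lm)),
                   paste0(rep(rownames(lm), each = 2), "_",
                          rep(c("ap_mm", "rl_mm"), 6))))))
      slices[[length(slices) + 1L]] <- list(
        id = id, level = normalizeLevel(ph$level), sex = normalizeSex(ph$sex),
        mask = rec@mask)
    }
    write.csv(truth, file.path(outDir, "truth.csv"), row.names = FALSE)
    manifest$stages$phantom <- list(rows_in = ph$n, rows_out = length(slices),
                                    excluded = 0L)
  } else {
    meta <- loadMetadata(metadata)
    for (i in seq_len(nrow(meta))) {
      row <- meta[i, ]
      res <- tryCatch(
        list(ok = TRUE, mask = readMask(row$mask_path, pixelSpacing)),
        error = function(e) list(ok = FALSE, reason = conditionMessage(e)))
      if (res$ok) {
        slices[[length(slices) + 1L]] <- list(
          id = row$id, level = row$level,
          sex = if (is.null(row$sex)) NA_character_ else row$sex,
          mask = res$mask)
      } else {
        exclusions <- rbind(exclusions, data.frame(
          id = row$id, level = row$level, stage = "read_mask",
          reason = res$reason, stringsAsFactors = FALSE))
      }
    }
    if (nrow(meta) > 0 && length(slices) < nrow(meta) / 2)
      stopCondition("DataError", sprintf(
        "more than half of the slices failed to read (%d of %d)",
        nrow(meta) - length(slices), nrow(meta)))
    manifest$stages$read_mask <- list(rows_in = nrow(meta),
                                      rows_out = length(slices),
                                      excluded = nrow(exclusions))
  }

  # ---- stage: landmarks + angles ----
  anglesPath <- file.path(outDir, "angles.csv")
  landmarksPath <- file.path(outDir, "landmarks.csv")
  nIn <- length(slices)
  if (nIn == 0)
    stopCondition("DataError", "no slices to process")
  rows <- list(); lmRows <- list()
  if (resume && file.exists(anglesPath) && file.exists(landmarksPath)) {
    angles <- read.csv(anglesPath, stringsAsFactors = FALSE)
    manifest$stages$angles <- list(rows_in = nIn, rows_out = nrow(angles),
                                   excluded = 0L, resumed = TRUE)
  } else {
    for (s in slices) {
      res <- tryCatch({
        lm <- extractLandmarks(s$mask)
        list(ok = TRUE, lm = lm, ang = computeAngles(lm))
      }, error = function(e) list(ok = FALSE, reason = conditionMessage(e)))
      if (res$ok) {
        co <- landmarkCoords(res$lm)
        lmRows[[length(lmRows) + 1L]] <- data.frame(
          id = s$id, level = s$level,
          t(setNames(as.vector(t(co)),
                     paste0(rep(rownames(co), each = 2), "_",
                            rep(c("ap_mm", "rl_mm"), 6)))))
        rows[[length(rows) + 1L]] <- data.frame(
          id = s$id, level = s$level, sex = s$sex,
          theta_left_deg = res$ang@thetaLeft,
          theta_right_deg = res$ang@thetaRight,
          asymmetry_deg = res$ang@asymmetry, stringsAsFactors = FALSE)
      } else {
        exclusions <- rbind(exclusions, data.frame(
          id = s$id, level = s$level, stage = "landmarks",
          reason = res$reason, stringsAsFactors = FALSE))
      }
    }
    if (nIn > 0 && length(rows) < nIn / 2)
      stopCondition("DataError", sprintf(
        "more than half of the slices failed landmark extraction (%d of %d)",
        nIn - length(rows), nIn))
    angles <- do.call(rbind, rows)
    write.csv(do.call(rbind, lmRows), landmarksPath, row.names = FALSE)
    write.csv(angles, anglesPath, row.names = FALSE)
    manifest$stages$angles <- list(rows_in = nIn, rows_out = nrow(angles),
                                   excluded = nIn - length(rows))
  }

  # ---- stage: cohort summary ----
  if (!is.null(angles) && nrow(angles) > 0 && !all(is.na(angles$sex))) {
    summ <- summarizeCohort(
      data.frame(id = angles$id, level = angles$level, sex = angles$sex,
                 thetaLeft = angles$theta_left_deg,
                 thetaRight = angles$theta_right_deg),
      thresholds = thresholds)
    write.csv(summ$cells, file.path(outDir, "cohort_cells.csv"),
              row.names = FALSE)
    write.csv(summ$prevalence, file.path(outDir, "cohort_prevalence.csv"),
              row.names = FALSE)
    write.csv(asymmetryHistogram(summ$distribution$asymmetry),
              file.path(outDir, "asymmetry_histogram.csv"), row.names = FALSE)
    manifest$stages$cohort <- list(rows_in = nrow(angles), rows_out = nrow(angles),
                                   excluded = 0L)
  }

  write.csv(exclusions, file.path(outDir, "exclusions.csv"), row.names = FALSE)
  manifest$exclusions <- nrow(exclusions)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
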
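#' Construct a PipelineConfig
#'
#' All analysis constants are explicit: the 4 mm seed sphere, the strict
#' 0.25 gray-matter threshold and the 1% selection fraction default to the
#' values of the reproduced analysis.
#'
#' @param sim a \linkS4class{SimConfig}.
#' @param mode \code{"maps"} or \code{"timeseries"}.
#' @param seedCenterMm seed-sphere center (mm); the anterior temporal seed
#'   coordinate by default (meaningful for full-size grids — reduced demo
#'   grids must supply an in-grid coordinate).
#' @param seedRadiusMm sphere radius (mm).
#' @param gmThreshold gray-matter cutoff (strict >).
#' @param contrast \code{"interaction"} or \code{"physio"} (control variant;
#'   timeseries mode only).
#' @param fraction selection fraction.
#' @param ranking \code{"weight"} or \code{"t"}.
#' @param lambdaBarMethod \code{"trace_p"} or \code{"nonzero"}.
#' @param outDir output directory.
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = simConfig(), mode = "maps",
                           seedCenterMm = c(58, 0, -12), seedRadiusMm = 4,
                           gmThreshold = 0.25, contrast = "interaction",
                           fraction = 0.01, ranking = "weight",
                           lambdaBarMethod = "trace_p",
                           outDir = tempfile("ppimlda_")) {
  new("PipelineConfig", sim = sim, mode = mode,
      seedCenterMm = as.numeric(seedCenterMm), seedRadiusMm = seedRadiusMm,
      gmThreshold = gmThreshold, contrast = contrast, fraction = fraction,
      ranking = ranking, lambdaBarMethod = lambdaBarMethod, outDir = outDir)
}

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf("PipelineConfig: mode %s, contrast %s\n",
              object@mode, object@contrast))
  cat(sprintf("  seed sphere r = %g mm at (%s) mm; gm > %g; top %g%% voxels (%s ranking)\n",
              object@seedRadiusMm, paste(object@seedCenterMm, collapse = ", "),
              object@gmThreshold, 100 * object@fraction, object@ranking))
  show(object@sim)
})

#' Write / read a PipelineConfig as JSON
#'
#' The round trip is lossless, so every emitted report can embed the exact
#' configuration (and its hash) that produced it.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path JSON file path.
#' @return \code{writePipelineConfig} returns \code{path} invisibly;
#'   \code{readPipelineConfig} returns the \linkS4class{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  sim <- config@sim
  simL <- lapply(slotNames(sim), function(s) slot(sim, s))
  names(simL) <- slotNames(sim)
  out <- list(sim = simL)
  for (s in setdiff(slotNames(config), "sim")) out[[s]] <- slot(config, s)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(simConfig, x$sim)
  do.call(pipelineConfig, c(list(sim = sim), x[setdiff(names(x), "sim")]))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writePipelineConfig(config, tf)
  # small rolling hash over the canonical JSON; stdlib-only fingerprint
  bytes <- as.integer(charToRaw(paste(readLines(tf, warn = FALSE), collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a cohort label/covariate table
#'
#' Delimited text with mandatory columns \code{subject_id} and \code{group}
#' (values control/patient); extra covariate columns are preserved.
#'
#' @param path file path (tab- or comma-separated, sniffed from the header).
#' @return data.frame with \code{group} as a factor (control, patient).
#' @export
readCohortTable <- function(path) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c("subject_id", "group"))
    if (!col %in% names(df))
      stop(sprintf("cohort table is missing mandatory column '%s'", col))
  bad <- setdiff(unique(df$group), c("control", "patient"))
  if (length(bad))
    stop(paste("unknown group labels:", paste(bad, collapse = ", ")))
  df$group <- factor(df$group, levels = c("control", "patient"))
  df
}

#' Write a cohort label table
#'
#' @param labels factor of groups.
#' @param path output path (tab-separated).
#' @param subjectIds subject identifiers.
#' @param covariates optional data.frame of extra columns.
#' @export
writeCohortTable <- function(labels, path,
                             subjectIds = paste0("S", seq_along(labels)),
                             covariates = NULL) {
  df <- data.frame(subject_id = subjectIds, group = as.character(labels))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an events table
#'
#' Tab-separated with columns \code{onset}, \code{duration},
#' \code{trial_type} (the common events format for task fMRI).
#'
#' @param path file path.
#' @param events an \linkS4class{EventSchedule}.
#' @return \code{readEvents} returns an \linkS4class{EventSchedule}.
#' @export
readEvents <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("onset", "duration", "trial_type"))
    if (!col %in% names(df))
      stop(sprintf("events table is missing mandatory column '%s'", col))
  new("EventSchedule", onsetsS = as.numeric(df$onset),
      durationsS = as.numeric(df$duration),
      conditions = as.character(df$trial_type))
}

#' @rdname readEvents
#' @export
writeEvents <- function(events, path) {
  df <- data.frame(onset = events@onsetsS, duration = events@durationsS,
                   trial_type = events@conditions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CVResult as a delimited table
#'
#' @param result a \linkS4class{CVResult}.
#' @param path output path (tab-separated: subject_id, true_label,
#'   decision_value, prediction).
#' @export
writeCVResult <- function(result, path) {
  df <- data.frame(subject_id = result@subjectIds,
                   true_label = as.character(result@trueLabels),
                   decision_value = result@decisionValues,
                   prediction = as.character(result@predictions))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a SyntheticCohort to disk
#'
#' One NIfTI per subject (3D map, or a 4D stack per run), a tab-separated
#' label table, the gray-matter/truth masks, and a JSON manifest recording
#' the generating configuration.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created).
#' @param events optional list of \linkS4class{EventSchedule}s to write
#'   (defaults to the schedules attached to a time-series cohort).
#' @return the directory path, invisibly.
#' @export
writeCohort <- function(cohort, dir, events = attr(cohort, "events")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort@maps)
  ids <- sprintf("S%02d", seq_len(n))
  aff <- if (is(cohort@maps[[1]], "VolumeGrid")) cohort@maps[[1]]@affine
         else cohort@maps[[1]][[1]]@affine
  for (s in seq_len(n)) {
    m <- cohort@maps[[s]]
    if (is(m, "VolumeGrid")) {
      writeVolume(m, file.path(dir, sprintf("%s_map.nii.gz", ids[s])))
    } else {
      for (r in seq_along(m))
        writeVolume(m[[r]], file.path(dir, sprintf("%s_run%d.nii.gz", ids[s], r)))
    }
  }
  writeCohortTable(cohort@labels, file.path(dir, "cohort.tsv"), subjectIds = ids)
  writeVolume(volumeGrid(array(as.numeric(cohort@mask), dim(cohort@mask)),
                         affine = aff),
              file.path(dir, "mask.nii.gz"))
  writeVolume(volumeGrid(array(as.numeric(cohort@truthMask),
                               dim(cohort@truthMask)), affine = aff),
              file.path(dir, "truth_mask.nii.gz"))
  if (!is.null(events))
    for (r in seq_along(events))
      writeEvents(events[[r]], file.path(dir, sprintf("events_run%d.tsv", r)))
  cfg <- cohort@config
  simL <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(simL) <- slotNames(cfg)
  jsonlite::write_json(simL, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full synthetic pipeline
#'
#' Generates the cohort (maps directly, or 4D time series followed by
#' first-level PPI t-maps), masks to gray-matter features, runs
#' leave-one-subject-out cross-validation of the maximum-uncertainty LDA
#' with nested feature selection, evaluates, and writes all artifacts
#' (config + hash, labels, CVResult table, metrics JSON, weight-map NIfTI)
#' to \code{config@outDir}.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param writeArtifacts write output files (default TRUE).
#' @return list with \code{cohort}, \code{features}, \code{cv}
#'   (\linkS4class{CVResult}), \code{metrics} (\linkS4class{MetricsReport}),
#'   \code{model} (full-sample fit), \code{weightMap}, \code{configHash}.
#' @export
runPipeline <- function(config, writeArtifacts = TRUE) {
  stopifnot(is(config, "PipelineConfig"))
  sim <- config@sim
  grid <- makeDefaultGrid(sim)
  gm <- makeGrayMatterMap(grid, rngSeed = sim@rngSeed + 1000L)
  mask <- gm@data > config@gmThreshold
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (config@mode == "maps") {
    cohort <- stage("simulate", generatePPIMaps(sim, mask, grid))
    fm <- stage("features", {
      fm0 <- cohortFeatureMatrix(cohort)
      list(X = fm0$X, y = fm0$y, index = fm0$index, dim = sim@gridShape)
    })
  } else {
    cohort <- stage("simulate", {
      seedRoi <- makeSphereROI(config@seedCenterMm, config@seedRadiusMm, grid)
      withr_seed(sim@rngSeed + 2000L, {
        events <- replicate(sim@nRuns, makeEventSchedule(sim), simplify = FALSE)
      })
      ch <- generateTimeseriesCohort(sim, mask, events = events, grid = grid,
                                     seedRoi = seedRoi)
      attr(ch, "events") <- events
      ch
    })
    fm <- stage("ppi", cohortPPIFeatures(cohort, attr(cohort, "events"),
                                         gm, config@gmThreshold,
                                         contrast = config@contrast))
  }
  cv <- stage("classify",
              loocvMLDA(fm$X, fm$y, fraction = config@fraction,
                        ranking = config@ranking,
                        lambdaBarMethod = config@lambdaBarMethod))
  metrics <- stage("evaluate", evaluateCVResult(cv))
  model <- stage("weight-map",
                 fitMLDAPipeline(fm$X, fm$y, config@fraction,
                                 config@ranking, config@lambdaBarMethod))
  wmap <- exportWeightMap(model, fm$index, sim@gridShape, grid@affine)
  hash <- config_hash(config)
  if (writeArtifacts) {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    writePipelineConfig(config, file.path(config@outDir, "config.json"))
    writeLines(hash, file.path(config@outDir, "config.hash"))
    writeCohortTable(cohort@labels, file.path(config@outDir, "cohort.tsv"))
    writeCVResult(cv, file.path(config@outDir, "cv_result.tsv"))
    ml <- metricsAsList(metrics)
    ml$config_hash <- hash
    ml$decisions <- list(lambda_bar = config@lambdaBarMethod,
                         ranking = config@ranking,
                         selection_nested_in_folds = TRUE)
    jsonlite::write_json(ml, file.path(config@outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    writeVolume(wmap, file.path(config@outDir, "weight_map.nii.gz"))
    writeVolume(gm, file.path(config@outDir, "gray_matter.nii.gz"))
  }
  list(cohort = cohort, features = fm, cv = cv, metrics = metrics,
       model = model, weightMap = wmap, configHash = hash)
}
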
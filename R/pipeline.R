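## End-to-end pipeline: simulate (or load) -> preprocess -> subject
## segmentation -> group maps -> backfit -> metrics -> statistics ->
## optional source imaging, driven by a validated nested config, with a
## provenance log and per-stage artifact reuse.

.configSchema <- list(
  seed = NULL, out = NULL, resume = NULL, input = NULL,
  simulation = c("nChannels", "samplingRate", "durationS", "K",
                 "meanDurationsMs", "oscillationFreqHz", "snr",
                 "amplitudeUv", "gammaShape"),
  cohort = c("groupSizes", "groupNames", "subjectSdLog", "corrTarget",
             "corrState", "corrDomain"),
  preprocess = c("filter", "lowHz", "highHz", "targetHz"),
  clustering = c("subjectKRange", "subjectRestarts", "groupKRange",
                 "groupRestarts", "minAssignCorr"),
  backfit = c("minCorr", "halfWidth", "smoothnessWeight",
              "minSegmentFrames"),
  sources = c("enabled", "nPoints", "lambda", "corrGate", "states"),
  stats = c("family", "alpha"))

.validateConfig <- function(config) {
  unknown <- setdiff(names(config), names(.configSchema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    allowed <- .configSchema[[sec]]
    if (is.null(allowed) || !is.list(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad))
      stop(sprintf("unknown config key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

## Polynomial rolling hash of the deparsed config, for provenance stamping
.configHash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full microstate pipeline
#'
#' Executes simulate -> preprocess -> subject segmentation -> group
#' clustering -> backfitting -> metrics -> group statistics (-> source
#' imaging when enabled) under one validated configuration, writing every
#' artifact plus a line-delimited provenance log into the run directory.
#' Deterministic under a fixed seed; with \code{resume}, stages whose
#' artifact files already exist are reused.
#'
#' @param config nested list, or path to a YAML file with the same
#'   structure; unknown keys are rejected. Sections: \code{simulation},
#'   \code{cohort}, \code{preprocess}, \code{clustering}, \code{backfit},
#'   \code{sources}, \code{stats}, plus top-level \code{seed} and
#'   \code{out}.
#' @return Invisibly, a list with the group \code{mapset}, \code{metrics},
#'   \code{stats} tables, questionnaire \code{domains}, source results and
#'   the run directory.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validateConfig(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- if (is.null(config$out)) tempfile("msrun") else config$out
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  resume <- isTRUE(config$resume)
  hash <- .configHash(config)
  logFile <- file.path(outDir, "provenance.jsonl")
  logStage <- function(stage, ...) {
    rec <- list(stage = stage, config_hash = hash,
                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = logFile,
        append = TRUE)
  }
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))

  simCfg <- do.call(simulationSpec,
                    modifyList(list(nChannels = 32, durationS = 60),
                               config$simulation %||% list()))
  cohCfg <- do.call(cohortSpec,
                    modifyList(list(groupSizes = c(4, 4, 4)),
                               config$cohort %||% list()))
  cl <- modifyList(list(subjectKRange = 2:6, subjectRestarts = 20,
                        groupKRange = 2:8, groupRestarts = 40,
                        minAssignCorr = 0.5), config$clustering %||% list())
  bf <- modifyList(list(minCorr = 0.5, halfWidth = 5, smoothnessWeight = 15,
                        minSegmentFrames = 5), config$backfit %||% list())
  pp <- modifyList(list(filter = FALSE, lowHz = 1, highHz = 40,
                        targetHz = NULL), config$preprocess %||% list())
  src <- modifyList(list(enabled = FALSE, nPoints = 200, lambda = 1 / 9,
                         corrGate = 0.9, states = 1), config$sources %||%
                      list())
  st <- modifyList(list(family = "per-parameter", alpha = 0.05),
                   config$stats %||% list())

  set.seed(seed)
  logStage("simulate", n_subjects = sum(cohCfg$groupSizes))
  coh <- simulateCohort(cohCfg, simCfg, seed = seed)
  writeMontage(coh$montage, file.path(outDir, "montage.tsv"))
  writeMapSet(coh$templates, file.path(outDir, "templates.tsv"))
  write.table(coh$truth, file.path(outDir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(coh$questionnaire, file.path(outDir, "questionnaire.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  recs <- lapply(coh$recordings, function(r) {
    if (isTRUE(pp$filter)) r <- bandpassFilter(r, pp$lowHz, pp$highHz)
    if (!is.null(pp$targetHz)) r <- downsampleRecording(r, pp$targetHz)
    averageReference(r)
  })

  mapsFile <- file.path(outDir, "group_maps.tsv")
  if (resume && file.exists(mapsFile)) {
    groupMaps <- readMapSet(mapsFile)
    logStage("group-maps", reused = TRUE)
  } else {
    logStage("subject-segmentation", k_range = range(cl$subjectKRange))
    subjSets <- vector("list", length(recs))
    for (i in seq_along(recs))
      subjSets[[i]] <- subjectSegmentation(
        recs[[i]], kRange = cl$subjectKRange, nRestarts = cl$subjectRestarts,
        minAssignCorr = cl$minAssignCorr, seed = seed + i * 131L)$mapset
    logStage("group-clustering", n_map_sets = length(subjSets))
    groupMaps <- groupClustering(subjSets, montage = coh$montage,
                                 kRange = cl$groupKRange,
                                 nRestarts = cl$groupRestarts,
                                 minAssignCorr = cl$minAssignCorr,
                                 seed = seed)
    writeMapSet(groupMaps, mapsFile)
  }

  logStage("backfit", k = nStates(groupMaps))
  segs <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    segs[[i]] <- backfitSubject(recs[[i]], groupMaps, minCorr = bf$minCorr,
                                halfWidth = bf$halfWidth,
                                smoothnessWeight = bf$smoothnessWeight,
                                minSegmentFrames = bf$minSegmentFrames)
    writeSegmentation(segs[[i]],
                      file.path(outDir, sprintf("seg_%s.tsv", names(recs)[i])))
  }
  names(segs) <- names(recs)

  logStage("metrics")
  met <- metricsTable(segs, groups = coh$groups,
                      stateLabels = stateLabels(groupMaps))
  writeMetrics(met, file.path(outDir, "metrics.tsv"))

  logStage("stats")
  stat <- groupComparisonReport(met, family = st$family, alpha = st$alpha)
  write.table(stat, file.path(outDir, "stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  domains <- arsqDomains(coh$questionnaire)
  write.table(domains, file.path(outDir, "arsq_domains.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  sourceRes <- NULL
  if (isTRUE(src$enabled)) {
    logStage("sources", n_points = src$nPoints)
    lf <- buildSphericalLeadfield(coh$montage, nPoints = src$nPoints,
                                  seed = seed)
    inv <- loretaInverse(lf, lambda = src$lambda)
    sourceRes <- lapply(src$states, function(s) {
      vals <- vapply(seq_along(recs), function(i)
        microstateSourceAverage(recs[[i]], segs[[i]], s, inv,
                                corrGate = src$corrGate)$values,
        numeric(nrow(pointCoords(lf))))
      rowMeans(vals, na.rm = TRUE)
    })
    names(sourceRes) <- paste0("state", src$states)
    srcTab <- data.frame(pointCoords(lf), sourceRes)
    write.table(srcTab, file.path(outDir, "sources.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  logStage("done")
  invisible(list(mapset = groupMaps, metrics = met, stats = stat,
                 domains = domains, sources = sourceRes, truth = coh$truth,
                 dir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
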
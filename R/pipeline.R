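## Pipeline orchestration: simulate -> connectivity -> behavior -> stats from
## a single validated config, with seeded reproducibility and a manifest.

pipelineConfigKeys <- c("mode", "out_dir", "seed", "cohort", "paths",
                        "analysis")

#' Validate a pipeline configuration
#'
#' Config is a named list (or a YAML file path). Recognized top-level keys:
#' `mode` ("simulate" or "analyze"), `out_dir`, `seed`, `cohort` (CohortSpec
#' fields for simulate mode), `paths` (nodes / ts_dir / behavior files for
#' analyze mode), `analysis` (jn_alpha, covariates, screen). Unknown keys are
#' rejected so typos fail fast, before any stage runs.
#'
#' @param config named list or YAML path.
#' @return the normalized config list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or YAML file path")
  unknown <- setdiff(names(config), pipelineConfigKeys)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(config$mode)) config$mode <- "simulate"
  if (!(config$mode %in% c("simulate", "analyze")))
    stopf("mode must be 'simulate' or 'analyze'")
  if (is.null(config$out_dir)) stopf("config requires out_dir")
  if (is.null(config$seed)) stopf("config requires an explicit seed")
  if (config$mode == "analyze") {
    p <- config$paths
    if (is.null(p$ts_dir) || !dir.exists(p$ts_dir))
      stopf("analyze mode requires an existing paths$ts_dir")
    if (is.null(p$nodes) || !file.exists(p$nodes))
      stopf("analyze mode requires an existing paths$nodes table")
  }
  config
}

## CohortSpec from the config's cohort block (all fields optional)
specFromConfig <- function(config) {
  co <- config$cohort
  args <- list(seed = as.integer(config$seed))
  map <- c(nSubjects = "n_subjects", ageRange = "age_range",
           nTimepoints = "n_timepoints", rWithin = "r_within_base",
           rBetween = "r_between_base", segAgeSlope = "seg_age_slope",
           rBetweenSd = "r_between_sd")
  for (nm in names(map)) if (!is.null(co[[map[nm]]])) args[[nm]] <- co[[map[nm]]]
  if (!is.null(co$network_sizes))
    args$networkSizes <- unlist(co$network_sizes)
  if (!is.null(co$behav_coefs))
    args$behavCoefs <- unlist(co$behav_coefs)
  do.call(cohortSpec, args)
}

#' Run the full pipeline
#'
#' In simulate mode: generates the cohort (time series, behavioral records,
#' ground truth), writes all intermediates, computes segregation profiles
#' from the written time series, production measures and composites from the
#' behavioral records, fits the study models, and writes tidy results plus a
#' manifest (input hashes, seeds, package version). Re-running with the same
#' config reproduces the outputs bit-identically.
#'
#' @param config named list or YAML path (see [validateConfig()]).
#' @return list with `results`, `jn`, `profiles`, `measures`, `manifest`.
#' @export
runPipeline <- function(config) {
  config <- validateConfig(config)
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  an <- config$analysis
  alpha <- if (!is.null(an$jn_alpha)) an$jn_alpha else 0.05
  doScreen <- if (!is.null(an$screen)) isTRUE(an$screen) else TRUE
  zeroPolicy <- if (!is.null(an$zero_policy)) an$zero_policy else "include"
  if (config$mode == "simulate") {
    spec <- specFromConfig(config)
    cohort <- simulateCohort(spec, timeseries = TRUE, transcripts = TRUE,
                             outDir = outDir)
    tsFiles <- setNames(
      file.path(outDir, "ts", paste0(cohort$truth$subject_id, ".tsv")),
      cohort$truth$subject_id)
    partition <- cohort$partition
    behavior <- cohort$records
    covTab <- cohort$truth[, c("subject_id", "age", "motion", "gm_volume")]
  } else {
    parc <- loadNodeTable(config$paths$nodes)
    partition <- setNames(parc@nodes$network, parc@nodes$id)
    tsPaths <- list.files(config$paths$ts_dir, pattern = "\\.tsv$",
                          full.names = TRUE)
    if (length(tsPaths) == 0) stopf("no .tsv time series in %s",
                                    config$paths$ts_dir)
    tsFiles <- setNames(tsPaths, sub("\\.tsv$", "", basename(tsPaths)))
    behavior <- readBehaviorFiles(config$paths)
    covTab <- read.csv(config$paths$covariates, stringsAsFactors = FALSE)
  }
  long <- cohortProfiles(tsFiles, partition, zeroPolicy = zeroPolicy)
  write.csv(long, file.path(outDir, "profiles.csv"), row.names = FALSE)
  wide <- profilesWide(long)
  measures <- compositeScores(productionMeasures(behavior))
  write.csv(measures, file.path(outDir, "measures.csv"), row.names = FALSE)
  merged <- merge(merge(measures, wide, by = "subject_id"), covTab,
                  by = "subject_id")
  models <- runStudyModels(merged, alpha = alpha, screen = doScreen)
  write.csv(models$results, file.path(outDir, "results.csv"),
            row.names = FALSE)
  jnTab <- do.call(rbind, lapply(names(models$jn), function(nm) {
    r <- models$jn[[nm]]
    data.frame(model = nm,
               boundary_lo = if (length(r@boundaries)) r@boundaries[1] else NA,
               boundary_hi = if (length(r@boundaries) > 1) r@boundaries[2]
                             else NA,
               side = r@side, alpha = r@alpha,
               range_lo = r@observedRange[1], range_hi = r@observedRange[2],
               stringsAsFactors = FALSE)
  }))
  write.csv(jnTab, file.path(outDir, "jn_regions.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(packageVersion("segconn")),
    seed = config$seed,
    mode = config$mode,
    files = as.list(tools::md5sum(
      list.files(outDir, pattern = "\\.csv$", full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = models$results, jn = models$jn,
                 profiles = long, measures = measures, manifest = manifest))
}

## read fluency/naming/transcript files into per-subject records
readBehaviorFiles <- function(paths) {
  fl <- read.csv(paths$fluency, stringsAsFactors = FALSE)
  nm <- read.csv(paths$naming, stringsAsFactors = FALSE)
  sids <- sort(unique(c(fl$subject_id, nm$subject_id)))
  out <- lapply(sids, function(sid) {
    tr <- file.path(paths$transcripts_dir, paste0(sid, ".txt"))
    list(fluency = fl[fl$subject_id == sid,
                      setdiff(names(fl), "subject_id"), drop = FALSE],
         naming = nm[nm$subject_id == sid,
                     setdiff(names(nm), "subject_id"), drop = FALSE],
         transcript = if (file.exists(tr)) readLines(tr) else character())
  })
  names(out) <- sids
  out
}
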
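## End-to-end orchestration: simulate -> predict -> summarize -> NTCP ->
## decide -> evaluate, from one validated config.

pipelineConfigSchema <- function() list(
  cohortSize = "numeric", masterSeed = "numeric",
  phantom = c("dims", "spacing", "centerJitterMm", "sizeJitter"),
  falloff = c("prescription", "lambdaXT", "lambdaPT", "bathXT", "bathPT",
              "noiseSd", "noiseCorrMm"),
  thresholds = c("t2Single", "t2Sum", "t3Single", "t3Sum", "xtGate",
                 "gateEnabled"),
  coefficientsPath = "character", outputDir = "character")

#' Pipeline configuration
#'
#' `defaultPipelineConfig()` returns the default configuration: a 48-case
#' cohort on the default phantom with the default falloff surrogate and
#' NIPP thresholds. `validatePipelineConfig()` checks a config against the
#' schema (unknown keys are rejected) and fills defaults for absent ones.
#' `loadPipelineConfig()` reads a JSON or YAML config file.
#'
#' @param config A named list (possibly partial).
#' @param path Path to a `.json`, `.yaml` or `.yml` config file.
#' @return A validated, fully populated config list.
#' @export
defaultPipelineConfig <- function() {
  fp <- falloffParams()
  list(
    cohortSize = 48L,
    masterSeed = 20260101L,
    phantom = list(dims = c(40L, 44L, 36L), spacing = c(4, 4, 4),
                   centerJitterMm = 3.5, sizeJitter = 0.18),
    falloff = list(prescription = fp@prescription, lambdaXT = fp@lambdaXT,
                   lambdaPT = fp@lambdaPT, bathXT = fp@bathXT,
                   bathPT = fp@bathPT, noiseSd = fp@noiseSd,
                   noiseCorrMm = fp@noiseCorrMm),
    thresholds = list(t2Single = 0.10, t2Sum = 0.15, t3Single = 0.05,
                      t3Sum = 0.075, xtGate = 0.10, gateEnabled = TRUE),
    coefficientsPath = NULL,
    outputDir = NULL
  )
}

#' @rdname defaultPipelineConfig
#' @export
validatePipelineConfig <- function(config) {
  schema <- pipelineConfigSchema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  full <- utils::modifyList(defaultPipelineConfig(), config,
                            keep.null = TRUE)
  for (grp in c("phantom", "falloff", "thresholds")) {
    bad <- setdiff(names(full[[grp]]), schema[[grp]])
    if (length(bad))
      stop("unknown config key(s) in '", grp, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (full$cohortSize < 1) stop("'cohortSize' must be >= 1", call. = FALSE)
  full$cohortSize <- as.integer(full$cohortSize)
  full$masterSeed <- as.integer(full$masterSeed)
  # constructor validity catches value errors early
  invisible(do.call(falloffParams, full$falloff))
  invisible(do.call(decisionThresholds, full$thresholds))
  full
}

#' @rdname defaultPipelineConfig
#' @export
loadPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  config <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml", call. = FALSE)
  validatePipelineConfig(config)
}

#' Run the full decision pipeline on a synthetic cohort
#'
#' Generates the cohort, reduces the (noisy) predicted doses to OAR mean
#' doses, evaluates the four NTCP models per modality, applies the decision
#' tree, and evaluates the decisions against the cohort's reference labels
#' (which come from the noise-free doses): confusion counts, accuracy /
#' sensitivity / specificity / F-score, rank-based AUC of the continuous
#' benefit score, per-OAR dose-prediction MAE/ME, and a paired t-test on
#' the grade-2 dysphagia NTCP between modalities.
#'
#' With `outputDir` set, all tabular artifacts, the decision traces, a
#' metrics JSON, and a plain-text run log (stage timing, warnings, the full
#' config and all seeds) are written there.
#'
#' @param config A config list (see [defaultPipelineConfig()]); partial
#'   configs are filled with defaults.
#' @return A list: `manifest` (per-case data.frame), `decisions`,
#'   `confusion`, `metrics`, `auc`, `doseStats`, `ntcpTest`, `config`.
#' @examples
#' \donttest{
#' res <- runPipeline(list(cohortSize = 8, masterSeed = 7))
#' res$metrics$accuracy
#' }
#' @export
runPipeline <- function(config = list()) {
  config <- validatePipelineConfig(config)
  log <- character()
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    log <<- c(log, line)
    message(line)
  }

  params <- do.call(falloffParams, config$falloff)
  thr <- do.call(decisionThresholds, config$thresholds)
  coeffs <- nippCoefficients(config$coefficientsPath)
  spec <- hnPhantomSpec(dims = config$phantom$dims,
                        spacing = config$phantom$spacing,
                        params = params,
                        centerJitterMm = config$phantom$centerJitterMm,
                        sizeJitter = config$phantom$sizeJitter,
                        cohortSize = config$cohortSize)

  say("simulate: generating %d-case cohort (master seed %d)",
      config$cohortSize, config$masterSeed)
  t0 <- proc.time()["elapsed"]
  cohort <- generateCohort(spec, n = config$cohortSize,
                           masterSeed = config$masterSeed, thresholds = thr)
  say("simulate: done in %.1f s", proc.time()["elapsed"] - t0)

  say("summarize/ntcp/decide: evaluating predicted doses")
  n <- config$cohortSize
  P <- params@prescription
  sumXT <- sumPT <- vector("list", n)
  xtProf <- ptProf <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- cohort$cases[[i]]
    sumXT[[i]] <- summarizeCase(cs$doseXT, cs$structures, prescription = P)
    sumPT[[i]] <- summarizeCase(cs$dosePT, cs$structures, prescription = P)
    xtProf[[i]] <- evaluateNTCP(sumXT[[i]], "XT", coeffs)
    ptProf[[i]] <- evaluateNTCP(sumPT[[i]], "PT", coeffs)
  }
  deltas <- lapply(seq_len(n), function(i)
    deltaProfile(xtProf[[i]], ptProf[[i]]))
  decisions <- lapply(deltas, decide, thresholds = thr)
  names(decisions) <- as.character(seq_len(n))

  say("evaluate: decisions against noise-free reference labels")
  predicted <- vapply(decisions, modality, character(1))
  referenceLabels <- cohort$manifest$referenceLabel
  counts <- confusionCounts(predicted, referenceLabels)
  metrics <- decisionMetrics(counts)
  scores <- vapply(deltas, benefitScore, numeric(1), thresholds = thr)
  auc <- if (length(unique(referenceLabels)) == 2)
    rocAuc(scores, referenceLabels) else NA_real_
  if (is.na(auc)) say("evaluate: single-class cohort, AUC undefined")

  doseStats <- doseErrorStats(
    pred = c(lapply(cohort$cases, `[[`, "doseXT"),
             lapply(cohort$cases, `[[`, "dosePT")),
    ref = c(lapply(cohort$cases, `[[`, "refDoseXT"),
            lapply(cohort$cases, `[[`, "refDosePT")),
    structureSets = rep(lapply(cohort$cases, `[[`, "structures"), 2),
    prescription = P)

  ntcpTest <- pairedTTest(
    vapply(xtProf, function(p) ntcpValues(p)[["Dys2+"]], numeric(1)),
    vapply(ptProf, function(p) ntcpValues(p)[["Dys2+"]], numeric(1)))

  manifest <- cohort$manifest
  manifest$predictedLabel <- predicted
  manifest$predictedRule <- vapply(decisions, ruleFired, character(1))
  manifest$benefitScore <- scores
  manifest$predDeltaDys2 <- vapply(deltas, function(d)
    deltaValues(d)[["Dys2+"]], numeric(1))
  manifest$agree <- manifest$predictedLabel == manifest$referenceLabel

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outputDir, f)
    say("write: artifacts to %s", config$outputDir)
    writeMeanDoseTable(c(stats::setNames(sumXT, paste0(seq_len(n), "_XT")),
                         stats::setNames(sumPT, paste0(seq_len(n), "_PT"))),
                       out("mean_doses.csv"))
    writeNtcpTable(c(stats::setNames(xtProf, seq_len(n)),
                     stats::setNames(ptProf, seq_len(n))), out("ntcp.csv"))
    writeDecisionTable(decisions, out("decisions.csv"))
    writeTracesJSON(decisions, out("traces.json"))
    utils::write.csv(manifest, out("manifest.csv"), row.names = FALSE)
    utils::write.csv(doseStats, out("dose_error_stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(confusion = as.list(counts),
           metrics = metrics[c("accuracy", "sensitivity", "specificity",
                               "f_score")],
           auc = auc),
      out("metrics.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(log, "config:",
                 jsonlite::toJSON(config, auto_unbox = TRUE, null = "null",
                                  digits = NA),
                 "case seeds:", paste(manifest$seed, collapse = " ")),
               out("run_log.txt"))
  }

  list(manifest = manifest, decisions = decisions, confusion = counts,
       metrics = metrics, auc = auc, doseStats = doseStats,
       ntcpTest = ntcpTest, config = config)
}
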
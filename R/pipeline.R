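#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the stages on a simulated study (or pre-assembled inputs):
#' ADR extraction, sigmoid recovery fits, reorientation scoring, the three
#' per-domain mixed models and the midazolam-free sensitivity analysis.
#' When \code{outputDir} is given, writes \code{adr_series.csv},
#' \code{fits.csv}, \code{rot.csv}, \code{lmm_<domain>.json}, a combined
#' \code{results_summary.csv}, an \code{exclusions.csv} error table and a
#' \code{manifest.json} (config hash, seed, package versions) so identical
#' config and seed reproduce identical outputs.
#'
#' @param config a [simConfig()]; used when \code{study} is NULL.
#' @param study an existing [simulateStudy()] result (optional).
#' @param path simulation path, \code{"features"} or \code{"full"}.
#' @param outputDir directory for output files, or NULL to skip writing.
#' @return list with \code{study}, \code{sessionTable}, \code{rot},
#'   \code{comparisons}, \code{models}, \code{sensitivity},
#'   \code{exclusions}.
#' @export
runPipeline <- function(config = simConfig(), study = NULL,
                        path = c("features", "full"), outputDir = NULL) {
  path <- match.arg(path)
  if (is.null(study))
    study <- simulateStudy(config, path = path)
  sess <- study$sessions

  rots <- scoreROTLog(study$rotLog)
  feats <- sess[, c("session_id", "t_max", "A", "tau")]
  covs <- sess[, c("session_id", "subject_id", "charge_mc",
                   "seizure_duration_s", "midazolam", "placement_bl",
                   "session_number", "sex_male", "age")]
  tab <- buildSessionTable(feats, covs, rots)

  rots$subject_id <- sess$subject_id[match(rots$session_id,
                                           sess$session_id)]
  comparisons <- tryCatch(compareDomains(rots),
                          error = function(e) {
                            warning(conditionMessage(e))
                            NULL
                          })

  models <- lapply(c(person = "person", place = "place", time = "time"),
                   function(d) fitDomainLMM(tab, d))
  sensitivity <- tryCatch(midazolamSensitivity(tab),
                          warning = function(w) NULL)

  out <- list(study = study, sessionTable = tab, rot = rots,
              comparisons = comparisons, models = models,
              sensitivity = sensitivity, exclusions = study$exclusions)
  if (!is.null(outputDir)) writePipelineOutputs(out, outputDir)
  out
}

#' Write pipeline outputs to a directory
#'
#' @param result a [runPipeline()] result.
#' @param outputDir output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
writePipelineOutputs <- function(result, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  study <- result$study

  if (!is.null(study$adr)) {
    rows <- lapply(names(study$adr), function(id) {
      s <- study$adr[[id]]
      data.frame(session_id = id, minute = s@minute, adr = s@adr,
                 n_windows = s@nWindows)
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(outputDir, "adr_series.csv"),
                     row.names = FALSE)
  }
  if (!is.null(study$fits)) {
    fitRows <- lapply(names(study$fits), function(id) {
      f <- study$fits[[id]]
      if (is.null(f)) return(NULL)
      data.frame(session_id = id, A = f@A, lam = f@lam, tau = f@tau,
                 U = f@U, r2 = f@rSquared, t_max = f@tMax,
                 converged = f@converged, qc_pass = f@qcPass)
    })
    utils::write.csv(do.call(rbind, fitRows),
                     file.path(outputDir, "fits.csv"), row.names = FALSE)
  }

  rot <- result$rot
  ord <- t(vapply(seq_len(nrow(rot)), function(i) {
    o <- domainOrder(c(person = rot$rot_person[i], place = rot$rot_place[i],
                       time = rot$rot_time[i]))
    c(paste(o$order, collapse = "-"), as.character(o$classic))
  }, c("", "")))
  rot$order <- ord[, 1]
  rot$classic_order_flag <- ord[, 2]
  utils::write.csv(rot, file.path(outputDir, "rot.csv"), row.names = FALSE)

  summaryRows <- list()
  for (d in names(result$models)) {
    m <- result$models[[d]]
    jsonlite::write_json(
      list(domain = d, method = m$method, n_obs = m$nObs,
           n_subjects = m$nSubjects, coefficients = m$coefficients,
           random_effect_sd = as.list(m$ranef), vif = m$vif,
           singular = m$singular, downgraded = m$downgraded,
           diagnostics = m$diagnostics),
      file.path(outputDir, paste0("lmm_", d, ".json")),
      auto_unbox = TRUE, digits = 10)
    co <- m$coefficients
    co$domain <- d
    summaryRows[[d]] <- co
  }
  utils::write.csv(do.call(rbind, summaryRows),
                   file.path(outputDir, "results_summary.csv"),
                   row.names = FALSE)

  utils::write.csv(
    data.frame(session_id = result$exclusions,
               stage = rep("recovery_fit", length(result$exclusions)),
               reason = rep("QC fail (R2 gate or no convergence)",
                            length(result$exclusions))),
    file.path(outputDir, "exclusions.csv"), row.names = FALSE)

  cfgFile <- tempfile()
  saveRDS(study$config, cfgFile)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfgFile)),
    seed = study$config$seed,
    n_sessions = nrow(study$sessions),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("postictalr")))
  unlink(cfgFile)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Write a simulated study to disk in standard formats
#'
#' Emits \code{sessions.csv} (covariates and outcomes),
#' \code{rot_log.csv} (question-level times), \code{truth.json} (ground
#' truth parameters and random effects), and optionally one EDF recording
#' per session (regenerated from the study's per-session seeds on the
#' full path).
#'
#' @param study a [simulateStudy()] result.
#' @param dir output directory.
#' @param writeEEG also synthesize and write per-session EDF files
#'   (slow; default FALSE).
#' @return Invisibly, \code{dir}.
#' @export
writeStudy <- function(study, dir, writeEEG = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$sessions, file.path(dir, "sessions.csv"),
                   row.names = FALSE)
  utils::write.csv(study$rotLog, file.path(dir, "rot_log.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(truth = study$truth, random_effects = study$randomEffects,
         latent_rot = study$latentROT),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = 10)
  if (writeEEG) {
    cfg <- study$config
    for (i in seq_len(nrow(study$truth))) {
      set.seed(study$config$seed + i)
      rec <- simulatePostictalEEG(
        study$truth[i, c("A", "lam", "tau", "U")],
        duration = cfg$postictalDuration, fs = cfg$fs,
        nChannels = cfg$nChannels, totalPower = cfg$totalPower,
        artifactRate = cfg$artifactRate)
      writeEDF(rec, file.path(dir, paste0(study$truth$session_id[i],
                                          ".edf")))
    }
  }
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file whose keys match the [simConfig()] arguments (plus an
#' optional \code{output_dir}) and validates them through the constructor;
#' unknown keys are rejected so that typos fail loudly.
#'
#' @param path YAML file path.
#' @return A list with \code{config} (a validated \code{SimConfig}) and
#'   \code{outputDir} (or NULL).
#' @export
readPipelineConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  outputDir <- raw$output_dir
  raw$output_dir <- NULL
  known <- names(formals(simConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (nm in c("randomEffectSds"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  list(config = do.call(simConfig, raw), outputDir = outputDir)
}
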
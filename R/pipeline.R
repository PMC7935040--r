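#' Pipeline configuration
#'
#' One object drives the whole analysis: either a synthetic cohort section
#' or paths to real input tables, plus the processing parameters. Every run
#' writes a provenance record (config echo, seed, versions) sufficient to
#' reproduce its outputs byte-identically.
#'
#' @param synthetic a [cohort_config()] or `NULL` when reading real data.
#' @param connectome_paths character vector of per-subject matrix files
#'   (ignored when `synthetic` is given).
#' @param volumetrics_path long-format volumetrics table (see
#'   [read_volumetrics()]).
#' @param atlas_path atlas file; default package atlas when `NULL`.
#' @param proportion proportional-threshold fraction (default 0.10, the
#'   "keep the strongest 10% of connections" convention).
#' @param scheme adjacency normalization scheme.
#' @param scale_within z-scaling variant, see [center_and_scale()].
#' @param responses outcomes to model (subset of `c("ac", "mc")`).
#' @param null_test run the null-network test for the first response?
#' @param null_replicates,swaps_per_edge null-model settings (reference
#'   analysis: 1000 replicates, 10 swaps per edge).
#' @param seed master seed for all randomness.
#' @param write_connectomes also write every thresholded matrix (off by
#'   default: large).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = cohort_config(),
                            connectome_paths = NULL,
                            volumetrics_path = NULL,
                            atlas_path = NULL,
                            proportion = 0.10,
                            scheme = c("singular_value", "spectral_radius",
                                       "none"),
                            scale_within = FALSE,
                            responses = "ac",
                            null_test = FALSE,
                            null_replicates = 1000,
                            swaps_per_edge = 10,
                            seed = 1L,
                            write_connectomes = FALSE) {
  scheme <- match.arg(scheme)
  if (!is.numeric(proportion) || proportion <= 0 || proportion > 1)
    stop_ctrl("proportion must lie in (0, 1]")
  if (!all(responses %in% c("ac", "mc")))
    stop_ctrl("responses must be a subset of c('ac', 'mc')")
  if (is.null(synthetic) &&
      (is.null(connectome_paths) || is.null(volumetrics_path)))
    stop_ctrl("either a synthetic section or input paths are required")
  structure(list(synthetic = synthetic,
                 connectome_paths = connectome_paths,
                 volumetrics_path = volumetrics_path,
                 atlas_path = atlas_path,
                 proportion = proportion,
                 scheme = scheme,
                 scale_within = scale_within,
                 responses = responses,
                 null_test = isTRUE(null_test),
                 null_replicates = as.integer(null_replicates),
                 swaps_per_edge = swaps_per_edge,
                 seed = as.integer(seed),
                 write_connectomes = isTRUE(write_connectomes)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Top-level keys mirror [pipeline_config()] arguments; a `synthetic`
#' object mirrors [cohort_config()] arguments.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- NULL
  if (!is.null(raw$synthetic)) syn <- do.call(cohort_config, raw$synthetic)
  args <- raw[setdiff(names(raw), "synthetic")]
  do.call(pipeline_config, c(list(synthetic = syn), args))
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full pipeline
#'
#' Stages, in order: ingest or generate; proportional threshold; control
#' metrics; study-table assembly; centering/scaling; models 1 and 2 (REML
#' reports) for each requested response; regional effects from model 2;
#' optional null-network test. Each stage writes its table under
#' `out_dir` before the next starts, so partial output survives a failure,
#' and any stage error halts with a stage-named message.
#'
#' @param config a [pipeline_config()] or path to a JSON config.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, list with `status` (0 on success), `dir`, and the
#'   named output `files`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    stop_ctrl("config must be a pipeline_config or a JSON path")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  files <- list()
  stage <- function(name, expr) {
    log_line(logf, "stage ", name, " ...")
    tryCatch(expr,
             error = function(e) stop_ctrl("stage '", name, "' failed: ",
                                           conditionMessage(e)))
  }

  cohort <- stage("ingest", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      syn$seed <- config$seed
      generate_cohort(syn)
    } else {
      atlas <- if (is.null(config$atlas_path)) default_atlas()
               else read_atlas(config$atlas_path)
      cons <- lapply(config$connectome_paths, read_connectome, atlas = atlas)
      names(cons) <- vapply(cons, `[[`, "", "subject_id")
      vols <- read_volumetrics(config$volumetrics_path, atlas)
      list(connectomes = cons, volumetrics = vols, atlas = atlas)
    }
  })
  files$volumetrics <- file.path(out_dir, "volumetrics.tsv")
  vol_df <- do.call(rbind, lapply(cohort$volumetrics, function(v)
    data.frame(subject_id = v$subject_id,
               region_name = names(v$rgm) %||% cohort$atlas$region_name,
               rgm = as.numeric(v$rgm), tiv = v$tiv)))
  utils::write.table(vol_df, files$volumetrics, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  thresholded <- stage("threshold", lapply(cohort$connectomes,
                                           threshold_proportional,
                                           proportion = config$proportion))
  if (config$write_connectomes) {
    cdir <- file.path(out_dir, "thresholded")
    dir.create(cdir, showWarnings = FALSE)
    for (C in thresholded)
      write_connectome(C, file.path(cdir, paste0(C$subject_id, ".tsv")))
  }

  profiles <- stage("control_metrics",
                    lapply(thresholded, control_profile, proportion = NULL,
                           scheme = config$scheme))
  files$profiles <- file.path(out_dir, "control_profiles.tsv")
  write_profiles(profiles, files$profiles)

  tab <- stage("assemble", assemble(profiles, cohort$volumetrics,
                                    atlas = cohort$atlas))
  tab <- stage("scale", center_and_scale(tab,
                                         scale_within = config$scale_within))
  files$study_table <- file.path(out_dir, "study_table.tsv")
  write_study_table(tab, files$study_table)

  for (resp in config$responses) {
    m1 <- stage(paste0("model1_", resp),
                fit_lme(tab, model_spec_one(resp), method = "REML"))
    m2 <- stage(paste0("model2_", resp),
                fit_lme(tab, model_spec_two(resp), method = "REML"))
    files[[paste0("model1_", resp)]] <-
      file.path(out_dir, paste0("model1_", resp, ".json"))
    files[[paste0("model2_", resp)]] <-
      file.path(out_dir, paste0("model2_", resp, ".json"))
    write_model_result(m1, files[[paste0("model1_", resp)]],
                       file.path(out_dir, paste0("model1_", resp, ".tsv")))
    write_model_result(m2, files[[paste0("model2_", resp)]],
                       file.path(out_dir, paste0("model2_", resp, ".tsv")))
    for (fam in c("rgm", "degree")) {
      re <- stage(paste0("regional_", fam, "_", resp),
                  regional_effects(m2, fam))
      fp <- file.path(out_dir,
                      paste0("regional_effects_", fam, "_", resp, ".tsv"))
      files[[paste0("regional_", fam, "_", resp)]] <- fp
      utils::write.table(re, fp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }

  if (config$null_test) {
    resp <- config$responses[1]
    nd <- stage("null_test",
                null_beta_test(cohort$connectomes, cohort$volumetrics,
                               spec = model_spec_one(resp),
                               n_replicates = config$null_replicates,
                               seed = seed_stream(config$seed, "nulltest"),
                               proportion = config$proportion,
                               scheme = config$scheme,
                               swaps_per_edge = config$swaps_per_edge,
                               scale_within = config$scale_within))
    files$null_test <- file.path(out_dir, "null_test.json")
    write_null_distribution(nd, file.path(out_dir, "null_betas.tsv"),
                            files$null_test)
  }

  files$provenance <- file.path(out_dir, "provenance.json")
  prov <- list(
    config = unclass_deep(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("connectrl")),
    r_version = R.version.string)
  jsonlite::write_json(prov, files$provenance, auto_unbox = TRUE,
                       digits = NA, null = "null")
  log_line(logf, "done")
  invisible(list(status = 0L, dir = out_dir, files = files))
}

# strip S3 classes recursively so jsonlite serializes configs plainly
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
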
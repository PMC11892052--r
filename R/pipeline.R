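.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.file_checksums <- function(paths) {
  paths <- unlist(paths, use.names = FALSE)
  paths <- paths[file.exists(paths) & !dir.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full classification and estimation pipeline
#'
#' Orchestrates an end-to-end run: obtain data (generate synthetically from a
#' \code{\link{generator_config}}, or read knowledge-base and survey files),
#' classify every prescription, aggregate prevalence and median-split
#' comparison tables, estimate the exposure-outcome regressions, and write
#' all stage outputs plus QC reports and a run manifest (config hash, seeds,
#' package version, input checksums, timestamps, output inventory) under
#' \code{out_dir}. Stage boundaries are logged with record counts so
#' tabulated Ns can be audited from the log.
#'
#' @param config A list with elements: either \code{simulate} (an
#'   \code{rx_generator_config}) or \code{inputs} (list with \code{kb_dir}
#'   and \code{survey_paths}); optional \code{groupers},
#'   \code{outcomes} (default \code{"ANYLMT"}), \code{estimators} (subset of
#'   lpm/probit/dml, default \code{"lpm"}), \code{dml} (list of learner /
#'   n_folds / num_trees settings), \code{rx_count_cap}.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the manifest and used for the estimation
#'   stage; a simulation's own seed lives in its generator config.
#' @param log Logger function taking a message string (default
#'   \code{message}); pass \code{function(...) {}} to silence.
#' @return List with \code{manifest} and the in-memory stage results
#'   (\code{kb}, \code{survey}, \code{classifications}, \code{exposures},
#'   \code{prevalence}, \code{classes}, \code{comparisons},
#'   \code{estimates}).
#' @export
run_pipeline <- function(config, out_dir, seed = 20160101L, log = message) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    if (is.data.frame(obj)) fwrite(obj, p) else
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, force = TRUE)
    outputs <<- c(outputs, p)
    p
  }

  ## stage: data
  if (!is.null(config$simulate)) {
    log("stage simulate: generating synthetic population")
    sim <- generate_data(config$simulate, out_dir = file.path(out_dir, "data"))
    kb <- sim$kb; survey <- sim$survey
    input_checksums <- .file_checksums(sim$paths)
  } else if (!is.null(config$inputs)) {
    log("stage ingest: reading knowledge base and survey files")
    kb <- read_knowledge_base(config$inputs$kb_dir)
    survey <- read_survey(config$inputs$survey_paths,
                          config$inputs$schema_config)
    input_checksums <- .file_checksums(c(
      file.path(config$inputs$kb_dir, c("drugs.csv", "pairs.csv")),
      config$inputs$survey_paths))
  } else {
    stop("config must provide either `simulate` or `inputs`")
  }
  log(sprintf("  persons=%d conditions=%d prescriptions=%d links=%d",
              nrow(survey$persons), nrow(survey$conditions),
              nrow(survey$prescriptions), nrow(survey$links)))

  ## stage: classify
  log("stage classify: computing use indicators")
  cls <- classify_all(kb, survey)
  qc <- attr(cls, "qc")
  log(sprintf("  classified=%d excluded=%d", qc$n_rx, qc$n_excluded))
  emit(cls, "classifications.csv")
  emit(qc, "classify_qc.json")
  exposures <- person_exposures(cls, survey, kb)
  emit(exposures, "person_exposures.csv")
  log(sprintf("  persons with in-scope prescriptions=%d", nrow(exposures)))

  ## stage: aggregate
  log("stage aggregate: prevalence and comparison tables")
  groupers <- if (is.null(config$groupers))
    c("sex", "education", "age_group", "race", "year") else config$groupers
  prev <- prevalence_table(cls, survey, groupers, kb = kb)
  emit(prev, "prevalence.csv")
  classes <- therapeutic_class_rates(cls, survey)
  emit(classes, "therapeutic_classes.csv")
  comparisons <- rbindlist(lapply(
    c("frac_indicated", "frac_contraindicated"),
    function(sv) {
      cmp <- median_split_compare(exposures, survey$persons, sv)
      cmp[, split_var := sv]
      cmp
    }))
  emit(comparisons, "median_split_comparisons.csv")

  ## stage: estimate
  outcomes <- if (is.null(config$outcomes)) "ANYLMT" else config$outcomes
  estimators <- if (is.null(config$estimators)) "lpm" else config$estimators
  log(sprintf("stage estimate: %d outcome(s) x {%s}", length(outcomes),
              paste(estimators, collapse = ", ")))
  af <- build_analysis_data(survey, exposures)
  cap <- if (is.null(config$rx_count_cap)) 30L else config$rx_count_cap
  results <- list()
  for (oc in outcomes) {
    for (es in estimators) {
      spec <- model_spec(oc, estimator = es, rx_count_cap = cap)
      res <- switch(es,
        lpm = fit_lpm(spec, af),
        probit = fit_probit(spec, af),
        dml = do.call(fit_dml_plr, c(list(spec = spec, data = af, seed = seed),
                                     config$dml)))
      results[[paste(oc, es, sep = ".")]] <- res
    }
  }
  summ <- summarize_models(results)
  emit(summ$table, "estimates.csv")
  emit(summ$comparison, "estimator_comparison.csv")

  manifest <- list(
    config_hash = .config_hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("rxscreen")),
    input_checksums = input_checksums,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("pipeline complete")
  list(manifest = manifest, kb = kb, survey = survey, classifications = cls,
       exposures = exposures, prevalence = prev, classes = classes,
       comparisons = comparisons, estimates = summ)
}
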
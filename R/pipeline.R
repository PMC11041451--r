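#' Default pipeline configuration
#'
#' @param out_dir run directory for artifacts.
#' @param seed master seed; sub-stage seeds derive from it.
#' @param generator a [generator_config()] (built from `seed` when `NULL`).
#' @param tagger named list of [ggo_tagger()] arguments.
#' @param tau size-change tolerance (mm) for the longitudinal stage.
#' @return a named list (class `ggo_pipeline_config`).
#' @export
pipeline_config <- function(out_dir = "ggo_run", seed = 1L,
                            generator = NULL, tagger = list(), tau = 0) {
  if (is.null(generator)) generator <- generator_config(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 generator = generator, tagger = tagger, tau = tau),
            class = "ggo_pipeline_config")
}

.stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the GGO pipeline end to end
#'
#' Executes generate -> train -> predict -> normalize -> evaluate -> cohort
#' (a subset is selectable via `stages`); each stage writes its artifacts
#' under the run directory together with a manifest (seed, config hash,
#' stage inputs). A stage whose inputs are missing aborts with an error
#' naming the missing artifact; no stage mutates its inputs.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of
#'   `c("generate", "train", "predict", "normalize", "evaluate", "cohort")`.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("generate", "train", "predict",
                                    "normalize", "evaluate", "cohort")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  artifacts <- list()

  if ("generate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    cohort <- generate_cohort(config$generator)
    write_notes_jsonl(cohort$corpus, p("gold.jsonl"))
    write_cohort_truth(cohort$truth, p("truth"))
    .stage_msg("generate", t0)
  }
  if (!file.exists(p("gold.jsonl")))
    stop("stage input missing: ", p("gold.jsonl"), " (run 'generate' first)")
  artifacts$gold <- p("gold.jsonl")

  if ("train" %in% stages) {
    t0 <- as.numeric(Sys.time())
    gold <- read_notes_jsonl(p("gold.jsonl"))
    args <- utils::modifyList(list(corpus = gold, seed = config$seed),
                              config$tagger)
    model <- do.call(ggo_tagger, args)
    saveRDS(model, p("model.rds"))
    .stage_msg("train", t0)
  }

  if ("predict" %in% stages) {
    if (!file.exists(p("model.rds")))
      stop("stage input missing: ", p("model.rds"), " (run 'train' first)")
    t0 <- as.numeric(Sys.time())
    model <- readRDS(p("model.rds"))
    gold <- read_notes_jsonl(p("gold.jsonl"))
    pred <- predict(model, gold)
    write_notes_jsonl(pred, p("pred.jsonl"))
    .stage_msg("predict", t0)
  }

  if ("normalize" %in% stages) {
    if (!file.exists(p("pred.jsonl")))
      stop("stage input missing: ", p("pred.jsonl"), " (run 'predict' first)")
    t0 <- as.numeric(Sys.time())
    pred <- read_notes_jsonl(p("pred.jsonl"))
    findings <- findings_from_notes(pred)
    utils::write.csv(findings, p("findings.csv"), row.names = FALSE)
    artifacts$findings <- p("findings.csv")
    .stage_msg("normalize", t0)
  }

  if ("evaluate" %in% stages) {
    if (!file.exists(p("pred.jsonl")))
      stop("stage input missing: ", p("pred.jsonl"), " (run 'predict' first)")
    t0 <- as.numeric(Sys.time())
    pred <- read_notes_jsonl(p("pred.jsonl"))
    gold <- read_notes_jsonl(p("gold.jsonl"))
    metrics <- score(pred, gold, mode = "exact")
    write_metrics_csv(metrics, p("metrics.csv"))
    artifacts$metrics <- p("metrics.csv")
    .stage_msg("evaluate", t0)
  }

  if ("cohort" %in% stages) {
    if (!file.exists(p("findings.csv")))
      stop("stage input missing: ", p("findings.csv"),
           " (run 'normalize' first)")
    t0 <- as.numeric(Sys.time())
    findings <- utils::read.csv(p("findings.csv"),
                                colClasses = c(note_date = "Date"))
    patients <- if (file.exists(p("truth", "patients.csv")))
      utils::read.csv(p("truth", "patients.csv"),
                      colClasses = c(diagnosis_date = "Date"))
      else NULL
    dir.create(p("summary"), showWarnings = FALSE)
    if (nrow(findings) == 0) {
      warning("no findings extracted; cohort summaries are empty")
    } else {
      tls <- build_timelines(findings, patients)
      summ <- cohort_summary(tls, tau = config$tau)
      for (nm in names(summ))
        utils::write.csv(summ[[nm]], p("summary", paste0(nm, ".csv")),
                         row.names = FALSE)
    }
    artifacts$summary <- p("summary")
    .stage_msg("cohort", t0)
  }

  manifest <- list(
    seed = config$seed, stages = stages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config_hash = sum(utf8ToInt(paste(deparse(unclass(
      config$generator)[setdiff(names(unclass(config$generator)),
                                "lexicon")]), collapse = ""))),
    n_patients = config$generator$n_patients)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(artifacts)
}
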
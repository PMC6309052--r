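## cli_config: end-to-end pipeline, configuration, logging -------------------

#' Pipeline configuration
#'
#' A single configuration object drives every run; all command-line flags
#' are overrides of these keys, so a run is reproducible from one file.
#' `NULL` resource paths fall back to the packaged defaults.
#'
#' @param corpus path to a corpus JSONL file (or `NULL` when `simulate`).
#' @param lexicon,positive_set,triggers resource file paths (`NULL` =
#'   packaged fixtures).
#' @param simulate logical; generate a synthetic corpus instead of reading
#'   one.
#' @param generator a [generator_config()] used when `simulate`.
#' @param modes feature modes to run.
#' @param fraction,folds,ratio,cutoff,cap,min_days,grid modeling knobs (see
#'   [run_experiment()]).
#' @param seed master seed, recorded in every artifact.
#' @param out output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus = NULL, lexicon = NULL,
                            positive_set = NULL, triggers = NULL,
                            simulate = is.null(corpus),
                            generator = generator_config(),
                            modes = c("proposed", "full_concepts",
                                      "filtered_concepts", "bag_of_words"),
                            fraction = 0.5, folds = 5L, ratio = 0.7,
                            cutoff = 0.5, cap = 10L, min_days = 120L,
                            grid = default_grid(), seed = 1L,
                            out = "recurrex_out") {
  structure(list(corpus = corpus, lexicon = lexicon,
                 positive_set = positive_set, triggers = triggers,
                 simulate = simulate, generator = generator, modes = modes,
                 fraction = fraction, folds = folds, ratio = ratio,
                 cutoff = cutoff, cap = cap, min_days = min_days,
                 grid = grid, seed = as.integer(seed), out = out),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(y$generator)) {
    args$generator <- do.call(generator_config, y$generator)
  }
  if (!is.null(y$grid)) args$grid <- y$grid
  do.call(pipeline_config, args)
}

resolve_resources <- function(config) {
  list(
    lexicon = if (is.null(config$lexicon)) default_lexicon()
              else load_lexicon(config$lexicon),
    positive = if (is.null(config$positive_set)) default_positive_set()
               else load_positive_set(config$positive_set),
    triggers = if (is.null(config$triggers)) default_triggers()
               else load_triggers(config$triggers))
}

json_line <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(json_line(x), f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full pipeline end to end
#'
#' Preprocess, tag, filter, gate, featurize, select, train, evaluate; every
#' artifact is stamped with the seed and a configuration hash, and a
#' JSON-lines log records the counts at each stage (the mention counts
#' reconcile: tagged = retained + dropped by cue + dropped by negation +
#' dropped by the positive gate). A stage failure aborts with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, list with `report`, `report_list`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out, "log.jsonl")
  logs <- character()
  log_event <- function(event, data = list()) {
    logs <<- c(logs, json_line(c(list(event = event), data)))
  }
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out <- NULL   # output location does not identify a run
  cfg_for_hash$generator <- unclass(config$generator)
  cfg_hash <- md5_of_object(cfg_for_hash)
  log_event("start", list(seed = config$seed, config_hash = cfg_hash))

  corpus <- stage("load_corpus", {
    if (config$simulate) {
      gen <- generate_corpus(config$generator, config$seed)
      write_corpus(gen$records, file.path(config$out, "corpus.jsonl"))
      gen$records
    } else {
      read_corpus(config$corpus)
    }
  })
  res <- stage("load_resources", resolve_resources(config))
  report <- stage("experiment", run_experiment(
    corpus, modes = config$modes, lexicon = res$lexicon,
    triggers = res$triggers, positive = res$positive,
    ratio = config$ratio, folds = config$folds,
    fraction = config$fraction, grid = config$grid,
    cutoff = config$cutoff, seed = config$seed, cap = config$cap,
    min_days = config$min_days))
  log_event("counts", report$counts)

  prepared <- stage("featurize_export", {
    p <- prepare_corpus(corpus, res$lexicon, res$triggers, res$positive)
    fm <- assemble_matrix(p$records, p, "proposed",
                          min_days = config$min_days, cap = config$cap)
    write_feature_matrix(fm, file.path(config$out, "features"))
    p
  })
  if ("proposed" %in% config$modes) {
    stage("model_export", save_model(report$modes$proposed$model,
                                     file.path(config$out, "model.rds")))
  }
  rl <- report_to_list(report)
  rl$seed <- config$seed
  rl$config_hash <- cfg_hash
  report_path <- file.path(config$out, "report.json")
  jsonlite::write_json(rl, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeLines(render_report_markdown(report),
             file.path(config$out, "report.md"))
  log_event("done", list(report_hash = unname(tools::md5sum(report_path))))
  writeLines(logs, log_path)
  invisible(list(report = report, report_list = rl,
                 paths = list(report = report_path, log = log_path,
                              out = config$out)))
}

#' Validate a corpus file
#'
#' Reads the corpus, reporting schema problems; returns summary counts.
#'
#' @param path corpus JSONL path.
#' @return list with `n_patients`, `n_notes`, `n_labeled`.
#' @export
validate_corpus <- function(path) {
  corpus <- read_corpus(path)
  list(n_patients = length(corpus),
       n_notes = sum(vapply(corpus, function(r) nrow(r$notes), integer(1))),
       n_labeled = sum(!is.na(corpus_labels(corpus))))
}
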
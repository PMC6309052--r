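## synthetic_corpus: labeled synthetic patient corpora -----------------------

read_pool <- function(file) {
  x <- readLines(system.file("extdata", file, package = "recurrex",
                             mustWork = TRUE), warn = FALSE,
                 encoding = "UTF-8")
  x[nzchar(trimws(x))]
}

#' Generator configuration
#'
#' Defaults mirror the study conditions: 701 patients at 27.53% recurrence
#' prevalence; class-conditional mean counts of qualifying (>= 120 days
#' post-diagnosis) pathology reports of 4.55 (recurrent) and 0.92
#' (non-recurrent), drawn from a negative binomial so the variance can
#' exceed the mean; template pools seeded from published example sentences
#' plus the packaged partial-sentence fixture.
#'
#' @param n_patients cohort size.
#' @param prevalence probability of a recurrence label.
#' @param notes_per_patient mean note count (min 1, Poisson).
#' @param sentences_per_note mean filler sentences per note (min 2,
#'   Poisson).
#' @param positive_templates,negative_templates,confound_templates,fillers,cue_fillers
#'   sentence pools; defaults come from the packaged plain-text files.
#' @param miss_rate probability a recurrent patient's notes carry no
#'   positive template (label noise in the narrative channel).
#' @param negative_template_rate probability a patient (either class)
#'   receives negative-context recurrence sentences, which the contextual
#'   filter is expected to drop.
#' @param confound_rate probability a non-recurrent patient receives
#'   distant/contralateral recurrence phrasing (and positive-class-like
#'   pathology counts), the study's false-positive failure mode.
#' @param cue_filler_rate per-note mean count (Poisson) of cue-bearing
#'   distractor sentences (inserted in both classes).
#' @param history_templates pool of breast-cancer-history and benign-workup
#'   sentences shared by both classes (every cohort member has a primary
#'   breast cancer history), so history vocabulary carries no label signal.
#' @param history_rate per-note probability of a history sentence.
#' @param pathology_mean_pos,pathology_mean_neg class-conditional means of
#'   the qualifying pathology-report count.
#' @param dispersion negative-binomial dispersion (variance = mu + disp *
#'   mu^2).
#' @param pre_dx_report_rate probability of one additional early (< 120
#'   days) report, exercising the window boundary.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 701L,
                             prevalence = 0.2753,
                             notes_per_patient = 4,
                             sentences_per_note = 4,
                             positive_templates = NULL,
                             negative_templates = NULL,
                             confound_templates = NULL,
                             fillers = NULL,
                             cue_fillers = NULL,
                             history_templates = NULL,
                             history_rate = 0.5,
                             miss_rate = 0.05,
                             negative_template_rate = 0.8,
                             confound_rate = 0.05,
                             cue_filler_rate = 0.8,
                             pathology_mean_pos = 4.55,
                             pathology_mean_neg = 0.92,
                             dispersion = 1.0,
                             pre_dx_report_rate = 0.5) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    prevalence = prevalence,
    notes_per_patient = notes_per_patient,
    sentences_per_note = sentences_per_note,
    positive_templates = positive_templates %||%
      read_pool("templates_positive.txt"),
    negative_templates = negative_templates %||%
      read_pool("templates_negative.txt"),
    ## confound phrasing is drawn from the positive pool plus
    ## distant/contralateral-specific sentences: progress-note phrasing does
    ## not reveal the recurrence site, so the narrative channel alone cannot
    ## separate these patients
    confound_templates = confound_templates %||%
      c(read_pool("templates_confound.txt"),
        positive_templates %||% read_pool("templates_positive.txt")),
    fillers = fillers %||% read_pool("templates_filler.txt"),
    cue_fillers = cue_fillers %||% read_pool("templates_cue_filler.txt"),
    history_templates = history_templates %||%
      read_pool("templates_history.txt"),
    history_rate = history_rate,
    miss_rate = miss_rate,
    negative_template_rate = negative_template_rate,
    confound_rate = confound_rate,
    cue_filler_rate = cue_filler_rate,
    pathology_mean_pos = pathology_mean_pos,
    pathology_mean_neg = pathology_mean_neg,
    dispersion = dispersion,
    pre_dx_report_rate = pre_dx_report_rate)
  stopifnot(cfg$prevalence >= 0, cfg$prevalence <= 1,
            cfg$miss_rate >= 0, cfg$miss_rate <= 1,
            cfg$confound_rate >= 0, cfg$confound_rate <= 1,
            cfg$pathology_mean_pos >= 0, cfg$pathology_mean_neg >= 0,
            length(cfg$positive_templates) > 0,
            length(cfg$fillers) > 0)
  structure(cfg, class = "generator_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fill_slots <- function(template) {
  out <- gsub("{LAT}", sample(c("left", "right"), 1L), template, fixed = TRUE)
  gsub("{YEAR}", sample(1995:2015, 1L), out, fixed = TRUE)
}

draw_count <- function(mu, dispersion) {
  if (mu <= 0) return(0L)
  if (dispersion <= 0) return(stats::rpois(1L, mu))
  stats::rnbinom(1L, mu = mu, size = 1 / dispersion)
}

capitalize <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substring(x, 2L))
}

#' Generate one synthetic patient
#'
#' Uses the caller's RNG stream; seed via `set.seed()` (or use
#' [generate_corpus()]).
#'
#' @param patient_id identifier.
#' @param label binary outcome to realize.
#' @param config a [generator_config()].
#' @return list with `record` (a `patient_record`) and `trace` (data frame
#'   of inserted template sentences with an `expect_survive` flag: whether
#'   the sentence should survive the contextual filters).
#' @export
generate_patient <- function(patient_id, label, config) {
  dx_date <- as.Date("2008-01-01") + sample.int(1461L, 1L) - 1L
  n_notes <- 1L + stats::rpois(1L, max(config$notes_per_patient - 1, 0))
  note_offsets <- sort(sample(30:2000, n_notes))
  trace <- list()
  inserted <- vector("list", n_notes)
  for (j in seq_len(n_notes)) inserted[[j]] <- character()
  add_template <- function(text, kind) {
    j <- sample.int(n_notes, 1L)
    inserted[[j]] <<- c(inserted[[j]], text)
    trace[[length(trace) + 1L]] <<- data.frame(
      patient_id = patient_id, note_id = sprintf("%s-n%02d", patient_id, j),
      kind = kind, text = text,
      expect_survive = !has_contextual_cue(normalize_text(text),
                                           default_triggers())$has,
      stringsAsFactors = FALSE)
  }
  confounded <- FALSE
  ## negation/uncertainty recurrence discussion occurs in both classes
  ## (every patient in the cohort is followed for recurrence), so cue-bearing
  ## sentences carry no label signal; the contextual filter must remove them
  if (length(config$negative_templates) &&
      stats::runif(1L) < config$negative_template_rate) {
    k <- 1L + stats::rpois(1L, 0.5)
    for (t in sample(config$negative_templates, k, replace = TRUE)) {
      add_template(fill_slots(t), "negative")
    }
  }
  if (label == 1L) {
    if (stats::runif(1L) >= config$miss_rate) {
      k <- 1L + stats::rpois(1L, 0.7)
      for (t in sample(config$positive_templates, k, replace = TRUE)) {
        add_template(fill_slots(t), "positive")
      }
    }
    mu <- config$pathology_mean_pos
  } else {
    confounded <- length(config$confound_templates) > 0 &&
      stats::runif(1L) < config$confound_rate
    if (confounded) {
      k <- 1L + stats::rpois(1L, 0.7)   # same multiplicity as true positives
      for (t in sample(config$confound_templates, k, replace = TRUE)) {
        add_template(fill_slots(t), "confound")
      }
    }
    mu <- if (confounded) config$pathology_mean_pos
          else config$pathology_mean_neg
  }
  notes <- empty_notes()
  for (j in seq_len(n_notes)) {
    n_fill <- 2L + stats::rpois(1L, max(config$sentences_per_note - 2, 0))
    sents <- sample(config$fillers, n_fill, replace = TRUE)
    n_cue <- if (length(config$cue_fillers))
      stats::rpois(1L, config$cue_filler_rate) else 0L
    if (n_cue > 0L) {
      sents <- c(sents, vapply(sample(config$cue_fillers, n_cue,
                                      replace = TRUE),
                               fill_slots, character(1)))
    }
    if (length(config$history_templates) &&
        stats::runif(1L) < config$history_rate) {
      sents <- c(sents, fill_slots(sample(config$history_templates, 1L)))
    }
    sents <- c(sents, inserted[[j]])
    sents <- sents[sample.int(length(sents))]
    notes <- rbind(notes, data.frame(
      note_id = sprintf("%s-n%02d", patient_id, j),
      date = dx_date + note_offsets[j],
      text = paste0(capitalize(sents), ".", collapse = " "),
      stringsAsFactors = FALSE))
  }
  k120 <- draw_count(mu, config$dispersion)
  pdates <- as.Date(character())
  if (k120 > 0L) {
    pdates <- dx_date + 120L + sample(0:1500, k120, replace = TRUE) - 0L
  }
  if (stats::runif(1L) < config$pre_dx_report_rate) {
    pdates <- c(pdates, dx_date + sample.int(119L, 1L) - 1L)
  }
  record <- patient_record(patient_id, dx_date, notes, sort(pdates), label)
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(patient_id = character(), note_id = character(),
               kind = character(), text = character(),
               expect_survive = logical(), stringsAsFactors = FALSE)
  list(record = record, trace = trace_df)
}

#' Generate a labeled synthetic corpus
#'
#' Labels are drawn at the configured prevalence; each patient is built by
#' [generate_patient()]. Fully deterministic given the seed: two runs with
#' the same seed produce byte-identical corpora via [write_corpus()].
#'
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @return object of class `generated_corpus`: list with `records`
#'   (`recurrex_corpus`), `trace`, `config`, `seed`.
#' @export
generate_corpus <- function(config = generator_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_patients
  labels <- stats::rbinom(n, 1L, config$prevalence)
  records <- vector("list", n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    g <- generate_patient(pid, labels[i], config)
    records[[i]] <- g$record
    traces[[i]] <- g$trace
  }
  names(records) <- vapply(records, function(r) r$patient_id, character(1))
  structure(list(
    records = structure(records, class = "recurrex_corpus"),
    trace = do.call(rbind, traces),
    config = config, seed = seed), class = "generated_corpus")
}
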
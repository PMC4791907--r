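# Pipeline orchestration: simulate -> casefind -> incidence -> validate,
# with CSV inputs/outputs, a JSON run summary and deterministic behaviour
# for a fixed seed. Dates are ISO-8601 throughout; intervals are closed on
# both ends.

#' Read the four cohort CSV tables
#'
#' Schemas: patients
#' `patient_id,birth_year,sex,spell_start,spell_end,death_date,comorbidities`
#' (one row per registration spell); events and prescriptions
#' `patient_id,date,code`; survey `patient_id,wave,date,mhi1..mhi5`.
#'
#' @param dir directory containing `patients.csv`, `events.csv`,
#'   `prescriptions.csv`, `survey.csv`.
#' @return list with the four data frames, dates parsed.
#' @export
read_population <- function(dir) {
  rd <- function(f, date_cols) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("input table not found: ", p, call. = FALSE)
    x <- utils::read.csv(p, colClasses = c(patient_id = "character"))
    for (col in intersect(date_cols, names(x))) {
      x[[col]] <- as.Date(as.character(x[[col]]))
    }
    x
  }
  list(
    patients = rd("patients.csv", c("spell_start", "spell_end", "death_date")),
    events = rd("events.csv", "date"),
    prescriptions = rd("prescriptions.csv", "date"),
    survey = rd("survey.csv", "date")
  )
}

#' Write a cohort to the four CSV tables
#'
#' Inverse of [read_population()]; dates serialised as ISO-8601. The
#' generator-only `latent_cmd` column of the survey table is dropped so
#' pipeline stages cannot see the latent truth.
#'
#' @param pop list with `patients`, `events`, `prescriptions`, `survey`.
#' @param dir output directory, created if needed.
#' @param keep_latent keep the `latent_cmd` column (for generator
#'   debugging only), default `FALSE`.
#' @return invisibly, `dir`.
#' @export
write_population <- function(pop, dir, keep_latent = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  survey <- pop$survey
  if (!keep_latent) survey$latent_cmd <- NULL
  tabs <- list(patients = pop$patients, events = pop$events,
               prescriptions = pop$prescriptions, survey = survey)
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' Pipeline configuration
#'
#' @param input_dir directory with the four cohort CSVs; `NULL` to
#'   simulate them from `sim` instead.
#' @param clinical_codes,drug_codes code list CSV paths; default the
#'   packaged fixture lists.
#' @param sim a `sim_config` used when `input_dir` is `NULL`.
#' @param algorithms algorithm ids to run (subset of 1..12).
#' @param cutpoint MHI-5 case cut-point, default 60.
#' @param years calendar years for the incidence table; default the
#'   simulated study period.
#' @param prevalence_period length-2 period (start, end) for period
#'   prevalence; default the study period.
#' @param misclassified_algorithm,misclassified_wave the algorithm x wave
#'   whose false positives/negatives are characterised (defaults 9 and 2:
#'   the diagnosis-and-treatment definition used in the wider literature).
#' @param seed integer seed forwarded to the simulator.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            clinical_codes = NULL, drug_codes = NULL,
                            sim = sim_config(seed = seed),
                            algorithms = 1:12, cutpoint = 60,
                            years = NULL, prevalence_period = NULL,
                            misclassified_algorithm = 9,
                            misclassified_wave = 2,
                            seed = 1L) {
  if (!all(algorithms %in% 1:12)) {
    stop("unknown algorithm id(s): ",
         paste(setdiff(algorithms, 1:12), collapse = ", "), call. = FALSE)
  }
  if (cutpoint < 0 || cutpoint > 100) {
    stop("cut-point must lie in [0, 100]", call. = FALSE)
  }
  structure(list(
    input_dir = input_dir, clinical_codes = clinical_codes,
    drug_codes = drug_codes, sim = sim, algorithms = as.integer(algorithms),
    cutpoint = cutpoint, years = years, prevalence_period = prevalence_period,
    misclassified_algorithm = as.integer(misclassified_algorithm),
    misclassified_wave = as.integer(misclassified_wave),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads a file whose top-level keys are [pipeline_config()] arguments;
#' a nested `sim` mapping is passed to [sim_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  if (is.null(raw$sim) && !is.null(raw$seed)) {
    raw$sim <- sim_config(seed = raw$seed)
  }
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' Simulates (or loads) the cohort, scores the survey, runs case-finding,
#' computes the incidence and prevalence tables, validates every requested
#' algorithm against the MHI-5 gold standard and characterises the
#' misclassified respondents of one chosen algorithm. All tables are
#' written to `out_dir` together with a `summary.json` recording the
#' config hash and every output row count. A stage failure aborts with a
#' stage-named error and removes partial outputs.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @param verbose log per-stage row counts to standard error.
#' @return invisibly, a list with all in-memory results (`population`,
#'   `casefinding`, `incidence`, `prevalence`, `validation`,
#'   `misclassified`, `summary`).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log <- function(...) if (verbose) message(sprintf(...))
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE, na = "")
    written <<- c(written, p)
    log("  wrote %s (%d rows)", name, nrow(x))
    p
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop_stage(stage, conditionMessage(e))
    })
  }

  lists <- run_stage("codelists", {
    if (is.null(config$clinical_codes)) example_code_lists()
    else load_code_lists(config$clinical_codes, config$drug_codes)
  })

  pop <- run_stage("simulate", {
    if (is.null(config$input_dir)) {
      log("simulate: %d patients, seed %d", config$sim$n_patients,
          config$sim$seed)
      p <- generate_population(config$sim, lists)
      write_population(p, out_dir)
      written <<- c(written, file.path(out_dir, c(
        "patients.csv", "events.csv", "prescriptions.csv", "survey.csv")))
      p
    } else {
      read_population(config$input_dir)
    }
  })

  cf <- run_stage("casefind", {
    res <- run_casefinding(pop$patients, pop$events, pop$prescriptions,
                           pop$survey, lists, config$algorithms)
    emit(transform(res$labels, case = as.integer(case)), "labels.csv")
    log("casefind: %d eligible respondent-waves", nrow(res$flags))
    res
  })

  study_years <- run_stage("incidence", {
    yrs <- config$years
    if (is.null(yrs)) {
      yrs <- seq(as.integer(format(config$sim$study_start, "%Y")),
                 as.integer(format(config$sim$study_end, "%Y")))
    }
    yrs
  })
  inc <- run_stage("incidence", {
    x <- annual_incidence(pop$patients, pop$events, lists, study_years)
    emit(x, "incidence.csv")
    x
  })
  prev <- run_stage("incidence", {
    period <- config$prevalence_period
    if (is.null(period)) {
      period <- c(as.Date(sprintf("%d-01-01", study_years[1])),
                  as.Date(sprintf("%d-12-31", study_years[length(study_years)])))
    }
    pr_dx <- period_prevalence(pop$patients, pop$events, lists,
                               period[1], period[2], include_symptoms = FALSE)
    pr_any <- period_prevalence(pop$patients, pop$events, lists,
                                period[1], period[2], include_symptoms = TRUE)
    tab <- data.frame(
      series = c("diagnosis", "diagnosis_or_symptom"),
      n_cases = c(pr_dx$n_cases, pr_any$n_cases),
      n_population = c(pr_dx$n_population, pr_any$n_population),
      prevalence_pct = c(pr_dx$prevalence_pct, pr_any$prevalence_pct))
    emit(tab, "prevalence.csv")
    tab
  })

  val <- run_stage("validate", {
    scored <- score_survey(pop$survey, cutpoint = config$cutpoint)
    vt <- validate_algorithms(cf, scored)
    emit(vt, "validation.csv")
    cm <- vt[vt$algorithm == config$misclassified_algorithm &
               vt$wave == config$misclassified_wave, ]
    if (nrow(cm)) {
      emit(cm[c("algorithm", "wave", "tp", "fp", "fn", "tn")],
           "confusion.csv")
    }
    # misclassified respondents of the chosen algorithm x wave
    fl <- cf$flags
    sel <- fl$wave == config$misclassified_wave
    fl <- fl[sel, , drop = FALSE]
    key <- paste(fl$patient_id, fl$wave)
    gold <- scored$gold_case[match(key, paste(scored$patient_id, scored$wave))]
    pred <- apply_algorithm(config$misclassified_algorithm, fl)
    keep <- !is.na(gold)
    mis <- characterize_misclassified(
      fl[keep, , drop = FALSE], gold[keep], pred[keep],
      comorbidity_table(pop$patients))
    mtab <- rbind(
      cbind(group = "false_negative", mis$false_negatives),
      cbind(group = "false_positive", mis$false_positives))
    emit(mtab, "misclassified.csv")
    list(table = vt, misclassified = mis)
  })

  summ <- run_stage("summary", {
    cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE)
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    s <- list(
      config_hash = unname(tools::md5sum(tmp)),
      seed = config$seed,
      row_counts = list(
        patients = nrow(pop$patients), events = nrow(pop$events),
        prescriptions = nrow(pop$prescriptions), survey = nrow(pop$survey),
        labels = nrow(cf$labels), incidence = nrow(inc),
        prevalence = nrow(prev), validation = nrow(val$table)
      )
    )
    unlink(tmp)
    jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    s
  })

  invisible(list(population = pop, casefinding = cf, incidence = inc,
                 prevalence = prev, validation = val$table,
                 misclassified = val$misclassified, summary = summ))
}

#' @noRd
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_deep)
  x
}
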
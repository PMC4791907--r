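# Case-finding: evaluate the twelve boolean case-finding algorithms for
# each survey respondent from dated coded events, prescriptions and
# registration spells. "Current" means a one-year window centred on the
# survey response date; "historical" means strictly before that window.

#' Descriptions of the twelve case-finding algorithms
#'
#' Flag abbreviations: D = current diagnosis, S = current symptom,
#' H = historical diagnosis, Hs = historical symptom, T = treatment
#' (at least one antidepressant, anxiolytic or hypnotic prescription)
#' in the current window.
#'
#' @format named character vector, names "1".."12".
#' @export
algorithm_descriptions <- c(
  "1"  = "Current treatment only [T]",
  "2"  = "Current diagnosis, treated or untreated [D]",
  "3"  = "Current diagnosis, treated [D & T]",
  "4"  = "Current diagnosis or symptom, treated or untreated [D | S]",
  "5"  = "Current diagnosis or symptom, treated only [(D | S) & T]",
  "6"  = "Current treatment plus untreated current diagnosis or symptom [T | D | S]",
  "7"  = "Historical or current diagnosis, currently treated [(H | D) & T]",
  "8"  = "Historical or current diagnosis or symptom, currently treated [(H | Hs | D | S) & T]",
  "9"  = "Historical diagnosis currently treated, plus current diagnosis [(H & T) | D]",
  "10" = "Historical diagnosis currently treated, plus current diagnosis or symptom [(H & T) | D | S]",
  "11" = "Historical or current diagnosis or symptom currently treated, plus current diagnosis [((H | Hs | D | S) & T) | D]",
  "12" = "Historical or current diagnosis or symptom currently treated, plus current diagnosis or symptom [((H | Hs | D | S) & T) | D | S]"
)

#' The current one-year window around a survey response
#'
#' The closed 365-day interval with the survey response date at its
#' midpoint: `[date - 182, date + 182]`. Day 183 on either side is
#' excluded. The wide window captures respondents who presented before
#' being diagnosed, or who delayed presenting.
#'
#' @param survey_date `Date` vector (or coercible).
#' @return data frame with columns `start` and `end` (`Date`), one row per
#'   survey date.
#' @export
#' @examples
#' current_window(as.Date("2008-07-01"))  # 2008-01-01 .. 2008-12-30
current_window <- function(survey_date) {
  d <- as_date(survey_date)
  data.frame(start = d - 182, end = d + 182)
}

# Merge a patient table (one row per registration spell) into maximal
# continuous spells: spells merge when the next starts no later than the
# day after the previous ends (a same-day or next-day practice transfer
# leaves no uncovered day); any uncovered day breaks continuity. Spell
# ends are capped at the death date; an NA end is open-ended.
#' @noRd
merged_spells <- function(patients) {
  start <- as_date(patients$spell_start)
  end <- as_date(patients$spell_end)
  bad <- which(!is.na(end) & end < start)
  if (length(bad)) {
    stop("registration spell ends before it starts for patient ",
         patients$patient_id[bad[1]], call. = FALSE)
  }
  end[is.na(end)] <- .far_date
  death <- as_date(patients$death_date %||% rep(NA, nrow(patients)))
  if (length(death)) end <- pmin(end, death, na.rm = TRUE)
  # a spell opening after death contributes nothing
  keep <- end >= start
  patients <- patients[keep, , drop = FALSE]
  start <- start[keep]; end <- end[keep]
  ord <- order(patients$patient_id, start)
  pid <- patients$patient_id[ord]
  s <- as.integer(start[ord]); e <- as.integer(end[ord])
  n <- length(pid)
  out_pid <- character(n); out_s <- integer(n); out_e <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (k > 0L && pid[i] == out_pid[k] && s[i] <= out_e[k] + 1L) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      k <- k + 1L
      out_pid[k] <- pid[i]; out_s[k] <- s[i]; out_e[k] <- e[i]
    }
  }
  data.frame(patient_id = out_pid[seq_len(k)],
             start = as.Date(out_s[seq_len(k)], origin = "1970-01-01"),
             end = as.Date(out_e[seq_len(k)], origin = "1970-01-01"))
}

#' Survey eligibility of a patient
#'
#' A respondent enters the validation only with continuous registration
#' over the whole one-year current window (one merged registration spell
#' covering it; a same-day practice transfer does not break continuity,
#' any uncovered day does) and age 18-74 at the survey date. Age is
#' computed from birth year as `year(survey_date) - birth_year`.
#'
#' @param patient data frame of the patient's rows from the patients table
#'   (columns `patient_id,birth_year,spell_start,spell_end,death_date`).
#' @param survey_date the survey response date.
#' @param window the current window, by default
#'   `current_window(survey_date)`.
#' @return `TRUE` or `FALSE`.
#' @export
is_eligible <- function(patient, survey_date,
                        window = current_window(survey_date)) {
  survey_date <- as_date(survey_date)
  age <- as.integer(format(survey_date, "%Y")) - patient$birth_year[1]
  if (is.na(age) || age < 18L || age > 74L) return(FALSE)
  sp <- merged_spells(patient)
  any(sp$start <= window$start & sp$end >= window$end)
}

#' Compute the feature flags for one respondent
#'
#' Classifies dated events and prescriptions against the code lists and a
#' current window. `current_dx` / `current_sx` are true with at least one
#' diagnosis-group / symptom-group event inside the closed window;
#' `historical_dx` / `historical_sx` with at least one strictly before the
#' window start (events after the window end post-date the survey and are
#' ignored); `current_treatment` with at least one prescription for an
#' antidepressant, anxiolytic or hypnotic inside the window.
#'
#' @param events data frame with columns `date,code` for one patient.
#' @param prescriptions data frame with columns `date,code`.
#' @param lists a `code_lists` object.
#' @param window one-row window from [current_window()].
#' @return named logical vector with elements `current_dx`, `current_sx`,
#'   `historical_dx`, `historical_sx`, `current_treatment`.
#' @export
compute_flags <- function(events, prescriptions, lists, window) {
  cat <- classify_code(events$code, lists)
  d <- as_date(events$date)
  dx <- is_diagnosis(cat, lists$diagnosis_categories)
  sx <- is_symptom(cat, lists$diagnosis_categories)
  in_win <- !is.na(d) & d >= window$start & d <= window$end
  hist <- !is.na(d) & d < window$start
  pd <- as_date(prescriptions$date)
  rx <- !is.na(classify_drug(prescriptions$code, lists)) &
    pd >= window$start & pd <= window$end
  c(current_dx = any(dx & in_win),
    current_sx = any(sx & in_win),
    historical_dx = any(dx & hist),
    historical_sx = any(sx & hist),
    current_treatment = any(rx))
}

#' Apply a case-finding algorithm to feature flags
#'
#' Pure boolean function of the five flags; vectorised over respondents.
#' "Plus" in the algorithm descriptions is set union (OR) of case-defining
#' clauses and "currently treated" binds as a conjunction to its preceding
#' clause. Algorithm 7 ("historical or current diagnosis") excludes
#' symptom history; algorithm 8 adds it.
#'
#' @param algo integer algorithm id in 1..12 (see
#'   [algorithm_descriptions]).
#' @param flags data frame or list with logical elements `current_dx`,
#'   `current_sx`, `historical_dx`, `historical_sx`, `current_treatment`.
#' @return logical vector of case labels.
#' @export
#' @examples
#' f <- list(current_dx = FALSE, current_sx = FALSE, historical_dx = TRUE,
#'           historical_sx = FALSE, current_treatment = TRUE)
#' apply_algorithm(9, f)  # historical diagnosis currently treated: case
#' apply_algorithm(2, f)  # no current diagnosis: not a case
apply_algorithm <- function(algo, flags) {
  D <- flags$current_dx; S <- flags$current_sx
  H <- flags$historical_dx; Hs <- flags$historical_sx
  Tt <- flags$current_treatment
  switch(as.character(algo),
    "1" = Tt,
    "2" = D,
    "3" = D & Tt,
    "4" = D | S,
    "5" = (D | S) & Tt,
    "6" = Tt | D | S,
    "7" = (H | D) & Tt,
    "8" = (H | Hs | D | S) & Tt,
    "9" = (H & Tt) | D,
    "10" = (H & Tt) | D | S,
    "11" = ((H | Hs | D | S) & Tt) | D,
    "12" = ((H | Hs | D | S) & Tt) | D | S,
    stop("unknown algorithm id: ", algo, call. = FALSE)
  )
}

# Vectorised eligibility + flag computation for all respondents.
#' @noRd
respondent_flags <- function(patients, events, prescriptions, survey, lists) {
  resp <- survey
  resp$date <- as_date(resp$date)
  known <- resp$patient_id %in% patients$patient_id
  if (any(!known)) {
    message(sum(!known), " survey respondent(s) with no matching patient record excluded")
    resp <- resp[known, , drop = FALSE]
  }
  if (!nrow(resp)) {
    return(data.frame(patient_id = character(), wave = integer(),
                      survey_date = as.Date(character()),
                      win_start = as.Date(character()),
                      win_end = as.Date(character()),
                      current_dx = logical(), current_sx = logical(),
                      historical_dx = logical(), historical_sx = logical(),
                      current_treatment = logical()))
  }
  win <- current_window(resp$date)
  resp$survey_date <- resp$date
  resp$win_start <- win$start
  resp$win_end <- win$end

  # eligibility: age 18-74 and one merged spell covering the window
  byear <- patients$birth_year[match(resp$patient_id, patients$patient_id)]
  age <- as.integer(format(resp$date, "%Y")) - byear
  age_ok <- !is.na(age) & age >= 18L & age <= 74L
  sp <- merged_spells(patients)
  resp$rid <- seq_len(nrow(resp))
  cov <- merge(resp[c("rid", "patient_id", "win_start", "win_end")], sp,
               by = "patient_id")
  cov_ok <- cov$rid[cov$start <= cov$win_start & cov$end >= cov$win_end]
  eligible <- age_ok & resp$rid %in% cov_ok
  resp <- resp[eligible, , drop = FALSE]
  if (!nrow(resp)) {
    for (col in c("current_dx", "current_sx", "historical_dx",
                  "historical_sx", "current_treatment")) {
      resp[[col]] <- logical(0)
    }
    resp$rid <- NULL
    return(resp)
  }

  flag_join <- function(tab, keep, label) {
    # keep: logical marker per event row (already classified); returns,
    # per respondent, any() of each window condition
    out <- matrix(FALSE, nrow(resp), length(label),
                  dimnames = list(NULL, label))
    if (!nrow(tab)) return(out)
    m <- merge(resp[c("rid", "patient_id", "win_start", "win_end")], tab,
               by = "patient_id")
    if (!nrow(m)) return(out)
    rix <- match(m$rid, resp$rid)
    for (j in label) {
      hit <- switch(j,
        current = m$mark & m$date >= m$win_start & m$date <= m$win_end,
        historical = m$mark & m$date < m$win_start)
      out[, j] <- tabulate(rix[hit], nbins = nrow(resp)) > 0
    }
    out
  }

  cat <- classify_code(events$code, lists)
  ev <- data.frame(patient_id = events$patient_id,
                   date = as_date(events$date))[!is.na(cat), , drop = FALSE]
  cat <- cat[!is.na(cat)]
  ev_dx <- ev; ev_dx$mark <- is_diagnosis(cat, lists$diagnosis_categories)
  ev_sx <- ev; ev_sx$mark <- is_symptom(cat, lists$diagnosis_categories)
  dxf <- flag_join(ev_dx[ev_dx$mark, ], TRUE, c("current", "historical"))
  sxf <- flag_join(ev_sx[ev_sx$mark, ], TRUE, c("current", "historical"))
  rx <- data.frame(patient_id = prescriptions$patient_id,
                   date = as_date(prescriptions$date),
                   mark = !is.na(classify_drug(prescriptions$code, lists)))
  rxf <- flag_join(rx[rx$mark, ], TRUE, "current")

  resp$current_dx <- dxf[, "current"]
  resp$current_sx <- sxf[, "current"]
  resp$historical_dx <- dxf[, "historical"]
  resp$historical_sx <- sxf[, "historical"]
  resp$current_treatment <- rxf[, "current"]
  resp$rid <- NULL
  rownames(resp) <- NULL
  resp
}

#' Run case-finding over a cohort
#'
#' Applies eligibility (continuous registration over the current window,
#' age 18-74), computes the five feature flags for every eligible survey
#' respondent from the event and prescription streams, and evaluates the
#' requested algorithms. Respondents with no matching patient record are
#' reported and excluded; ineligible respondents are excluded silently.
#'
#' @param patients patients table (one row per registration spell):
#'   `patient_id,birth_year,sex,spell_start,spell_end,death_date`.
#' @param events clinical events table: `patient_id,date,code`.
#' @param prescriptions prescriptions table: `patient_id,date,code`.
#' @param survey survey table: `patient_id,wave,date` (item columns
#'   ignored here).
#' @param lists a `code_lists` object.
#' @param algorithms integer vector of algorithm ids, default all 12.
#' @return object of class `casefinding_result`: `labels` (long data frame
#'   `patient_id,wave,algorithm,case`) and `flags` (one row per eligible
#'   respondent with the window and the five feature flags).
#' @export
run_casefinding <- function(patients, events, prescriptions, survey, lists,
                            algorithms = 1:12) {
  if (!all(algorithms %in% 1:12)) {
    stop("unknown algorithm id(s): ",
         paste(setdiff(algorithms, 1:12), collapse = ", "), call. = FALSE)
  }
  flags <- respondent_flags(patients, events, prescriptions, survey, lists)
  labels <- if (nrow(flags)) {
    do.call(rbind, lapply(algorithms, function(a) {
      data.frame(patient_id = flags$patient_id, wave = flags$wave,
                 algorithm = a, case = apply_algorithm(a, flags))
    }))
  }
  if (is.null(labels)) {
    labels <- data.frame(patient_id = character(), wave = integer(),
                         algorithm = integer(), case = logical())
  }
  structure(list(labels = labels, flags = flags, algorithms = algorithms),
            class = "casefinding_result")
}

#' @export
print.casefinding_result <- function(x, ...) {
  cat("Case-finding over", nrow(x$flags), "eligible respondent-waves,",
      length(x$algorithms), "algorithm(s)\n")
  if (nrow(x$labels)) {
    tab <- stats::aggregate(case ~ algorithm, x$labels, sum)
    cat("identified cases by algorithm:\n")
    print(stats::setNames(tab$case, tab$algorithm))
  }
  invisible(x)
}
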
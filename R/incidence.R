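# Incidence and prevalence of recorded anxiety/depression. Annual rates
# are per 1000 person-years at risk (PYAR). The first 183 days after the
# start of a registration spell are excluded from both person-time and
# episode counting, so that retrospective recording of prevalent cases is
# not counted as incident; an episode is incident only when no event of
# the same series occurred in the 365 days strictly before it.

#' Days at risk contributed by one patient in one calendar year
#'
#' Registration spells are first merged into continuous runs (a same-day
#' or next-day practice transfer leaves no uncovered day and does not
#' restart the post-registration exclusion; any uncovered day starts a new
#' run). Per run: the at-risk interval starts at the later of 1 January of
#' the year and run start + 183 days, and ends at the earliest of run end,
#' death date and 31 December; the contribution is the (non-negative)
#' length of that closed interval in days, summed over runs. The
#' minimum-follow-up rule (patients with under 365 cumulative at-risk days
#' contribute nothing) is applied at cohort level by [annual_incidence()],
#' not here.
#'
#' @param patient data frame of the patient's spell rows
#'   (`spell_start,spell_end,death_date`).
#' @param year calendar year (integer).
#' @return integer number of days at risk in `year`.
#' @export
#' @examples
#' p <- data.frame(patient_id = "a", spell_start = "2000-06-01",
#'                 spell_end = NA, death_date = NA)
#' person_time(p, 2002)  # full year: 365
#' person_time(p, 2004)  # leap year: 366
person_time <- function(patient, year) {
  jan1 <- as.Date(sprintf("%d-01-01", year))
  dec31 <- as.Date(sprintf("%d-12-31", year))
  runs <- merged_spells(patient)
  at_start <- pmax(jan1, runs$start + 183)
  at_end <- pmin(runs$end, dec31)
  sum(pmax(0L, as.integer(at_end - at_start) + 1L))
}

# Person-time for every patient and year: data frame patient_id, year, days.
#' @noRd
person_time_table <- function(patients, years) {
  split_pat <- split(patients, patients$patient_id)
  do.call(rbind, lapply(names(split_pat), function(id) {
    p <- split_pat[[id]]
    data.frame(patient_id = id, year = years,
               days = vapply(years, function(y) person_time(p, y), 0))
  }))
}

# Map events to the requested series via the code lists. "either" pools
# diagnosis- and symptom-group events into one series (shared lookback).
#' @noRd
series_events <- function(events, lists, series) {
  cat <- classify_code(events$code, lists)
  keep <- switch(series,
    diagnosis = is_diagnosis(cat, lists$diagnosis_categories),
    symptom = is_symptom(cat, lists$diagnosis_categories),
    either = is_diagnosis(cat, lists$diagnosis_categories) |
      is_symptom(cat, lists$diagnosis_categories),
    stop("unknown series: ", series, call. = FALSE))
  data.frame(patient_id = events$patient_id,
             date = as_date(events$date))[keep, , drop = FALSE]
}

#' Incident episodes of recorded anxiety/depression
#'
#' An event opens a new episode when no event of the same series was
#' recorded in the `lookback_days` days strictly before it (the lookback
#' may use pre-study data) and the event does not fall within the first
#' 183 days of its registration spell. The "either" series pools
#' diagnosis- and symptom-group events, both for the event itself and for
#' its lookback.
#'
#' @param events events table `patient_id,date,code`.
#' @param lists a `code_lists` object.
#' @param series `"diagnosis"`, `"symptom"` or `"either"`.
#' @param patients patients table, used for the 183-day post-registration
#'   exclusion; `NULL` skips that exclusion.
#' @param lookback_days washout length, default 365.
#' @return data frame `patient_id,episode_date,series` of incident
#'   episodes.
#' @export
incident_episodes <- function(events, lists,
                              series = c("diagnosis", "symptom", "either"),
                              patients = NULL, lookback_days = 365) {
  series <- match.arg(series)
  ev <- series_events(events, lists, series)
  if (!nrow(ev)) {
    return(data.frame(patient_id = character(),
                      episode_date = as.Date(character()),
                      series = character()))
  }
  ev <- ev[order(ev$patient_id, ev$date), ]
  same_pat <- c(FALSE, ev$patient_id[-1] == ev$patient_id[-nrow(ev)])
  gap <- c(NA, as.integer(diff(ev$date)))
  # incident iff first event for the patient or the previous same-series
  # event is more than lookback_days before (strict window [d-365, d-1])
  incident <- !same_pat | gap > lookback_days
  ev <- ev[incident, , drop = FALSE]
  if (!is.null(patients) && nrow(ev)) {
    sp <- merged_spells(patients)
    m <- merge(ev, sp, by = "patient_id")
    settled <- m[m$date >= m$start + 183 & m$date <= m$end, ]
    key <- paste(ev$patient_id, ev$date)
    ev <- ev[key %in% paste(settled$patient_id, settled$date), , drop = FALSE]
  }
  data.frame(patient_id = ev$patient_id, episode_date = ev$date,
             series = rep(series, nrow(ev)), row.names = NULL)
}

#' Annual incidence per 1000 person-years at risk
#'
#' For each requested year and each series (diagnosis, symptom, either),
#' counts incident episodes among patients with at least one year's
#' follow-up (>= 365 cumulative at-risk days over the requested years;
#' patients below that contribute neither episodes nor person-time) and
#' divides by person-years at risk:
#' `rate = episodes / (days / 365.25) * 1000`, rounded to 1 decimal.
#'
#' @param patients patients table (one row per spell).
#' @param events events table `patient_id,date,code`.
#' @param lists a `code_lists` object.
#' @param years integer vector of target calendar years. Events may (and
#'   for a clean first year, should) extend at least one lookback year
#'   before `min(years)`.
#' @param lookback_days washout passed to [incident_episodes()].
#' @return data frame of class `incidence_table`:
#'   `year,series,episodes,pyar,rate_per_1000`; rows with zero
#'   person-time report `NA` rates.
#' @export
annual_incidence <- function(patients, events, lists, years,
                             lookback_days = 365) {
  pt <- person_time_table(patients, years)
  tot <- tapply(pt$days, pt$patient_id, sum)
  keep_ids <- names(tot)[tot >= 365]
  pt <- pt[pt$patient_id %in% keep_ids, , drop = FALSE]
  pyar_by_year <- tapply(pt$days, pt$year, sum) / 365.25

  out <- do.call(rbind, lapply(c("diagnosis", "symptom", "either"),
                               function(ser) {
    epi <- incident_episodes(events, lists, ser, patients = patients,
                             lookback_days = lookback_days)
    epi <- epi[epi$patient_id %in% keep_ids, , drop = FALSE]
    eyear <- as.integer(format(epi$episode_date, "%Y"))
    n <- vapply(years, function(y) sum(eyear == y), 0L)
    pyar <- as.numeric(pyar_by_year[as.character(years)])
    pyar[is.na(pyar)] <- 0
    data.frame(year = years, series = ser, episodes = n,
               pyar = round(pyar, 1),
               rate_per_1000 = ifelse(pyar > 0,
                                      round_half_up(n / pyar * 1000, 1),
                                      NA_real_))
  }))
  rownames(out) <- NULL
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' @export
print.incidence_table <- function(x, ...) {
  cat("Annual incidence per 1000 person-years at risk\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Period prevalence of recorded anxiety/depression
#'
#' Proportion of the continuously registered population (patients with one
#' merged registration spell covering the whole period, deaths included in
#' spell capping) with at least one diagnosis-group event -- optionally
#' also symptom-group events -- recorded during the period.
#'
#' @param patients patients table.
#' @param events events table.
#' @param lists a `code_lists` object.
#' @param period_start,period_end period bounds (`Date` or string).
#' @param include_symptoms also count symptom-group events, default
#'   `FALSE`.
#' @return list with `n_cases`, `n_population` and `prevalence_pct`
#'   (half-up rounded to 1 decimal).
#' @export
period_prevalence <- function(patients, events, lists, period_start,
                              period_end, include_symptoms = FALSE) {
  period_start <- as_date(period_start)
  period_end <- as_date(period_end)
  sp <- merged_spells(patients)
  denom_ids <- unique(sp$patient_id[sp$start <= period_start &
                                      sp$end >= period_end])
  if (!length(denom_ids)) stop("empty denominator population", call. = FALSE)
  ser <- if (include_symptoms) "either" else "diagnosis"
  ev <- series_events(events, lists, ser)
  ev <- ev[ev$date >= period_start & ev$date <= period_end, , drop = FALSE]
  num_ids <- intersect(unique(ev$patient_id), denom_ids)
  list(n_cases = length(num_ids), n_population = length(denom_ids),
       prevalence_pct = round_ratio(100 * length(num_ids),
                                    length(denom_ids), 1))
}
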
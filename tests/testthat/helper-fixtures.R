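# Shared fixtures and independent brute-force oracles.

fixture_lists <- example_code_lists()

# one diagnosis-group, one symptom-group and one drug code from the fixture
a_dx_code <- fixture_lists$clinical$code[
  fixture_lists$clinical$category == "depression_diagnosis"][1]
a_sx_code <- fixture_lists$clinical$code[
  fixture_lists$clinical$category == "depression_symptom"][1]
a_rx_code <- fixture_lists$drugs$code[1]

make_patient <- function(id = "p1", birth_year = 1960,
                         spell_start = "1995-01-01", spell_end = NA,
                         death_date = NA) {
  data.frame(patient_id = id, birth_year = birth_year, sex = "F",
             spell_start = as.Date(spell_start),
             spell_end = as.Date(spell_end),
             death_date = as.Date(death_date),
             comorbidities = "")
}

make_events <- function(id, dates, codes) {
  if (!length(dates)) {
    return(data.frame(patient_id = character(), date = as.Date(character()),
                      code = character()))
  }
  data.frame(patient_id = id, date = as.Date(dates), code = codes)
}

no_events <- make_events("x", character(), character())

# day-by-day person-time oracle: marks every covered calendar day from
# first registration to year end, detects continuous runs of coverage by
# run-length encoding, drops the first 183 days of each run, and counts
# what is left inside the target year
bf_person_time <- function(patient, year) {
  dec31 <- as.Date(sprintf("%d-12-31", year))
  if (min(patient$spell_start) > dec31) return(0L)
  days <- seq(min(patient$spell_start), dec31, by = "day")
  covered <- rep(FALSE, length(days))
  for (i in seq_len(nrow(patient))) {
    s <- patient$spell_start[i]
    e <- patient$spell_end[i]
    if (is.na(e)) e <- dec31
    if (!is.na(patient$death_date[i])) e <- min(e, patient$death_date[i])
    covered <- covered | (days >= s & days <= e)
  }
  at_risk <- rep(FALSE, length(days))
  r <- rle(covered)
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    run <- seq(pos[k], pos[k] + r$lengths[k] - 1L)
    at_risk[run[-seq_len(min(183L, length(run)))]] <- TRUE
  }
  sum(at_risk & format(days, "%Y") == as.character(year))
}

# brute-force feature flags: plain loops and date comparisons, no window
# helper reuse
bf_flags <- function(events, prescriptions, lists, survey_date) {
  survey_date <- as.Date(survey_date)
  lo <- survey_date - 182
  hi <- survey_date + 182
  dx_set <- lists$clinical$code[lists$clinical$category %in%
    c("anxiety_diagnosis", "mixed_anxiety_depression", "panic",
      "depression_diagnosis")]
  sx_set <- lists$clinical$code[lists$clinical$category %in%
    c("anxiety_symptom", "depression_symptom")]
  f <- c(current_dx = FALSE, current_sx = FALSE, historical_dx = FALSE,
         historical_sx = FALSE, current_treatment = FALSE)
  for (i in seq_len(nrow(events))) {
    d <- as.Date(events$date[i]); code <- events$code[i]
    if (code %in% dx_set) {
      if (d >= lo && d <= hi) f["current_dx"] <- TRUE
      if (d < lo) f["historical_dx"] <- TRUE
    }
    if (code %in% sx_set) {
      if (d >= lo && d <= hi) f["current_sx"] <- TRUE
      if (d < lo) f["historical_sx"] <- TRUE
    }
  }
  for (i in seq_len(nrow(prescriptions))) {
    d <- as.Date(prescriptions$date[i])
    if (prescriptions$code[i] %in% lists$drugs$code && d >= lo && d <= hi) {
      f["current_treatment"] <- TRUE
    }
  }
  f
}

# the 32 flag combinations in a fixed enumeration order (current_dx
# fastest), shared by the truth-table tests
all_flag_combos <- expand.grid(current_dx = c(FALSE, TRUE),
                               current_sx = c(FALSE, TRUE),
                               historical_dx = c(FALSE, TRUE),
                               historical_sx = c(FALSE, TRUE),
                               current_treatment = c(FALSE, TRUE))
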
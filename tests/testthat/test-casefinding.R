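test_that("the current window is a closed 365-day interval centred on the survey", {
  w <- current_window(as.Date("2008-07-01"))
  expect_equal(w$start, as.Date("2008-01-01"))
  expect_equal(w$end, as.Date("2008-12-30"))
  # day-count oracle over random dates
  set.seed(11)
  for (d in sample(seq(as.Date("2000-01-01"), as.Date("2009-12-31"), 1), 20)) {
    d <- as.Date(d, origin = "1970-01-01")
    w <- current_window(d)
    days <- seq(w$start, w$end, by = "day")
    expect_length(days, 365L)
    expect_equal(days[183], d)  # survey date at the midpoint
  }
  # boundary: the survey date itself is inside, day 183 beyond is not
  w <- current_window(as.Date("2005-06-15"))
  inside <- function(d) d >= w$start & d <= w$end
  expect_true(inside(as.Date("2005-06-15")))
  expect_true(inside(as.Date("2005-06-15") + 182))
  expect_false(inside(as.Date("2005-06-15") + 183))
  expect_false(inside(as.Date("2005-06-15") - 183))
})

test_that("eligibility requires a covering spell and age 18-74", {
  d <- as.Date("2008-07-01")
  expect_true(is_eligible(make_patient(), d))
  # spell starting inside the window breaks continuity
  expect_false(is_eligible(make_patient(spell_start = "2008-03-01"), d))
  # a one-day gap between spells inside the window breaks continuity
  gap <- rbind(make_patient(spell_start = "1995-01-01",
                            spell_end = "2008-05-01"),
               make_patient(spell_start = "2008-05-03"))
  expect_false(is_eligible(gap, d))
  # a same-day (or next-day) practice transfer does not
  transfer <- rbind(make_patient(spell_start = "1995-01-01",
                                 spell_end = "2008-05-01"),
                    make_patient(spell_start = "2008-05-02"))
  expect_true(is_eligible(transfer, d))
  # age bounds at the survey date
  expect_false(is_eligible(make_patient(birth_year = 2008 - 75), d))
  expect_true(is_eligible(make_patient(birth_year = 2008 - 74), d))
  expect_false(is_eligible(make_patient(birth_year = 2008 - 17), d))
  # death during the window truncates the spell
  expect_false(is_eligible(make_patient(death_date = "2008-10-01"), d))
})

test_that("feature flags follow the window arithmetic", {
  lists <- fixture_lists
  d <- as.Date("2008-07-01")
  w <- current_window(d)
  f0 <- compute_flags(no_events, no_events, lists, w)
  expect_false(any(f0))
  # one antidepressant prescription inside the window: treatment only
  f1 <- compute_flags(no_events, make_events("p1", d - 10, a_rx_code),
                      lists, w)
  expect_true(f1["current_treatment"])
  expect_false(any(f1[c("current_dx", "current_sx", "historical_dx",
                        "historical_sx")]))
  # diagnosis two years back plus a current prescription
  f2 <- compute_flags(make_events("p1", d - 730, a_dx_code),
                      make_events("p1", d + 100, a_rx_code), lists, w)
  expect_true(f2["historical_dx"])
  expect_true(f2["current_treatment"])
  expect_false(f2["current_dx"])
  # events after the window end are ignored entirely
  f3 <- compute_flags(make_events("p1", d + 183, a_dx_code), no_events,
                      lists, w)
  expect_false(any(f3))
  # unknown codes never raise a flag
  f4 <- compute_flags(make_events("p1", d, "XXXX."), no_events, lists, w)
  expect_false(any(f4))
})

test_that("feature flags agree with a brute-force scan on random cases", {
  set.seed(12)
  lists <- fixture_lists
  pool <- c(lists$clinical$code, "XXXX.", "YYYY.")
  for (i in 1:25) {
    d <- as.Date("2004-06-01") + sample(-500:500, 1)
    ev <- make_events("p1", d + sample(-900:250, 8, replace = TRUE),
                      sample(pool, 8, replace = TRUE))
    rx <- make_events("p1", d + sample(-400:250, 3, replace = TRUE),
                      sample(c(lists$drugs$code, "ZZZZ."), 3, replace = TRUE))
    expect_equal(compute_flags(ev, rx, lists, current_window(d)),
                 bf_flags(ev, rx, lists, d))
  }
})

test_that("algorithm evaluation distinguishes historical from current clauses", {
  f_all_false <- as.list(stats::setNames(rep(FALSE, 5),
    c("current_dx", "current_sx", "historical_dx", "historical_sx",
      "current_treatment")))
  for (a in 1:12) expect_false(apply_algorithm(a, f_all_false))
  # historical diagnosis currently treated: algorithm 9 yes, 2 no
  f <- f_all_false
  f$historical_dx <- TRUE
  f$current_treatment <- TRUE
  expect_true(apply_algorithm(9, f))
  expect_false(apply_algorithm(2, f))
  # historical symptom separates algorithms 7 and 8
  g <- f_all_false
  g$historical_sx <- TRUE
  g$current_treatment <- TRUE
  expect_false(apply_algorithm(7, g))
  expect_true(apply_algorithm(8, g))
  expect_error(apply_algorithm(13, f), "unknown algorithm")
})

test_that("algorithm case sets nest along the documented subset chains", {
  chains <- list(c(3, 2, 4), c(5, 4), c(1, 6), c(7, 8), c(9, 10, 12),
                 c(11, 12))
  out <- vapply(1:12, function(a) apply_algorithm(a, all_flag_combos),
                logical(nrow(all_flag_combos)))
  for (ch in chains) {
    for (k in seq_len(length(ch) - 1)) {
      expect_true(all(out[, ch[k]] <= out[, ch[k + 1]]),
                  label = sprintf("cases(%d) subset of cases(%d)",
                                  ch[k], ch[k + 1]))
    }
  }
})

test_that("case labels are invariant to event order", {
  set.seed(13)
  lists <- fixture_lists
  d <- as.Date("2006-03-10")
  ev <- make_events("p1", d + sample(-800:180, 10, replace = TRUE),
                    sample(lists$clinical$code, 10, replace = TRUE))
  rx <- make_events("p1", d + sample(-180:180, 4, replace = TRUE),
                    sample(lists$drugs$code, 4, replace = TRUE))
  w <- current_window(d)
  base <- compute_flags(ev, rx, lists, w)
  for (i in 1:5) {
    perm <- sample(nrow(ev))
    expect_equal(compute_flags(ev[perm, ], rx[sample(nrow(rx)), ], lists, w),
                 base)
  }
})

test_that("cohort case-finding matches the per-respondent flag oracle", {
  set.seed(14)
  cfg <- sim_config(n_patients = 120, seed = 901)
  pop <- generate_population(cfg)
  lists <- fixture_lists
  res <- run_casefinding(pop$patients, pop$events, pop$prescriptions,
                         pop$survey, lists)
  expect_gt(nrow(res$flags), 0)
  # independent route: loop respondents, recompute flags, apply algorithms
  for (i in sample(nrow(res$flags), 30)) {
    row <- res$flags[i, ]
    ev <- pop$events[pop$events$patient_id == row$patient_id, ]
    rx <- pop$prescriptions[pop$prescriptions$patient_id == row$patient_id, ]
    f <- bf_flags(ev, rx, lists, row$survey_date)
    expect_equal(unlist(row[names(f)]), f,
                 ignore_attr = TRUE)
    for (a in c(2, 9, 12)) {
      lab <- res$labels[res$labels$patient_id == row$patient_id &
                          res$labels$wave == row$wave &
                          res$labels$algorithm == a, "case"]
      expect_equal(lab, unname(apply_algorithm(a, as.list(f))))
    }
  }
})

test_that("degenerate cohorts are handled", {
  lists <- fixture_lists
  empty_survey <- data.frame(patient_id = character(), wave = integer(),
                             date = as.Date(character()))
  res <- run_casefinding(make_patient(), no_events, no_events, empty_survey,
                         lists)
  expect_equal(nrow(res$labels), 0L)
  # an eligible respondent with no events is a non-case everywhere
  survey <- data.frame(patient_id = "p1", wave = 1,
                       date = as.Date("2001-11-01"))
  res <- run_casefinding(make_patient(), no_events, no_events, survey, lists)
  expect_false(any(res$labels$case))
  expect_equal(nrow(res$labels), 12L)
  # a respondent with no patient record is reported and excluded
  survey2 <- rbind(survey, data.frame(patient_id = "ghost", wave = 1,
                                      date = as.Date("2001-11-01")))
  expect_message(
    res2 <- run_casefinding(make_patient(), no_events, no_events, survey2,
                            lists),
    "no matching patient")
  expect_equal(unique(res2$labels$patient_id), "p1")
  expect_error(run_casefinding(make_patient(), no_events, no_events, survey,
                               lists, algorithms = c(1, 13)),
               "unknown algorithm")
})
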
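test_that("person-time applies the six-month exclusion and censoring", {
  # registered throughout: full years, leap year included
  p <- make_patient(spell_start = "1995-06-01")
  expect_equal(person_time(p, 2002), 365L)
  expect_equal(person_time(p, 2004), 366L)
  # registration 2002-03-01: at risk from 2002-08-31 (183 days later)
  p2 <- make_patient(spell_start = "2002-03-01")
  expect_equal(as.Date("2002-03-01") + 183, as.Date("2002-08-31"))
  expect_equal(person_time(p2, 2002), bf_person_time(p2, 2002))
  expect_equal(person_time(p2, 2002),
               as.integer(as.Date("2002-12-31") - as.Date("2002-08-31")) + 1L)
  # death on 2 January with long-standing registration: two days
  p3 <- make_patient(death_date = "2003-01-02")
  expect_equal(person_time(p3, 2003), 2L)
  expect_equal(person_time(p3, 2003), bf_person_time(p3, 2003))
  # exclusion can swallow the whole year
  p4 <- make_patient(spell_start = "2002-10-01", spell_end = "2003-03-01")
  expect_equal(person_time(p4, 2002), 0L)
})

test_that("person-time equals day-by-day counting on random cohorts", {
  set.seed(21)
  years <- 2000:2004
  for (i in 1:40) {
    n_spells <- sample(1:3, 1)
    starts <- sort(as.Date("1998-01-01") + sample(0:2200, n_spells))
    ends <- starts + sample(50:1500, n_spells, replace = TRUE)
    ends[n_spells] <- if (runif(1) < 0.3) NA else ends[n_spells]
    death <- if (runif(1) < 0.2) starts[1] + sample(100:2500, 1) else NA
    p <- data.frame(patient_id = "p", birth_year = 1960, sex = "F",
                    spell_start = starts, spell_end = as.Date(ends),
                    death_date = as.Date(rep(death, n_spells)),
                    comorbidities = "")
    for (y in years) {
      expect_equal(person_time(p, y), bf_person_time(p, y),
                   label = sprintf("cohort %d year %d", i, y))
    }
  }
})

test_that("incident episodes respect the one-year lookback per series", {
  lists <- fixture_lists
  p <- make_patient(spell_start = "1998-01-01")
  # two same-series events 100 days apart: one episode
  ev <- make_events("p1", as.Date("2002-03-01") + c(0, 100), a_dx_code)
  expect_equal(nrow(incident_episodes(ev, lists, "diagnosis", p)), 1L)
  # 400 days apart: two episodes
  ev <- make_events("p1", as.Date("2002-03-01") + c(0, 400), a_dx_code)
  expect_equal(nrow(incident_episodes(ev, lists, "diagnosis", p)), 2L)
  # exactly 365 days: the second is inside the strict lookback window
  ev <- make_events("p1", as.Date("2002-03-01") + c(0, 365), a_dx_code)
  expect_equal(nrow(incident_episodes(ev, lists, "diagnosis", p)), 1L)
  ev <- make_events("p1", as.Date("2002-03-01") + c(0, 366), a_dx_code)
  expect_equal(nrow(incident_episodes(ev, lists, "diagnosis", p)), 2L)
  # a symptom 100 days after a diagnosis: incident as a symptom, not in
  # the pooled either series
  ev <- rbind(make_events("p1", "2002-03-01", a_dx_code),
              make_events("p1", "2002-06-09", a_sx_code))
  expect_equal(nrow(incident_episodes(ev, lists, "symptom", p)), 1L)
  either <- incident_episodes(ev, lists, "either", p)
  expect_equal(nrow(either), 1L)
  expect_equal(either$episode_date, as.Date("2002-03-01"))
  # events in the first 183 days of registration never open an episode
  p_new <- make_patient(spell_start = "2002-01-01")
  ev <- make_events("p1", "2002-03-01", a_dx_code)
  expect_equal(nrow(incident_episodes(ev, lists, "diagnosis", p_new)), 0L)
})

test_that("annual incidence rates follow the PYAR arithmetic", {
  lists <- fixture_lists
  p <- make_patient(spell_start = "1998-01-01")
  # one patient at risk all of 2002 with one incident diagnosis:
  # 1 / (365/365.25) * 1000 = 1000.7 per 1000 PYAR
  ev <- make_events("p1", "2002-06-01", a_dx_code)
  inc <- annual_incidence(p, ev, lists, 2002)
  dx_row <- inc[inc$series == "diagnosis", ]
  expect_equal(dx_row$episodes, 1L)
  expect_equal(dx_row$rate_per_1000, 1000.7)
  # zero events: all rates zero
  inc0 <- annual_incidence(p, no_events, lists, 2000:2002)
  expect_true(all(inc0$rate_per_1000 == 0))
  # patients with under a year's follow-up contribute nothing
  p_short <- make_patient(id = "p2", spell_start = "2002-01-01",
                          spell_end = "2002-12-31")
  inc_s <- annual_incidence(p_short, no_events, lists, 2002)
  expect_true(all(inc_s$pyar == 0))
})

test_that("incidence is invariant to event order and either <= dx + sx", {
  set.seed(22)
  cfg <- sim_config(n_patients = 150, mode = "event_stream", seed = 902)
  pop <- generate_population(cfg)
  lists <- fixture_lists
  inc <- annual_incidence(pop$patients, pop$events, lists, 2000:2009)
  perm <- pop$events[sample(nrow(pop$events)), ]
  expect_equal(annual_incidence(pop$patients, perm, lists, 2000:2009), inc)
  by_year <- split(inc, inc$year)
  for (b in by_year) {
    expect_lte(b$episodes[b$series == "either"],
               b$episodes[b$series == "diagnosis"] +
                 b$episodes[b$series == "symptom"])
  }
  # no patient has two same-series episodes under 365 days apart
  epi <- incident_episodes(pop$events, lists, "diagnosis", pop$patients)
  gaps <- unlist(tapply(as.integer(epi$episode_date), epi$patient_id,
                        function(d) diff(sort(d))))
  if (length(gaps)) expect_true(all(gaps > 365))
})

test_that("period prevalence counts the continuously registered", {
  lists <- fixture_lists
  p <- rbind(make_patient(id = "a", spell_start = "1999-01-01"),
             make_patient(id = "b", spell_start = "1999-01-01"),
             make_patient(id = "c", spell_start = "2003-01-01"))
  ev <- rbind(make_events("a", "2004-05-01", a_dx_code),
              make_events("c", "2004-05-01", a_dx_code),
              make_events("b", "2004-06-01", a_sx_code))
  pr <- period_prevalence(p, ev, lists, "2000-01-01", "2009-12-31")
  # c is not continuously registered; b has only a symptom code
  expect_equal(pr$n_population, 2L)
  expect_equal(pr$n_cases, 1L)
  expect_equal(pr$prevalence_pct, 50)
  pr2 <- period_prevalence(p, ev, lists, "2000-01-01", "2009-12-31",
                           include_symptoms = TRUE)
  expect_equal(pr2$n_cases, 2L)
  pr0 <- period_prevalence(p, no_events, lists, "2000-01-01", "2009-12-31")
  expect_equal(pr0$prevalence_pct, 0)
  expect_error(period_prevalence(p, ev, lists, "1980-01-01", "2009-12-31"),
               "empty denominator")
})
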
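# Synthetic primary-care cohort generator. Produces patients (registration
# spells, deaths, comorbidity flags), dated coded events, prescriptions and
# two-wave survey responses with a known latent CMD status, so every
# downstream stage of the pipeline is testable without access to real
# records. Two modes:
#  - "independent": recording flags are drawn independently given the
#    latent state and then materialised as dated events; admits closed-form
#    sensitivity/specificity oracles (see expected_flag_rates()).
#  - "event_stream": Poisson event streams over registration spells with a
#    calendar trend in symptom recording; exercises the windowing,
#    person-time and incident-episode date logic.

#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_population()].
#' Defaults describe a two-wave postal survey cohort (response dates about
#' seven years apart) linked to a decade of primary-care records: latent
#' CMD prevalence about 32% / 33% by wave; sparse current diagnosis
#' recording (5% given CMD) with more frequent historical diagnoses (30%)
#' and a high treatment rate given any recording (80%); low recording
#' rates in non-CMD respondents; and a rising calendar trend in symptom
#' recording with stable diagnosis recording.
#'
#' @param n_patients number of patients.
#' @param study_start,study_end study period bounds.
#' @param wave1_date,wave2_date nominal survey response dates; individual
#'   dates are jittered by up to `survey_date_jitter` days.
#' @param survey_date_jitter half-width (days) of the uniform jitter on
#'   response dates.
#' @param latent_prevalence_w1,latent_prevalence_w2 probability of latent
#'   CMD (true MHI-5 score at or below the cut-point) per wave.
#' @param p_current_dx_given_cmd,p_current_sx_given_cmd,p_historical_dx_given_cmd,p_historical_sx_given_cmd
#'   recording probabilities given latent CMD (independent mode).
#' @param p_dx_given_noncmd,p_sx_given_noncmd,p_historical_dx_given_noncmd,p_historical_sx_given_noncmd
#'   recording probabilities given no CMD.
#' @param p_treatment_given_recorded probability of a current-window
#'   prescription given any recording flag.
#' @param p_treatment_background prescription probability with no
#'   recording (e.g. hypnotics for unrelated indications).
#' @param symptom_trend per-calendar-year multiplier on the symptom
#'   recording rate (event-stream mode); diagnosis recording is stable.
#' @param base_dx_rate,base_sx_rate per-person-year Poisson rates of
#'   diagnosis / symptom events in the first study year (event-stream
#'   mode).
#' @param registration_churn annual deregistration probability
#'   (event-stream mode).
#' @param annual_death_prob annual death hazard (event-stream mode).
#' @param comorbidity_probs named probabilities of the
#'   `pain, chronic_disease, other_cmd, alcohol` flags given latent CMD at
#'   wave 1; non-CMD patients carry each flag at half that probability.
#' @param mode `"independent"` or `"event_stream"`.
#' @param seed integer RNG seed; required for reproducibility.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2800,
                       study_start = "2000-01-01",
                       study_end = "2009-12-31",
                       wave1_date = "2001-11-01",
                       wave2_date = "2008-11-01",
                       survey_date_jitter = 30,
                       latent_prevalence_w1 = 0.32,
                       latent_prevalence_w2 = 0.33,
                       p_current_dx_given_cmd = 0.05,
                       p_current_sx_given_cmd = 0.05,
                       p_historical_dx_given_cmd = 0.30,
                       p_historical_sx_given_cmd = 0.15,
                       p_dx_given_noncmd = 0.01,
                       p_sx_given_noncmd = 0.02,
                       p_historical_dx_given_noncmd = 0.04,
                       p_historical_sx_given_noncmd = 0.04,
                       p_treatment_given_recorded = 0.80,
                       p_treatment_background = 0.08,
                       symptom_trend = 1.14,
                       base_dx_rate = 0.0203,
                       base_sx_rate = 0.0065,
                       registration_churn = 0.05,
                       annual_death_prob = 0.01,
                       comorbidity_probs = c(pain = 0.71,
                                             chronic_disease = 0.50,
                                             other_cmd = 0.14,
                                             alcohol = 0.07),
                       mode = c("independent", "event_stream"),
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    study_start = as_date(study_start), study_end = as_date(study_end),
    wave1_date = as_date(wave1_date), wave2_date = as_date(wave2_date),
    survey_date_jitter = as.integer(survey_date_jitter),
    latent_prevalence_w1 = latent_prevalence_w1,
    latent_prevalence_w2 = latent_prevalence_w2,
    p_current_dx_given_cmd = p_current_dx_given_cmd,
    p_current_sx_given_cmd = p_current_sx_given_cmd,
    p_historical_dx_given_cmd = p_historical_dx_given_cmd,
    p_historical_sx_given_cmd = p_historical_sx_given_cmd,
    p_dx_given_noncmd = p_dx_given_noncmd,
    p_sx_given_noncmd = p_sx_given_noncmd,
    p_historical_dx_given_noncmd = p_historical_dx_given_noncmd,
    p_historical_sx_given_noncmd = p_historical_sx_given_noncmd,
    p_treatment_given_recorded = p_treatment_given_recorded,
    p_treatment_background = p_treatment_background,
    symptom_trend = symptom_trend,
    base_dx_rate = base_dx_rate, base_sx_rate = base_sx_rate,
    registration_churn = registration_churn,
    annual_death_prob = annual_death_prob,
    comorbidity_probs = comorbidity_probs,
    mode = match.arg(mode),
    seed = as.integer(seed)
  )
  probs <- c(cfg$latent_prevalence_w1, cfg$latent_prevalence_w2,
             cfg$p_current_dx_given_cmd, cfg$p_current_sx_given_cmd,
             cfg$p_historical_dx_given_cmd, cfg$p_historical_sx_given_cmd,
             cfg$p_dx_given_noncmd, cfg$p_sx_given_noncmd,
             cfg$p_historical_dx_given_noncmd, cfg$p_historical_sx_given_noncmd,
             cfg$p_treatment_given_recorded, cfg$p_treatment_background,
             cfg$registration_churn, cfg$annual_death_prob,
             cfg$comorbidity_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_patients <= 0L) stop("n_patients must be positive", call. = FALSE)
  if (cfg$study_start >= cfg$study_end) {
    stop("study_start must precede study_end", call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("seed is required", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Packaged representative code lists
#'
#' Loads the small, synthetic clinical and drug code lists shipped with
#' the package (Read-code-like strings, a few per category). These are
#' representative fixtures for testing, not a published extraction list.
#'
#' @return a `code_lists` object.
#' @export
example_code_lists <- function() {
  load_code_lists(
    system.file("extdata", "clinical_codes.csv", package = "cmdcasefind"),
    system.file("extdata", "drug_codes.csv", package = "cmdcasefind")
  )
}

# Draw 5 oriented MHI-5 items (each 1..5) with a fixed total: start at
# all-1 and distribute the remainder uniformly over items with headroom.
#' @noRd
compose_items <- function(totals) {
  t(vapply(totals, function(s) {
    it <- rep(1L, 5L)
    add <- s - 5L
    while (add > 0L) {
      cand <- which(it < 5L)
      i <- cand[sample.int(length(cand), 1L)]
      it[i] <- it[i] + 1L
      add <- add - 1L
    }
    it
  }, integer(5)))
}

# Oriented item totals consistent with the latent state under the 0-100
# transform: total <= 17 gives score <= 60 (case); total >= 18 gives
# score >= 65 (non-case).
#' @noRd
draw_item_totals <- function(latent) {
  n <- length(latent)
  tot <- integer(n)
  tot[latent] <- sample(5:17, sum(latent), replace = TRUE)
  tot[!latent] <- sample(18:25, sum(!latent), replace = TRUE)
  tot
}

#' @noRd
sample_codes <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]

#' Generate a synthetic cohort
#'
#' Deterministic for a fixed config (the config seed is set on entry).
#' In independent mode every patient holds one registration spell opening
#' two years before the study and responds to both survey waves; recording
#' flags are drawn independently given the latent state and materialised
#' as dated events (current events inside the respondent's one-year
#' window, historical events before the first wave's window, so a wave's
#' current flags are exactly the drawn flags). In event-stream mode
#' patients enter and leave registration (churn, deaths) and diagnosis /
#' symptom events arrive as Poisson streams, the symptom rate scaled by
#' `symptom_trend` per calendar year.
#'
#' MHI-5 items are drawn so the transformed score is at or below 60
#' exactly when the latent state is CMD, making the gold standard
#' consistent by construction. The `latent_cmd` column of the survey
#' table is generator-only truth: downstream stages must use the item
#' scores.
#'
#' @param config a `sim_config`.
#' @param lists a `code_lists` object to sample codes from; defaults to
#'   the packaged fixture lists.
#' @return list of class `synthetic_population` with data frames
#'   `patients`, `events`, `prescriptions`, `survey`.
#' @export
generate_population <- function(config, lists = example_code_lists()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  dx_codes <- lists$clinical$code[
    is_diagnosis(lists$clinical$category, lists$diagnosis_categories)]
  sx_codes <- lists$clinical$code[
    is_symptom(lists$clinical$category, lists$diagnosis_categories)]
  rx_codes <- lists$drugs$code

  patients <- data.frame(
    patient_id = ids,
    birth_year = sample(1930:1983, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    spell_start = config$study_start - 730,
    spell_end = as.Date(NA),
    death_date = as.Date(NA),
    comorbidities = ""
  )

  if (config$mode == "independent") {
    out <- generate_independent(config, patients, dx_codes, sx_codes, rx_codes)
  } else {
    out <- generate_event_stream(config, patients, dx_codes, sx_codes, rx_codes)
  }
  # comorbidity flags, conditional on wave-1 latent state
  w1 <- out$survey[out$survey$wave == 1, ]
  cmd1 <- stats::setNames(w1$latent_cmd, w1$patient_id)[out$patients$patient_id]
  cmd1[is.na(cmd1)] <- FALSE
  flags <- vapply(names(config$comorbidity_probs), function(f) {
    p <- ifelse(cmd1, config$comorbidity_probs[[f]],
                config$comorbidity_probs[[f]] / 2)
    stats::rbinom(length(p), 1, p) == 1
  }, logical(nrow(out$patients)))
  if (is.null(dim(flags))) {
    flags <- matrix(flags, nrow = 1,
                    dimnames = list(NULL, names(config$comorbidity_probs)))
  }
  out$patients$comorbidities <- apply(flags, 1, function(r) {
    paste(names(config$comorbidity_probs)[r], collapse = ";")
  })
  structure(out, class = "synthetic_population")
}

#' @noRd
generate_independent <- function(config, patients, dx_codes, sx_codes,
                                 rx_codes) {
  n <- nrow(patients)
  ids <- patients$patient_id
  events <- list(); rx <- list(); survey <- list()
  win1_start_min <- config$wave1_date - config$survey_date_jitter - 182
  jit <- config$survey_date_jitter
  for (w in 1:2) {
    prev <- if (w == 1) config$latent_prevalence_w1 else config$latent_prevalence_w2
    wave_date <- if (w == 1) config$wave1_date else config$wave2_date
    latent <- stats::rbinom(n, 1, prev) == 1
    sdate <- wave_date + sample(seq(-jit, jit), n, replace = TRUE)
    p_of <- function(p_cmd, p_non) ifelse(latent, p_cmd, p_non)
    D <- stats::rbinom(n, 1, p_of(config$p_current_dx_given_cmd,
                                  config$p_dx_given_noncmd)) == 1
    S <- stats::rbinom(n, 1, p_of(config$p_current_sx_given_cmd,
                                  config$p_sx_given_noncmd)) == 1
    H <- stats::rbinom(n, 1, p_of(config$p_historical_dx_given_cmd,
                                  config$p_historical_dx_given_noncmd)) == 1
    Hs <- stats::rbinom(n, 1, p_of(config$p_historical_sx_given_cmd,
                                   config$p_historical_sx_given_noncmd)) == 1
    recorded <- D | S | H | Hs
    Tt <- stats::rbinom(n, 1, ifelse(recorded,
                                     config$p_treatment_given_recorded,
                                     config$p_treatment_background)) == 1

    mk_current <- function(sel, pool) {
      m <- sum(sel)
      if (!m) return(NULL)
      data.frame(patient_id = ids[sel],
                 date = sdate[sel] + sample(seq(-182, 182), m, replace = TRUE),
                 code = sample_codes(pool, m))
    }
    # historical events sit before the earliest wave-1 window so they can
    # never leak into any wave's current window
    mk_hist <- function(sel, pool) {
      m <- sum(sel)
      if (!m) return(NULL)
      span <- as.integer(win1_start_min - 1 - patients$spell_start[1])
      data.frame(patient_id = ids[sel],
                 date = patients$spell_start[1] +
                   sample.int(span, m, replace = TRUE) - 1,
                 code = sample_codes(pool, m))
    }
    events <- c(events, list(
      mk_current(D, dx_codes), mk_current(S, sx_codes),
      mk_hist(H, dx_codes), mk_hist(Hs, sx_codes)))
    if (any(Tt)) {
      rx <- c(rx, list(data.frame(
        patient_id = ids[Tt],
        date = sdate[Tt] + sample(seq(-182, 182), sum(Tt), replace = TRUE),
        code = sample_codes(rx_codes, sum(Tt)))))
    }
    raw <- compose_items(draw_item_totals(latent))
    raw <- sweep_orientation(raw, mhi5_reverse_default)
    survey[[w]] <- data.frame(patient_id = ids, wave = w, date = sdate,
                              mhi1 = raw[, 1], mhi2 = raw[, 2],
                              mhi3 = raw[, 3], mhi4 = raw[, 4],
                              mhi5 = raw[, 5], latent_cmd = latent)
  }
  list(patients = patients,
       events = bind_events(events),
       prescriptions = bind_events(rx),
       survey = do.call(rbind, survey))
}

#' @noRd
generate_event_stream <- function(config, patients, dx_codes, sx_codes,
                                  rx_codes) {
  n <- nrow(patients)
  ids <- patients$patient_id
  # staggered entry: most patients registered before the study opens (the
  # lookback year), the rest joining during it
  pre <- stats::runif(n) < 0.7
  entry_span <- as.integer(config$study_end - config$study_start) - 365L
  patients$spell_start <- config$study_start - 365 +
    ifelse(pre, 0L, sample.int(entry_span, n, replace = TRUE))
  # churn: geometric registration length; death: exponential hazard
  dur_years <- stats::rgeom(n, max(config$registration_churn, 1e-9)) + 1L
  dur_days <- dur_years * 365L + sample.int(365L, n, replace = TRUE)
  spell_end <- patients$spell_start + dur_days
  death_off <- stats::rexp(n, config$annual_death_prob / 365.25)
  death <- patients$spell_start + round(death_off)
  has_death <- death <= spell_end & death <= config$study_end
  patients$death_date <- as.Date(ifelse(has_death, death, NA),
                                 origin = "1970-01-01")
  spell_end <- pmin(spell_end, death)
  open <- spell_end > config$study_end + 365
  patients$spell_end <- as.Date(ifelse(open, NA, spell_end),
                                origin = "1970-01-01")

  year0 <- as.integer(format(config$study_start, "%Y"))
  years <- (year0 - 1L):as.integer(format(config$study_end, "%Y"))
  ev <- list()
  for (y in years) {
    jan1 <- as.Date(sprintf("%d-01-01", y))
    dec31 <- as.Date(sprintf("%d-12-31", y))
    os <- pmax(jan1, patients$spell_start)
    oe <- pmin(dec31, spell_end)
    frac <- pmax(0, as.integer(oe - os) + 1L) / 365.25
    lam_dx <- config$base_dx_rate * frac
    lam_sx <- config$base_sx_rate * config$symptom_trend^(y - year0) * frac
    draw <- function(lam, pool) {
      k <- stats::rpois(n, lam)
      tot <- sum(k)
      if (!tot) return(NULL)
      i <- rep.int(seq_len(n), k)
      span <- pmax(1L, as.integer(oe[i] - os[i]) + 1L)
      data.frame(patient_id = ids[i],
                 date = os[i] + floor(stats::runif(tot) * span),
                 code = sample_codes(pool, tot))
    }
    ev <- c(ev, list(draw(lam_dx, dx_codes), draw(lam_sx, sx_codes)))
  }
  events <- bind_events(ev)
  # one prescription shortly after a treated diagnosis event
  dx_ev <- events[!is.na(match(events$code, dx_codes)), , drop = FALSE]
  treated <- stats::runif(nrow(dx_ev)) < config$p_treatment_given_recorded
  rx <- dx_ev[treated, , drop = FALSE]
  if (nrow(rx)) {
    rx$date <- rx$date + sample(0:14, nrow(rx), replace = TRUE)
    send <- spell_end[match(rx$patient_id, ids)]
    rx$date <- pmin(rx$date, send)
    rx$code <- sample_codes(rx_codes, nrow(rx))
  }

  # survey responses from patients registered around each wave date
  survey <- list()
  for (w in 1:2) {
    prev <- if (w == 1) config$latent_prevalence_w1 else config$latent_prevalence_w2
    wave_date <- if (w == 1) config$wave1_date else config$wave2_date
    sdate <- wave_date + sample(seq(-config$survey_date_jitter,
                                    config$survey_date_jitter),
                                n, replace = TRUE)
    covered <- patients$spell_start <= sdate - 182 & spell_end >= sdate + 182
    latent <- stats::rbinom(n, 1, prev) == 1
    raw <- compose_items(draw_item_totals(latent))
    raw <- sweep_orientation(raw, mhi5_reverse_default)
    survey[[w]] <- data.frame(patient_id = ids, wave = w, date = sdate,
                              mhi1 = raw[, 1], mhi2 = raw[, 2],
                              mhi3 = raw[, 3], mhi4 = raw[, 4],
                              mhi5 = raw[, 5],
                              latent_cmd = latent)[covered, , drop = FALSE]
  }
  list(patients = patients, events = events,
       prescriptions = if (nrow(rx)) rx else empty_events(),
       survey = do.call(rbind, survey))
}

#' @noRd
sweep_orientation <- function(oriented, reverse) {
  for (j in which(reverse)) oriented[, j] <- 6L - oriented[, j]
  oriented
}

#' @noRd
empty_events <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
             code = character())
}

#' @noRd
bind_events <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(empty_events())
  out <- do.call(rbind, lst)
  out <- out[order(out$patient_id, out$date, out$code), ]
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("Synthetic cohort:", length(unique(x$patients$patient_id)), "patients,",
      nrow(x$events), "clinical events,", nrow(x$prescriptions),
      "prescriptions,", nrow(x$survey), "survey responses\n")
  invisible(x)
}

#' Comorbidity flags as a logical table
#'
#' Expands the semicolon-separated `comorbidities` column of a patients
#' table into one logical column per flag.
#'
#' @param patients patients table.
#' @param flags flag names to extract.
#' @return data frame `patient_id` + one logical column per flag (one row
#'   per patient).
#' @export
comorbidity_table <- function(patients,
                              flags = c("pain", "chronic_disease",
                                        "other_cmd", "alcohol")) {
  pp <- patients[!duplicated(patients$patient_id), ]
  parts <- strsplit(pp$comorbidities %||% rep("", nrow(pp)), ";", fixed = TRUE)
  out <- data.frame(patient_id = pp$patient_id)
  for (f in flags) out[[f]] <- vapply(parts, function(p) f %in% p, logical(1))
  out
}

#' Closed-form accuracy of the current-window algorithms
#'
#' For a configuration in independent-flag mode, returns the exact
#' sensitivity and specificity implied by the recording probabilities for
#' the algorithms that depend only on current-window flags: 1 (treatment
#' only), 2 (current diagnosis) and 4 (current diagnosis or symptom).
#' Used as the oracle in parameter-recovery tests. Historical flags in a
#' generated event stream accumulate across waves, so algorithms using
#' them have no closed form here.
#'
#' @param config a `sim_config` with `mode = "independent"`.
#' @return data frame `algorithm,sensitivity,specificity`.
#' @export
expected_flag_rates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "independent") {
    stop("closed-form rates exist only in independent-flag mode",
         call. = FALSE)
  }
  p_any <- function(pd, ps, ph, phs) 1 - (1 - pd) * (1 - ps) * (1 - ph) * (1 - phs)
  p_t <- function(p_rec) p_rec * config$p_treatment_given_recorded +
    (1 - p_rec) * config$p_treatment_background
  rec_cmd <- p_any(config$p_current_dx_given_cmd, config$p_current_sx_given_cmd,
                   config$p_historical_dx_given_cmd,
                   config$p_historical_sx_given_cmd)
  rec_non <- p_any(config$p_dx_given_noncmd, config$p_sx_given_noncmd,
                   config$p_historical_dx_given_noncmd,
                   config$p_historical_sx_given_noncmd)
  data.frame(
    algorithm = c(1L, 2L, 4L),
    sensitivity = c(
      p_t(rec_cmd),
      config$p_current_dx_given_cmd,
      1 - (1 - config$p_current_dx_given_cmd) *
        (1 - config$p_current_sx_given_cmd)),
    specificity = c(
      1 - p_t(rec_non),
      1 - config$p_dx_given_noncmd,
      (1 - config$p_dx_given_noncmd) * (1 - config$p_sx_given_noncmd))
  )
}
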
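# Validation against the MHI-5 gold standard: 2x2 cross-tabulation,
# sensitivity / specificity / PPV with decimal half-up rounding, and
# characterisation of misclassified respondents.

#' Cross-tabulate predicted case labels against the gold standard
#'
#' @param gold logical vector of gold-standard case flags (no missing
#'   values; respondents with a missing MHI-5 score are excluded listwise
#'   before validation).
#' @param predicted logical vector of algorithm case labels, same length
#'   and respondent order as `gold`.
#' @return object of class `confusion_matrix` with integer counts
#'   `tp,fp,fn,tn`.
#' @export
#' @examples
#' confusion(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
#'           c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
confusion <- function(gold, predicted) {
  if (length(gold) != length(predicted)) {
    stop("gold and predicted label sets differ in size", call. = FALSE)
  }
  if (anyNA(gold) || anyNA(predicted)) {
    stop("missing labels: exclude respondents with missing gold standard first",
         call. = FALSE)
  }
  structure(
    list(tp = sum(gold & predicted), fp = sum(!gold & predicted),
         fn = sum(gold & !predicted), tn = sum(!gold & !predicted)),
    class = "confusion_matrix"
  )
}

#' Build a confusion matrix from raw counts
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return a `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("algorithm case", "algorithm non-case"),
                              c("gold case", "gold non-case")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and positive predictive value
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(fp+tn)`,
#' `ppv = tp/(tp+fp)`. Reported values are rounded half-up to 2 decimals
#' in exact integer arithmetic (so 764/800 = 0.955 reports as 0.96);
#' unrounded values are returned alongside. A zero denominator yields a
#' missing metric, never 0. `n_identified = tp + fp` with its percentage
#' of all respondents at 1 decimal.
#'
#' @param cm a `confusion_matrix`.
#' @return object of class `validation_metrics`: `sensitivity`,
#'   `specificity`, `ppv` (2 dp), their `*_raw` counterparts,
#'   `n_identified`, `identified_pct`, and the four counts.
#' @export
#' @examples
#' metrics(confusion_counts(tp = 115, fp = 36, fn = 280, tn = 764))
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  raw <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    sensitivity = round_ratio(cm$tp, cm$tp + cm$fn, 2),
    specificity = round_ratio(cm$tn, cm$fp + cm$tn, 2),
    ppv = round_ratio(cm$tp, cm$tp + cm$fp, 2),
    sensitivity_raw = raw(cm$tp, cm$tp + cm$fn),
    specificity_raw = raw(cm$tn, cm$fp + cm$tn),
    ppv_raw = raw(cm$tp, cm$tp + cm$fp),
    n_identified = cm$tp + cm$fp,
    identified_pct = round_ratio(100 * (cm$tp + cm$fp), n, 1),
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn
  ), class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.2f  specificity %.2f  PPV %s  identified %d (%.1f%%)\n",
    x$sensitivity, x$specificity,
    if (is.na(x$ppv)) "NA" else sprintf("%.2f", x$ppv),
    x$n_identified, x$identified_pct))
  invisible(x)
}

#' Per-algorithm, per-wave validation table
#'
#' Joins case-finding labels to scored survey responses (listwise dropping
#' respondents with a missing gold standard) and computes the validation
#' metrics for every algorithm x wave combination present.
#'
#' @param result a `casefinding_result` from [run_casefinding()], or its
#'   long `labels` data frame.
#' @param survey_scored survey table carrying `patient_id,wave,gold_case`
#'   (see [score_survey()]).
#' @return data frame of class `validation_table`, one row per algorithm x
#'   wave: counts, the three metrics (2 dp), and `n_identified` with
#'   `identified_pct`.
#' @export
validate_algorithms <- function(result, survey_scored) {
  labels <- if (inherits(result, "casefinding_result")) result$labels else result
  gold <- survey_scored[c("patient_id", "wave", "gold_case")]
  gold <- gold[!is.na(gold$gold_case), , drop = FALSE]
  m <- merge(labels, gold, by = c("patient_id", "wave"))
  combos <- unique(m[c("algorithm", "wave")])
  combos <- combos[order(combos$algorithm, combos$wave), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- m[m$algorithm == combos$algorithm[i] & m$wave == combos$wave[i], ]
    met <- metrics(confusion(sub$gold_case, sub$case))
    data.frame(algorithm = combos$algorithm[i], wave = combos$wave[i],
               tp = met$tp, fp = met$fp, fn = met$fn, tn = met$tn,
               sensitivity = met$sensitivity, specificity = met$specificity,
               ppv = met$ppv, n_identified = met$n_identified,
               identified_pct = met$identified_pct)
  }))
  if (is.null(out)) {
    out <- data.frame(algorithm = integer(), wave = integer(),
                      tp = integer(), fp = integer(), fn = integer(),
                      tn = integer(), sensitivity = numeric(),
                      specificity = numeric(), ppv = numeric(),
                      n_identified = integer(), identified_pct = numeric())
  }
  rownames(out) <- NULL
  class(out) <- c("validation_table", "data.frame")
  out
}

#' @export
print.validation_table <- function(x, ...) {
  cat("Validation against the MHI-5 gold standard\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Characterise misclassified respondents
#'
#' Among the false negatives of one algorithm (survey cases the algorithm
#' missed): the proportions currently treated without any diagnosis code
#' (current or historical), with current symptom codes, with historical
#' diagnosis codes but not currently treated, and with no recorded
#' attendance (no classified event or treatment prescription in the
#' current window), plus the proportion carrying each comorbidity flag.
#' Among the false positives: the proportions with a historical diagnosis
#' and currently treated. Percentages half-up rounded to 1 decimal.
#'
#' @param flags respondent flag table (the `flags` element of a
#'   `casefinding_result`) restricted to one wave, carrying
#'   `patient_id,wave` and the five feature flags.
#' @param gold logical gold-standard flags aligned with `flags` rows.
#' @param predicted logical algorithm labels aligned with `flags` rows.
#' @param comorbidities optional data frame `patient_id` + logical columns
#'   (e.g. `pain,chronic_disease,other_cmd,alcohol`).
#' @return list with data frames `false_negatives` and `false_positives`
#'   (`feature,n,pct`), plus counts `n_fn`, `n_fp`.
#' @export
characterize_misclassified <- function(flags, gold, predicted,
                                       comorbidities = NULL) {
  stopifnot(nrow(flags) == length(gold), length(gold) == length(predicted))
  fn <- which(gold & !predicted)
  fp <- which(!gold & predicted)
  pct_row <- function(feature, hits, n) {
    data.frame(feature = feature, n = sum(hits),
               pct = round_ratio(100 * sum(hits), n, 1))
  }
  fn_tab <- if (length(fn)) {
    f <- flags[fn, , drop = FALSE]
    no_dx <- !f$current_dx & !f$historical_dx
    rows <- rbind(
      pct_row("treated_no_diagnosis_codes", f$current_treatment & no_dx,
              length(fn)),
      pct_row("current_symptom_codes", f$current_sx, length(fn)),
      pct_row("historical_diagnosis_untreated",
              f$historical_dx & !f$current_treatment, length(fn)),
      pct_row("no_attendance",
              !f$current_dx & !f$current_sx & !f$current_treatment &
                !f$historical_dx & !f$historical_sx, length(fn))
    )
    if (!is.null(comorbidities)) {
      cm <- comorbidities[match(f$patient_id, comorbidities$patient_id), ,
                          drop = FALSE]
      for (col in setdiff(names(comorbidities), "patient_id")) {
        rows <- rbind(rows, pct_row(paste0("comorbid_", col),
                                    cm[[col]] %in% TRUE, length(fn)))
      }
    }
    rows
  } else {
    data.frame(feature = character(), n = integer(), pct = numeric())
  }
  fp_tab <- if (length(fp)) {
    f <- flags[fp, , drop = FALSE]
    rbind(pct_row("historical_diagnosis", f$historical_dx, length(fp)),
          pct_row("currently_treated", f$current_treatment, length(fp)))
  } else {
    data.frame(feature = character(), n = integer(), pct = numeric())
  }
  list(false_negatives = fn_tab, false_positives = fp_tab,
       n_fn = length(fn), n_fp = length(fp))
}
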
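# MHI-5 scoring: the five-item Mental Health Inventory subscale of the
# SF-36, transformed to 0-100 (lower = poorer mental health), with
# half-scale person-mean imputation and a case cut-point (default <=60).

#' Default item orientation for the MHI-5
#'
#' `TRUE` marks a positively worded item ("calm and peaceful", "happy":
#' items 3 and 5 in the usual ordering) whose raw 1..5 response must be
#' reversed (`6 - x`) so that, after orientation, higher always means
#' better mental health. SF-36 v2 item coding varies between
#' distributions, so the map is configuration, not a constant.
#'
#' @format logical vector of length 5.
#' @export
mhi5_reverse_default <- c(FALSE, FALSE, TRUE, FALSE, TRUE)

#' Score one MHI-5 response
#'
#' Orients the five raw items so higher = better, imputes up to two missing
#' items with the person-mean of the present oriented items (the half-scale
#' rule: at least 3 of 5 items must be present), and linearly transforms the
#' oriented sum to 0-100: `score = (sum - 5) / 20 * 100`. With more than two
#' items missing the score, and hence the case classification, is missing.
#'
#' @param items numeric vector of 5 raw responses in 1..5; `NA` allowed.
#' @param reverse logical vector of length 5 marking items to reverse.
#' @return a list of class `mhi5_result`: `raw_items`, `oriented` (with
#'   imputed values), `n_missing`, `score` (0-100 or `NA`).
#' @export
#' @examples
#' score_mhi5(c(5, 5, 1, 5, 1))$score  # best possible mental health: 100
#' score_mhi5(c(3, 3, 3, NA, 3), reverse = rep(FALSE, 5))$score  # imputed: 50
score_mhi5 <- function(items, reverse = mhi5_reverse_default) {
  if (length(items) != 5L) stop("MHI-5 requires exactly 5 items", call. = FALSE)
  stopifnot(length(reverse) == 5L, is.logical(reverse))
  ok <- is.na(items) | (items >= 1 & items <= 5)
  if (!all(ok)) {
    stop("item response outside 1..5 at position ", which(!ok)[1],
         call. = FALSE)
  }
  oriented <- ifelse(reverse, 6 - items, items)
  n_missing <- sum(is.na(oriented))
  if (n_missing <= 2L) {
    if (n_missing > 0L) {
      oriented[is.na(oriented)] <- mean(oriented, na.rm = TRUE)
    }
    score <- (sum(oriented) - 5) / 20 * 100
  } else {
    score <- NA_real_
  }
  structure(
    list(raw_items = items, oriented = oriented,
         n_missing = n_missing, score = score),
    class = "mhi5_result"
  )
}

#' @export
print.mhi5_result <- function(x, ...) {
  cat("MHI-5: score",
      if (is.na(x$score)) "missing (>2 items missing)"
      else format(x$score, digits = 4),
      sprintf("(%d item%s imputed)\n", x$n_missing,
              if (x$n_missing == 1) "" else "s"))
  invisible(x)
}

#' Classify gold-standard CMD cases from MHI-5 scores
#'
#' A respondent is a gold-standard case of common mental disorder when
#' their MHI-5 score is at or below the cut-point (boundary inclusive:
#' a score of exactly 60 is a case at the default cut-point). Scores are
#' compared at full floating precision. Missing scores give a missing
#' classification; such respondents are excluded from validation.
#'
#' @param score numeric vector of MHI-5 scores in \[0, 100\].
#' @param cutpoint case threshold, default 60.
#' @return logical vector, `NA` where `score` is `NA`.
#' @export
classify_case <- function(score, cutpoint = 60) {
  stopifnot(length(cutpoint) == 1L, cutpoint >= 0, cutpoint <= 100)
  score <= cutpoint
}

#' Score a survey table
#'
#' Vectorised scoring of a survey data frame with item columns
#' `mhi1..mhi5`; appends `mhi5_score` and `gold_case`.
#'
#' @param survey data frame with columns `mhi1`..`mhi5` (and typically
#'   `patient_id`, `wave`, `date`).
#' @param reverse per-item reversal map, as in [score_mhi5()].
#' @param cutpoint case threshold passed to [classify_case()].
#' @return `survey` with `mhi5_score` and `gold_case` columns appended.
#' @export
score_survey <- function(survey, reverse = mhi5_reverse_default,
                         cutpoint = 60) {
  cols <- paste0("mhi", 1:5)
  if (!all(cols %in% names(survey))) {
    stop("survey table must have columns ", paste(cols, collapse = ","),
         call. = FALSE)
  }
  m <- as.matrix(survey[cols])
  if (any(m < 1 | m > 5, na.rm = TRUE)) {
    stop("item responses outside 1..5 in survey table", call. = FALSE)
  }
  m <- sweep(m, 2, ifelse(reverse, 1, 0), function(x, r) ifelse(r == 1, 6 - x, x))
  n_missing <- rowSums(is.na(m))
  person_mean <- rowMeans(m, na.rm = TRUE)
  imputed <- m
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) imputed[idx] <- person_mean[idx[, 1]]
  score <- (rowSums(imputed) - 5) / 20 * 100
  score[n_missing > 2] <- NA_real_
  survey$mhi5_score <- score
  survey$gold_case <- classify_case(score, cutpoint)
  survey
}
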
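# Code lists: classification of clinical and drug codes into the semantic
# categories that drive case-finding and incidence. Matching is exact string
# equality against the loaded list -- no hierarchical prefix expansion of the
# Read code tree; the lists themselves are the inputs.

#' Clinical recording categories
#'
#' The six recording categories for anxiety and depression: diagnoses and
#' symptoms for each condition, plus mixed anxiety-depression and panic.
#' Codes for phobias, OCD, PTSD, psychoses, behavioural and adjustment
#' disorders are deliberately outside the closed set.
#'
#' @format character vector of length 6.
#' @export
clinical_categories <- c(
  "anxiety_diagnosis", "anxiety_symptom", "mixed_anxiety_depression",
  "panic", "depression_diagnosis", "depression_symptom"
)

#' Default diagnosis-group categories
#'
#' Categories counted as "diagnosis" when splitting recorded codes into
#' diagnosis vs symptom groups. Mixed anxiety-depression and panic are
#' classed with the diagnoses; the grouping is configurable via the
#' `diagnosis_categories` argument of [load_code_lists()].
#'
#' @format character vector.
#' @export
diagnosis_group_default <- c(
  "anxiety_diagnosis", "mixed_anxiety_depression",
  "panic", "depression_diagnosis"
)

#' Drug classes counted as CMD treatment
#' @format character vector of length 3.
#' @export
drug_classes <- c("antidepressant", "anxiolytic", "hypnotic")

#' Load and validate clinical and drug code lists
#'
#' Reads a clinical code list (columns `code,description,category`) and a
#' drug code list (columns `code,drug_class`) from CSV, validating that
#' every code is non-empty and unique within its list and every category /
#' drug class belongs to its closed set. Validation failures report the
#' offending row number.
#'
#' @param clinical_path path to the clinical code list CSV.
#' @param drug_path path to the drug code list CSV.
#' @param diagnosis_categories categories forming the diagnosis group; the
#'   remaining clinical categories form the symptom group.
#' @return an object of class `code_lists` with elements `clinical`
#'   (data frame `code,description,category`), `drugs` (data frame
#'   `code,drug_class`) and `diagnosis_categories`.
#' @export
#' @examples
#' cl <- system.file("extdata", "clinical_codes.csv", package = "cmdcasefind")
#' dr <- system.file("extdata", "drug_codes.csv", package = "cmdcasefind")
#' lists <- load_code_lists(cl, dr)
#' lists
load_code_lists <- function(clinical_path, drug_path,
                            diagnosis_categories = diagnosis_group_default) {
  for (p in c(clinical_path, drug_path)) {
    if (!file.exists(p)) stop("code list file not found: ", p, call. = FALSE)
  }
  clinical <- utils::read.csv(clinical_path, colClasses = "character")
  need <- c("code", "description", "category")
  if (!all(need %in% names(clinical))) {
    stop("clinical code list must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  clinical <- clinical[need]
  check_codes(clinical$code, clinical_path)
  bad <- which(!clinical$category %in% clinical_categories)
  if (length(bad)) {
    stop(sprintf("unknown category '%s' at row %d of %s",
                 clinical$category[bad[1]], bad[1], clinical_path),
         call. = FALSE)
  }

  drugs <- utils::read.csv(drug_path, colClasses = "character")
  need <- c("code", "drug_class")
  if (!all(need %in% names(drugs))) {
    stop("drug code list must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  drugs <- drugs[need]
  check_codes(drugs$code, drug_path)
  bad <- which(!drugs$drug_class %in% drug_classes)
  if (length(bad)) {
    stop(sprintf("unknown drug_class '%s' at row %d of %s",
                 drugs$drug_class[bad[1]], bad[1], drug_path),
         call. = FALSE)
  }

  stopifnot(all(diagnosis_categories %in% clinical_categories))
  structure(
    list(clinical = clinical, drugs = drugs,
         diagnosis_categories = diagnosis_categories),
    class = "code_lists"
  )
}

#' @noRd
check_codes <- function(codes, path) {
  bad <- which(is.na(codes) | !nzchar(trimws(codes)))
  if (length(bad)) {
    stop(sprintf("empty code at row %d of %s", bad[1], path), call. = FALSE)
  }
  dup <- which(duplicated(codes))
  if (length(dup)) {
    stop(sprintf("duplicate code '%s' at row %d of %s",
                 codes[dup[1]], dup[1], path), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write code lists back to CSV
#'
#' Inverse of [load_code_lists()]; a load -> write -> load round trip
#' reproduces an identical `code_lists` value.
#'
#' @param lists a `code_lists` object.
#' @param clinical_path,drug_path output CSV paths.
#' @return invisibly, `lists`.
#' @export
write_code_lists <- function(lists, clinical_path, drug_path) {
  stopifnot(inherits(lists, "code_lists"))
  utils::write.csv(lists$clinical, clinical_path, row.names = FALSE)
  utils::write.csv(lists$drugs, drug_path, row.names = FALSE)
  invisible(lists)
}

#' Classify clinical codes
#'
#' Maps codes to their recording category by exact string match. Codes
#' absent from the list are not cases by design and map to `NA`.
#'
#' @param code character vector of codes.
#' @param lists a `code_lists` object.
#' @return character vector of categories, `NA` for unknown codes.
#' @export
classify_code <- function(code, lists) {
  stopifnot(inherits(lists, "code_lists"))
  lists$clinical$category[match(code, lists$clinical$code)]
}

#' Classify drug codes
#'
#' @param code character vector of prescription codes.
#' @param lists a `code_lists` object.
#' @return character vector of drug classes, `NA` for unknown codes.
#' @export
classify_drug <- function(code, lists) {
  stopifnot(inherits(lists, "code_lists"))
  lists$drugs$drug_class[match(code, lists$drugs$code)]
}

#' Diagnosis-group and symptom-group membership
#'
#' The six clinical categories partition into a diagnosis group (by default
#' anxiety/depression diagnoses, mixed anxiety-depression, panic) and a
#' symptom group (anxiety/depression symptoms). Every category belongs to
#' exactly one group; `NA` (unknown code) belongs to neither.
#'
#' @param category character vector of categories, as returned by
#'   [classify_code()].
#' @param diagnosis_categories categories forming the diagnosis group.
#' @return logical vector; `FALSE` for `NA` input.
#' @export
is_diagnosis <- function(category,
                         diagnosis_categories = diagnosis_group_default) {
  !is.na(category) & category %in% diagnosis_categories
}

#' @rdname is_diagnosis
#' @export
is_symptom <- function(category,
                       diagnosis_categories = diagnosis_group_default) {
  !is.na(category) & category %in% clinical_categories &
    !category %in% diagnosis_categories
}

#' @export
print.code_lists <- function(x, ...) {
  cat("Code lists:", nrow(x$clinical), "clinical codes,",
      nrow(x$drugs), "drug codes\n")
  cat("  clinical categories:",
      paste(sort(unique(x$clinical$category)), collapse = ", "), "\n")
  cat("  diagnosis group:",
      paste(x$diagnosis_categories, collapse = ", "), "\n")
  invisible(x)
}
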
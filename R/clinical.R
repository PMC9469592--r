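#' Decode a possibly censored age string
#'
#' Clinical age entries are either plain integers or boundary-coded
#' censored values of the form `"<=k"` (at most k years) or `">=k"`
#' (at least k years). Censored ages are carried at their boundary
#' value downstream, with the censoring flag preserved.
#'
#' @param raw Character vector of age strings.
#' @return A tibble with one row per input: `age` (integer, the
#'   boundary-coded value) and `age_censor` (`"none"`, `"at_most"` or
#'   `"at_least"`).
#' @export
#' @examples
#' code_age(c("66", "<=30", ">=80"))
code_age <- function(raw) {
  raw <- trimws(as.character(raw))
  censor <- dplyr::case_when(
    grepl("^<=\\s*[0-9]+$", raw) ~ "at_most",
    grepl("^>=\\s*[0-9]+$", raw) ~ "at_least",
    grepl("^[0-9]+$", raw) ~ "none",
    TRUE ~ NA_character_
  )
  if (anyNA(censor)) {
    bad <- raw[is.na(censor)]
    abort(paste0("unparseable age value(s): ", paste(unique(bad), collapse = ", ")))
  }
  value <- as.integer(gsub("[^0-9]", "", raw))
  if (any(value <= 0)) {
    abort("ages must be positive")
  }
  tibble::tibble(age = value, age_censor = censor)
}

#' Assign Oncotype DX DCIS risk groups from scores
#'
#' The Oncotype DX DCIS score (0-100) is stratified into the standard
#' three recurrence-risk groups: low (< 39), intermediate (39-54,
#' inclusive) and high (>= 55).
#'
#' @param dx_score Integer vector of Oncotype DX DCIS scores, 0-100.
#' @return A factor with levels `low`, `intermediate`, `high`.
#' @export
#' @examples
#' assign_risk_group(c(0, 33, 39, 54, 55, 78))
assign_risk_group <- function(dx_score) {
  if (any(is.na(dx_score))) abort("dx_score must not be missing")
  if (any(dx_score < 0)) abort("dx_score must be non-negative")
  if (any(dx_score > 100)) abort("dx_score must be at most 100")
  cut(dx_score,
    breaks = c(-Inf, 38.5, 54.5, Inf),
    labels = c("low", "intermediate", "high")
  )
}

risk_group_levels <- c("low", "intermediate", "high")

clinical_required_cols <- c(
  "patient_id", "dx_score", "age", "nuclear_grade",
  "follow_up_years", "treatment", "recurrence"
)

#' Read a DCIS clinical cohort table
#'
#' Parses a cohort CSV with one row per patient: identifier, Oncotype
#' DX DCIS score, age (integer or boundary-censored `"<=k"` / `">=k"`),
#' nuclear grade (`N1`/`N2`/`N3`, or missing), follow-up, treatment and
#' recurrence status. Censored ages are boundary-coded via
#' [code_age()] and risk groups are derived from the score via
#' [assign_risk_group()].
#'
#' @param path Path to the clinical CSV. The packaged 41-patient table
#'   is at `dcismir_example("dcis_cohort41.csv")`.
#' @return A tibble with columns `patient_id`, `dx_score`, `age`,
#'   `age_censor`, `nuclear_grade` (integer 1-3 or `NA`), `risk_group`
#'   (factor), `follow_up_years`, `treatment`, `recurrence`.
#' @export
#' @examples
#' clin <- read_clinical(dcismir_example("dcis_cohort41.csv"))
#' dplyr::count(clin, risk_group)
read_clinical <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character()
  )
  if (nrow(raw) == 0) abort("clinical table is empty")
  missing_cols <- setdiff(clinical_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "clinical table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad_score <- which(!grepl("^[0-9]+$", trimws(raw$dx_score)))
  if (length(bad_score) > 0) {
    abort(paste0(
      "non-numeric dx_score in row(s): ", paste(bad_score, collapse = ", "),
      " (patient ", paste(raw$patient_id[bad_score], collapse = ", "), ")"
    ))
  }
  if (anyDuplicated(raw$patient_id)) {
    abort("patient_id values must be unique")
  }
  ages <- code_age(raw$age)
  grade_chr <- trimws(raw$nuclear_grade)
  grade <- dplyr::case_when(
    grade_chr %in% c("N1", "N2", "N3") ~ match(grade_chr, c("N1", "N2", "N3")),
    grade_chr %in% c("", "NA", "-", "–") ~ NA_integer_,
    TRUE ~ -1L
  )
  if (any(grade == -1L, na.rm = TRUE)) {
    abort(paste0(
      "unrecognised nuclear_grade value(s): ",
      paste(unique(grade_chr[which(grade == -1L)]), collapse = ", ")
    ))
  }
  dx <- as.integer(raw$dx_score)
  tibble::tibble(
    patient_id = raw$patient_id,
    dx_score = dx,
    age = ages$age,
    age_censor = ages$age_censor,
    nuclear_grade = grade,
    risk_group = assign_risk_group(dx),
    follow_up_years = suppressWarnings(as.numeric(dplyr::na_if(trimws(raw$follow_up_years), "NA"))),
    treatment = dplyr::na_if(trimws(raw$treatment), "NA"),
    recurrence = dplyr::na_if(trimws(raw$recurrence), "NA")
  )
}

#' Count patients per risk group
#'
#' @param clinical A clinical tibble from [read_clinical()] (or any
#'   data frame with a `dx_score` or `risk_group` column).
#' @return A tibble with one row per risk group (`low`, `intermediate`,
#'   `high`, always all three) and a count `n`; counts sum to
#'   `nrow(clinical)`.
#' @export
#' @examples
#' clin <- read_clinical(dcismir_example("dcis_cohort41.csv"))
#' risk_group_counts(clin)
risk_group_counts <- function(clinical) {
  grp <- if ("risk_group" %in% names(clinical)) {
    factor(clinical$risk_group, levels = risk_group_levels)
  } else {
    assign_risk_group(clinical$dx_score)
  }
  tibble::tibble(
    risk_group = factor(risk_group_levels, levels = risk_group_levels),
    n = as.integer(table(grp)[risk_group_levels])
  )
}

#' Cohort age summaries
#'
#' Mean and median patient age, overall or stratified by risk group.
#' Censored ages enter at their boundary code (e.g. `"<=30"` as 30),
#' the only coding consistent with the cohort's reported group means.
#' Means are rounded to one decimal for reporting; medians are exact
#' (midpoint of the two central values for even n).
#'
#' @param clinical A clinical tibble from [read_clinical()].
#' @param by_group If `TRUE`, summarise per risk group as well as
#'   overall.
#' @return A tibble with columns `group`, `n`, `mean_age`,
#'   `median_age`. Empty groups yield `NA` summaries, not errors.
#' @export
#' @examples
#' clin <- read_clinical(dcismir_example("dcis_cohort41.csv"))
#' cohort_age_summary(clin, by_group = TRUE)
cohort_age_summary <- function(clinical, by_group = FALSE) {
  summarise_ages <- function(age) {
    tibble::tibble(
      n = length(age),
      mean_age = if (length(age)) round(mean(age), 1) else NA_real_,
      median_age = if (length(age)) median(age) else NA_real_
    )
  }
  overall <- dplyr::bind_cols(group = "overall", summarise_ages(clinical$age))
  if (!by_group) {
    return(overall)
  }
  grp <- factor(clinical$risk_group, levels = risk_group_levels)
  per_group <- purrr::map_dfr(risk_group_levels, function(g) {
    dplyr::bind_cols(group = g, summarise_ages(clinical$age[grp == g & !is.na(grp)]))
  })
  dplyr::bind_rows(overall, per_group)
}

#' Nuclear grade by risk group contingency analysis
#'
#' Cross-tabulates nuclear grade against Oncotype DX DCIS risk group
#' and tests independence with a Pearson chi-square test (no
#' continuity correction). Patients with missing grade are excluded
#' listwise. Optionally the intermediate and high groups are pooled
#' into a single column, the comparison under which grade and risk
#' group show a significant association in this cohort.
#'
#' @param clinical A clinical tibble from [read_clinical()].
#' @param collapse_int_high Pool intermediate + high into one column.
#' @return An object of class `dcis_contingency`: a list with
#'   `observed` (grade x group integer matrix), `statistic`, `df`,
#'   `p_value` and `n`. `tidy()` and `glance()` methods are provided.
#' @export
#' @examples
#' clin <- read_clinical(dcismir_example("dcis_cohort41.csv"))
#' grade_group_contingency(clin, collapse_int_high = TRUE)
grade_group_contingency <- function(clinical, collapse_int_high = FALSE) {
  keep <- !is.na(clinical$nuclear_grade)
  grade <- factor(paste0("N", clinical$nuclear_grade[keep]),
    levels = c("N1", "N2", "N3")
  )
  group <- factor(clinical$risk_group[keep], levels = risk_group_levels)
  tab <- table(grade, group)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (collapse_int_high) {
    tab <- cbind(
      low = tab[, "low"],
      int_high = tab[, "intermediate"] + tab[, "high"]
    )
  }
  res <- chi_sq_independence(unclass(tab))
  structure(
    list(
      observed = unclass(tab),
      statistic = res$statistic,
      df = res$df,
      p_value = res$p_value,
      n = sum(tab)
    ),
    class = "dcis_contingency"
  )
}

#' @export
print.dcis_contingency <- function(x, ...) {
  cat("Grade x risk-group contingency (Pearson chi-square, no correction)\n")
  print(x$observed)
  cat(sprintf(
    "X-squared = %.4f, df = %d, p = %.5g (n = %d)\n",
    x$statistic, x$df, x$p_value, x$n
  ))
  invisible(x)
}

#' @method tidy dcis_contingency
#' @export
tidy.dcis_contingency <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$observed),
    responseName = "count",
    stringsAsFactors = FALSE
  ))
}

#' @method glance dcis_contingency
#' @export
glance.dcis_contingency <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value, n = x$n
  )
}
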